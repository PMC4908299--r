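#' Freeze the slow variable of the analog model: the fast subsystem
#'
#' Burst analysis treats the slow variable `q` of the three-variable analog
#' model as a bifurcation parameter of its two-variable spike-generation
#' (fast) subsystem. `fast_subsystem()` returns that reduced model.
#'
#' @param model An [analog_sn()] model.
#' @param q The frozen slow-variable value (amps).
#' @return An object of class `c("analog_fast", "qsn_model")` with state
#'   variables `v`, `n`.
#' @export
fast_subsystem <- function(model, q) {
  stopifnot(inherits(model, "analog_sn"), is.finite(q))
  structure(list(base = model, q = q),
            class = c("analog_fast", "qsn_model"))
}

#' @rdname vector_field
#' @export
vector_field.analog_fast <- function(model, state, I_stim = 0, ...) {
  f <- vector_field(model$base,
                    c(v = state[["v"]], n = state[["n"]], q = model$q),
                    I_stim)
  f[c("v", "n")]
}

#' @rdname simulate_neuron
#' @export
simulate_neuron.analog_fast <- function(model, state0,
                                        stim = stimulus_protocol(),
                                        dt = 1e-5, T, v_bound = 10, ...) {
  frozen <- model$base
  frozen$tau_q <- 1e12     # q effectively constant over any run
  tr <- simulate_neuron(frozen,
                        c(v = state0[["v"]], n = state0[["n"]], q = model$q),
                        stim, dt = dt, T = T, v_bound = v_bound)
  tr$q <- NULL
  tr
}

# ---- internal model-generic hooks -----------------------------------------

# characteristic magnitude of the terms in the v equation, for residual
# normalisation
.model_scale <- function(model) UseMethod(".model_scale")
#' @noRd
.model_scale.analog_sn <- function(model)
  max(model$fm$M, model$g$S, model$fn$M, abs(model$I_a), 1e-12)
#' @noRd
.model_scale.analog_fast <- function(model) .model_scale(model$base)
#' @noRd
.model_scale.ulp_sn <- function(model)
  max(model$curve_v$M, ulp_r_plateau(model$theta_r, model$consts, model$I_0P),
      abs(model$I_av), 1e-13)
#' @noRd
.model_scale.dssn <- function(model) 1

# scalar equilibrium condition h(v) (all other state variables slaved to v)
# and its analytic derivative
.eq_fn <- function(model, I_stim) UseMethod(".eq_fn")
#' @noRd
.eq_fn.analog_fast <- function(model, I_stim) {
  b <- model$base; cs <- b$consts; q <- model$q
  list(
    h = function(v)
      sigmoid_current(b$fm, cs, v) - tanh_current(b$g, cs, v) -
        sigmoid_current(b$fn, cs, v) - q + b$I_a + I_stim,
    dh = function(v)
      .sigmoid_slope(b$fm, cs, v) - .tanh_slope(b$g, cs, v) -
        .sigmoid_slope(b$fn, cs, v))
}
#' @noRd
.eq_fn.analog_sn <- function(model, I_stim) {
  cs <- model$consts
  list(
    h = function(v)
      sigmoid_current(model$fm, cs, v) - tanh_current(model$g, cs, v) -
        sigmoid_current(model$fn, cs, v) - sigmoid_current(model$fq, cs, v) +
        model$I_a + I_stim,
    dh = function(v)
      .sigmoid_slope(model$fm, cs, v) - .tanh_slope(model$g, cs, v) -
        .sigmoid_slope(model$fn, cs, v) - .sigmoid_slope(model$fq, cs, v))
}
#' @noRd
.eq_fn.ulp_sn <- function(model, I_stim) {
  cs <- model$consts
  list(
    h = function(v)
      .ulp_f(model$curve_v, cs, v) - ulp_g(model$curve_v, cs, model$I_0P, v) +
        model$I_av + I_stim -
        (.ulp_f(model$curve_n, cs, v) - ulp_g(model$curve_n, cs, model$I_0P, v) +
           model$I_an),
    dh = function(v)
      .ulp_f_slope(model$curve_v, cs, v) -
        .ulp_g_slope(model$curve_v, cs, model$I_0P, v) -
        .ulp_f_slope(model$curve_n, cs, v) +
        .ulp_g_slope(model$curve_n, cs, model$I_0P, v))
}
#' @noRd
.eq_fn.dssn <- function(model, I_stim) {
  list(h = function(v) dssn_f(model, v) + model$I_0 + I_stim - dssn_g(model, v),
       dh = function(v) .dssn_f_slope(model, v) - .dssn_g_slope(model, v))
}

# full state at an equilibrium with membrane voltage v
.eq_state <- function(model, v, I_stim) UseMethod(".eq_state")
#' @noRd
.eq_state.analog_fast <- function(model, v, I_stim)
  c(v = v, n = sigmoid_current(model$base$fn, model$base$consts, v))
#' @noRd
.eq_state.analog_sn <- function(model, v, I_stim)
  c(v = v, n = sigmoid_current(model$fn, model$consts, v),
    q = sigmoid_current(model$fq, model$consts, v))
#' @noRd
.eq_state.ulp_sn <- function(model, v, I_stim) {
  cs <- model$consts
  rn <- .ulp_f(model$curve_n, cs, v) -
    ulp_g(model$curve_n, cs, model$I_0P, v) + model$I_an
  plateau <- ulp_r_plateau(model$theta_r, cs, model$I_0P)
  rn <- min(max(rn, plateau * 1e-12), plateau * (1 - 1e-12))
  c(v = v, n = ulp_r_inv(model$theta_r, cs, model$I_0P, rn))
}

# a root of the scalar condition is a genuine equilibrium only if the
# recovery current it requires lies inside the open range of r
.valid_eq_v <- function(model, v, I_stim) UseMethod(".valid_eq_v")
#' @noRd
.valid_eq_v.default <- function(model, v, I_stim) TRUE
#' @noRd
.valid_eq_v.ulp_sn <- function(model, v, I_stim) {
  cs <- model$consts
  rn <- .ulp_f(model$curve_n, cs, v) -
    ulp_g(model$curve_n, cs, model$I_0P, v) + model$I_an
  plateau <- ulp_r_plateau(model$theta_r, cs, model$I_0P)
  rn > 0 && rn < plateau
}
#' @noRd
.eq_state.dssn <- function(model, v, I_stim) c(v = v, n = dssn_g(model, v))

# default search interval for v
.default_v_range <- function(model) UseMethod(".default_v_range")
#' @noRd
.default_v_range.analog_fast <- function(model) .default_v_range(model$base)
#' @noRd
.default_v_range.analog_sn <- function(model) {
  centers <- c(model$fm$delta, model$fn$delta, model$fq$delta,
               model$g$theta_v)
  w <- 8 * model$consts$U_T / model$consts$kappa
  c(min(centers) - w, max(centers) + w)
}
#' @noRd
.default_v_range.ulp_sn <- function(model) {
  centers <- c(model$curve_v$delta, model$curve_v$theta,
               model$curve_n$delta, model$curve_n$theta)
  w <- 8 * model$consts$U_T / model$consts$kappa
  c(min(centers) - w, max(centers) + w)
}
#' @noRd
.default_v_range.dssn <- function(model) c(-3, 3)

#' Spike-detection threshold of a model
#'
#' The digital model defines a spike as `v` exceeding 0. The analog models
#' have no published threshold; presets carry a `spike_threshold` attribute
#' (chosen midway between the preset's resting potential and its observed
#' spike peak), and in its absence the midpoint voltage of the fast
#' activation curve is used.
#'
#' @param model A `qsn_model`.
#' @return Scalar threshold in the model's voltage unit.
#' @export
spike_threshold <- function(model) {
  th <- attr(model, "spike_threshold")
  if (!is.null(th)) return(th)
  if (inherits(model, "dssn")) return(0)
  if (inherits(model, "analog_fast")) return(spike_threshold(model$base))
  if (inherits(model, "analog_sn")) return(model$fm$delta)
  if (inherits(model, "ulp_sn")) return(model$curve_v$delta)
  stop("unknown model class")
}

#' Analytic Jacobian of a model at a state
#'
#' Exact partial derivatives of the model's vector field; agrees with
#' centered finite differences to better than 1e-6 relative.
#'
#' @param model A `qsn_model`.
#' @param state Named numeric state.
#' @param I_stim Stimulus value.
#' @return A square numeric matrix (2x2, or 3x3 for the full analog model).
#' @export
jacobian_at <- function(model, state, I_stim = 0) UseMethod("jacobian_at")

#' @export
jacobian_at.analog_fast <- function(model, state, I_stim = 0) {
  b <- model$base; cs <- b$consts; v <- state[["v"]]
  matrix(c((.sigmoid_slope(b$fm, cs, v) - .tanh_slope(b$g, cs, v)) / b$C_v,
           .sigmoid_slope(b$fn, cs, v) / b$tau_n,
           -1 / b$C_v,
           -1 / b$tau_n),
         2, 2, dimnames = list(c("v", "n"), c("v", "n")))
}

#' @export
jacobian_at.analog_sn <- function(model, state, I_stim = 0) {
  cs <- model$consts; v <- state[["v"]]
  J <- matrix(0, 3, 3, dimnames = list(c("v", "n", "q"), c("v", "n", "q")))
  J["v", "v"] <- (.sigmoid_slope(model$fm, cs, v) -
                    .tanh_slope(model$g, cs, v)) / model$C_v
  J["v", "n"] <- -1 / model$C_v
  J["v", "q"] <- -1 / model$C_v
  J["n", "v"] <- .sigmoid_slope(model$fn, cs, v) / model$tau_n
  J["n", "n"] <- -1 / model$tau_n
  J["q", "v"] <- .sigmoid_slope(model$fq, cs, v) / model$tau_q
  J["q", "q"] <- -1 / model$tau_q
  J
}

#' @export
jacobian_at.ulp_sn <- function(model, state, I_stim = 0) {
  cs <- model$consts; v <- state[["v"]]; n <- state[["n"]]
  rp <- ulp_r_prime(model$theta_r, cs, model$I_0P, n)
  matrix(c((.ulp_f_slope(model$curve_v, cs, v) -
              .ulp_g_slope(model$curve_v, cs, model$I_0P, v)) / model$C_v,
           (.ulp_f_slope(model$curve_n, cs, v) -
              .ulp_g_slope(model$curve_n, cs, model$I_0P, v)) / model$C_n,
           -rp / model$C_v,
           -rp / model$C_n),
         2, 2, dimnames = list(c("v", "n"), c("v", "n")))
}

#' @export
jacobian_at.dssn <- function(model, state, I_stim = 0) {
  v <- state[["v"]]
  matrix(c(model$phi / model$tau * .dssn_f_slope(model, v),
           .dssn_g_slope(model, v) / model$tau,
           -model$phi / model$tau,
           -1 / model$tau),
         2, 2, dimnames = list(c("v", "n"), c("v", "n")))
}

.classify_eigen <- function(ev, tol = 1e-9) {
  re <- Re(ev); im <- Im(ev)
  s <- max(abs(ev), 1e-300)
  complex_pair <- any(abs(im) > tol * s)
  if (any(re > tol * s) && any(re < -tol * s)) return("saddle")
  stable <- all(re < 0)
  if (complex_pair) {
    if (stable) "stable_focus" else "unstable_focus"
  } else {
    if (stable) "stable_node" else "unstable_node"
  }
}

#' Find and classify the equilibria of a model
#'
#' Roots of the scalar equilibrium condition in `v` (the remaining state
#' variables are slaved to `v` at equilibrium) are bracketed by sign changes
#' on a dense grid, refined by bisection and Newton polishing, and
#' classified by the eigenvalues of the analytic Jacobian. For the
#' three-variable analog model, pass `slow_value` to analyse the fast
#' subsystem with `q` frozen (the usual phase-plane view); with
#' `slow_value = NULL` the full three-variable equilibria are returned.
#'
#' @param model A `qsn_model`.
#' @param I_stim Stimulus value.
#' @param v_range Search interval for `v` (defaults to the model's curve
#'   support).
#' @param n_grid Grid resolution for sign-change bracketing.
#' @param slow_value Frozen `q` for the analog fast subsystem, or NULL.
#' @return A data frame of class `qsn_equilibria`: one row per equilibrium,
#'   ordered by `v`, with the state coordinates, eigenvalues
#'   (`eig1_re`, `eig1_im`, ...), `label` in stable_node / stable_focus /
#'   saddle / unstable_node / unstable_focus, and the vector-field
#'   `residual` relative to the model's current scale. May have zero rows.
#' @examples
#' m <- qsn_preset("dssn_class1")
#' find_equilibria(m)        # three equilibria: stable, saddle, unstable
#' @export
find_equilibria <- function(model, I_stim = 0, v_range = NULL,
                            n_grid = 2000L, slow_value = NULL) {
  if (!is.null(slow_value) && inherits(model, "analog_sn"))
    model <- fast_subsystem(model, slow_value)
  if (is.null(v_range)) v_range <- .default_v_range(model)
  fns <- .eq_fn(model, I_stim)
  vg <- seq(v_range[1], v_range[2], length.out = n_grid)
  hg <- fns$h(vg)
  sgn <- sign(hg)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  roots <- numeric()
  for (i in idx) {
    r <- stats::uniroot(fns$h, c(vg[i], vg[i + 1]),
                        tol = .Machine$double.eps^0.75)$root
    for (it in 1:8) {   # Newton polish to machine-precision residual
      d <- fns$dh(r)
      if (!is.finite(d) || d == 0) break
      step <- fns$h(r) / d
      r <- r - step
      if (abs(step) < 1e-16 * max(1, abs(r))) break
    }
    if (.valid_eq_v(model, r, I_stim)) roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (!length(roots)) {
    out <- data.frame(v = numeric())
    class(out) <- c("qsn_equilibria", "data.frame")
    return(out)
  }
  scale <- .model_scale(model)
  rows <- lapply(roots, function(r) {
    st <- .eq_state(model, r, I_stim)
    J <- jacobian_at(model, st, I_stim)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    resid <- abs(fns$h(r)) / scale
    row <- as.data.frame(as.list(st))
    for (k in seq_along(ev)) {
      row[[paste0("eig", k, "_re")]] <- Re(ev[k])
      row[[paste0("eig", k, "_im")]] <- Im(ev[k])
    }
    row$label <- .classify_eigen(ev)
    row$residual <- resid
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qsn_equilibria", "data.frame")
  out
}
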