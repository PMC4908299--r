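#' The digital spiking silicon neuron (DSSN) model
#'
#' A two-variable dimensionless model designed for digital arithmetic
#' circuits:
#' \deqn{\dot v = \frac{\phi}{\tau}(f(v) - n + I_0 + I_{stim}), \qquad
#'       \dot n = \frac{g(v) - n}{\tau},}
#' where `f` and `g` are piecewise quadratic, `a (v - b)^2 + c` on each
#' branch. `f` branches at `v = 0` and realizes the N-shaped v-nullcline
#' `n = f(v) + I_0` without variable-variable multiplications; `g` branches
#' at `v = r_g` and gives the n-nullcline `n = g(v)`. A spike is the time
#' when `v` exceeds 0. The model is solved by forward Euler, optionally in
#' emulated fixed-point arithmetic (see [fixed_point_format()]).
#'
#' Continuity of `f` at 0 and of `g` at `r_g` is checked at construction;
#' residuals beyond `continuity_tol` are an error.
#'
#' @param phi Dimensionless time-scale ratio between `v` and `n` (> 0).
#' @param tau Time constant in seconds (> 0).
#' @param I_0 Dimensionless bias.
#' @param a_fn,b_fn,c_fn Coefficients of `f` on `v < 0`.
#' @param a_fp,b_fp,c_fp Coefficients of `f` on `v >= 0`.
#' @param a_gn,b_gn,c_gn Coefficients of `g` on `v < r_g`.
#' @param a_gp,b_gp,c_gp Coefficients of `g` on `v >= r_g`.
#' @param r_g Breakpoint of `g`.
#' @param continuity_tol Maximum allowed branch-joint residual (default 1e-9).
#' @return An object of class `c("dssn", "qsn_model")`; the continuity
#'   residuals are stored in its `continuity` field.
#' @export
dssn <- function(phi, tau, I_0,
                 a_fn, b_fn, c_fn, a_fp, b_fp, c_fp,
                 a_gn, b_gn, c_gn, a_gp, b_gp, c_gp,
                 r_g, continuity_tol = 1e-9) {
  stopifnot(phi > 0, tau > 0)
  res_f <- abs((a_fn * b_fn^2 + c_fn) - (a_fp * b_fp^2 + c_fp))
  res_g <- abs((a_gn * (r_g - b_gn)^2 + c_gn) - (a_gp * (r_g - b_gp)^2 + c_gp))
  if (res_f > continuity_tol)
    stop(sprintf("f discontinuous at 0 (residual %.3g)", res_f))
  if (res_g > continuity_tol)
    stop(sprintf("g discontinuous at r_g (residual %.3g)", res_g))
  structure(list(phi = phi, tau = tau, I_0 = I_0,
                 a_fn = a_fn, b_fn = b_fn, c_fn = c_fn,
                 a_fp = a_fp, b_fp = b_fp, c_fp = c_fp,
                 a_gn = a_gn, b_gn = b_gn, c_gn = c_gn,
                 a_gp = a_gp, b_gp = b_gp, c_gp = c_gp,
                 r_g = r_g,
                 continuity = c(f = res_f, g = res_g)),
            class = c("dssn", "qsn_model"))
}

#' Piecewise-quadratic nullcline-shaping functions of the DSSN
#'
#' @param p A [dssn()] model.
#' @param v Numeric vector.
#' @return `dssn_f(p, v)` evaluates `a_fn (v-b_fn)^2 + c_fn` for `v < 0` and
#'   the `fp` branch otherwise; `dssn_g` branches at `r_g`.
#' @export
dssn_f <- function(p, v) {
  ifelse(v < 0,
         p$a_fn * (v - p$b_fn)^2 + p$c_fn,
         p$a_fp * (v - p$b_fp)^2 + p$c_fp)
}

#' @rdname dssn_f
#' @export
dssn_g <- function(p, v) {
  ifelse(v < p$r_g,
         p$a_gn * (v - p$b_gn)^2 + p$c_gn,
         p$a_gp * (v - p$b_gp)^2 + p$c_gp)
}

.dssn_f_slope <- function(p, v)
  ifelse(v < 0, 2 * p$a_fn * (v - p$b_fn), 2 * p$a_fp * (v - p$b_fp))

.dssn_g_slope <- function(p, v)
  ifelse(v < p$r_g, 2 * p$a_gn * (v - p$b_gn), 2 * p$a_gp * (v - p$b_gp))

#' @rdname vector_field
#' @export
vector_field.dssn <- function(model, state, I_stim = 0, ...) {
  v <- state[["v"]]; n <- state[["n"]]
  c(v = model$phi / model$tau * (dssn_f(model, v) - n + model$I_0 + I_stim),
    n = (dssn_g(model, v) - n) / model$tau)
}

#' Nullclines of the DSSN model
#' @param model A [dssn()] model.
#' @param v Numeric grid.
#' @param I_stim Dimensionless stimulus.
#' @return Data frame with `v`, `v_null = f(v) + I_0 + I_stim`,
#'   `n_null = g(v)`.
#' @export
dssn_nullclines <- function(model, v, I_stim = 0) {
  data.frame(v = v, v_null = dssn_f(model, v) + model$I_0 + I_stim,
             n_null = dssn_g(model, v))
}

#' Two's-complement fixed-point number format
#'
#' Describes the emulated arithmetic of the digital neuron: `total_bits`
#' two's-complement bits of which `frac_bits` are fractional, so the
#' representable range is `[-2^(total-frac-1), 2^(total-frac-1) - 2^-frac]`
#' on a grid of spacing `2^-frac`. `rounding` selects truncation (drop the
#' low bits, i.e. round toward minus infinity, as shift-based hardware does)
#' or round-to-nearest. On overflow the value either saturates at the range
#' limits or raises an error.
#'
#' @param total_bits Total word length (3..64).
#' @param frac_bits Fractional bits (2 <= frac_bits < total_bits).
#' @param rounding "truncate" or "nearest".
#' @param overflow "saturate" or "error".
#' @return An object of class `fixed_point_format`.
#' @examples
#' fmt <- fixed_point_format(18, 10)
#' quantize(0.625, fixed_point_format(8, 2))  # 0.5
#' @export
fixed_point_format <- function(total_bits = 18L, frac_bits = 10L,
                               rounding = c("truncate", "nearest"),
                               overflow = c("saturate", "error")) {
  rounding <- match.arg(rounding)
  overflow <- match.arg(overflow)
  total_bits <- as.integer(total_bits); frac_bits <- as.integer(frac_bits)
  stopifnot(frac_bits >= 2L, frac_bits < total_bits, total_bits <= 64L)
  structure(list(total_bits = total_bits, frac_bits = frac_bits,
                 rounding = rounding, overflow = overflow,
                 lo = -2^(total_bits - frac_bits - 1L),
                 hi = 2^(total_bits - frac_bits - 1L) - 2^(-frac_bits),
                 eps = 2^(-frac_bits)),
            class = "fixed_point_format")
}

#' Quantize values to a fixed-point format
#'
#' Idempotent and monotone: `quantize(quantize(x)) == quantize(x)` and
#' `x <= y` implies `quantize(x) <= quantize(y)`.
#'
#' @param x Finite numeric vector.
#' @param fmt A [fixed_point_format()].
#' @return Numeric vector of representable values.
#' @export
quantize <- function(x, fmt) {
  if (any(!is.finite(x))) stop("non-finite x")
  s <- x / fmt$eps
  q <- if (fmt$rounding == "truncate") floor(s) else floor(s + 0.5)
  q <- q * fmt$eps
  over <- q < fmt$lo | q > fmt$hi
  if (any(over)) {
    if (fmt$overflow == "error")
      stop(sprintf("fixed-point overflow: value %.6g outside [%g, %g]",
                   x[which(over)[1L]], fmt$lo, fmt$hi))
    q <- pmin(pmax(q, fmt$lo), fmt$hi)
  }
  q
}

.fmt_vec <- function(fmt) {
  if (is.null(fmt)) c(0, 0, 0, 0)   # double-precision mode
  else c(fmt$frac_bits, if (fmt$rounding == "truncate") 0 else 1,
         if (fmt$overflow == "saturate") 0 else 1,
         fmt$total_bits)
}

.dssn_param_vec <- function(model)
  c(model$phi, model$tau, model$I_0,
    model$a_fn, model$b_fn, model$c_fn, model$a_fp, model$b_fp, model$c_fp,
    model$a_gn, model$b_gn, model$c_gn, model$a_gp, model$b_gp, model$c_gp,
    model$r_g)

#' One forward-Euler step of the DSSN model
#'
#' With a fixed-point format every multiply and add result is quantized
#' (constant-times-variable products once, after the multiply, mirroring
#' shift-add hardware); without one the arithmetic is double precision. The
#' step constants `phi*dt/tau` and `dt/tau` are quantized once up front.
#'
#' @param model A [dssn()] model.
#' @param state Named numeric `c(v=, n=)`.
#' @param I_stim Dimensionless stimulus.
#' @param dt Step (seconds, > 0); the network default is 375 us.
#' @param fmt Optional [fixed_point_format()].
#' @return The next state, named like `state`.
#' @export
euler_step <- function(model, state, I_stim = 0, dt = 375e-6, fmt = NULL) {
  stopifnot(dt > 0)
  res <- dssn_euler_cpp(.dssn_param_vec(model),
                        c(state[["v"]], state[["n"]]),
                        numeric(), numeric(), c(I_stim), # constant stimulus
                        dt, 1L, 100, .fmt_vec(fmt), TRUE)
  c(v = res[2, 1], n = res[2, 2])
}

#' @rdname simulate_neuron
#' @param fmt Optional [fixed_point_format()] (DSSN only): emulate
#'   fixed-point forward Euler instead of double precision.
#' @export
simulate_neuron.dssn <- function(model, state0, stim = stimulus_protocol(),
                                 dt = 375e-6, T, v_bound = 100,
                                 fmt = NULL, ...) {
  .check_sim_args(dt, T)
  stim <- .as_stim(stim, T)
  n_steps <- as.integer(round(T / dt))
  res <- dssn_euler_cpp(.dssn_param_vec(model),
                        c(state0[["v"]], state0[["n"]]),
                        stim$start, stim$end, stim$amplitude,
                        dt, n_steps, v_bound, .fmt_vec(model_fmt <- fmt),
                        FALSE)
  .new_trajectory(dt * (0:n_steps), data.frame(v = res[, 1], n = res[, 2]),
                  model = model, dt = dt)
}

#' Spike times of a DSSN trajectory
#'
#' A spike is the time when `v` exceeds 0, linearly interpolated between
#' samples.
#'
#' @param traj A trajectory from [simulate_neuron()].
#' @return Strictly increasing numeric vector of spike times.
#' @export
dssn_spike_times <- function(traj) spike_times(traj, threshold = 0)
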