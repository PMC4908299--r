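#' Sigmoid and tanh V-I characteristic curves
#'
#' `sigmoid_spec()` describes the idealized differential-pair curve
#' \deqn{f_x(v) = M_x / (1 + \exp(-(\kappa/U_T)(v - \delta_x))),}
#' a saturating sigmoid with amplitude `M` (amps) and midpoint `delta`
#' (volts). `tanh_spec()` describes the transconductance-amplifier curve
#' \deqn{g(v) = S \tanh\!\big(\tfrac{\kappa}{2 U_T}\,(v - \theta_v)/(1 + 1/\kappa)\big),}
#' odd-symmetric about `theta_v` with saturation `S`; the `1 + 1/kappa`
#' divisor makes it shallower than the sigmoid, which is what lets their
#' difference be N-shaped.
#'
#' @param M,S Saturation currents in amps (non-negative).
#' @param delta,theta_v Midpoint voltages in volts.
#' @return Objects of class `sigmoid_spec` / `tanh_spec`.
#' @seealso [sigmoid_current()], [tanh_current()]
#' @export
sigmoid_spec <- function(M, delta) {
  stopifnot(is.finite(M), M >= 0, is.finite(delta))
  structure(list(M = M, delta = delta), class = "sigmoid_spec")
}

#' @rdname sigmoid_spec
#' @export
tanh_spec <- function(S, theta_v) {
  stopifnot(is.finite(S), S >= 0, is.finite(theta_v))
  structure(list(S = S, theta_v = theta_v), class = "tanh_spec")
}

#' Evaluate the differential-pair sigmoid current
#'
#' @param spec A [sigmoid_spec()].
#' @param consts [thermal_constants()].
#' @param v Voltage(s) in volts; must be finite.
#' @return Current(s) in amps, strictly increasing in `v`, in `(0, M)`.
#' @examples
#' f <- sigmoid_spec(M = 1e-9, delta = 0.3)
#' sigmoid_current(f, thermal_constants(), 0.3)  # M/2 at the midpoint
#' @export
sigmoid_current <- function(spec, consts, v) {
  if (any(!is.finite(v))) stop("non-finite v")
  spec$M * stats::plogis(.k_over_ut(consts) * (v - spec$delta))
}

# d f / d v, analytic
.sigmoid_slope <- function(spec, consts, v) {
  k <- .k_over_ut(consts)
  s <- stats::plogis(k * (v - spec$delta))
  spec$M * k * s * (1 - s)
}

#' Evaluate the transconductance-amplifier tanh current
#'
#' @inheritParams sigmoid_current
#' @param spec A [tanh_spec()].
#' @return Current(s) in amps, odd about `theta_v`, in `(-S, S)`.
#' @examples
#' g <- tanh_spec(S = 1e-9, theta_v = 0)
#' tanh_current(g, thermal_constants(), 0)  # 0 at the center
#' @export
tanh_current <- function(spec, consts, v) {
  if (any(!is.finite(v))) stop("non-finite v")
  a <- .k_over_ut(consts) * (v - spec$theta_v) /
    (1 + 1 / consts$kappa)
  spec$S * tanh(a / 2)
}

.tanh_slope <- function(spec, consts, v) {
  b <- .k_over_ut(consts) / (1 + 1 / consts$kappa) / 2
  a2 <- tanh(b * (v - spec$theta_v))
  spec$S * b * (1 - a2 * a2)
}

#' The three-variable analog silicon neuron model
#'
#' The ideal model of the configurable low-power analog silicon neuron:
#' \deqn{C_v \dot v = -g(v) + f_m(v) - n - q + I_a + I_{stim}}
#' \deqn{\dot n = (f_n(v) - n)/\tau_n, \qquad \dot q = (f_q(v) - q)/\tau_q}
#' where `v` is the membrane potential, `n` the abstracted fast ionic-channel
#' activity, and `q` a slow negative-feedback current. `v` and `n` form the
#' spike-generation (fast) subsystem; `q` sweeps it slowly, which is what
#' produces bursting. All quantities are SI (volts, amps, seconds, farads).
#'
#' @param C_v Membrane capacitance (farads, > 0).
#' @param I_a Constant bias current (amps).
#' @param tau_n,tau_q Time constants of `n` and `q` (seconds, > 0).
#' @param fm,fn,fq [sigmoid_spec()]s of the three differential-pair curves.
#' @param g [tanh_spec()] of the transconductance amplifier.
#' @param consts [thermal_constants()].
#' @return An object of class `c("analog_sn", "qsn_model")`.
#' @seealso [vector_field()], [analog_nullclines()], [simulate_neuron()]
#' @export
analog_sn <- function(C_v, I_a, tau_n, tau_q, fm, fn, fq, g,
                      consts = thermal_constants()) {
  stopifnot(C_v > 0, tau_n > 0, tau_q > 0,
            inherits(fm, "sigmoid_spec"), inherits(fn, "sigmoid_spec"),
            inherits(fq, "sigmoid_spec"), inherits(g, "tanh_spec"),
            inherits(consts, "thermal_constants"))
  structure(list(C_v = C_v, I_a = I_a, tau_n = tau_n, tau_q = tau_q,
                 fm = fm, fn = fn, fq = fq, g = g, consts = consts),
            class = c("analog_sn", "qsn_model"))
}

#' Model vector field
#'
#' Evaluates the time derivatives of a model's state variables.
#'
#' @param model A `qsn_model`.
#' @param state Named numeric state vector (`v`,`n`,`q` for `analog_sn`;
#'   `v`,`n` for `ulp_sn` and `dssn`).
#' @param I_stim Stimulus current (amps; dimensionless for `dssn`).
#' @param ... Further arguments for methods.
#' @return Named numeric vector of derivatives.
#' @export
vector_field <- function(model, state, I_stim = 0, ...) {
  UseMethod("vector_field")
}

#' @rdname vector_field
#' @export
vector_field.analog_sn <- function(model, state, I_stim = 0, ...) {
  if (any(!is.finite(unlist(state)))) stop("non-finite state")
  v <- state[["v"]]; n <- state[["n"]]; q <- state[["q"]]
  dv <- (-tanh_current(model$g, model$consts, v) +
           sigmoid_current(model$fm, model$consts, v) -
           n - q + model$I_a + I_stim) / model$C_v
  dn <- (sigmoid_current(model$fn, model$consts, v) - n) / model$tau_n
  dq <- (sigmoid_current(model$fq, model$consts, v) - q) / model$tau_q
  c(v = dv, n = dn, q = dq)
}

#' Nullclines of the analog model
#'
#' On the fast-subsystem phase plane (with the slow variable `q` held as a
#' parameter) the v-nullcline is
#' `n = f_m(v) - g(v) - q + I_a + I_stim` (at `q = 0` this reduces to the
#' q-absorbed form `f_m(v) - g(v) + I_a + I_stim`), the n-nullcline is
#' `n = f_n(v)`, and the q-nullcline is `q = f_q(v)`.
#'
#' @param model An [analog_sn()] model.
#' @param v Voltage grid (volts).
#' @param q Fixed slow-variable value (amps) for the v-nullcline.
#' @param I_stim Stimulus current (amps).
#' @return A data frame with columns `v`, `v_null` (n on the v-nullcline),
#'   `n_null` (n on the n-nullcline) and `q_null` (q on the q-nullcline).
#' @export
analog_nullclines <- function(model, v, q = 0, I_stim = 0) {
  data.frame(
    v = v,
    v_null = sigmoid_current(model$fm, model$consts, v) -
      tanh_current(model$g, model$consts, v) - q + model$I_a + I_stim,
    n_null = sigmoid_current(model$fn, model$consts, v),
    q_null = sigmoid_current(model$fq, model$consts, v))
}

#' First-order low-pass response of the Tau-cell integrator
#'
#' The Tau-cell is a current-mode integrator with
#' \deqn{dI_{out}/dt = (I_{in} - I_{out}) / (C U_T / I_\tau),}
#' i.e. a first-order low-pass with time constant `tau = C * U_T / I_tau`.
#' For a piecewise-constant input the solution is piecewise exponential and
#' is computed here in closed form (no discretization error at the sample
#' points).
#'
#' @param C Capacitance (farads, > 0).
#' @param I_tau Time-constant-setting current (amps, > 0).
#' @param consts [thermal_constants()].
#' @param I_in A [stimulus_protocol()] giving the piecewise-constant input
#'   current, or a single constant value.
#' @param I_out0 Initial output current (amps).
#' @param T Duration (seconds, > 0).
#' @param dt Output sampling step (seconds).
#' @return Data frame with columns `t`, `I_out`.
#' @examples
#' tc <- tau_cell_response(C = 1e-12, I_tau = 1e-11, I_in = 1e-9,
#'                         I_out0 = 0, T = 0.02, dt = 1e-4)
#' @export
tau_cell_response <- function(C, I_tau, consts = thermal_constants(),
                              I_in, I_out0 = 0, T, dt = T / 1000) {
  stopifnot(C > 0, I_tau > 0, T > 0, dt > 0)
  tau <- C * consts$U_T / I_tau
  if (!inherits(I_in, "stimulus_protocol")) I_in <- constant_stimulus(I_in, T)
  t <- seq(0, T, by = dt)
  # breakpoints where the input changes
  bp <- sort(unique(c(0, I_in$start, I_in$end, T)))
  bp <- bp[bp >= 0 & bp <= T]
  out <- numeric(length(t))
  x0 <- I_out0; t0 <- 0
  for (i in seq_len(length(bp) - 1L)) {
    a <- bp[i]; b <- bp[i + 1L]
    u <- stimulus_at(I_in, (a + b) / 2)
    sel <- t >= a - 1e-15 & t <= b + 1e-15
    out[sel] <- u + (x0 - u) * exp(-(t[sel] - a) / tau)
    x0 <- u + (x0 - u) * exp(-(b - a) / tau)
  }
  data.frame(t = t, I_out = out)
}

#' Integrate a silicon neuron model
#'
#' Fixed-step integration of a model's equations: classical fourth-order
#' Runge-Kutta for the smooth analog models (default step 10 us), forward
#' Euler for the digital model (matching its hardware arithmetic; default
#' step 375 us). The integration loops run in compiled code. An error is
#' raised, naming the time of blow-up, if `|v|` exceeds `v_bound`.
#'
#' @param model A `qsn_model`.
#' @param state0 Named initial state.
#' @param stim A [stimulus_protocol()] (or a single constant amplitude).
#' @param dt Time step in seconds (> 0).
#' @param T Total duration in seconds (>= dt).
#' @param v_bound Divergence bound on `|v|` (10 V analog; 100 digital units).
#' @param ... Passed to methods ([simulate_neuron.dssn()] accepts `fmt`, a
#'   [fixed_point_format()]).
#' @return A trajectory data frame (`t` plus state columns).
#' @export
simulate_neuron <- function(model, state0, stim = stimulus_protocol(),
                            dt, T, ...) {
  UseMethod("simulate_neuron")
}

.check_sim_args <- function(dt, T) stopifnot(dt > 0, T >= dt)

.as_stim <- function(stim, T) {
  if (!inherits(stim, "stimulus_protocol"))
    stim <- constant_stimulus(stim, T)
  stim
}

#' @rdname simulate_neuron
#' @export
simulate_neuron.analog_sn <- function(model, state0, stim = stimulus_protocol(),
                                      dt = 1e-5, T, v_bound = 10, ...) {
  .check_sim_args(dt, T)
  stim <- .as_stim(stim, T)
  n_steps <- as.integer(round(T / dt))
  p <- c(model$C_v, model$I_a, model$tau_n, model$tau_q,
         model$fm$M, model$fm$delta, model$fn$M, model$fn$delta,
         model$fq$M, model$fq$delta, model$g$S, model$g$theta_v,
         .k_over_ut(model$consts), 1 + 1 / model$consts$kappa)
  res <- analog_rk4_cpp(p, c(state0[["v"]], state0[["n"]], state0[["q"]]),
                        stim$start, stim$end, stim$amplitude,
                        dt, n_steps, v_bound)
  .new_trajectory(dt * (0:n_steps),
                  data.frame(v = res[, 1], n = res[, 2], q = res[, 3]),
                  model = model, dt = dt)
}
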