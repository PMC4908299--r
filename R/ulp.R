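#' V-I curve of the cascode sigmoid block of the ultralow-power neuron
#'
#' A `ulp_curve_spec` bundles, for one state variable `x` of the
#' ultralow-power model, the rising differential-pair curve
#' `f_x(v) = M_x / (1 + exp(-(kappa/U_T)(v - delta_x)))` and the cascode
#' curve
#' \deqn{g_x(v) = I_{0P} R_{x20} e^{(\kappa/U_T)\theta_x} /
#'       (1 + R_{x21} e^{-(\kappa/U_T)(v-\theta_x)}).}
#' `R20` (1 or 0.5) and `R21` (1 or 2) are the discrete current-mirror
#' ratios used to shift the cascode curve horizontally; its saturation is
#' `I_0P * R20 * exp((kappa/U_T) * theta)`.
#'
#' @param M Saturation current of `f_x` (amps, >= 0).
#' @param delta Midpoint voltage of `f_x` (volts).
#' @param R20 Mirror ratio, 0.5 or 1.
#' @param R21 Mirror ratio, 1 or 2.
#' @param theta Cascode midpoint-setting voltage (volts).
#' @return An object of class `ulp_curve_spec`.
#' @export
ulp_curve_spec <- function(M, delta, R20 = 1, R21 = 1, theta) {
  stopifnot(is.finite(M), M >= 0, is.finite(delta), is.finite(theta),
            R20 %in% c(0.5, 1), R21 %in% c(1, 2))
  structure(list(M = M, delta = delta, R20 = R20, R21 = R21, theta = theta),
            class = "ulp_curve_spec")
}

#' The two-variable ultralow-power silicon neuron model
#'
#' The ideal model of the ultralow-power analog silicon nerve membrane:
#' \deqn{C_v \dot v = f_v(v) - g_v(v) + I_{av} - r(n) + I_{stim}}
#' \deqn{C_n \dot n = f_n(v) - g_n(v) + I_{an} - r(n)}
#' Both state variables are capacitor voltages; the leak/recovery current is
#' carried by the shared sigmoid
#' `r(n) = I_0P * exp((kappa/U_T) theta_r) / (1 + exp(-(kappa/U_T)(n - theta_r)))`.
#' Because `r` is strictly increasing it is invertible, and the substitution
#' `ntilde = r(n)` gives an equivalent system on the `(v, ntilde)` plane (see
#' [ulp_transformed_vector_field()]) whose v-nullcline is
#' `ntilde = f_v(v) - g_v(v) + I_av + I_stim`.
#'
#' @param C_v,C_n Capacitances (farads, > 0); defaults are the fabricated
#'   MIMCAP values 1.5 and 2.0 pF.
#' @param I_av,I_an Parameter currents (amps).
#' @param I_0P Current-scaling constant of the common-sized PMOS devices
#'   (amps, > 0).
#' @param curve_v,curve_n [ulp_curve_spec()]s for the `v` and `n` equations.
#' @param theta_r Midpoint voltage of `r` (volts).
#' @param consts [thermal_constants()].
#' @return An object of class `c("ulp_sn", "qsn_model")`.
#' @export
ulp_sn <- function(C_v = 1.5e-12, C_n = 2.0e-12, I_av, I_an, I_0P,
                   curve_v, curve_n, theta_r,
                   consts = thermal_constants()) {
  stopifnot(C_v > 0, C_n > 0, I_0P > 0,
            inherits(curve_v, "ulp_curve_spec"),
            inherits(curve_n, "ulp_curve_spec"),
            inherits(consts, "thermal_constants"))
  structure(list(C_v = C_v, C_n = C_n, I_av = I_av, I_an = I_an,
                 I_0P = I_0P, curve_v = curve_v, curve_n = curve_n,
                 theta_r = theta_r, consts = consts),
            class = c("ulp_sn", "qsn_model"))
}

# log(1 + e^x) without overflow
.log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(pmin(x, 33))))

#' Cascode curve g_x(v) of the ultralow-power model
#'
#' Evaluated in the log domain so that large exponents never overflow.
#'
#' @param curve A [ulp_curve_spec()].
#' @param consts [thermal_constants()].
#' @param I_0P Current-scaling constant (amps).
#' @param v Voltage(s), volts.
#' @return Current(s), amps; increasing in `v` with saturation
#'   `I_0P * R20 * exp((kappa/U_T) * theta)`.
#' @export
ulp_g <- function(curve, consts, I_0P, v) {
  k <- .k_over_ut(consts)
  la <- log(curve$R21) - k * (v - curve$theta)
  exp(log(I_0P * curve$R20) + k * curve$theta - .log1pexp(la))
}

.ulp_g_slope <- function(curve, consts, I_0P, v) {
  k <- .k_over_ut(consts)
  g <- ulp_g(curve, consts, I_0P, v)
  sat <- I_0P * curve$R20 * exp(k * curve$theta)
  k * g * (1 - g / sat)
}

.ulp_f <- function(curve, consts, v)
  sigmoid_current(sigmoid_spec(curve$M, curve$delta), consts, v)

.ulp_f_slope <- function(curve, consts, v)
  .sigmoid_slope(sigmoid_spec(curve$M, curve$delta), consts, v)

#' Recovery-current sigmoid r(n), its derivative and closed-form inverse
#'
#' `r(n) = plateau / (1 + exp(-(kappa/U_T)(n - theta_r)))` with
#' `plateau = I_0P * exp((kappa/U_T) * theta_r)`. `r` is strictly
#' increasing; `ulp_r_inv()` is the exact logit inverse, defined on
#' `(0, plateau)`.
#'
#' @param theta_r Midpoint voltage (volts).
#' @param consts [thermal_constants()].
#' @param I_0P Current-scaling constant (amps).
#' @param n Voltage(s) (volts); for the inverse, `ntilde` current(s) in
#'   amps inside `(0, plateau)`.
#' @return `ulp_r`: current(s); `ulp_r_prime`: dr/dn (amps/volt);
#'   `ulp_r_inv`: voltage(s); `ulp_r_plateau`: the plateau current.
#' @export
ulp_r <- function(theta_r, consts, I_0P, n) {
  k <- .k_over_ut(consts)
  ulp_r_plateau(theta_r, consts, I_0P) * stats::plogis(k * (n - theta_r))
}

#' @rdname ulp_r
#' @export
ulp_r_plateau <- function(theta_r, consts, I_0P)
  I_0P * exp(.k_over_ut(consts) * theta_r)

#' @rdname ulp_r
#' @export
ulp_r_prime <- function(theta_r, consts, I_0P, n) {
  k <- .k_over_ut(consts)
  s <- stats::plogis(k * (n - theta_r))
  ulp_r_plateau(theta_r, consts, I_0P) * k * s * (1 - s)
}

#' @rdname ulp_r
#' @param ntilde Transformed current(s), strictly inside `(0, plateau)`.
#' @export
ulp_r_inv <- function(theta_r, consts, I_0P, ntilde) {
  plateau <- ulp_r_plateau(theta_r, consts, I_0P)
  if (any(ntilde <= 0 | ntilde >= plateau))
    stop("ntilde outside the open range (0, plateau) of r")
  theta_r + stats::qlogis(ntilde / plateau) / .k_over_ut(consts)
}

#' @rdname vector_field
#' @export
vector_field.ulp_sn <- function(model, state, I_stim = 0, ...) {
  if (any(!is.finite(unlist(state)))) stop("non-finite state")
  v <- state[["v"]]; n <- state[["n"]]
  cs <- model$consts
  rn <- ulp_r(model$theta_r, cs, model$I_0P, n)
  dv <- (.ulp_f(model$curve_v, cs, v) - ulp_g(model$curve_v, cs, model$I_0P, v) +
           model$I_av - rn + I_stim) / model$C_v
  dn <- (.ulp_f(model$curve_n, cs, v) - ulp_g(model$curve_n, cs, model$I_0P, v) +
           model$I_an - rn) / model$C_n
  c(v = dv, n = dn)
}

#' Vector field of the transformed (v, ntilde) system
#'
#' With `ntilde = r(n)` the model becomes
#' \deqn{C_v \dot v = f_v(v) - g_v(v) + I_{av} - \tilde n + I_{stim}}
#' \deqn{C_n \dot{\tilde n} = r'(r^{-1}(\tilde n))
#'       (f_n(v) - g_n(v) + I_{an} - \tilde n).}
#' The two formulations are equivalent; the transformed one is what the
#' nullcline-drawing amplifiers of the circuit observe.
#'
#' @param model A [ulp_sn()] model.
#' @param v Membrane voltage (volts).
#' @param ntilde Transformed recovery current (amps), strictly inside the
#'   open range of `r` (error otherwise).
#' @param I_stim Stimulus current (amps).
#' @return Named vector `c(v = dv/dt, ntilde = dntilde/dt)`.
#' @export
ulp_transformed_vector_field <- function(model, v, ntilde, I_stim = 0) {
  cs <- model$consts
  n <- ulp_r_inv(model$theta_r, cs, model$I_0P, ntilde)
  rp <- ulp_r_prime(model$theta_r, cs, model$I_0P, n)
  dv <- (.ulp_f(model$curve_v, cs, v) - ulp_g(model$curve_v, cs, model$I_0P, v) +
           model$I_av - ntilde + I_stim) / model$C_v
  dnt <- rp * (.ulp_f(model$curve_n, cs, v) -
                 ulp_g(model$curve_n, cs, model$I_0P, v) +
                 model$I_an - ntilde) / model$C_n
  c(v = dv, ntilde = dnt)
}

#' Nullclines of the ultralow-power model on the (v, ntilde) plane
#'
#' @param model A [ulp_sn()] model.
#' @param v Voltage grid (volts).
#' @param I_stim Stimulus current (amps).
#' @return Data frame with columns `v`, `v_null`
#'   (`ntilde = f_v - g_v + I_av + I_stim`) and `n_null`
#'   (`ntilde = f_n - g_n + I_an`).
#' @export
ulp_nullclines <- function(model, v, I_stim = 0) {
  cs <- model$consts
  data.frame(
    v = v,
    v_null = .ulp_f(model$curve_v, cs, v) -
      ulp_g(model$curve_v, cs, model$I_0P, v) + model$I_av + I_stim,
    n_null = .ulp_f(model$curve_n, cs, v) -
      ulp_g(model$curve_n, cs, model$I_0P, v) + model$I_an)
}

.ulp_param_vec <- function(model) {
  cs <- model$consts
  c(model$C_v, model$C_n, model$I_av, model$I_an, model$I_0P,
    model$curve_v$M, model$curve_v$delta, model$curve_v$R20,
    model$curve_v$R21, model$curve_v$theta,
    model$curve_n$M, model$curve_n$delta, model$curve_n$R20,
    model$curve_n$R21, model$curve_n$theta,
    model$theta_r, .k_over_ut(cs))
}

#' @rdname simulate_neuron
#' @param transformed Integrate the `(v, ntilde)` system instead of the raw
#'   `(v, n)` system (ULP model only). The returned trajectory always
#'   carries `v`, `n` and `ntilde` columns (one of the latter two derived
#'   through `r` / its inverse).
#' @export
simulate_neuron.ulp_sn <- function(model, state0, stim = stimulus_protocol(),
                                   dt = 1e-5, T, v_bound = 10,
                                   transformed = FALSE, ...) {
  .check_sim_args(dt, T)
  stim <- .as_stim(stim, T)
  n_steps <- as.integer(round(T / dt))
  p <- .ulp_param_vec(model)
  if (transformed) {
    nt0 <- if ("ntilde" %in% names(state0)) state0[["ntilde"]]
           else ulp_r(model$theta_r, model$consts, model$I_0P, state0[["n"]])
    res <- ulp_rk4_cpp(p, c(state0[["v"]], nt0),
                       stim$start, stim$end, stim$amplitude,
                       dt, n_steps, v_bound, TRUE)
    ntilde <- res[, 2]
    n <- ulp_r_inv(model$theta_r, model$consts, model$I_0P,
                   pmin(pmax(ntilde, 1e-300),
                        ulp_r_plateau(model$theta_r, model$consts,
                                      model$I_0P) * (1 - 1e-15)))
  } else {
    res <- ulp_rk4_cpp(p, c(state0[["v"]], state0[["n"]]),
                       stim$start, stim$end, stim$amplitude,
                       dt, n_steps, v_bound, FALSE)
    n <- res[, 2]
    ntilde <- ulp_r(model$theta_r, model$consts, model$I_0P, n)
  }
  .new_trajectory(dt * (0:n_steps),
                  data.frame(v = res[, 1], n = n, ntilde = ntilde),
                  model = model, dt = dt)
}
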