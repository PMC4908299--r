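# Shared fixtures, built in code. Presets load from the installed package.

consts_rt <- thermal_constants()          # room-temperature defaults

# an analog model whose curves are all switched off: the null system
analog_null_model <- function(I_a = 0)
  analog_sn(C_v = 1e-12, I_a = I_a, tau_n = 1e-3, tau_q = 1e-2,
            fm = sigmoid_spec(0, 0), fn = sigmoid_spec(0, 0),
            fq = sigmoid_spec(0, 0), g = tanh_spec(0, 0))

# independent re-implementation of the analog equations for the
# duplicate-formula oracle (deliberately written differently from the
# package code: raw exp() forms)
analog_rhs_oracle <- function(m, v, n, q, I_stim) {
  k <- m$consts$kappa / m$consts$U_T
  f <- function(M, d) M / (1 + exp(-k * (v - d)))
  a <- k * (v - m$g$theta_v) / (1 + 1 / m$consts$kappa)
  g <- m$g$S * (1 - exp(-a)) / (1 + exp(-a))
  c((-g + f(m$fm$M, m$fm$delta) - n - q + m$I_a + I_stim) / m$C_v,
    (f(m$fn$M, m$fn$delta) - n) / m$tau_n,
    (f(m$fq$M, m$fq$delta) - q) / m$tau_q)
}

# independent DSSN piecewise-quadratic evaluation
dssn_f_oracle <- function(p, v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    if (v[i] < 0) out[i] <- p$a_fn * v[i]^2 - 2 * p$a_fn * p$b_fn * v[i] +
        p$a_fn * p$b_fn^2 + p$c_fn
    else out[i] <- p$a_fp * v[i]^2 - 2 * p$a_fp * p$b_fp * v[i] +
        p$a_fp * p$b_fp^2 + p$c_fp
  }
  out
}

# centred finite-difference Jacobian
fd_jacobian <- function(model, state, I_stim = 0, h = NULL) {
  nm <- names(state)
  J <- matrix(0, length(state), length(state),
              dimnames = list(nm, nm))
  for (j in seq_along(state)) {
    hj <- if (is.null(h)) max(abs(state[[j]]), 1e-3) * 1e-6 else h
    up <- state; up[[j]] <- up[[j]] + hj
    dn <- state; dn[[j]] <- dn[[j]] - hj
    J[, j] <- (vector_field(model, up, I_stim) -
                 vector_field(model, dn, I_stim)) / (2 * hj)
  }
  J
}

# network test fixtures: small pattern sets are enough for most checks
small_patterns <- function(N = 16L, count = 2L, seed = 5L)
  generate_patterns(N, count, seed = seed, max_pairwise_overlap = 1)
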