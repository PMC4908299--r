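test_that("sigmoid current has the differential-pair form", {
  f <- sigmoid_spec(M = 1e-9, delta = 0.3)
  # midpoint and saturation
  expect_equal(sigmoid_current(f, consts_rt, 0.3), 0.5e-9)
  expect_gt(sigmoid_current(f, consts_rt, 1.0), 0.999e-9)
  expect_lt(sigmoid_current(f, consts_rt, -1.0), 1e-12)
  # high-precision direct evaluation at v = 0.35
  expect_equal(sigmoid_current(f, consts_rt, 0.35),
               1e-9 / (1 + exp(-(0.7 / 0.026) * 0.05)),
               tolerance = 1e-12)
  expect_equal(sigmoid_current(f, consts_rt, 0.35), 0.7935e-9,
               tolerance = 1e-4)
  # strictly increasing on a dense grid
  vg <- seq(-0.2, 0.8, length.out = 1000)
  expect_true(all(diff(sigmoid_current(f, consts_rt, vg)) > 0))
  expect_error(sigmoid_current(f, consts_rt, NaN), "non-finite")
})

test_that("tanh current is odd, shallow and saturating", {
  g <- tanh_spec(S = 1e-9, theta_v = 0)
  expect_equal(tanh_current(g, consts_rt, 0), 0)
  expect_gt(tanh_current(g, consts_rt, 2), 0.999e-9)
  expect_lt(tanh_current(g, consts_rt, -2), -0.999e-9)
  # equals S * tanh(a/2) with the (1 + 1/kappa) shallowness divisor
  a <- (0.7 / 0.026) * 0.05 / (1 + 1 / 0.7)
  expect_equal(tanh_current(g, consts_rt, 0.05), 1e-9 * tanh(a / 2),
               tolerance = 1e-12)
  expect_equal(tanh_current(g, consts_rt, 0.05), 0.2703e-9,
               tolerance = 1e-3)
  # odd about theta_v, monotone
  vg <- seq(-0.3, 0.3, length.out = 1000)
  expect_equal(tanh_current(g, consts_rt, vg),
               -tanh_current(g, consts_rt, -vg))
  expect_true(all(diff(tanh_current(g, consts_rt, vg)) > 0))
})

test_that("analog vector field matches the membrane equations", {
  m0 <- analog_null_model()
  expect_equal(unname(vector_field(m0, c(v = 0.12, n = 0, q = 0))),
               c(0, 0, 0))
  # duplicate-formula oracle at random states
  m <- qsn_preset("analog_square_wave")
  set.seed(1)
  for (i in 1:20) {
    st <- c(v = runif(1, -0.2, 0.2), n = runif(1, 0, 1e-10),
            q = runif(1, 0, 1e-10))
    I <- runif(1, -5e-11, 5e-11)
    expect_equal(unname(vector_field(m, st, I)),
                 analog_rhs_oracle(m, st[["v"]], st[["n"]], st[["q"]], I),
                 tolerance = 1e-13)
  }
  # root-finder oracle: derivatives vanish at reported equilibria of the
  # fast subsystem
  f <- fast_subsystem(m, 29e-12)
  eq <- find_equilibria(f)
  for (i in seq_len(nrow(eq))) {
    st <- c(v = eq$v[i], n = eq$n[i])
    fld <- vector_field(f, st)
    expect_lt(abs(fld[["v"]]) * m$C_v / qsn:::.model_scale(m), 1e-10)
    expect_lt(abs(fld[["n"]]) * m$tau_n / qsn:::.model_scale(m), 1e-10)
  }
})

test_that("analog nullclines include the slow current and are N-shaped", {
  m <- qsn_preset("analog_square_wave")
  v <- seq(-0.2, 0.2, length.out = 400)
  # flat v-nullcline when the curves are off
  m0 <- analog_null_model(I_a = 3e-11)
  nc0 <- analog_nullclines(m0, v)
  expect_true(all(abs(nc0$v_null - 3e-11) < 1e-25))
  # n-nullcline midpoint
  ncm <- analog_nullclines(m, m$fn$delta)
  expect_equal(ncm$n_null, m$fn$M / 2)
  # -q enters the v-nullcline linearly; q = 0 reduces to the printed form
  nc <- analog_nullclines(m, v, q = 6e-11)
  ncz <- analog_nullclines(m, v, q = 0)
  expect_equal(nc$v_null, ncz$v_null - 6e-11)
  # N-shape: the derivative changes sign exactly twice for the preset
  d <- diff(ncz$v_null)
  expect_equal(sum(diff(sign(d)) != 0), 2)
})

test_that("Tau-cell response matches the first-order closed form", {
  C <- 1e-12; I_tau <- 1e-11
  tau <- C * consts_rt$U_T / I_tau
  # constant input equal to the initial output is a fixed point
  fp <- tau_cell_response(C, I_tau, consts_rt, I_in = 2e-10,
                          I_out0 = 2e-10, T = 5 * tau)
  expect_true(all(abs(fp$I_out - 2e-10) < 1e-22))
  # step response: 1 - exp(-t/tau), checked at tau and at 10 sampled times
  st <- tau_cell_response(C, I_tau, consts_rt, I_in = 1e-9, I_out0 = 0,
                          T = 5 * tau, dt = tau / 20)
  at_tau <- st$I_out[which.min(abs(st$t - tau))]
  expect_equal(at_tau, 1e-9 * (1 - exp(-1)), tolerance = 1e-6)
  idx <- round(seq(2, nrow(st), length.out = 10))
  expect_equal(st$I_out[idx], 1e-9 * (1 - exp(-st$t[idx] / tau)),
               tolerance = 1e-9)
})

test_that("analog integration: null system, gating relaxation, RK4 order", {
  # null system stays put
  m0 <- analog_null_model()
  tr <- simulate_neuron(m0, c(v = 0.05, n = 0, q = 0), dt = 1e-5, T = 1e-3)
  expect_true(all(abs(tr$v - 0.05) < 1e-15))
  # with a huge membrane capacitance v is effectively clamped and n
  # relaxes exponentially toward f_n(v) with time constant tau_n
  m <- qsn_preset("analog_square_wave")
  mc <- m; mc$C_v <- 1    # farad-scale: v frozen over milliseconds
  v0 <- 0.01
  tr <- simulate_neuron(mc, c(v = v0, n = 0, q = 0), dt = 1e-6, T = 5e-3)
  n_inf <- sigmoid_current(m$fn, m$consts, v0)
  expect_equal(tr$n, n_inf * (1 - exp(-tr$t / m$tau_n)), tolerance = 1e-4)
  # step-halving on a smooth burst segment: 4th-order convergence means
  # the dt and dt/2 solutions agree far better than dt vs dt*2
  s0 <- c(v = 0.05, n = 2e-11, q = 2.5e-11)
  end_v <- vapply(c(4e-5, 2e-5, 1e-5), function(h)
    tail(simulate_neuron(m, s0, dt = h, T = 0.02)$v, 1), numeric(1))
  e_coarse <- abs(end_v[1] - end_v[3])
  e_fine <- abs(end_v[2] - end_v[3])
  expect_lt(e_fine, e_coarse / 8)  # >= 3rd order observed
})

test_that("gating variables stay inside their saturation ranges", {
  m <- qsn_preset("analog_square_wave")
  tr <- simulate_neuron(m, c(v = 0.05, n = 2e-11, q = 2.5e-11),
                        dt = 2e-5, T = 3)
  expect_true(all(tr$n >= 0 & tr$n <= m$fn$M))
  expect_true(all(tr$q >= 0 & tr$q <= m$fq$M))
})

test_that("divergence raises an error naming the blow-up time", {
  runaway <- analog_sn(C_v = 1e-13, I_a = 1e-9, tau_n = 1e-3, tau_q = 1e-2,
                       fm = sigmoid_spec(5e-9, 0), fn = sigmoid_spec(0, 0),
                       fq = sigmoid_spec(0, 0), g = tanh_spec(0, 0))
  expect_error(simulate_neuron(runaway, c(v = 0, n = 0, q = 0),
                               dt = 1e-5, T = 1),
               "blow-up at t = ")
})
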