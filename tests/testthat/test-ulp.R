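test_that("cascode curve g_x saturates and halves/thirds at its midpoint", {
  k <- consts_rt$kappa / consts_rt$U_T
  cv <- ulp_curve_spec(M = 1e-9, delta = 0.5, R20 = 1, R21 = 1, theta = 0.1)
  sat <- 1e-12 * exp(k * 0.1)
  expect_equal(ulp_g(cv, consts_rt, 1e-12, 2), sat, tolerance = 1e-9)
  expect_equal(ulp_g(cv, consts_rt, 1e-12, 0.1), sat / 2, tolerance = 1e-12)
  # R21 = 2 gives the 1/(1+2) factor at v = theta
  cv2 <- ulp_curve_spec(M = 1e-9, delta = 0.5, R20 = 1, R21 = 2, theta = 0.1)
  expect_equal(ulp_g(cv2, consts_rt, 1e-12, 0.1), sat / 3, tolerance = 1e-12)
  # increasing, and log-domain evaluation survives far-left inputs
  vg <- seq(-2, 2, length.out = 500)
  gv <- ulp_g(cv, consts_rt, 1e-12, vg)
  expect_true(all(is.finite(gv)))
  expect_true(all(diff(gv) >= 0))
})

test_that("recovery sigmoid r is invertible with analytic derivative", {
  th_r <- 0.42; I_0P <- 2e-14
  plateau <- ulp_r_plateau(th_r, consts_rt, I_0P)
  expect_equal(ulp_r(th_r, consts_rt, I_0P, th_r), plateau / 2)
  # analytic r' vs centred differences at 20 sampled points
  ns <- seq(0.3, 0.55, length.out = 20)
  h <- 1e-7
  fd <- (ulp_r(th_r, consts_rt, I_0P, ns + h) -
           ulp_r(th_r, consts_rt, I_0P, ns - h)) / (2 * h)
  expect_equal(ulp_r_prime(th_r, consts_rt, I_0P, ns), fd,
               tolerance = 1e-6)
  expect_true(all(ulp_r_prime(th_r, consts_rt, I_0P, ns) > 0))
  # closed-form logit inverse round-trips to 1e-12 V
  expect_equal(ulp_r_inv(th_r, consts_rt, I_0P,
                         ulp_r(th_r, consts_rt, I_0P, ns)),
               ns, tolerance = 1e-12)
  expect_error(ulp_r_inv(th_r, consts_rt, I_0P, plateau * 1.01),
               "outside the open range")
})

test_that("ULP vector field vanishes at equilibria and at zero currents", {
  m <- qsn_preset("ulp_class2")
  eq <- find_equilibria(m, v_range = c(0.05, 1.0))
  for (i in seq_len(nrow(eq))) {
    fld <- vector_field(m, c(v = eq$v[i], n = eq$n[i]))
    scale <- qsn:::.model_scale(m)
    expect_lt(abs(fld[["v"]]) * m$C_v / scale, 1e-10)
    expect_lt(abs(fld[["n"]]) * m$C_n / scale, 1e-10)
  }
  # with every current source switched off the field is numerically zero
  m0 <- ulp_sn(I_av = 0, I_an = 0, I_0P = 1e-30,
               curve_v = ulp_curve_spec(0, 0.5, 1, 1, 0.4),
               curve_n = ulp_curve_spec(0, 0.5, 1, 1, 0.4), theta_r = 0.4)
  fld0 <- vector_field(m0, c(v = 0.4, n = 0.2))
  expect_lt(max(abs(fld0)), 1e-12)
})

test_that("raw and ntilde-transformed systems are equivalent", {
  m <- qsn_preset("ulp_class2")
  plateau <- ulp_r_plateau(m$theta_r, m$consts, m$I_0P)
  eq <- find_equilibria(m, v_range = c(0.05, 1.0))
  s0 <- c(v = eq$v[1] + 0.03, n = eq$n[1])
  # subthreshold relaxation over 100 ms: the two charts agree to a
  # fraction of the plateau far below 1e-6
  tr_raw <- simulate_neuron(m, s0, dt = 2e-6, T = 0.1)
  tr_tf <- simulate_neuron(m, s0, dt = 2e-6, T = 0.1, transformed = TRUE)
  expect_lt(max(abs(tr_raw$ntilde - tr_tf$ntilde)), 1e-6 * plateau)
  # on a spiking run the charts produce the same spike train
  th <- spike_threshold(m)
  stim <- constant_stimulus(0.15e-9, 0.08)
  sp_raw <- spike_times(simulate_neuron(m, s0, stim, dt = 2e-6, T = 0.08), th)
  sp_tf <- spike_times(simulate_neuron(m, s0, stim, dt = 2e-6, T = 0.08,
                                       transformed = TRUE), th)
  expect_equal(length(sp_raw), length(sp_tf))
  expect_equal(sp_raw, sp_tf, tolerance = 1e-3)
  # the dntilde/dt sign equals the sign of the current balance (r' > 0)
  vf <- ulp_transformed_vector_field(m, eq$v[1] + 0.1,
                                     ulp_r(m$theta_r, m$consts, m$I_0P,
                                           m$theta_r))
  bal <- qsn:::.ulp_f(m$curve_n, m$consts, eq$v[1] + 0.1) -
    ulp_g(m$curve_n, m$consts, m$I_0P, eq$v[1] + 0.1) + m$I_an -
    ulp_r(m$theta_r, m$consts, m$I_0P, m$theta_r)
  expect_equal(sign(vf[["ntilde"]]), sign(bal))
})

test_that("ntilde stays inside the open range of r on trajectories", {
  m <- qsn_preset("ulp_class1")
  plateau <- ulp_r_plateau(m$theta_r, m$consts, m$I_0P)
  eq <- find_equilibria(m, v_range = c(0.05, 1.0))
  tr <- simulate_neuron(m, c(v = eq$v[1], n = eq$n[1]),
                        constant_stimulus(0.15e-9, 0.05), dt = 2e-6, T = 0.05)
  expect_true(all(tr$ntilde > 0 & tr$ntilde < plateau))
})

test_that("ULP presets separate the excitability classes", {
  m1 <- qsn_preset("ulp_class1")
  m2 <- qsn_preset("ulp_class2")
  eq1 <- find_equilibria(m1, v_range = c(0.05, 1.0))
  eq2 <- find_equilibria(m2, v_range = c(0.05, 1.0))
  expect_equal(nrow(eq1), 3)
  expect_equal(sub("_.*", "", eq1$label), c("stable", "saddle", "unstable"))
  expect_equal(nrow(eq2), 1)
  expect_match(eq2$label, "^stable")
  # Class II graded response: spike peak strictly increases with pulse
  # amplitude over the probed range
  g2 <- graded_response_test(m2, seq(0.5, 4, by = 0.5) * 1e-9,
                             width = 5e-4, T_run = 0.015, dt = 1e-6)
  pk <- g2$peak_v[g2$spiked]
  expect_gte(length(pk), 4)
  expect_true(all(diff(pk) > 0))
})
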