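test_that("equilibria of the digital presets match the class geometries", {
  eq1 <- find_equilibria(qsn_preset("dssn_class1"))
  expect_equal(nrow(eq1), 3)
  expect_equal(sub("_.*", "", eq1$label), c("stable", "saddle", "unstable"))
  expect_true(all(eq1$residual < 1e-10))
  eq2 <- find_equilibria(qsn_preset("dssn_class2"))
  expect_equal(nrow(eq2), 1)
  expect_match(eq2$label, "^stable")
  # stability labels are consistent with the eigenvalue real parts
  for (eq in list(eq1, eq2)) {
    for (i in seq_len(nrow(eq))) {
      re <- c(eq$eig1_re[i], eq$eig2_re[i])
      lab <- eq$label[i]
      if (grepl("^stable", lab)) expect_true(all(re < 1e-9))
      if (grepl("^unstable", lab)) expect_true(all(re > -1e-9))
      if (lab == "saddle") expect_true(max(re) > 0 && min(re) < 0)
    }
  }
})

test_that("analytic Jacobians agree with centred finite differences", {
  models <- list(
    dssn = qsn_preset("dssn_class2"),
    ulp = qsn_preset("ulp_class2"),
    analog = qsn_preset("analog_square_wave"))
  states <- list(
    dssn = function() c(v = runif(1, -0.8, 0.6), n = runif(1, 0, 1)),
    ulp = function() c(v = runif(1, 0.3, 0.6), n = runif(1, 0.3, 0.5)),
    analog = function() c(v = runif(1, -0.1, 0.1), n = runif(1, 0, 1e-10),
                          q = runif(1, 0, 1e-10)))
  set.seed(4)
  for (nm in names(models)) {
    for (i in 1:3) {
      st <- states[[nm]]()
      # piecewise model: stay off the breakpoints
      if (nm == "dssn" && min(abs(st[["v"]] - c(0, models$dssn$r_g))) < 0.02)
        st[["v"]] <- st[["v"]] + 0.05
      J <- jacobian_at(models[[nm]], st)
      Jfd <- fd_jacobian(models[[nm]], st)
      expect_equal(J, Jfd, tolerance = 1e-5)
    }
  }
  # the fast-subsystem (2x2) Jacobian drops the frozen q row/column
  m <- models$analog
  Jf <- jacobian_at(fast_subsystem(m, 3e-11), c(v = 0.01, n = 5e-11))
  expect_equal(dim(Jf), c(2L, 2L))
})

test_that("stimulus sweep finds the Class I snic with diverging period", {
  m1 <- qsn_preset("dssn_class1")
  bd <- sweep_bifurcation(m1, "I_stim", c(0.02, 0.25), resolution = 24,
                          T_run = 3, dt = 1e-4)
  expect_true("snic" %in% bd$events$type ||
                "saddle_node" %in% bd$events$type)
  # equilibrium count drops 3 -> 1 across the fold
  expect_equal(max(bd$samples$n_eq), 3)
  expect_equal(min(bd$samples$n_eq), 1)
  # period near onset far exceeds the far-field period
  per <- bd$samples$period[bd$samples$cycle]
  expect_gt(max(per) / min(per), 3)
})

test_that("stimulus sweep finds the Class II subcritical Hopf and fold", {
  m2 <- qsn_preset("dssn_class2")
  bd <- sweep_bifurcation(m2, "I_stim", c(0.4, 0.6), resolution = 21,
                          T_run = 3, dt = 1e-4)
  hop <- bd$events[bd$events$type == "hopf", ]
  expect_gte(nrow(hop), 1)
  expect_match(hop$note[1], "subcritical")
  expect_true("fold_of_cycles" %in% bd$events$type)
  expect_true(any(bd$samples$bistable))
})

test_that("f-I sweep classifies the digital presets by onset frequency", {
  m1 <- qsn_preset("dssn_class1")
  # coarse sweep for the plateau plus a fine grid near the snic onset
  fi_coarse <- fi_curve(m1, c(0.04, attr(m1, "I_plateau")), resolution = 10,
                        T_run = 2)
  Ic <- attr(m1, "I_snic")
  fi_fine <- fi_curve(m1, I_values = Ic + seq(0, 0.004, by = 4e-4),
                      T_run = 4)
  fi1 <- rbind(fi_fine, fi_coarse)
  fi1 <- fi1[order(fi1$I_stim), ]
  cls1 <- classify_excitability(fi1)
  expect_equal(cls1$class, "class1")
  m2 <- qsn_preset("dssn_class2")
  fi2 <- fi_curve(m2, c(attr(m2, "I_probe_lo"), attr(m2, "I_probe_hi")),
                  resolution = 15, T_run = 2)
  cls2 <- classify_excitability(fi2)
  expect_equal(cls2$class, "class2")
  expect_gt(cls2$onset_freq, 0.5 * cls2$plateau)
  # a silent model raises the documented error
  silent <- qsn_preset("dssn_class1")
  expect_error(classify_excitability(fi_curve(silent, c(0, 0.02),
                                              resolution = 4, T_run = 0.5)),
               "below threshold")
})

test_that("ISI-based frequencies agree with an FFT estimate on periodic runs", {
  m2 <- qsn_preset("dssn_class2")
  tr <- simulate_neuron(m2, c(v = -0.2, n = 0.2),
                        constant_stimulus(0.7, 3), dt = 1e-4, T = 3)
  keep <- tr$t >= 1.5
  sp <- spike_times(tr[keep, , drop = FALSE], 0)
  f_isi <- 1 / mean(diff(sp))
  x <- tr$v[keep] - mean(tr$v[keep])
  spec <- Mod(fft(x))[2:(length(x) %/% 2)]
  f_fft <- (which.max(spec)) / (length(x) * 1e-4)
  expect_equal(f_isi, f_fft, tolerance = 0.02)
})

test_that("graded responses are strong for Class II and weak for Class I", {
  g1 <- graded_response_test(qsn_preset("dssn_class1"),
                             seq(0.1, 0.5, by = 0.05), width = 0.002)
  g2 <- graded_response_test(qsn_preset("dssn_class2"),
                             seq(0.5, 2.5, by = 0.25), width = 0.002)
  expect_gt(attr(g2, "spread"), 2 * attr(g1, "spread"))
  # zero amplitude: no spike, peak at rest
  g0 <- graded_response_test(qsn_preset("dssn_class2"), 0, width = 0.002)
  expect_false(g0$spiked[1])
  rest <- find_equilibria(qsn_preset("dssn_class2"))$v[1]
  expect_equal(g0$peak_v[1], rest, tolerance = 1e-3)
  # identical amplitudes give identical peaks (determinism)
  gr <- graded_response_test(qsn_preset("dssn_class2"), c(1, 1, 1),
                             width = 0.002)
  expect_equal(gr$peak_v[1], gr$peak_v[2])
  expect_equal(gr$peak_v[2], gr$peak_v[3])
})

test_that("burst segmentation follows the median-ISI gap rule", {
  # ISIs {10,10,10,200,10,10} ms -> bursts of 4 and 3 spikes
  sp <- cumsum(c(0, 10, 10, 10, 200, 10, 10)) * 1e-3
  b <- segment_bursts(sp)
  expect_equal(b$n_spikes, c(4L, 3L))
  # evenly spaced spikes form a single burst
  expect_equal(nrow(segment_bursts(seq(0, 1, by = 0.01))), 1L)
  # degenerate cases
  expect_equal(nrow(segment_bursts(numeric())), 0L)
  expect_equal(segment_bursts(0.5)$n_spikes, 1L)
  # every spike lands in exactly one burst, bursts ordered (property)
  set.seed(6)
  for (i in 1:10) {
    tr <- sort(runif(60, 0, 2))
    b <- segment_bursts(tr)
    expect_equal(sum(b$n_spikes), length(tr))
    expect_true(all(diff(b$start) > 0))
    expect_true(all(b$end >= b$start))
  }
})

test_that("spike-count sequences are labelled tonic / periodic / aperiodic", {
  lbl <- qsn:::.burst_label
  expect_equal(lbl(rep(3L, 50), 40), "periodic-3")
  expect_equal(lbl(c(2L, rep(1L, 50), 2L), 40), "periodic-1")
  expect_equal(lbl(5L, 40), "tonic")
  set.seed(7)
  expect_equal(lbl(sample(2:9, 60, replace = TRUE), 40), "aperiodic")
})

test_that("the mode tuner verifies easy targets and reports infeasibility", {
  # near-feasible box around the Class II geometry: the annealer must find
  # and verify a class2 candidate
  tpl <- qsn_preset("dssn_class2")
  rep <- tune_mode(tpl, "class2",
                   bounds = list(a_gn = c(1.5, 2.2), I_0 = c(-0.05, 0.05)),
                   seed = 3, n_iter = 40, I_test = c(0.6, 0.8))
  expect_true(rep$passed)
  expect_equal(rep$verification$classification$class, "class2")
  # infeasible: a flat membrane curve can never produce the geometry
  m <- qsn_preset("analog_square_wave")
  bad <- tune_mode(m, "class1", bounds = list(M_m = c(0, 0)),
                   seed = 1, n_iter = 10)
  expect_false(bad$passed)
  expect_gt(bad$penalty, 0)
})
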