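test_that("pattern generation is seeded and respects the overlap bound", {
  a <- generate_patterns(256, 4, seed = 42)
  b <- generate_patterns(256, 4, seed = 42)
  expect_identical(a, b)
  for (u in 1:3) for (w in (u + 1):4)
    expect_lte(abs(sum(a[[u]] * a[[w]])) / 256, 0.25)
  expect_true(all(unlist(a) %in% c(-1, 1)))
  # overlap bound 1 never rejects; impossible bound errors out
  expect_length(generate_patterns(64, 3, seed = 1, max_pairwise_overlap = 1), 3)
  expect_error(generate_patterns(4, 6, seed = 1, max_pairwise_overlap = 0,
                                 max_tries = 20), "budget")
})

test_that("pixel flipping negates exactly the requested fraction", {
  p <- generate_patterns(256, 1, seed = 13)[[1]]
  expect_identical(flip_pixels(p, 0), p)
  expect_identical(flip_pixels(p, 1), -p)
  f <- flip_pixels(p, 0.1, seed = 2)
  expect_equal(sum(f != p), 26)   # round(0.1 * 256)
  # same seed, same flips
  expect_identical(flip_pixels(p, 0.1, seed = 2), f)
})

test_that("pattern grid files round-trip through the #/. format", {
  p <- generate_patterns(16, 1, seed = 3)[[1]]
  path <- tempfile(fileext = ".txt")
  write_pattern(p, path)
  expect_equal(read_pattern(path), p)
  writeLines(c("#.", "#x"), path)
  expect_error(read_pattern(path), "characters")
})

test_that("spike phases interpolate linearly between bracketing spikes", {
  train <- list(seq(0, 1, by = 0.1))
  expect_equal(spike_phases(train, 0.5), 0)
  expect_equal(spike_phases(train, 0.55), pi)
  # advances linearly across an ISI
  ts <- seq(0.5, 0.6, by = 0.01)
  ph <- vapply(ts, function(t) spike_phases(train, t), numeric(1))
  expect_equal(ph, 2 * pi * (ts - 0.5) / 0.1, tolerance = 1e-10)
  # undefined outside the bracketing range or with < 2 spikes
  expect_true(is.na(spike_phases(list(c(0.2)), 0.5)))
  expect_true(is.na(spike_phases(train, 1.5)))
})

test_that("overlap index and PSI behave as circular order parameters", {
  N <- 256
  pat <- rep(c(1, -1), length.out = N)
  # anti-phase groups arranged by the pattern give overlap 1
  th <- ifelse(pat > 0, 0.7, 0.7 + pi)
  expect_equal(overlap_index(th, pat), 1, tolerance = 1e-12)
  expect_equal(psi(th, moment = 2), 1, tolerance = 1e-12)
  # all in phase: balanced pattern cancels, PSI is 1
  th1 <- rep(1.2, N)
  expect_equal(overlap_index(th1, pat), 0, tolerance = 1e-12)
  expect_equal(psi(th1), 1)
  # half at 0, half at pi: first-moment PSI cancels
  expect_equal(psi(th), 0, tolerance = 1e-12)
  # uniform random phases: Rayleigh expectation ~ sqrt(pi/(4N)) ~ 0.055
  set.seed(14)
  ms <- replicate(100, overlap_index(runif(N, 0, 2 * pi), pat))
  expect_lt(mean(ms), 0.1)
  ps <- replicate(100, psi(runif(N, 0, 2 * pi)))
  expect_lt(mean(ps), 0.1)
  # invariance under a global phase shift
  th2 <- runif(N, 0, 2 * pi)
  expect_equal(overlap_index(th2, pat), overlap_index((th2 + 1.1) %% (2 * pi),
                                                      pat), tolerance = 1e-12)
  expect_equal(psi(th2), psi((th2 + 1.1) %% (2 * pi)), tolerance = 1e-12)
  # masking contract
  expect_error(overlap_index(rep(NA_real_, 4), rep(1, 4)), "undefined")
})

test_that("an uncoupled network of identical neurons stays synchronized", {
  pats <- small_patterns(N = 32L, count = 1L)
  ones <- list(rep(1, 32))
  cfg <- retrieval_config(mode = "class1", T_total = 1.5,
                          pulse_steps = 10L)
  r <- simulate_assoc_network(matrix(0, 32, 32), ones, ones[[1]], cfg,
                              correct_u = 1)
  # every neuron got the same pulse and the same input: identical trains
  expect_true(all(vapply(r$spikes, function(s)
    isTRUE(all.equal(s, r$spikes[[1]])), logical(1))))
  md <- r$metrics
  expect_gt(mean(md$PSI, na.rm = TRUE), 0.99)
})

test_that("network simulation is deterministic", {
  pats <- generate_patterns(64, 2, seed = 21)
  W <- correlation_weights(pats)
  cfg <- retrieval_config(mode = "class1", T_total = 1, c_scale = 0.02)
  r1 <- simulate_assoc_network(W, pats, pats[[1]], cfg, correct_u = 1)
  r2 <- simulate_assoc_network(W, pats, pats[[1]], cfg, correct_u = 1)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("a stored pattern is retrieved and held from a clean input", {
  pats <- generate_patterns(256, 4, seed = 42)
  W <- correlation_weights(pats)
  cfg <- retrieval_config(mode = "class1")
  r <- simulate_assoc_network(W, pats, pats[[2]], cfg, correct_u = 2)
  md <- r$metrics
  final <- md$t >= cfg$T_total / 2
  expect_true(all(md$M_2[final] > cfg$theta_M, na.rm = TRUE))
  expect_true(isTRUE(r$success))
  expect_false(isTRUE(r$anti))
})
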