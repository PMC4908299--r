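test_that("kinetic synapse rises to 1, decays exponentially, stays in [0,1]", {
  p <- synapse_params(alpha = 450, beta = 100)
  # held depolarized: fixed point at 1
  s <- 0
  for (i in 1:2000) s <- synapse_step(s, p, v_pre = 1, dt = 375e-6)
  expect_equal(s, 1, tolerance = 1e-6)
  # decay from 1: Euler at dt = 375 us within 2% of exp(-beta t) at 10 ms
  s <- 1
  n_steps <- round(0.01 / 375e-6)
  for (i in seq_len(n_steps)) s <- synapse_step(s, p, v_pre = -1, dt = 375e-6)
  expect_equal(s, exp(-100 * n_steps * 375e-6), tolerance = 0.02)
  # zero state is invariant under hyperpolarization
  expect_equal(synapse_step(0, p, -1, 375e-6), 0)
  # forward invariance under an arbitrary v sequence
  set.seed(8)
  s <- runif(1)
  for (v in rnorm(500)) {
    s <- synapse_step(s, p, v, 375e-6)
    expect_true(s >= 0 && s <= 1)
  }
  expect_error(synapse_step(0.5, p, 1, dt = 1), "unstable")
})

test_that("the accumulator computes the weighted synaptic sum", {
  # W = 0 passes the external stimulus through
  expect_equal(accumulate(matrix(0, 3, 3), 2, c(0.1, 0.2, 0.3),
                          c(1, 2, 3)), c(1, 2, 3))
  # hand arithmetic, N = 2
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(accumulate(W, 2, c(0.5, 0.25), 0), c(0.5, 1.0))
  # random instance vs a naive double loop, exact
  set.seed(9)
  N <- 17
  W <- matrix(rnorm(N * N), N, N); diag(W) <- 0
  Is <- runif(N); Ie <- rnorm(N)
  loop <- numeric(N)
  for (j in 1:N) {
    acc <- 0
    for (i in 1:N) acc <- acc + W[j, i] * Is[i]
    loop[j] <- Ie[j] + 0.7 * acc
  }
  expect_equal(accumulate(W, 0.7, Is, Ie), loop)
})

test_that("the exponential learning curve is even with the closed-form root", {
  p <- suppressWarnings(stdp_params(1.0, 0.5, 0.010, 0.020))
  expect_equal(stdp_delta(p, 0), 0.5)
  expect_lt(abs(stdp_delta(p, 20 * 0.020)), 1e-6)
  tstar <- log(1.0 / 0.5) / (1 / 0.010 - 1 / 0.020)
  expect_equal(tstar, 0.013863, tolerance = 1e-4)
  expect_lt(abs(stdp_delta(p, tstar)), 1e-9)
  # even in delta t; positive inside |dt| < t*, negative beyond
  dts <- seq(-0.05, 0.05, by = 1e-3)
  expect_equal(stdp_delta(p, dts), stdp_delta(p, -dts))
  expect_true(all(stdp_delta(p, dts[abs(dts) < tstar - 1e-6]) > 0))
  expect_true(all(stdp_delta(p, dts[abs(dts) > tstar + 1e-6]) < 0))
  expect_warning(stdp_params(0.5, 1.0, 0.020, 0.010), "Mexican-hat")
})

test_that("nearest-neighbour pairing picks the closest presynaptic spike", {
  expect_equal(nearest_pair_deltas(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  # j at 10 ms, i at {4, 25} ms: nearest is 4 ms, signed +6 ms
  expect_equal(nearest_pair_deltas(0.010, c(0.004, 0.025)), 0.006)
  expect_length(nearest_pair_deltas(numeric(), c(1, 2)), 0)
  expect_length(nearest_pair_deltas(c(1, 2), numeric()), 0)
  # agrees with the compiled batch version
  set.seed(10)
  tj <- sort(runif(15)); ti <- sort(runif(12))
  p <- suppressWarnings(stdp_params(1, 0.5, 0.01, 0.02))
  dW <- qsn:::stdp_dw_cpp(list(tj, ti), 1, 0.5, 0.01, 0.02)
  expect_equal(dW[1, 2], sum(stdp_delta(p, nearest_pair_deltas(tj, ti))),
               tolerance = 1e-12)
})

test_that("correlation storage is the scaled outer product with zero diagonal", {
  # the canonical 4-pattern case has entries on the quarter grid
  pats <- generate_patterns(16, 4, seed = 11, max_pairwise_overlap = 1)
  W <- correlation_weights(pats)
  expect_true(all(diag(W) == 0))
  expect_true(all(W %in% c(-1, -0.5, 0, 0.5, 1)))
  expect_equal(W, t(W))
  # identical all-ones patterns saturate every off-diagonal entry
  ones <- replicate(4, rep(1, 8), simplify = FALSE)
  W1 <- correlation_weights(ones)
  expect_true(all(W1[upper.tri(W1)] == 1))
  # hand sum: (1*1 + 1*(-1) + 1*(-1) + 1*1)/4 = 0
  ps <- list(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1),
             c(1, 1, 1, 1))
  expect_equal(correlation_weights(ps)[1, 2], 0)
  expect_error(correlation_weights(list(c(1, 0, -1))), "valued")
})

test_that("STDP training saturates a forced-synchrony pair and errors on a
           degenerate rule", {
  m <- qsn_preset("dssn_class1")
  pats2 <- list(c(1, 1), c(1, -1))
  cfg <- retrieval_config(model = m, T_total = 0.4, I_ext = 0.1,
                          c_scale = 0, pulse_steps = 10L)
  # two neurons driven identically fire synchronously: their weight grows
  # monotonically to saturation and training stops there
  p <- suppressWarnings(stdp_params(0.05, 0.02, 0.002, 0.05))
  out <- stdp_training(m, pats2, p, cfg, max_presentations = 60L)
  expect_true(out$saturated)
  expect_equal(max(abs(out$W)), 1)
  expect_true(all(diff(out$log$max_abs_W) >= 0))
  # A+ = A-, tau+ = tau-: the learning curve is identically zero and the
  # presentation budget runs out
  pz <- suppressWarnings(stdp_params(0.05, 0.05, 0.01, 0.01))
  expect_error(stdp_training(m, pats2, pz, cfg, max_presentations = 6L),
               "did not saturate")
})
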