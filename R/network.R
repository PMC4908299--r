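#' Retrieval protocol configuration
#'
#' Bundles the run protocol of the auto-associative retrieval experiment:
#' the neuron mode, the integration step (375 us), the sustained stimulus
#' that keeps every neuron repetitively spiking, the initial phase-seed
#' pulse applied only to the +1 pixels of the input pattern, the
#' accumulator scaling, and the success thresholds.
#'
#' @param mode "class1" or "class2": selects the digital-neuron preset and
#'   its characterized sustained stimulus, unless `model`/`I_ext` are given
#'   explicitly.
#' @param model Optional [dssn()] model overriding the preset.
#' @param dt Integration step (seconds; default 375 us).
#' @param T_total Total run length (seconds).
#' @param I_ext Sustained stimulus amplitude (dimensionless); default from
#'   the preset's characterization.
#' @param pulse_amp Phase-seed pulse amplitude (default 2 * I_ext).
#' @param pulse_steps Phase-seed pulse length in steps (default 5).
#' @param c_scale Accumulator scaling `c`.
#' @param alpha,beta Synapse rates (1/s).
#' @param theta_M Success threshold on the correct overlap (default 0.8).
#' @param theta_other Ceiling on the other overlaps (default 0.5).
#' @param metric_dt Metric sampling interval (seconds).
#' @return An object of class `retrieval_config`.
#' @export
retrieval_config <- function(mode = c("class2", "class1"), model = NULL,
                             dt = 375e-6, T_total = 3,
                             I_ext = NULL, pulse_amp = NULL,
                             pulse_steps = 20L, c_scale = NULL,
                             alpha = 3000, beta = 400,
                             theta_M = 0.8, theta_other = 0.5,
                             metric_dt = 5e-3) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, theta_M > 0, theta_M < 1)
  if (is.null(model)) model <- qsn_preset(paste0("dssn_", mode))
  if (is.null(I_ext)) I_ext <- attr(model, "sustained_I")
  if (is.null(I_ext)) stop("I_ext not given and preset has no sustained_I")
  if (is.null(pulse_amp)) pulse_amp <- 2 * I_ext
  if (is.null(c_scale)) c_scale <- attr(model, "c_scale")
  if (is.null(c_scale)) c_scale <- 0.1 * I_ext
  structure(list(mode = mode, model = model, dt = dt, T_total = T_total,
                 I_ext = I_ext, pulse_amp = pulse_amp,
                 pulse_steps = as.integer(pulse_steps), c_scale = c_scale,
                 alpha = alpha, beta = beta, theta_M = theta_M,
                 theta_other = theta_other, metric_dt = metric_dt),
            class = "retrieval_config")
}

#' Spike phases at given times
#'
#' The phase of neuron `j` at time `t` interpolates linearly between its
#' bracketing spikes: `theta_j(t) = 2 pi (t - t_last) / (t_next - t_last)`,
#' in [0, 2 pi). Neurons without two bracketing spikes are masked (NA).
#'
#' @param trains List of sorted spike-time vectors.
#' @param t A single time.
#' @return Numeric vector of phases (NA where undefined).
#' @export
spike_phases <- function(trains, t) {
  vapply(trains, function(tr) {
    if (length(tr) < 2L) return(NA_real_)
    i <- findInterval(t, tr)
    if (i < 1L || i >= length(tr)) return(NA_real_)
    ph <- 2 * pi * (t - tr[i]) / (tr[i + 1L] - tr[i])
    ph %% (2 * pi)
  }, numeric(1))
}

#' Pattern overlap index M_u
#'
#' The pattern-weighted circular order parameter
#' `M_u = |(1/N') sum_j x_j^u exp(i theta_j)|` over the `N'` unmasked
#' neurons: 0 when the spiking phases have no relation to the pattern, and
#' approaching 1 when the +1 and -1 pixel groups spike in anti-phase
#' according to the pattern.
#'
#' @param theta Phase vector (radians; NA = masked).
#' @param pattern A +-1 vector of the same length.
#' @return `M_u` in \[0, 1\]. Error if every neuron is masked.
#' @export
overlap_index <- function(theta, pattern) {
  stopifnot(length(theta) == length(pattern))
  ok <- !is.na(theta)
  if (!any(ok)) stop("all phases undefined")
  Mod(mean(pattern[ok] * exp(1i * theta[ok])))
}

#' Phase synchronization index (circular order parameter)
#'
#' `PSI = |(1/N') sum_j exp(i m theta_j)|`: 0 for fully asynchronous
#' spiking and approaching 1 as the spike timing synchronizes. `m = 1` is
#' the Kuramoto order parameter; `m = 2` is the two-cluster order
#' parameter, which also approaches 1 when the network fires in two
#' anti-phase groups - the configuration a retrieved bipolar pattern
#' produces, in which the first-moment index cancels to ~0 for a balanced
#' pattern. Retrieval metrics therefore report both (`PSI`, `PSI2`).
#'
#' @param theta Phase vector (radians; NA = masked).
#' @param moment Circular moment `m` (default 1).
#' @return PSI in \[0, 1\]. Error if every neuron is masked.
#' @export
psi <- function(theta, moment = 1) {
  ok <- !is.na(theta)
  if (!any(ok)) stop("all phases undefined")
  Mod(mean(exp(1i * moment * theta[ok])))
}

#' Simulate the all-to-all associative network and score retrieval
#'
#' Co-simulates N digital neurons, one kinetic synapse per neuron, and the
#' weighted accumulator by forward Euler at a common step. Protocol: a
#' short positive pulse is applied for `pulse_steps` steps only to the
#' neurons whose input-pattern pixel is +1 (arranging the initial spiking
#' phases), then the sustained stimulus `I_ext` drives every neuron. The
#' overlap indices `M_u` for every stored pattern and the synchronization
#' index PSI are sampled every `metric_dt`.
#'
#' Success verdict: the overlap with the correct pattern exceeds
#' `theta_M` while every other overlap stays below `theta_other`,
#' throughout the final half of the run. Retrieval of the reversed pattern
#' (the sign structure inverted relative to the phase seed) is reported in
#' `anti` and not counted as success.
#'
#' @param W N x N weight matrix.
#' @param patterns List of stored +-1 patterns.
#' @param input_pattern The (possibly corrupted) +-1 input pattern.
#' @param cfg A [retrieval_config()].
#' @param correct_u Index of the pattern the input derives from (default:
#'   highest input overlap).
#' @param metrics Compute metric time series (set FALSE inside training
#'   loops that only need the spike trains).
#' @return List of class `retrieval_result`: `spikes` (list of spike
#'   trains), `metrics` (data frame `t`, `M_1`.., `PSI`), `success`,
#'   `retrieved` (index or NA), `anti` (logical), `correct_u`.
#' @export
simulate_assoc_network <- function(W, patterns, input_pattern, cfg,
                                   correct_u = NULL, metrics = TRUE) {
  model <- cfg$model
  N <- length(input_pattern)
  stopifnot(is.matrix(W), nrow(W) == N, ncol(W) == N)
  if (is.null(correct_u))
    correct_u <- which.max(vapply(patterns, function(p)
      sum(p * input_pattern), numeric(1)))
  n_steps <- as.integer(round(cfg$T_total / cfg$dt))
  # all neurons start identically at the zero-stimulus rest state; during
  # the seed window only the +1-pixel neurons are driven (and start
  # spiking), then the sustained stimulus reaches every neuron
  rest <- .rest_state(model, 0)
  v0 <- rest[["v"]]
  res <- assoc_net_cpp(.dssn_param_vec(model), W, cfg$c_scale,
                       cfg$alpha, cfg$beta,
                       rep(cfg$I_ext, N),
                       ifelse(input_pattern > 0, cfg$pulse_amp, 0),
                       cfg$pulse_steps, cfg$dt, n_steps,
                       rep(v0, N), rep(rest[["n"]], N),
                       numeric(N), 100)
  spikes <- res$spikes
  n_sp <- lengths(spikes)
  if (!any(n_sp > 0))
    stop("silent network: no neuron spiked during the sustained phase")
  out <- list(spikes = spikes, correct_u = correct_u)
  if (metrics) {
    # stop a few inter-spike intervals short of the end: a phase needs a
    # later bracketing spike, so the trailing edge is always masked
    ts <- seq(cfg$metric_dt, cfg$T_total - 0.08, by = cfg$metric_dt)
    P <- length(patterns)
    M <- matrix(NA_real_, length(ts), P)
    PSIv <- PSI2v <- rep(NA_real_, length(ts))
    align <- rep(NA_real_, length(ts))
    seeded <- input_pattern > 0
    for (k in seq_along(ts)) {
      th <- spike_phases(spikes, ts[k])
      # masked (non-spiking) neurons are excluded from the indices; a row
      # needs a nontrivial spiking subpopulation to be meaningful at all
      if (mean(!is.na(th)) < 0.1) next
      for (u in seq_len(P)) M[k, u] <- overlap_index(th, patterns[[u]])
      PSIv[k] <- psi(th)
      PSI2v[k] <- psi(th, moment = 2)
      # sign of the correct pattern's order parameter relative to the
      # seeded (+1-input) group: negative means the reversed pattern
      ok <- !is.na(th)
      Zu <- mean(patterns[[correct_u]][ok] * exp(1i * th[ok]))
      Zs <- mean(exp(1i * th[ok & seeded]))
      align[k] <- Re(Zu * Conj(Zs))
    }
    mdf <- data.frame(t = ts, M, PSI = PSIv, PSI2 = PSI2v)
    names(mdf) <- c("t", paste0("M_", seq_len(P)), "PSI", "PSI2")
    final <- ts >= cfg$T_total / 2
    okf <- final & !is.na(PSIv)
    held <- function(u) all(M[okf, u] > cfg$theta_M)
    others_low <- all(M[okf, -correct_u, drop = FALSE] < cfg$theta_other)
    correct_held <- any(okf) && held(correct_u)
    anti <- correct_held && mean(align[okf]) < 0
    success <- correct_held && others_low && !anti
    retrieved <- if (any(okf)) {
      cand <- which(vapply(seq_len(P), held, logical(1)))
      if (length(cand) == 1L) cand else NA_integer_
    } else NA_integer_
    out$metrics <- mdf
    out$success <- success
    out$retrieved <- retrieved
    out$anti <- anti
  }
  class(out) <- "retrieval_result"
  out
}

#' Error-level sweep of retrieval performance
#'
#' Runs seeded retrieval trials at each error level (fraction of flipped
#' pixels) and tabulates the success rate. Defaults mirror the reference
#' protocol: levels 5-50% in 5% steps, 10 trials per level; each trial
#' corrupts a cyclically chosen stored pattern with a trial-specific seed.
#'
#' @param patterns Stored patterns.
#' @param W Weight matrix (e.g. [correlation_weights()] of `patterns`).
#' @param cfg A [retrieval_config()].
#' @param error_levels Fractions in (0, 1).
#' @param trials_per_level Trials per level.
#' @param seed Base seed; trial seeds derive deterministically from it.
#' @return Data frame with `error_level`, `successes`, `trials`, `rate`.
#' @export
error_sweep <- function(patterns, W, cfg,
                        error_levels = seq(0.05, 0.5, by = 0.05),
                        trials_per_level = 10L, seed = 1L) {
  out <- vector("list", length(error_levels))
  for (li in seq_along(error_levels)) {
    lev <- error_levels[li]
    succ <- 0L
    for (tr in seq_len(trials_per_level)) {
      u <- ((tr - 1L) %% length(patterns)) + 1L
      trial_seed <- (seed * 1000L + li * 100L + tr) %% .Machine$integer.max
      input <- flip_pixels(patterns[[u]], lev, seed = trial_seed)
      r <- simulate_assoc_network(W, patterns, input, cfg, correct_u = u)
      if (isTRUE(r$success)) succ <- succ + 1L
    }
    out[[li]] <- data.frame(error_level = lev, successes = succ,
                            trials = trials_per_level,
                            rate = succ / trials_per_level)
  }
  do.call(rbind, out)
}
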