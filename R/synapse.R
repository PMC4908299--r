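#' Kinetic silicon synapse
#'
#' The silicon synapse integrates the presynaptic membrane potential into a
#' postsynaptic stimulus variable `I_s` in \[0, 1\]:
#' \deqn{dI_s/dt = \alpha (1 - I_s) \text{ when } v \ge 0, \quad
#'       -\beta I_s \text{ when } v < 0,}
#' solved by forward Euler at the network step. The rise toward 1 during a
#' (suprathreshold) spike and exponential decay afterwards follow the
#' kinetic description of transmitter release, and let the synapse carry the
#' analog information of graded Class II spikes.
#'
#' @param alpha,beta Rise and decay rates (1/seconds, > 0).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "synapse_params")
}

#' One forward-Euler step of the synapse state
#'
#' @param I_s Current synapse state(s) in \[0, 1\].
#' @param p A [synapse_params()].
#' @param v_pre Presynaptic membrane potential(s) (the `v >= 0` branch is
#'   the transmitter-release phase).
#' @param dt Step (seconds); must satisfy `dt * max(alpha, beta) < 1`.
#' @return Updated state(s), clipped to \[0, 1\].
#' @export
synapse_step <- function(I_s, p, v_pre, dt) {
  stopifnot(dt > 0)
  if (dt * max(p$alpha, p$beta) >= 1)
    stop("unstable Euler step: dt * max(alpha, beta) must be < 1")
  out <- ifelse(v_pre >= 0,
                I_s + dt * p$alpha * (1 - I_s),
                I_s - dt * p$beta * I_s)
  pmin(pmax(out, 0), 1)
}

#' Weighted synaptic accumulation
#'
#' The accumulator computes each neuron's stimulus input
#' `I_stim_j = I_ext_j + c * sum_i W[j, i] * I_s_i`.
#'
#' @param W N x N weight matrix, `W[j, i]` = weight from presynaptic `i` to
#'   postsynaptic `j`.
#' @param c_scale Scaling parameter `c`.
#' @param I_s Length-N vector of synapse states.
#' @param I_ext Length-N vector of external stimuli (default 0).
#' @return Length-N vector of stimulus inputs.
#' @export
accumulate <- function(W, c_scale, I_s, I_ext = 0) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), nrow(W) == length(I_s))
  if (length(I_ext) == 1L) I_ext <- rep(I_ext, length(I_s))
  stopifnot(length(I_ext) == length(I_s))
  drop(I_ext + c_scale * (W %*% I_s))
}

#' Exponential spike-timing-dependent learning rule
#'
#' `stdp_params()` holds the amplitudes and time constants of the
#' exponential-difference learning curve
#' \deqn{\Delta W = A_+ e^{-|\Delta t|/\tau_+} - A_- e^{-|\Delta t|/\tau_-},}
#' which is even in the spike-time difference and Mexican-hat-shaped
#' (positive inside `|Delta t| < t*`, negative beyond) when `A_+ > A_-` and
#' `tau_+ < tau_-`; a warning is given otherwise. The zero crossing is at
#' `t* = log(A_+/A_-) / (1/tau_+ - 1/tau_-)`.
#'
#' @param A_plus,A_minus Amplitudes (> 0).
#' @param tau_plus,tau_minus Time constants (seconds, > 0).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A_plus, A_minus, tau_plus, tau_minus) {
  stopifnot(A_plus > 0, A_minus > 0, tau_plus > 0, tau_minus > 0)
  if (!(A_plus > A_minus && tau_plus < tau_minus))
    warning("Mexican-hat shape requires A_plus > A_minus and tau_plus < tau_minus")
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "stdp_params")
}

#' @rdname stdp_params
#' @param p An `stdp_params` object.
#' @param delta_t Spike-time difference(s) (seconds, any sign).
#' @return `stdp_delta()`: the weight change(s).
#' @export
stdp_delta <- function(p, delta_t) {
  a <- abs(delta_t)
  p$A_plus * exp(-a / p$tau_plus) - p$A_minus * exp(-a / p$tau_minus)
}

#' Nearest-neighbour spike-pair time differences
#'
#' For each spike of the postsynaptic train `train_j`, the signed time to
#' the nearest spike of the presynaptic train `train_i`
#' (`delta_t = t_j - t_i`). The learning curve is even in `delta_t`, so the
#' sign convention does not affect the applied weight change.
#'
#' @param train_j,train_i Sorted spike-time vectors.
#' @return Numeric vector of signed differences, one per spike of `j`
#'   (empty if either train is empty).
#' @export
nearest_pair_deltas <- function(train_j, train_i) {
  if (!length(train_j) || !length(train_i)) return(numeric())
  idx <- findInterval(train_j, train_i)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(train_i))
  d_lo <- train_j - train_i[lo]
  d_hi <- train_j - train_i[hi]
  ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
}

#' Correlation (outer-product) storage of bipolar patterns
#'
#' Hebbian one-shot storage:
#' `W[i, j] = (1/P) * sum_u x_i^u x_j^u` for `i != j`, zero on the
#' diagonal. For the canonical four stored patterns the divisor is 4 and
#' the entries lie in {-1, -0.5, 0, 0.5, 1}; other pattern counts use
#' `1/P`.
#'
#' @param patterns List of +-1 vectors of a common length.
#' @return Symmetric N x N matrix with zero diagonal, entries in \[-1, 1\].
#' @examples
#' pats <- replicate(4, sample(c(-1, 1), 16, TRUE), simplify = FALSE)
#' W <- correlation_weights(pats)
#' @export
correlation_weights <- function(patterns) {
  stopifnot(length(patterns) >= 1L)
  X <- do.call(cbind, patterns)
  if (!all(X %in% c(-1, 1))) stop("patterns must be +-1 valued")
  W <- X %*% t(X) / length(patterns)
  diag(W) <- 0
  W
}

#' Train the network weights with the STDP rule
#'
#' Presents the stored patterns to a running network in the block schedule
#' pattern, reversed pattern, repeated `reps_per_block` times, cycling over
#' all patterns, and after each presentation applies the learning curve
#' over the nearest-neighbour spike pairings of every ordered neuron pair,
#' clipping weights to \[-1, 1\]. Training stops as soon as any `|W[i, j]|`
#' reaches 1 (weight saturation); exhausting `max_presentations` first is
#' an error carrying diagnostics.
#'
#' @param model A [dssn()] model (the network neuron).
#' @param patterns List of stored +-1 patterns.
#' @param p [stdp_params()].
#' @param cfg A [retrieval_config()] providing the run protocol.
#' @param W0 Initial weight matrix (default zero).
#' @param reps_per_block Pattern/anti-pattern repetitions per block.
#' @param max_presentations Presentation budget.
#' @param clamp Disable the recurrent accumulator during the training
#'   presentations (teacher clamping, default TRUE): the spike phases then
#'   follow the applied pattern alone, so every stored pattern is imprinted
#'   with equal strength. With `clamp = FALSE` the evolving weights feed
#'   back during training, which lets an early-stored pattern capture the
#'   dynamics and monopolize the weights.
#' @param seed Integer seed (reserved; presentations are deterministic).
#' @return List of class `stdp_training`: `W`, `presentations`,
#'   `saturated` (TRUE), `log` (per-presentation max |W| and mean |dW|).
#' @export
stdp_training <- function(model, patterns, p, cfg,
                          W0 = NULL, reps_per_block = 8L,
                          max_presentations = 400L, clamp = TRUE,
                          seed = 1L) {
  N <- length(patterns[[1L]])
  if (is.null(W0)) W0 <- matrix(0, N, N)
  W <- W0
  train_cfg <- cfg
  if (clamp) train_cfg$c_scale <- 0
  schedule <- list()
  for (u in seq_along(patterns)) {
    for (r in seq_len(reps_per_block)) {
      schedule[[length(schedule) + 1L]] <- patterns[[u]]
      schedule[[length(schedule) + 1L]] <- -patterns[[u]]
    }
  }
  log <- list()
  pres <- 0L
  repeat {
    for (pat in schedule) {
      pres <- pres + 1L
      sim <- simulate_assoc_network(W, patterns, pat, train_cfg,
                                    metrics = FALSE)
      dW <- stdp_dw_cpp(sim$spikes, p$A_plus, p$A_minus,
                        p$tau_plus, p$tau_minus)
      diag(dW) <- 0
      W <- pmin(pmax(W + dW, -1), 1)
      log[[length(log) + 1L]] <- data.frame(
        presentation = pres, max_abs_W = max(abs(W)),
        mean_abs_dW = mean(abs(dW)))
      if (max(abs(W)) >= 1)
        return(structure(list(W = W, presentations = pres, saturated = TRUE,
                              log = do.call(rbind, log)),
                         class = "stdp_training"))
      if (pres >= max_presentations)
        stop(sprintf(paste0("STDP training did not saturate within %d ",
                            "presentations (max |W| = %.4f, last mean ",
                            "|dW| = %.3g)"),
                     max_presentations, max(abs(W)),
                     log[[length(log)]]$mean_abs_dW))
    }
  }
}
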