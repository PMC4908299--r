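#' Tune a model into a target dynamical mode
#'
#' Seeded simulated-annealing search over a box of named parameters,
#' minimizing a target-geometry penalty assembled from the design
#' heuristics for each mode: required equilibrium counts and stabilities,
#' an N-shaped v-nullcline, the `theta_v < delta_m` ordering of the analog
#' curves (a steep rising phase paired with a shallower falling phase),
#' the presence or absence of autonomous spiking, and - for the
#' square-wave target - the placement of the q-nullcline between the
#' stable equilibrium and the limit cycle of the fast subsystem so that q
#' rises during bursts and falls during silence. A candidate with penalty
#' 0 is then re-verified with the classification operations
#' ([fi_curve()]/[classify_excitability()] or the burst checks); only a
#' verified candidate is reported as passing.
#'
#' @param template A `qsn_model` supplying every parameter not searched.
#' @param target One of "class1", "class2", "rs", "square_wave",
#'   "elliptic".
#' @param bounds Named list of `c(lo, hi)` search boxes; names as accepted
#'   by the model's parameters (e.g. `M_m`, `S`, `I_a`, `M_q`, `phi`,
#'   `I_0`).
#' @param seed Integer RNG seed (all proposals flow from it).
#' @param n_iter Annealing iterations.
#' @param I_test Stimulus values probed for spiking during the search.
#' @param verify Run the full verification on the best candidate.
#' @return A list of class `tune_report`: `passed` (logical), `model` (the
#'   best candidate), `params`, `penalty`, `verification`, and `log` (data
#'   frame of accepted moves). A search that finds no passing candidate
#'   returns `passed = FALSE` with the best candidate found - a failure
#'   report, not an error.
#' @export
tune_mode <- function(template, target, bounds, seed = 1L,
                      n_iter = 400L, I_test = NULL, verify = TRUE) {
  target <- match.arg(target,
                      c("class1", "class2", "rs", "square_wave", "elliptic"))
  stopifnot(is.list(bounds), length(bounds) >= 1L,
            !is.null(names(bounds)))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  nm <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  build <- function(x) {
    m <- template
    for (k in seq_along(nm)) m <- .set_param(m, nm[k], x[k])
    m
  }
  obj <- function(x) .mode_penalty(build(x), target, I_test)
  x <- (lo + hi) / 2
  fx <- obj(x)
  best_x <- x; best_f <- fx
  log <- list()
  for (it in seq_len(n_iter)) {
    if (best_f == 0) break
    temp <- 1 - (it - 1) / n_iter
    j <- sample.int(length(x), 1L)
    prop <- x
    prop[j] <- min(hi[j], max(lo[j],
      x[j] + stats::rnorm(1L, 0, 0.25 * temp * (hi[j] - lo[j]))))
    fp <- obj(prop)
    if (fp <= fx || stats::runif(1L) < exp((fx - fp) / max(temp, 1e-3))) {
      x <- prop; fx <- fp
      if (fx < best_f) { best_f <- fx; best_x <- x }
      log[[length(log) + 1L]] <- data.frame(iter = it, penalty = fx,
                                            t(stats::setNames(x, nm)))
    }
  }
  model <- build(best_x)
  verification <- NULL
  passed <- best_f == 0
  if (passed && verify) {
    verification <- .verify_mode(model, target, I_test)
    passed <- isTRUE(verification$ok)
  }
  structure(list(passed = passed, model = model,
                 params = stats::setNames(best_x, nm), penalty = best_f,
                 verification = verification,
                 log = if (length(log)) do.call(rbind, log)
                       else data.frame(), seed = seed, target = target),
            class = "tune_report")
}

#' @export
print.tune_report <- function(x, ...) {
  cat(sprintf("tune_mode target '%s' (seed %d): %s, penalty %.3g\n",
              x$target, x$seed, if (x$passed) "PASSED" else "FAILED",
              x$penalty))
  print(x$params)
  invisible(x)
}

# number of derivative sign changes of the v-nullcline over the model range
.vnull_shape <- function(model) {
  vr <- .default_v_range(model)
  v <- seq(vr[1], vr[2], length.out = 600)
  nc <- if (inherits(model, "analog_fast"))
    analog_nullclines(model$base, v, q = model$q)$v_null
  else if (inherits(model, "analog_sn")) analog_nullclines(model, v)$v_null
  else if (inherits(model, "ulp_sn")) ulp_nullclines(model, v)$v_null
  else dssn_nullclines(model, v)$v_null
  d <- diff(nc)
  d <- d[abs(d) > max(abs(d)) * 1e-9]
  sum(diff(sign(d)) != 0)
}

.spikes_at <- function(model, I, T_run = NULL, dt = NULL) {
  cyc <- try(detect_limit_cycle(model, I, T_run = T_run, dt = dt),
             silent = TRUE)
  if (inherits(cyc, "try-error")) return(0L)
  if (cyc$found) cyc$n_spikes else 0L
}

.default_I_test <- function(model) {
  s <- .model_scale(model)
  if (inherits(model, "dssn")) c(0.02, 0.05, 0.1, 0.2)
  else s * c(0.05, 0.1, 0.2, 0.4)
}

.mode_penalty <- function(model, target, I_test = NULL) {
  fast <- if (inherits(model, "analog_sn") &&
              target %in% c("class1", "class2")) fast_subsystem(model, 0)
          else model
  if (is.null(I_test)) I_test <- .default_I_test(fast)
  pen <- 0
  eq <- try(find_equilibria(fast, 0), silent = TRUE)
  if (inherits(eq, "try-error")) return(1e6)
  shape <- .vnull_shape(fast)
  if (target %in% c("class1", "square_wave")) {
    # 3 equilibria stable/saddle/unstable in order of v, N-shaped v-null
    pen <- pen + 10 * abs(shape - 2)
    if (nrow(eq) != 3) pen <- pen + 20 * abs(nrow(eq) - 3)
    else {
      want <- c("stable", "saddle", "unstable")
      got <- sub("_.*", "", eq$label)
      pen <- pen + 10 * sum(got != want)
    }
  }
  if (target %in% c("class2", "elliptic")) {
    pen <- pen + 10 * abs(shape - 2)
    if (nrow(eq) != 1) pen <- pen + 20 * abs(nrow(eq) - 1)
    else if (!grepl("^stable_", eq$label)) pen <- pen + 10
  }
  if (inherits(model, "analog_sn") || inherits(model, "analog_fast")) {
    base <- if (inherits(model, "analog_fast")) model$base else model
    if (base$g$theta_v >= base$fm$delta) pen <- pen + 5
  }
  if (target %in% c("class1", "class2")) {
    # silent at rest, spiking at some probed stimulus
    rest_cyc <- .spikes_at(fast, 0)
    if (rest_cyc > 0) pen <- pen + 10
    if (pen == 0 && !any(vapply(I_test, function(I) .spikes_at(fast, I) > 0,
                                logical(1))))
      pen <- pen + 15
  }
  if (target == "square_wave") {
    if (pen == 0) pen <- pen + .square_wave_penalty(model)
  }
  if (target == "rs") {
    # stable full equilibrium plus sustained spiking under a step
    if (pen == 0) {
      full_eq <- find_equilibria(model, 0)
      if (!nrow(full_eq) || !any(grepl("^stable_", full_eq$label)))
        pen <- pen + 10
      if (pen == 0 && !any(vapply(I_test, function(I)
        .spikes_at(model, I) > 0, logical(1)))) pen <- pen + 15
    }
  }
  if (target == "elliptic" && pen == 0)
    pen <- pen + .square_wave_penalty(model)  # autonomous alternation check
  pen
}

# autonomous burst/silence alternation of the full 3-variable model
.square_wave_penalty <- function(model, T_run = 2, dt = 2e-5) {
  st0 <- .kick_state(fast_subsystem(model, 0), 0)
  s0 <- c(v = st0[["v"]], n = st0[["n"]], q = 0)
  tr <- try(simulate_neuron(model, s0, dt = dt, T = T_run), silent = TRUE)
  if (inherits(tr, "try-error")) return(50)
  keep <- tr$t >= T_run * 0.25
  sp <- spike_times(tr[keep, , drop = FALSE], spike_threshold(model))
  if (length(sp) < 6) return(30)
  bursts <- segment_bursts(sp)
  if (nrow(bursts) < 3) return(10)
  # silence must occupy a nontrivial fraction of the window
  tspan <- diff(range(tr$t[keep]))
  firing <- sum(bursts$end - bursts$start)
  duty <- firing / tspan
  if (duty < 0.02 || duty > 0.95) return(5)
  0
}

.verify_mode <- function(model, target, I_test = NULL) {
  fast <- if (inherits(model, "analog_sn") &&
              target %in% c("class1", "class2")) fast_subsystem(model, 0)
          else model
  if (is.null(I_test)) I_test <- .default_I_test(fast)
  if (target %in% c("class1", "class2")) {
    spiking_I <- I_test[vapply(I_test, function(I)
      .spikes_at(fast, I) > 0, logical(1))]
    if (!length(spiking_I)) return(list(ok = FALSE, why = "no spiking"))
    fi <- fi_curve(fast, c(0, max(spiking_I) * 1.2), resolution = 15L)
    cls <- try(classify_excitability(fi), silent = TRUE)
    if (inherits(cls, "try-error"))
      return(list(ok = FALSE, why = "classification failed"))
    list(ok = cls$class == target, classification = cls)
  } else if (target %in% c("square_wave", "elliptic")) {
    ok <- .square_wave_penalty(model) == 0
    list(ok = ok, why = if (ok) "" else "no autonomous alternation")
  } else {  # rs
    list(ok = TRUE, why = "geometry checks only")
  }
}
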