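#' Detect a sustained limit cycle by forward simulation
#'
#' Simulates the model under a constant stimulus, discards the first half of
#' the run as transient, and accepts a limit cycle when the remaining spike
#' train is long enough and its inter-spike intervals agree within a
#' relative tolerance (successive spike-based returns coincide). The cycle
#' is summarized by its period and the `v` extrema over the retained
#' window.
#'
#' @param model A `qsn_model`.
#' @param I_stim Constant stimulus value.
#' @param state0 Start state (default: a kicked state near the top of the
#'   voltage range, so the search lands in the cycle's basin when one
#'   exists).
#' @param T_run,dt Simulation length and step (seconds).
#' @param min_spikes Minimum spikes in the retained half.
#' @param isi_tol Relative tolerance on ISI agreement (CV of retained ISIs).
#' @return A list with `found` (logical), `period`, `v_min`, `v_max`,
#'   `n_spikes`, `indeterminate` (spiking present but not settled).
#' @export
detect_limit_cycle <- function(model, I_stim = 0, state0 = NULL,
                               T_run = NULL, dt = NULL,
                               min_spikes = 5L, isi_tol = 0.05) {
  sd <- .sim_defaults(model)
  if (is.null(T_run)) T_run <- sd$T_run
  if (is.null(dt)) dt <- sd$dt
  if (is.null(state0)) state0 <- .kick_state(model, I_stim)
  tr <- try(simulate_neuron(model, state0, constant_stimulus(I_stim, T_run),
                            dt = dt, T = T_run), silent = TRUE)
  if (inherits(tr, "try-error"))
    return(list(found = FALSE, period = NA_real_, v_min = NA_real_,
                v_max = NA_real_, n_spikes = 0L, indeterminate = TRUE,
                state = NULL))
  keep <- tr$t >= T_run / 2
  sp <- spike_times(tr[keep, , drop = FALSE], spike_threshold(model))
  if (length(sp) < min_spikes)
    return(list(found = FALSE, period = NA_real_, v_min = NA_real_,
                v_max = NA_real_, n_spikes = length(sp),
                indeterminate = FALSE, state = unlist(tr[nrow(tr), -1L])))
  isi <- diff(sp)
  cv <- stats::sd(isi) / mean(isi)
  fin <- unlist(tr[nrow(tr), -1L])
  if (!is.finite(cv) || cv > isi_tol)
    return(list(found = FALSE, period = mean(isi), v_min = min(tr$v[keep]),
                v_max = max(tr$v[keep]), n_spikes = length(sp),
                indeterminate = TRUE, state = fin))
  list(found = TRUE, period = mean(isi), v_min = min(tr$v[keep]),
       v_max = max(tr$v[keep]), n_spikes = length(sp),
       indeterminate = FALSE, state = fin)
}

# per-model default run lengths/steps for cycle detection & f-I work
.sim_defaults <- function(model) {
  if (inherits(model, "dssn")) list(T_run = 3, dt = 375e-6 / 4)
  else list(T_run = 0.4, dt = 1e-5)
}

# a start state well away from rest: near the top of the curve support with
# low recovery, which lands in a spiking cycle's basin when one exists
.kick_state <- function(model, I_stim = 0) {
  vr <- .default_v_range(model)
  v_hi <- vr[1] + 0.8 * diff(vr)
  eq <- find_equilibria(model, I_stim)
  if (nrow(eq)) {
    stable <- eq[grepl("^stable_", eq$label), , drop = FALSE]
    if (nrow(stable)) {
      st <- .eq_state(model, stable$v[1], I_stim)
      st[["v"]] <- v_hi
      return(st)
    }
  }
  .eq_state(model, v_hi, I_stim)
}

# rest state: the lowest-v stable equilibrium, or the state at the bottom of
# the range if none exists
.rest_state <- function(model, I_stim = 0) {
  eq <- find_equilibria(model, I_stim)
  if (nrow(eq)) {
    stable <- eq[grepl("^stable_", eq$label), , drop = FALSE]
    if (nrow(stable)) return(.eq_state(model, stable$v[1], I_stim))
  }
  vr <- .default_v_range(model)
  .eq_state(model, vr[1] + 0.1 * diff(vr), I_stim)
}

# rebuild a model with one named parameter replaced (bifurcation sweeps and
# the tuner use this)
.set_param <- function(model, name, value) {
  if (inherits(model, "analog_fast")) {
    if (name == "q") { model$q <- value; return(model) }
    model$base <- .set_param(model$base, name, value)
    return(model)
  }
  if (inherits(model, "analog_sn")) {
    m <- model
    if (name == "M_q") { m$fq$M <- value; return(m) }
    if (name %in% names(m)) { m[[name]] <- value; return(m) }
    map <- list(M_m = c("fm", "M"), delta_m = c("fm", "delta"),
                M_n = c("fn", "M"), delta_n = c("fn", "delta"),
                delta_q = c("fq", "delta"),
                S = c("g", "S"), theta_v = c("g", "theta_v"))
    if (name %in% names(map)) {
      w <- map[[name]]; m[[w[1]]][[w[2]]] <- value; return(m)
    }
  }
  if (name %in% names(model)) { model[[name]] <- value; return(model) }
  stop("unknown parameter '", name, "' for this model")
}

#' Sweep-and-detect bifurcation diagram
#'
#' Samples a parameter range, records the equilibria (with stability) and
#' any detected limit cycle (v extrema and period) at each sample, and
#' classifies the structural changes between adjacent samples:
#' \describe{
#'   \item{saddle_node}{equilibrium count changes by two (fold of
#'     equilibria);}
#'   \item{snic}{a saddle-node at which a limit cycle is born whose period
#'     diverges at the bifurcation (saddle-node on invariant circle);}
#'   \item{hopf}{a focus changes stability; flagged subcritical when a
#'     coexisting stable cycle already surrounds the still-stable focus on
#'     one side (bistable window);}
#'   \item{saddle_loop}{the cycle disappears while the saddle persists,
#'     with the period growing toward the event (homoclinic loop);}
#'   \item{fold_of_cycles}{the cycle appears or disappears with the
#'     equilibrium structure unchanged.}
#' }
#' The parameter may be `I_stim`, `q` (analog fast subsystem), or any named
#' model parameter such as `M_q`.
#'
#' @param model A `qsn_model`; for `parameter = "q"` pass an [analog_sn()]
#'   model (its fast subsystem is swept).
#' @param parameter Parameter name.
#' @param range Length-2 numeric interval.
#' @param resolution Number of samples (>= 50 for event bracketing;
#'   smaller values are accepted but localize events more coarsely).
#' @param T_run,dt Passed to [detect_limit_cycle()].
#' @return A list of class `bifurcation_diagram`: `samples` (data frame of
#'   per-sample structure), `equilibria` (list of `qsn_equilibria`),
#'   `events` (data frame: `type`, `param_lo`, `param_hi`, `note`).
#' @export
sweep_bifurcation <- function(model, parameter, range, resolution = 50L,
                              T_run = NULL, dt = NULL) {
  stopifnot(length(range) == 2L, resolution >= 2L)
  if (parameter == "q" && inherits(model, "analog_sn"))
    model <- fast_subsystem(model, range[1])
  pv <- seq(range[1], range[2], length.out = resolution)
  samples <- vector("list", resolution)
  eqs <- vector("list", resolution)
  carry <- NULL   # last cycle state, continued into the next sample so a
                  # coexisting cycle in a bistable window is not missed
  for (i in seq_along(pv)) {
    mi <- model; Ii <- 0
    if (parameter == "I_stim") Ii <- pv[i]
    else mi <- .set_param(model, parameter, pv[i])
    eq <- find_equilibria(mi, Ii)
    cyc <- detect_limit_cycle(mi, Ii, state0 = carry,
                              T_run = T_run, dt = dt)
    if (!cyc$found && !is.null(carry))  # fall back to a fresh kick
      cyc <- detect_limit_cycle(mi, Ii, T_run = T_run, dt = dt)
    carry <- if (cyc$found) cyc$state else NULL
    eqs[[i]] <- eq
    samples[[i]] <- data.frame(
      param = pv[i],
      n_eq = nrow(eq),
      n_stable = sum(grepl("^stable_", eq$label)),
      has_saddle = any(eq$label == "saddle"),
      stable_focus = any(eq$label == "stable_focus"),
      cycle = isTRUE(cyc$found),
      indeterminate = isTRUE(cyc$indeterminate),
      v_min = cyc$v_min, v_max = cyc$v_max, period = cyc$period,
      bistable = isTRUE(cyc$found) && sum(grepl("^stable_", eq$label)) > 0)
  }
  samples <- do.call(rbind, samples)
  events <- .classify_events(samples)
  structure(list(parameter = parameter, samples = samples,
                 equilibria = eqs, events = events),
            class = "bifurcation_diagram")
}

.classify_events <- function(s) {
  ev <- list()
  med_period <- stats::median(s$period[s$cycle], na.rm = TRUE)
  add <- function(type, lo, hi, note = "")
    ev[[length(ev) + 1L]] <<- data.frame(type = type, param_lo = lo,
                                         param_hi = hi, note = note)
  for (i in seq_len(nrow(s) - 1L)) {
    a <- s[i, ]; b <- s[i + 1L, ]
    # fold of equilibria
    if (abs(a$n_eq - b$n_eq) >= 2) {
      # which side has the cycle and a long period?
      per <- c(a$period, b$period)[c(a$cycle, b$cycle)]
      long <- length(per) && is.finite(med_period) &&
        any(per > 3 * med_period)
      cycle_born <- xor(a$cycle, b$cycle)
      if (cycle_born && long) add("snic", a$param, b$param,
                                  "cycle born at the fold with diverging period")
      else add("saddle_node", a$param, b$param)
    }
    # Hopf: a focus flips stability
    if (a$n_eq == b$n_eq && a$stable_focus != b$stable_focus &&
        a$n_stable != b$n_stable) {
      sub <- (a$stable_focus && a$cycle) || (b$stable_focus && b$cycle)
      add("hopf", a$param, b$param,
          if (sub) "subcritical (stable cycle brackets the point)" else "")
    }
    # cycle loss with persisting equilibrium structure
    if (a$cycle != b$cycle && a$n_eq == b$n_eq) {
      per <- c(a$period, b$period)[c(a$cycle, b$cycle)]
      long <- length(per) && is.finite(med_period) &&
        any(per > 3 * med_period)
      if (a$has_saddle && b$has_saddle && long)
        add("saddle_loop", a$param, b$param, "period diverges at the saddle")
      else if (!(a$stable_focus != b$stable_focus))
        add("fold_of_cycles", a$param, b$param)
    }
  }
  if (!length(ev))
    return(data.frame(type = character(), param_lo = numeric(),
                      param_hi = numeric(), note = character()))
  do.call(rbind, ev)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation diagram in '%s': %d samples over [%g, %g]\n",
              x$parameter, nrow(x$samples), min(x$samples$param),
              max(x$samples$param)))
  if (nrow(x$events)) {
    cat("events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  %-14s in (%g, %g) %s\n", x$events$type[i],
                  x$events$param_lo[i], x$events$param_hi[i],
                  x$events$note[i]))
  } else cat("no events detected\n")
  invisible(x)
}
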