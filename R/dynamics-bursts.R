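#' Segment a spike train into bursts
#'
#' Splits a spike train wherever the inter-spike interval exceeds
#' `gap_factor` times the median ISI (default 3; the alternation between
#' tonic-firing and silent phases has no published segmentation rule, so
#' this is the package's own convention). Every spike belongs to exactly
#' one burst; bursts are ordered and non-overlapping.
#'
#' @param spikes Sorted numeric vector of spike times.
#' @param gap_factor Gap threshold as a multiple of the median ISI.
#' @return Data frame of class `burst_sequence` with columns `start`,
#'   `end`, `n_spikes`; zero rows for an empty train, one degenerate row
#'   for a single spike.
#' @examples
#' sp <- c(0, 0.01, 0.02, 0.03, 0.23, 0.24, 0.25) # 2 bursts
#' segment_bursts(sp)
#' @export
segment_bursts <- function(spikes, gap_factor = 3) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer())
  class(empty) <- c("burst_sequence", "data.frame")
  if (!length(spikes)) return(empty)
  if (length(spikes) == 1L) {
    out <- data.frame(start = spikes, end = spikes, n_spikes = 1L)
    class(out) <- c("burst_sequence", "data.frame")
    return(out)
  }
  isi <- diff(spikes)
  gap <- which(isi > gap_factor * stats::median(isi))
  starts <- c(1L, gap + 1L)
  ends <- c(gap, length(spikes))
  out <- data.frame(start = spikes[starts], end = spikes[ends],
                    n_spikes = ends - starts + 1L)
  class(out) <- c("burst_sequence", "data.frame")
  out
}

#' Burst-pattern sweep of the slow-current amplitude
#'
#' Sweeps `M_q` (the saturation of the slow-current activation curve) of a
#' square-wave-bursting analog model and labels the firing regime at each
#' value: `tonic` (no burst gaps), `periodic-k` (regular bursting with k
#' spikes per burst), or `chaotic`. A sample is labeled chaotic only when
#' the spikes-per-burst sequence is aperiodic over at least `min_bursts`
#' bursts AND a second run from an initial condition displaced by `pert`
#' decorrelates from the first (max |v| difference exceeding 10% of the
#' spike amplitude). The theory of slow-nullcline placement predicts the
#' regime ordering tonic, chaotic (via a period-doubling cascade), then
#' regular bursting with the spike count per burst decreasing to 1.
#'
#' @param model An [analog_sn()] model in a square-wave mode.
#' @param Mq_range Length-2 interval of `M_q` values (amps).
#' @param resolution Number of sweep samples.
#' @param T_run,dt Simulation length and step per sample.
#' @param min_bursts Minimum bursts for a chaos verdict.
#' @param pert Initial-condition perturbation for the decorrelation test.
#' @return Data frame with `M_q`, `label`, `n_bursts`, `mean_spikes`,
#'   `count_pattern` (comma-separated spikes-per-burst sequence, truncated).
#' @export
spikes_per_burst_sweep <- function(model, Mq_range, resolution = 10L,
                                   T_run = 6, dt = 2e-5,
                                   min_bursts = 40L, pert = 1e-9) {
  stopifnot(inherits(model, "analog_sn"))
  th <- spike_threshold(model)
  out <- vector("list", resolution)
  Mqs <- seq(Mq_range[1], Mq_range[2], length.out = resolution)
  for (i in seq_along(Mqs)) {
    mi <- .set_param(model, "M_q", Mqs[i])
    st0 <- .kick_state(fast_subsystem(mi, 0), 0)
    s0 <- c(v = st0[["v"]], n = st0[["n"]], q = 0)
    tr <- simulate_neuron(mi, s0, dt = dt, T = T_run)
    keep <- tr$t >= T_run * 0.2
    sp <- spike_times(tr[keep, , drop = FALSE], th)
    bursts <- segment_bursts(sp)
    counts <- bursts$n_spikes
    label <- .burst_label(counts, min_bursts)
    if (label == "aperiodic") {
      # certify chaos: decorrelation under a tiny perturbation
      s1 <- s0; s1[["v"]] <- s1[["v"]] + pert
      tr2 <- simulate_neuron(mi, s1, dt = dt, T = T_run)
      amp <- diff(range(tr$v[keep]))
      dv <- max(abs(tr$v - tr2$v))
      label <- if (dv > 0.1 * amp) "chaotic" else "indeterminate"
    }
    out[[i]] <- data.frame(
      M_q = Mqs[i], label = label, n_bursts = nrow(bursts),
      mean_spikes = if (length(counts)) mean(counts) else NA_real_,
      count_pattern = paste(utils::head(counts, 20L), collapse = ","))
  }
  do.call(rbind, out)
}

# classify a spikes-per-burst sequence; "aperiodic" is a provisional label
# that the caller upgrades to "chaotic" after the decorrelation test
.burst_label <- function(counts, min_bursts) {
  if (!length(counts)) return("indeterminate")
  if (length(counts) == 1L) return("tonic")
  # drop first and last (possibly clipped) bursts
  core <- counts[-c(1L, length(counts))]
  if (!length(core)) core <- counts
  if (all(core == core[1L])) return(sprintf("periodic-%d", core[1L]))
  if (length(core) >= min_bursts) {
    # short repeating cycle?
    for (p in 2:4)
      if (length(core) >= 3 * p &&
          all(core == rep_len(core[1:p], length(core))))
        return(sprintf("periodic-%d", max(core[1:p])))
    return("aperiodic")
  }
  "indeterminate"
}
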