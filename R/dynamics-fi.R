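#' f-I curve of a model
#'
#' Sweeps a constant-stimulus range and records the sustained firing
#' frequency at each intensity. The state is carried from one intensity to
#' the next (so that up- and down-sweeps expose hysteresis of bistable
#' systems), the first half of every run is discarded as transient, and the
#' frequency is the reciprocal mean inter-spike interval of the retained
#' spikes (0 if fewer than 3 spikes remain).
#'
#' @param model A `qsn_model`.
#' @param I_range Length-2 stimulus interval; must bracket the spiking
#'   onset.
#' @param resolution Number of intensities.
#' @param direction "up" (default) or "down".
#' @param T_run,dt Run length and step per intensity (model defaults).
#' @param I_values Optional explicit intensity values (overriding
#'   `I_range`/`resolution`); useful to refine the grid near a Class I
#'   onset, where the frequency falls off as a square root and a uniform
#'   grid undersamples the low-frequency tail.
#' @return A data frame of class `fi_curve` with columns `I_stim`, `freq`
#'   (Hz), in sweep order; the sweep direction is kept in the `direction`
#'   attribute.
#' @export
fi_curve <- function(model, I_range, resolution = 20L,
                     direction = c("up", "down"),
                     T_run = NULL, dt = NULL, I_values = NULL) {
  direction <- match.arg(direction)
  sd <- .sim_defaults(model)
  if (is.null(T_run)) T_run <- sd$T_run
  if (is.null(dt)) dt <- sd$dt
  Is <- if (!is.null(I_values)) sort(I_values)
        else seq(I_range[1], I_range[2], length.out = resolution)
  if (direction == "down") Is <- rev(Is)
  th <- spike_threshold(model)
  state <- .rest_state(model, Is[1])
  if (direction == "down") state <- .kick_state(model, Is[1])
  freq <- numeric(length(Is))
  for (i in seq_along(Is)) {
    tr <- simulate_neuron(model, state, constant_stimulus(Is[i], T_run),
                          dt = dt, T = T_run)
    state <- unlist(tr[nrow(tr), -1L])
    keep <- tr$t >= T_run / 2
    sp <- spike_times(tr[keep, , drop = FALSE], th)
    freq[i] <- if (length(sp) >= 3L) 1 / mean(diff(sp)) else 0
  }
  structure(data.frame(I_stim = Is, freq = freq),
            direction = direction, class = c("fi_curve", "data.frame"))
}

#' Hodgkin excitability class from f-I curves
#'
#' Class I neurons start firing at an arbitrarily low frequency (the onset
#' frequency is a small fraction of the plateau frequency, here < 10%);
#' Class II neurons start at a nonzero minimum frequency. Hysteresis (the
#' up- and down-sweep onsets differing) is reported when a down-sweep is
#' supplied.
#'
#' @param fi_up An up-sweep [fi_curve()].
#' @param fi_down Optional down-sweep.
#' @param onset_fraction Classification threshold (default 0.1).
#' @return A list: `class` ("class1"/"class2"), `onset_freq`, `plateau`,
#'   `onset_I`, `hysteresis` (NA without a down-sweep).
#' @export
classify_excitability <- function(fi_up, fi_down = NULL,
                                  onset_fraction = 0.1) {
  nz <- fi_up$freq > 0
  if (!any(nz)) stop("range below threshold: no spiking anywhere in the sweep")
  plateau <- max(fi_up$freq)
  onset_idx <- which(nz)[1]
  onset_freq <- fi_up$freq[onset_idx]
  onset_I <- fi_up$I_stim[onset_idx]
  hyst <- NA_real_
  if (!is.null(fi_down)) {
    nzd <- fi_down$freq > 0
    if (any(nzd)) {
      off_I <- fi_down$I_stim[rev(which(nzd))[1]]  # last spiking I going down
      hyst <- onset_I - off_I
    }
  }
  list(class = if (onset_freq < onset_fraction * plateau) "class1"
               else "class2",
       onset_freq = onset_freq, plateau = plateau, onset_I = onset_I,
       hysteresis = hyst)
}

#' Graded-response probe: spike peak vs pulse amplitude
#'
#' Applies a brief current pulse of each amplitude to the rested model and
#' records the peak `v` reached after pulse onset. Class II spike
#' generation yields peaks that grow with the stimulus (graded response);
#' Class I yields nearly stereotyped peaks. The summary spread is
#' `(max - min) / |median|` over the suprathreshold peaks.
#'
#' @param model A `qsn_model`.
#' @param amplitudes Ascending pulse amplitudes.
#' @param width Pulse width (seconds).
#' @param T_run,dt Simulation window and step.
#' @return Data frame with `amplitude`, `peak_v`, `spiked`; the spread of
#'   the suprathreshold peaks is in the `spread` attribute (NA if fewer
#'   than 2 spikes).
#' @export
graded_response_test <- function(model, amplitudes, width,
                                 T_run = NULL, dt = NULL) {
  stopifnot(!is.unsorted(amplitudes))
  sd <- .sim_defaults(model)
  if (is.null(T_run)) T_run <- sd$T_run
  if (is.null(dt)) dt <- sd$dt
  th <- spike_threshold(model)
  rest <- .rest_state(model, 0)
  t_on <- T_run / 5
  peaks <- vapply(amplitudes, function(a) {
    stim <- if (a == 0) stimulus_protocol()
            else stimulus_protocol(t_on, t_on + width, a)
    tr <- simulate_neuron(model, rest, stim, dt = dt, T = T_run)
    max(tr$v[tr$t >= t_on])
  }, numeric(1))
  spiked <- peaks > th
  spread <- if (sum(spiked) >= 2L) {
    p <- peaks[spiked]
    (max(p) - min(p)) / abs(stats::median(p))
  } else NA_real_
  structure(data.frame(amplitude = amplitudes, peak_v = peaks,
                       spiked = spiked),
            spread = spread, class = c("graded_response", "data.frame"))
}
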