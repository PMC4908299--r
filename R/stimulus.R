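#' Piecewise-constant stimulus protocol
#'
#' A stimulus protocol is an ordered set of non-overlapping segments, each
#' holding a constant stimulus current; the stimulus is zero outside all
#' segments. Amplitudes are amps for the analog models and dimensionless for
#' the digital model.
#'
#' @param start,end Numeric vectors of segment start/end times (seconds).
#' @param amplitude Numeric vector of per-segment amplitudes.
#' @return An object of class `stimulus_protocol` (a data frame with columns
#'   `start`, `end`, `amplitude`).
#' @examples
#' stim <- stimulus_protocol(start = c(0.1, 0.5), end = c(0.2, 0.8),
#'                           amplitude = c(50e-12, -20e-12))
#' stimulus_at(stim, c(0, 0.15, 0.6, 1))
#' @export
stimulus_protocol <- function(start = numeric(), end = numeric(),
                              amplitude = numeric()) {
  stopifnot(length(start) == length(end), length(end) == length(amplitude))
  if (length(start)) {
    stopifnot(all(is.finite(start)), all(is.finite(end)),
              all(is.finite(amplitude)), all(end >= start))
    o <- order(start)
    start <- start[o]; end <- end[o]; amplitude <- amplitude[o]
    if (length(start) > 1L && any(start[-1L] < end[-length(end)] - 1e-15))
      stop("stimulus segments must not overlap")
  }
  structure(data.frame(start = start, end = end, amplitude = amplitude),
            class = c("stimulus_protocol", "data.frame"))
}

#' Constant-stimulus protocol covering `[0, T]`
#' @param amplitude Stimulus amplitude.
#' @param T Duration in seconds (default effectively unbounded).
#' @rdname stimulus_protocol
#' @export
constant_stimulus <- function(amplitude, T = Inf) {
  if (amplitude == 0) return(stimulus_protocol())
  stimulus_protocol(0, T, amplitude)
}

#' Evaluate a stimulus protocol at given times
#' @param stim A `stimulus_protocol`.
#' @param t Numeric vector of times (seconds).
#' @return Numeric vector of stimulus values; zero outside all segments.
#'   Segments are half-open `[start, end)`.
#' @rdname stimulus_protocol
#' @export
stimulus_at <- function(stim, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(stim)))
    out[t >= stim$start[i] & t < stim$end[i]] <- stim$amplitude[i]
  out
}
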