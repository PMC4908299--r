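#' Trajectories and spike trains
#'
#' Simulated trajectories are data frames with a time column `t` (seconds)
#' and one column per state variable, uniformly sampled at the integration
#' step. Spike trains are strictly increasing numeric vectors of
#' threshold-crossing times.
#'
#' @name trajectory
NULL

.new_trajectory <- function(t, states, model = NULL, dt = NULL) {
  df <- data.frame(t = t, states)
  attr(df, "model") <- model
  attr(df, "dt") <- dt
  class(df) <- c("qsn_trajectory", "data.frame")
  df
}

#' Spike times of a trajectory
#'
#' A spike is registered at each upward crossing of `v` through `threshold`,
#' with the crossing time linearly interpolated between the two bracketing
#' samples. For the digital neuron the threshold is 0 (a spike is the time
#' when v exceeds 0); analog models take an explicit threshold.
#'
#' @param traj A trajectory data frame (columns `t` and `var`), or a numeric
#'   vector of samples together with `t`.
#' @param threshold Crossing level (same unit as `var`).
#' @param var Name of the state column to threshold (default "v").
#' @return Numeric vector of spike times (possibly empty), strictly
#'   increasing.
#' @examples
#' tr <- data.frame(t = seq(0, 1, 0.01), v = sin(2 * pi * seq(0, 1, 0.01)))
#' spike_times(tr, threshold = 0)
#' @export
spike_times <- function(traj, threshold = 0, var = "v") {
  if (is.data.frame(traj)) {
    t <- traj$t
    x <- traj[[var]]
    if (is.null(x)) stop("trajectory has no column '", var, "'")
  } else stop("traj must be a data frame with columns t and ", var)
  stopifnot(length(t) == length(x))
  n <- length(x)
  if (n < 2L) return(numeric())
  below <- x < threshold
  idx <- which(below[-n] & !below[-1L])   # upward crossing between idx, idx+1
  if (!length(idx)) return(numeric())
  x0 <- x[idx]; x1 <- x[idx + 1L]
  frac <- (threshold - x0) / (x1 - x0)
  frac[!is.finite(frac)] <- 0
  t[idx] + frac * (t[idx + 1L] - t[idx])
}

#' Write a trajectory as CSV
#'
#' Canonical interchange format: a header row then full-double-precision
#' values (17 significant digits), SI units.
#'
#' @param traj Trajectory data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(lapply(traj, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col))
  names(df) <- names(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
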