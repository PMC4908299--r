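#' Synthetic bipolar pattern generator
#'
#' Generates seeded random +-1 patterns (16 x 16 grids by default) standing
#' in for stored-pattern sets that are published only graphically.
#' Rejection sampling keeps every normalized pairwise overlap
#' `|sum_i x_i^u x_i^w| / N` at or below `max_pairwise_overlap`, so the
#' stored patterns are close to orthogonal, as an associative memory
#' requires.
#'
#' @param N Pattern length (default 256; a perfect square when rendered as
#'   a grid).
#' @param count Number of patterns.
#' @param seed Integer RNG seed; the same seed reproduces the same
#'   patterns.
#' @param max_pairwise_overlap Overlap bound in \[0, 1\].
#' @param max_tries Rejection budget (error when exceeded).
#' @return List of `count` numeric +-1 vectors of length `N`.
#' @examples
#' pats <- generate_patterns(256, 4, seed = 42)
#' @export
generate_patterns <- function(N = 256L, count = 4L, seed = 1L,
                              max_pairwise_overlap = 0.25,
                              max_tries = 1000L) {
  stopifnot(count >= 1L, N >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  pats <- list()
  tries <- 0L
  while (length(pats) < count) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("rejection budget exceeded: could not satisfy the overlap bound")
    cand <- sample(c(-1, 1), N, replace = TRUE)
    ok <- all(vapply(pats, function(p)
      abs(sum(p * cand)) / N <= max_pairwise_overlap, logical(1)))
    if (ok) pats[[length(pats) + 1L]] <- cand
  }
  pats
}

#' Flip a fixed fraction of pattern pixels
#'
#' Negates exactly `round(fraction * N)` distinct positions, chosen by
#' seeded sampling without replacement - the input-pattern corruption used
#' in the retrieval experiments.
#'
#' @param pattern A +-1 vector.
#' @param fraction Fraction of pixels to flip, in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return The corrupted pattern.
#' @export
flip_pixels <- function(pattern, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  k <- round(fraction * length(pattern))
  if (k == 0) return(pattern)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  idx <- sample.int(length(pattern), k)
  pattern[idx] <- -pattern[idx]
  pattern
}

#' Read and write pattern-grid text files
#'
#' Plain-text grid format: one row per grid line, `#` for +1 and `.` for
#' -1.
#'
#' @param path File path.
#' @return `read_pattern()`: a +-1 vector (row-major).
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  chars <- strsplit(lines, "")
  widths <- lengths(chars)
  if (length(unique(widths)) != 1L) stop("ragged pattern grid")
  vals <- unlist(chars)
  if (!all(vals %in% c("#", "."))) stop("pattern characters must be # or .")
  ifelse(vals == "#", 1, -1)
}

#' @rdname read_pattern
#' @param pattern A +-1 vector whose length is a perfect square.
#' @export
write_pattern <- function(pattern, path) {
  side <- sqrt(length(pattern))
  if (side != round(side)) stop("pattern length must be a perfect square")
  m <- matrix(ifelse(pattern > 0, "#", "."), nrow = side, byrow = TRUE)
  writeLines(apply(m, 1, paste0, collapse = ""), path)
  invisible(path)
}
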