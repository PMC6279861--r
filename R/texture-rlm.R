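# Enumerate traversal lines of the bounding-box grid for one direction.
# Each line is the vector of gray bins (NA outside the mask) along the line.
rlm_lines <- function(g, angle) {
  nr <- nrow(g); nc <- ncol(g)
  switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) g[r, ]),
    "90" = lapply(seq_len(nc), function(c) g[, c]),
    "45" = lapply(2:(nr + nc), function(s) {
      cs <- max(1L, s - nr):min(nc, s - 1L)
      g[cbind(s - cs, cs)]
    }),
    "135" = lapply((1L - nc):(nr - 1L), function(t) {
      cs <- max(1L, 1L - t):min(nc, nr - t)
      g[cbind(t + cs, cs)]
    }),
    stop_invalid("angle must be one of 0, 45, 90, 135")
  )
}

#' Gray-level run-length matrix of a quantized patch
#'
#' Pixels inside the ROI are traversed along lines in the given direction,
#' sampled with stride `offset`: offset 1 is the classical run-length
#' construction (maximal same-bin runs of adjacent pixels), and for
#' `offset = d` each line is split into its `d` interleaved subsequences, so
#' the stride-d subsequences partition the mask and every mask pixel is
#' covered exactly once per direction. Runs are broken at mask boundaries.
#' The stride reading of "offset" is a documented modelling choice; see the
#' package vignette.
#'
#' @param qpatch a `quantized_patch`.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param offset traversal stride `d >= 1`.
#' @return Object of class `rlm`: integer count matrix `counts` (`ng` rows,
#'   max run length columns), total run count `n_runs`, covered pixel count
#'   `n_pixels`, and the parameters.
#' @export
compute_rlm <- function(qpatch, angle, offset) {
  if (offset < 1) stop_invalid("`offset` must be >= 1")
  d <- as.integer(offset)
  g <- qpatch_grid(qpatch)
  vals_all <- integer(0)
  lens_all <- integer(0)
  for (line in rlm_lines(g, angle)) {
    line[is.na(line)] <- 0L # sentinel: breaks runs, dropped below
    L <- length(line)
    for (p in seq_len(min(d, L))) {
      sub <- line[seq.int(p, L, by = d)]
      r <- rle(sub)
      keep <- r$values > 0L
      if (any(keep)) {
        vals_all <- c(vals_all, r$values[keep])
        lens_all <- c(lens_all, r$lengths[keep])
      }
    }
  }
  n_pixels <- length(qpatch$bins) # each mask pixel traversed exactly once
  if (length(vals_all) == 0L) {
    stop(errorCondition(
      "no run found (empty traversal)",
      class = c("nawmrad_degenerate_rlm", "nawmrad_error")
    ))
  }
  rmax <- max(lens_all)
  counts <- matrix(
    tabulate((vals_all - 1L) * rmax + lens_all, nbins = qpatch$ng * rmax),
    nrow = qpatch$ng, ncol = rmax, byrow = TRUE
  )
  structure(
    list(
      counts = counts, ng = qpatch$ng, angle = angle, offset = d,
      n_runs = sum(counts), n_pixels = n_pixels
    ),
    class = "rlm"
  )
}

#' Run-length features of a run-length matrix
#'
#' Direct-summation Galloway/Chu run-length statistics of the count matrix
#' `r(i, l)` (gray level i, run length l), with `Nr` total runs and `Np`
#' traversed pixels: ShortRunEmphasis, LongRunEmphasis,
#' GreyLevelNonuniformity, RunLengthNonuniformity, RunPercentage = Nr / Np,
#' Low/HighGreyLevelRunEmphasis and the four joint short/long x low/high
#' emphases.
#'
#' @param R an `rlm` object.
#' @return Named numeric vector of the eleven features.
#' @export
rlm_features <- function(R) {
  counts <- R$counts
  if (sum(counts) < 1) {
    stop(errorCondition(
      "run-length matrix holds no runs",
      class = c("nawmrad_degenerate_rlm", "nawmrad_error")
    ))
  }
  ng <- nrow(counts); rmax <- ncol(counts)
  i <- matrix(seq_len(ng), ng, rmax)
  l <- matrix(seq_len(rmax), ng, rmax, byrow = TRUE)
  nr <- sum(counts)
  c(
    ShortRunEmphasis = sum(counts / l^2) / nr,
    LongRunEmphasis = sum(counts * l^2) / nr,
    GreyLevelNonuniformity = sum(rowSums(counts)^2) / nr,
    RunLengthNonuniformity = sum(colSums(counts)^2) / nr,
    RunPercentage = nr / R$n_pixels,
    LowGreyLevelRunEmphasis = sum(counts / i^2) / nr,
    HighGreyLevelRunEmphasis = sum(counts * i^2) / nr,
    ShortRunLowGreyLevelEmphasis = sum(counts / (i^2 * l^2)) / nr,
    ShortRunHighGreyLevelEmphasis = sum(counts * i^2 / l^2) / nr,
    LongRunLowGreyLevelEmphasis = sum(counts * l^2 / i^2) / nr,
    LongRunHighGreyLevelEmphasis = sum(counts * i^2 * l^2) / nr
  )
}
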