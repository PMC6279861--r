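glcm_displacement <- function(angle, offset) {
  switch(as.character(angle),
    "0"   = c(0L, offset),
    "45"  = c(-offset, offset),
    "90"  = c(-offset, 0L),
    "135" = c(-offset, -offset),
    stop_invalid("angle must be one of 0, 45, 90, 135")
  )
}

#' Gray-level co-occurrence matrix of a quantized patch
#'
#' Counts ordered pixel pairs `(p, p + d * u_theta)` with both endpoints
#' inside the ROI (mask-aware: pairs crossing the ROI boundary are excluded),
#' optionally symmetrizes by adding the transpose, and normalizes to unit sum.
#' `u_theta` is the unit displacement of the angle: (0,1) for 0 degrees,
#' (-1,1) for 45, (-1,0) for 90 and (-1,-1) for 135, in (row, column) pixel
#' coordinates.
#'
#' @param qpatch a `quantized_patch` from [quantize()].
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param offset pixel displacement `d >= 1`.
#' @param symmetric add the transposed counts (default `TRUE`).
#' @return Object of class `glcm`: the `ng x ng` probability matrix `P`, the
#'   valid ordered-pair count `n_pairs`, and the parameters.
#' @export
compute_glcm <- function(qpatch, angle, offset, symmetric = TRUE) {
  if (offset < 1) stop_invalid("`offset` must be >= 1")
  d <- glcm_displacement(angle, as.integer(offset))
  g <- qpatch_grid(qpatch)
  nr <- nrow(g); nc <- ncol(g)
  r0 <- max(1L, 1L - d[1]):min(nr, nr - d[1])
  c0 <- max(1L, 1L - d[2]):min(nc, nc - d[2])
  counts <- matrix(0, qpatch$ng, qpatch$ng)
  n_pairs <- 0L
  if (length(r0) > 0 && length(c0) > 0 && r0[1] <= r0[length(r0)] &&
      c0[1] <= c0[length(c0)]) {
    a <- g[r0, c0, drop = FALSE]
    b <- g[r0 + d[1], c0 + d[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ai <- a[ok]; bi <- b[ok]
      tab <- tabulate((ai - 1L) * qpatch$ng + bi, nbins = qpatch$ng^2)
      counts <- matrix(tab, qpatch$ng, qpatch$ng, byrow = TRUE)
      n_pairs <- sum(tab)
    }
  }
  if (n_pairs == 0L) {
    stop(errorCondition(
      sprintf("no valid pixel pair for angle %s offset %d", angle, offset),
      class = c("nawmrad_degenerate_glcm", "nawmrad_error")
    ))
  }
  if (symmetric) counts <- counts + t(counts)
  structure(
    list(
      P = counts / sum(counts), ng = qpatch$ng, angle = angle,
      offset = as.integer(offset), symmetric = symmetric, n_pairs = n_pairs
    ),
    class = "glcm"
  )
}

#' Haralick features of a co-occurrence matrix
#'
#' Direct-summation Haralick statistics of a normalized GLCM `P(i, j)`:
#' Energy, Entropy, InverseDifferenceMoment, Contrast, Correlation,
#' SumAverage, SumEntropy, DifferenceEntropy, ClusterShade and
#' ClusterProminence, with the `0 * log 0 == 0` convention. When the marginal
#' variance vanishes (e.g. a one-bin patch), Correlation is reported as 0 and
#' the result carries a `degenerate_correlation` attribute.
#'
#' @param G a `glcm` object (or a normalized matrix).
#' @param log_base logarithm base for the entropies (default 2).
#' @return Named numeric vector of the ten features.
#' @export
glcm_features <- function(G, log_base = 2) {
  P <- if (inherits(G, "glcm")) G$P else G
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  degenerate <- (sx * sy) == 0
  corr <- if (degenerate) 0 else (sum(i * j * P) - mux * muy) / (sx * sy)
  # sum (k = i + j in 2..2ng) and difference (k = |i - j| in 0..ng-1) marginals
  psum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  pdif <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  out <- c(
    Energy = sum(P^2),
    Entropy = plogp(P, log_base),
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    SumAverage = sum((2:(2 * ng)) * psum),
    SumEntropy = plogp(psum, log_base),
    DifferenceEntropy = plogp(pdif, log_base),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P)
  )
  if (degenerate) attr(out, "degenerate_correlation") <- TRUE
  out
}
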