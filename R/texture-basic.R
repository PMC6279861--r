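#' Quantize a masked patch to discrete gray bins
#'
#' Equal-width binning of the ROI's own intensity range into `ng` gray levels,
#' the standard preprocessing for co-occurrence and run-length statistics. A
#' constant patch maps every pixel to bin 1.
#'
#' @param patch a `masked_patch` from [extract_patch()].
#' @param ng number of gray bins (>= 2).
#' @param mode binning mode; `"minmax"` (the default and currently only mode)
#'   bins the closed interval `[min, max]` of the ROI pixels.
#' @return An object of class `quantized_patch`: integer `bins` in `1..ng`
#'   plus the original 0-based coordinates.
#' @export
quantize <- function(patch, ng = 16, mode = "minmax") {
  mode <- match.arg(mode, "minmax")
  if (length(patch$values) == 0L) stop_invalid("empty patch")
  if (!is.numeric(ng) || ng < 2) stop_invalid("`ng` must be >= 2")
  ng <- as.integer(ng)
  v <- patch$values
  rng <- range(v)
  if (rng[2] > rng[1]) {
    bins <- pmin(ng, floor((v - rng[1]) / (rng[2] - rng[1]) * ng) + 1L)
  } else {
    bins <- rep.int(1L, length(v))
  }
  structure(
    list(
      bins = as.integer(bins), rows = patch$rows, cols = patch$cols,
      ng = ng, shape = patch$shape
    ),
    class = "quantized_patch"
  )
}

# Dense gray-bin grid on the patch bounding box; NA outside the mask.
qpatch_grid <- function(qpatch) {
  r <- qpatch$rows - min(qpatch$rows) + 1L
  c <- qpatch$cols - min(qpatch$cols) + 1L
  g <- matrix(NA_integer_, max(r), max(c))
  g[cbind(r, c)] <- qpatch$bins
  g
}

#' First-order (histogram) features of a masked patch
#'
#' Moments and percentiles are computed on the raw intensities; Uniformity
#' (histogram energy, the sum of squared bin probabilities) and entropy are
#' computed on the `ng`-bin quantized histogram. Skewness and kurtosis are the
#' population moment ratios `m3 / m2^1.5` and `m4 / m2^2`; `stdDeviation` is
#' the population standard deviation. A constant patch has Uniformity 1 and
#' entropy 0.
#'
#' @param patch a `masked_patch`.
#' @param ng number of histogram bins for Uniformity/entropy.
#' @param log_base logarithm base for the entropy (default 2, bits).
#' @return Named numeric vector.
#' @export
histogram_features <- function(patch, ng = 16, log_base = 2) {
  v <- patch$values
  if (length(v) == 0L) stop_invalid("empty patch")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  q <- stats::quantile(v, c(.05, .10, .25, .50, .75, .90, .95), names = FALSE)
  p <- tabulate(quantize(patch, ng = ng)$bins, nbins = ng) / length(v)
  c(
    mean = m, stdDeviation = sdv, skewness = skew, kurtosis = kurt,
    Uniformity = sum(p^2), entropy = plogp(p, log_base),
    Percentile05 = q[1], Percentile10 = q[2], Percentile25 = q[3],
    Percentile50 = q[4], Percentile75 = q[5], Percentile90 = q[6],
    Percentile95 = q[7]
  )
}

#' Form-factor (shape) features of an ROI mask
#'
#' Pixel-based shape descriptors: area (pixel count times spacing squared),
#' perimeter (length of exposed pixel edges times spacing), compactness
#' `4 * pi * area / perimeter^2`, equivalent circular diameter, and the
#' eccentricity of the inertia-equivalent ellipse from the second central
#' moments of the pixel coordinates.
#'
#' @param mask a `roi_mask` or logical matrix.
#' @param pixel_spacing in-plane pixel spacing (isotropic), default 1.
#' @return Named numeric vector.
#' @export
form_factor_features <- function(mask, pixel_spacing = 1) {
  px <- mask_pixels(mask)
  n <- sum(px)
  if (n == 0L) stop_invalid("empty mask")
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  exposed <- sum(core & !pad[1:nr, 2:(nc + 1L)]) +
    sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) +
    sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
  area <- n * pixel_spacing^2
  perim <- exposed * pixel_spacing
  idx <- which(px, arr.ind = TRUE)
  mu <- colMeans(idx)
  dr <- idx[, 1] - mu[1]; dc <- idx[, 2] - mu[2]
  cov <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
  c(
    area = area, perimeter = perim,
    compactness = 4 * pi * area / perim^2,
    equivalentDiameter = 2 * sqrt(area / pi),
    eccentricity = ecc
  )
}

#' Aggregate a per-angle feature over the four directions
#'
#' The `AllDirection` value of a GLCM/RLM feature is the arithmetic mean over
#' the four analysis angles (0, 45, 90, 135 degrees) and the `_SD` variant is
#' their population standard deviation (divisor 4).
#'
#' @param per_angle_values numeric vector of exactly four values.
#' @return Named vector `c(AllDirection = ..., AllDirection_SD = ...)`; if any
#'   input is non-finite both aggregates are `NA` with a warning.
#' @export
aggregate_directions <- function(per_angle_values) {
  if (length(per_angle_values) != 4L) {
    stop_invalid("exactly four per-angle values are required")
  }
  if (!all(is.finite(per_angle_values))) {
    warning("non-finite per-angle value; aggregate reported as missing")
    return(c(AllDirection = NA_real_, AllDirection_SD = NA_real_))
  }
  c(
    AllDirection = mean(per_angle_values),
    AllDirection_SD = pop_sd(per_angle_values)
  )
}
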