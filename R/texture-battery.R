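#' Configuration of the texture-feature battery
#'
#' @param ng gray-level count for quantization (equal-width over the ROI
#'   min-max range).
#' @param angles analysis angles in degrees.
#' @param offsets pixel offsets (GLCM displacement / RLM stride).
#' @param log_base entropy logarithm base.
#' @param feature_groups which groups to compute.
#' @param symmetric symmetrize GLCMs.
#' @param pixel_spacing in-plane pixel spacing.
#' @param min_pixels minimum ROI size enforced by [extract_battery()].
#' @return A list of class `battery_config`.
#' @export
battery_config <- function(ng = 16, angles = c(0, 45, 90, 135),
                           offsets = c(1, 4, 7), log_base = 2,
                           feature_groups = c("histogram", "form", "glcm", "rlm"),
                           symmetric = TRUE, pixel_spacing = 1,
                           min_pixels = 100) {
  feature_groups <- match.arg(feature_groups,
                              c("histogram", "form", "glcm", "rlm"),
                              several.ok = TRUE)
  structure(
    list(
      ng = as.integer(ng), angles = angles, offsets = as.integer(offsets),
      log_base = log_base, feature_groups = feature_groups,
      symmetric = symmetric, pixel_spacing = pixel_spacing,
      min_pixels = min_pixels
    ),
    class = "battery_config"
  )
}

glcm_feature_names <- function() {
  c("Energy", "Entropy", "InverseDifferenceMoment", "Contrast", "Correlation",
    "SumAverage", "SumEntropy", "DifferenceEntropy", "ClusterShade",
    "ClusterProminence")
}

rlm_feature_names <- function() {
  c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
    "RunLengthNonuniformity", "RunPercentage", "LowGreyLevelRunEmphasis",
    "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
    "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
    "LongRunHighGreyLevelEmphasis")
}

directional_names <- function(base_names, angles, offsets) {
  out <- character(0)
  for (d in offsets) {
    for (f in base_names) {
      out <- c(
        out,
        sprintf("%s_angle%d_offset%d", f, angles, d),
        sprintf("%s_AllDirection_offset%d", f, d),
        sprintf("%s_AllDirection_offset%d_SD", f, d)
      )
    }
  }
  out
}

#' Battery manifest: the exact feature composition
#'
#' Enumerates every feature name the battery emits under a configuration, in
#' the deterministic output order, with its group. Directional features follow
#' the `<Feature>_<angle..|AllDirection>_offset<d>[_SD]` naming convention.
#'
#' @param config a [battery_config()].
#' @return A data.frame with columns `feature` and `group`.
#' @export
battery_manifest <- function(config = battery_config()) {
  feats <- character(0); grp <- character(0)
  if ("histogram" %in% config$feature_groups) {
    h <- c("mean", "stdDeviation", "skewness", "kurtosis", "Uniformity",
           "entropy", "Percentile05", "Percentile10", "Percentile25",
           "Percentile50", "Percentile75", "Percentile90", "Percentile95")
    feats <- c(feats, h); grp <- c(grp, rep("histogram", length(h)))
  }
  if ("form" %in% config$feature_groups) {
    f <- c("area", "perimeter", "compactness", "equivalentDiameter",
           "eccentricity")
    feats <- c(feats, f); grp <- c(grp, rep("form", length(f)))
  }
  if ("glcm" %in% config$feature_groups) {
    g <- directional_names(glcm_feature_names(), config$angles, config$offsets)
    feats <- c(feats, g); grp <- c(grp, rep("glcm", length(g)))
  }
  if ("rlm" %in% config$feature_groups) {
    r <- directional_names(rlm_feature_names(), config$angles, config$offsets)
    feats <- c(feats, r); grp <- c(grp, rep("rlm", length(r)))
  }
  data.frame(feature = feats, group = grp, stringsAsFactors = FALSE)
}

directional_block <- function(per_angle, angles, offset) {
  # per_angle: matrix features x angles
  out <- numeric(0)
  for (f in rownames(per_angle)) {
    v <- per_angle[f, ]
    agg <- aggregate_directions(v)
    block <- c(v, unname(agg))
    names(block) <- c(
      sprintf("%s_angle%d_offset%d", f, angles, offset),
      sprintf("%s_AllDirection_offset%d", f, offset),
      sprintf("%s_AllDirection_offset%d_SD", f, offset)
    )
    out <- c(out, block)
  }
  out
}

#' Extract the full texture-feature battery for one ROI
#'
#' Computes histogram, form-factor, GLCM and RLM features on the image pixels
#' inside the mask. Directional features are computed per angle and offset and
#' aggregated into `AllDirection` (mean over the four angles) and
#' `AllDirection_SD` (population SD) variants. Degenerate sub-computations
#' (e.g. no valid co-occurring pair at a large offset) yield `NA` values with
#' a warning, never silent zeros.
#'
#' @param image numeric matrix.
#' @param mask a `roi_mask` or logical matrix of the same shape.
#' @param config a [battery_config()].
#' @return Named numeric vector in the [battery_manifest()] order.
#' @export
extract_battery <- function(image, mask, config = battery_config()) {
  v <- validate_roi(mask, config$min_pixels)
  if (!v$pass) {
    stop_invalid(sprintf(
      "ROI has %d pixels; battery requires >= %d", v$n_pixels, v$min_pixels
    ))
  }
  # Crop to the mask bounding box: texture statistics only see masked pixels.
  px <- mask_pixels(mask)
  idx <- which(px, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  img_c <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk_c <- px[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  patch <- extract_patch(img_c, msk_c)
  out <- numeric(0)
  if ("histogram" %in% config$feature_groups) {
    out <- c(out, histogram_features(patch, config$ng, config$log_base))
  }
  if ("form" %in% config$feature_groups) {
    out <- c(out, form_factor_features(msk_c, config$pixel_spacing))
  }
  needs_q <- any(c("glcm", "rlm") %in% config$feature_groups)
  if (needs_q) qp <- quantize(patch, config$ng)
  if ("glcm" %in% config$feature_groups) {
    fnames <- glcm_feature_names()
    for (d in config$offsets) {
      per_angle <- matrix(
        NA_real_, length(fnames), length(config$angles),
        dimnames = list(fnames, NULL)
      )
      for (ai in seq_along(config$angles)) {
        fa <- tryCatch(
          glcm_features(
            compute_glcm(qp, config$angles[ai], d, config$symmetric),
            config$log_base
          ),
          nawmrad_degenerate_glcm = function(e) {
            warning(conditionMessage(e))
            stats::setNames(rep(NA_real_, length(fnames)), fnames)
          }
        )
        per_angle[, ai] <- fa[fnames]
      }
      out <- c(out, directional_block(per_angle, config$angles, d))
    }
  }
  if ("rlm" %in% config$feature_groups) {
    fnames <- rlm_feature_names()
    for (d in config$offsets) {
      per_angle <- matrix(
        NA_real_, length(fnames), length(config$angles),
        dimnames = list(fnames, NULL)
      )
      for (ai in seq_along(config$angles)) {
        fa <- tryCatch(
          rlm_features(compute_rlm(qp, config$angles[ai], d)),
          nawmrad_degenerate_rlm = function(e) {
            warning(conditionMessage(e))
            stats::setNames(rep(NA_real_, length(fnames)), fnames)
          }
        )
        per_angle[, ai] <- fa[fnames]
      }
      out <- c(out, directional_block(per_angle, config$angles, d))
    }
  }
  out
}
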