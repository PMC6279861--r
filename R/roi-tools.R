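#' Region-of-interest masks
#'
#' A `roi_mask` is a binary pixel mask tied to a 2D image slice, carrying a
#' tissue-class label. Coordinates are 0-based (row, column) in the exported
#' patch representation and masks share the shape of their image. Labels follow
#' the longitudinal white-matter design: `WMH_baseline` and `WMH_followup` are
#' the visible hyperintensity at the two time points, `dNAWM` is
#' normal-appearing white matter that converts to WMH between scans (the
#' follow-up-minus-baseline annulus), `non_dNAWM` is normal-appearing tissue
#' that does not convert, and `NWM` is control white matter.
#'
#' @param pixels logical (or 0/1) matrix; `TRUE` marks pixels inside the ROI.
#' @param label one of `"WMH_baseline"`, `"WMH_followup"`, `"dNAWM"`,
#'   `"non_dNAWM"`, `"NWM"`.
#' @param subject_id optional subject identifier carried through the pipeline.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, label, subject_id = NA_character_) {
  if (!is.matrix(pixels)) stop_invalid("`pixels` must be a matrix")
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.logical(pixels)) stop_invalid("`pixels` must be logical or 0/1")
  labels <- c("WMH_baseline", "WMH_followup", "dNAWM", "non_dNAWM", "NWM")
  label <- match.arg(label, labels)
  structure(
    list(pixels = pixels, label = label, subject_id = subject_id),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> label=%s subject=%s size=%dx%d pixels=%d\n",
    x$label, x$subject_id, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)
  ))
  invisible(x)
}

mask_pixels <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$pixels else mask
}

#' Subtract the baseline WMH mask from the follow-up WMH mask
#'
#' The developing-NAWM region is defined as the set difference between the
#' follow-up and baseline white-matter-hyperintensity masks on co-registered
#' images: tissue that was normal-appearing at baseline but hyperintense at
#' follow-up. Inputs must already be in a common space; the function does not
#' register anything. If the baseline mask is not contained in the follow-up
#' mask (possible with manual delineations), the stray baseline-only pixels
#' are reported with a warning and ignored.
#'
#' @param followup_wmh,baseline_wmh `roi_mask` objects (or logical matrices)
#'   of identical shape.
#' @return A `roi_mask` labelled `dNAWM` containing `followup & !baseline`.
#' @export
subtract_masks <- function(followup_wmh, baseline_wmh) {
  f <- mask_pixels(followup_wmh)
  b <- mask_pixels(baseline_wmh)
  if (!all(dim(f) == dim(b))) {
    stop_invalid("follow-up and baseline masks must share their shape")
  }
  stray <- sum(b & !f)
  if (stray > 0) {
    warning(sprintf(
      "baseline WMH has %d pixel(s) outside the follow-up WMH; ignored", stray
    ))
  }
  diff <- f & !b
  if (!any(diff)) {
    stop(errorCondition(
      "follow-up minus baseline WMH is empty: no developing region",
      class = c("nawmrad_degenerate_roi", "nawmrad_error")
    ))
  }
  sid <- if (inherits(followup_wmh, "roi_mask")) followup_wmh$subject_id else NA_character_
  roi_mask(diff, "dNAWM", sid)
}

#' Mirror a mask about a vertical axis
#'
#' Reflects an ROI about the image's vertical midline (or a supplied axis
#' column), the construction used to place the non-developing NAWM reference
#' region symmetrically in the contralateral hemisphere.
#'
#' @param mask a `roi_mask` or logical matrix.
#' @param axis_column axis of reflection in column units; defaults to the
#'   image midline `(ncol + 1) / 2`. A pixel in column `c` maps to column
#'   `2 * axis_column - c`.
#' @param label label for the reflected mask (default `"non_dNAWM"`).
#' @return The reflected `roi_mask`; pixel count is preserved.
#' @export
mirror_mask <- function(mask, axis_column = NULL, label = "non_dNAWM") {
  px <- mask_pixels(mask)
  nc <- ncol(px)
  if (is.null(axis_column)) axis_column <- (nc + 1) / 2
  idx <- which(px, arr.ind = TRUE)
  new_col <- round(2 * axis_column - idx[, 2])
  if (any(new_col < 1 | new_col > nc)) {
    stop(errorCondition(
      "mirrored mask exits the image bounds",
      class = c("nawmrad_out_of_bounds", "nawmrad_error")
    ))
  }
  out <- matrix(FALSE, nrow(px), nc)
  out[cbind(idx[, 1], new_col)] <- TRUE
  sid <- if (inherits(mask, "roi_mask")) mask$subject_id else NA_character_
  roi_mask(out, label, sid)
}

#' Validate an ROI against the minimum-size rule
#'
#' Analysis ROIs must contain at least `min_pixels` pixels (default 100, the
#' threshold used for all analyzed regions) so that texture statistics are
#' estimable.
#'
#' @param mask a `roi_mask` or logical matrix.
#' @param min_pixels minimum admissible pixel count.
#' @return A list with `pass` (logical), `n_pixels`, and `min_pixels`.
#' @export
validate_roi <- function(mask, min_pixels = 100) {
  n <- sum(mask_pixels(mask))
  list(pass = n >= min_pixels, n_pixels = n, min_pixels = min_pixels)
}

#' Extract masked pixel values and coordinates
#'
#' Returns the intensities and integer pixel coordinates (0-based row, column,
#' row-major order) of the pixels inside an ROI — the raw material for the
#' texture battery.
#'
#' @param image numeric matrix (the image slice).
#' @param mask a `roi_mask` or logical matrix of the same shape.
#' @return An object of class `masked_patch` with fields `values`, `rows`,
#'   `cols` (0-based), and `shape`.
#' @export
extract_patch <- function(image, mask) {
  px <- mask_pixels(mask)
  if (!all(dim(image) == dim(px))) {
    stop_invalid("image and mask must share their shape")
  }
  idx <- which(t(px), arr.ind = TRUE) # transpose => row-major order
  rows <- idx[, 2]
  cols <- idx[, 1]
  structure(
    list(
      values = image[cbind(rows, cols)],
      rows = rows - 1L,
      cols = cols - 1L,
      shape = dim(image)
    ),
    class = "masked_patch"
  )
}
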