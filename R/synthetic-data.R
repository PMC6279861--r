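#' Texture parameters for one tissue class
#'
#' Parameters of the stationary random-field texture model used by the
#' synthetic cohort generator. The base field is spectrally filtered Gaussian
#' noise with marginal standard deviation `noise_sd` and autocorrelation
#' scale `correlation_length`. Tissue heterogeneity is additionally encoded
#' by `dispersion`, a gray-level dispersion weight in `[0, 1]`: a monotone
#' pixel-wise transform that interpolates the field's marginal distribution
#' from Gaussian (`0`: intensities cluster around a mode, the homogeneous
#' extreme) to uniform (`1`: intensities fill their range, the heterogeneous
#' extreme). Under the battery's ROI min-max quantization the histogram and
#' co-occurrence statistics of a Gaussian field are invariant to rescaling
#' `noise_sd`, so the graded tissue-class heterogeneity is carried by
#' `dispersion` (primary) and `correlation_length` (secondary), with
#' `noise_sd` acting on the raw intensity scale; see the package vignette.
#'
#' @param mean_intensity mean intensity, arbitrary units in `[0, 1000]`.
#' @param noise_sd marginal SD of the field (>= 0).
#' @param correlation_length autocorrelation scale in pixels (> 0).
#' @param lesion_intensity_boost intensity added to the follow-up WMH region.
#' @param dispersion gray-level dispersion weight in `[0, 1]`.
#' @return A list of class `texture_params`.
#' @export
texture_params <- function(mean_intensity = 500, noise_sd = 30,
                           correlation_length = 3,
                           lesion_intensity_boost = 0,
                           dispersion = 0) {
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (correlation_length <= 0) stop_invalid("`correlation_length` must be > 0")
  if (lesion_intensity_boost < 0) stop_invalid("`lesion_intensity_boost` must be >= 0")
  if (dispersion < 0 || dispersion > 1) {
    stop_invalid("`dispersion` must be in [0, 1]")
  }
  structure(
    list(
      mean_intensity = mean_intensity, noise_sd = noise_sd,
      correlation_length = correlation_length,
      lesion_intensity_boost = lesion_intensity_boost,
      dispersion = dispersion
    ),
    class = "texture_params"
  )
}

#' Default per-class texture parameters
#'
#' Encodes the graded heterogeneity the analysis assumes: control white
#' matter (`NWM`) is the most homogeneous, non-developing NAWM
#' (`non_dNAWM`) intermediate, and developing NAWM (`dNAWM`) the most
#' heterogeneous (larger gray-level dispersion, coarser spatially coherent
#' patchiness, larger raw SD). The `dNAWM` entry's `lesion_intensity_boost`
#' sets the visible-WMH hyperintensity on the images.
#'
#' @return Named list of [texture_params()] for `NWM`, `non_dNAWM`, `dNAWM`.
#' @export
default_class_params <- function() {
  list(
    NWM = texture_params(
      mean_intensity = 480, noise_sd = 30, correlation_length = 2.2,
      dispersion = 0
    ),
    non_dNAWM = texture_params(
      mean_intensity = 484, noise_sd = 34, correlation_length = 2.5,
      dispersion = 0.25
    ),
    dNAWM = texture_params(
      mean_intensity = 490, noise_sd = 55, correlation_length = 3.0,
      dispersion = 0.75, lesion_intensity_boost = 220
    )
  )
}

#' Cohort specification
#'
#' @param n_cases number of case subjects (each contributes a `dNAWM` and a
#'   `non_dNAWM` ROI); default 51 mirrors the study design.
#' @param n_controls number of control subjects (each contributes one `NWM`
#'   ROI); default 51.
#' @param image_size image dimensions in pixels, `c(rows, cols)`.
#' @param roi_min_pixels minimum admissible analysis-ROI size.
#' @param class_params named list of [texture_params()] for `NWM`,
#'   `non_dNAWM`, `dNAWM`.
#' @param subject_variation between-subject biological variability: log-SD
#'   multipliers applied per subject to `noise_sd` and `correlation_length`,
#'   an additive SD on `dispersion` (clamped to `[0, 0.85]`), and an additive
#'   SD on `mean_intensity`. Without it, per-ROI texture estimates (hundreds
#'   of pixels each) would separate even nearby classes almost perfectly.
#' @param seed integer seed; all generation is a pure function of the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 51, n_controls = 51,
                        image_size = c(96, 96), roi_min_pixels = 100,
                        class_params = default_class_params(),
                        subject_variation = list(
                          noise_sd = 0.10, correlation_length = 0.08,
                          dispersion = 0.06, mean_intensity = 15
                        ),
                        seed = 1) {
  if (n_cases < 1 || n_controls < 1) stop_invalid("group sizes must be > 0")
  if (roi_min_pixels < 1) stop_invalid("`roi_min_pixels` must be >= 1")
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  stopifnot(all(c("NWM", "non_dNAWM", "dNAWM") %in% names(class_params)))
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      image_size = as.integer(image_size),
      roi_min_pixels = as.integer(roi_min_pixels),
      class_params = class_params, subject_variation = subject_variation,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Per-subject realization of the class texture parameters: a subject random
# effect shared by all of that subject's tissue classes.
jitter_class_params <- function(class_params, variation) {
  if (is.null(variation)) return(class_params)
  m_sd <- exp(stats::rnorm(1, 0, variation$noise_sd %||% 0))
  m_cl <- exp(stats::rnorm(1, 0, variation$correlation_length %||% 0))
  d_w <- stats::rnorm(1, 0, variation$dispersion %||% 0)
  d_mu <- stats::rnorm(1, 0, variation$mean_intensity %||% 0)
  lapply(class_params, function(p) {
    p$noise_sd <- p$noise_sd * m_sd
    p$correlation_length <- p$correlation_length * m_cl
    p$dispersion <- min(0.85, max(0, p$dispersion + d_w))
    p$mean_intensity <- p$mean_intensity + d_mu
    p
  })
}

# Gaussian random field via spectral filtering of white noise; called inside
# an already-seeded RNG context.
gaussian_field <- function(size, correlation_length) {
  nr <- size[1]; nc <- size[2]
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  k2 <- outer(fr^2, fc^2, `+`)
  filt <- exp(-2 * (pi * correlation_length)^2 * k2)
  f <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / (nr * nc)
  f
}

#' Generate a stationary textured field
#'
#' Spectrally filtered Gaussian white noise: a Gaussian transfer function in
#' the frequency domain gives a stationary field with autocorrelation scale
#' `correlation_length`. When `dispersion > 0` the standardized field `z` is
#' blended pixel-wise with its probability-integral (rank) transform,
#' `(1 - w) z + w sqrt(12) (Phi(z) - 1/2)`, which interpolates the marginal
#' between Gaussian and uniform while preserving spatial coherence. The
#' result is standardized to the requested mean and (population) marginal
#' SD. Deterministic given `seed`.
#'
#' @param size `c(rows, cols)` (or a scalar), both >= 16.
#' @param params a [texture_params()].
#' @param seed integer seed.
#' @return Numeric matrix of intensities.
#' @export
generate_texture_field <- function(size, params, seed) {
  if (length(size) == 1L) size <- rep(size, 2L)
  size <- as.integer(size)
  if (any(size < 16L)) stop_invalid("field size must be at least 16x16")
  if (!inherits(params, "texture_params")) {
    params <- do.call(texture_params, params)
  }
  with_local_seed(seed, {
    if (params$noise_sd == 0) {
      return(matrix(params$mean_intensity, size[1], size[2]))
    }
    f <- gaussian_field(size, params$correlation_length)
    z <- (f - mean(f)) / pop_sd(as.vector(f))
    w <- params$dispersion
    if (w > 0) {
      z <- (1 - w) * z + w * sqrt(12) * (stats::pnorm(z) - 0.5)
      z <- (z - mean(z)) / pop_sd(as.vector(z))
    }
    params$mean_intensity + params$noise_sd * z
  })
}

# Elliptical mask helper (row/col center and radii in pixels).
ellipse_mask <- function(size, center, radii) {
  r <- matrix(seq_len(size[1]), size[1], size[2])
  c <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

# Draw lesion geometry for one subject; returns baseline/follow-up WMH masks
# with followup a strict superset of baseline. Retries until the annulus
# (follow-up minus baseline) reaches roi_min_pixels.
draw_lesion_geometry <- function(spec) {
  sz <- spec$image_size
  for (attempt in 1:25) {
    center <- c(
      round(stats::runif(1, 0.42, 0.58) * sz[1]),
      round(stats::runif(1, 0.26, 0.36) * sz[2])
    )
    base_r <- c(stats::runif(1, 6, 9), stats::runif(1, 4.5, 6.5))
    grow <- stats::runif(2, 4.5, 6.5)
    fu_r <- base_r + grow
    base <- ellipse_mask(sz, center, base_r)
    fu <- ellipse_mask(sz, center, fu_r)
    annulus <- fu & !base
    if (sum(annulus) >= spec$roi_min_pixels && all(fu[base]) &&
        sum(fu) > sum(base)) {
      return(list(baseline = base, followup = fu))
    }
  }
  stop(errorCondition(
    sprintf(
      "could not draw a lesion annulus with >= %d pixels in a %dx%d image",
      spec$roi_min_pixels, sz[1], sz[2]
    ),
    class = c("nawmrad_generation_failure", "nawmrad_error")
  ))
}

# Paint class-textured pixels into an image within a mask.
paint <- function(image, mask, field) {
  image[mask] <- field[mask]
  image
}

#' Generate one case subject
#'
#' Builds a co-registered baseline/follow-up pair: the baseline image holds a
#' visible WMH blob plus, in the annulus that the lesion will grow into, the
#' heterogeneous developing-NAWM texture; a mirror-symmetric contralateral
#' region carries the non-developing NAWM texture; everything else is control
#' texture. The follow-up image shows the enlarged WMH (baseline blob strictly
#' contained in the follow-up blob, raised by the lesion intensity boost).
#' Masks provided: `WMH_baseline`, `WMH_followup`, `dNAWM` (the annulus, via
#' [subtract_masks()]), `non_dNAWM` (via [mirror_mask()]).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this subject.
#' @param subject_id identifier string.
#' @return A list of class `subject_record` with fields `subject_id`, `group`,
#'   `baseline`, `followup`, `masks`, `metadata`.
#' @export
generate_case_subject <- function(spec, seed, subject_id = "case_1") {
  with_local_seed(seed, {
    cp <- jitter_class_params(spec$class_params, spec$subject_variation)
    geom <- draw_lesion_geometry(spec)
    dnawm <- geom$followup & !geom$baseline
    non_dnawm_mask <- mirror_mask(
      roi_mask(dnawm, "dNAWM", subject_id)
    )$pixels
    if (sum(non_dnawm_mask) < spec$roi_min_pixels) {
      stop(errorCondition(
        "mirrored non-dNAWM region is too small",
        class = c("nawmrad_generation_failure", "nawmrad_error")
      ))
    }
    sz <- spec$image_size
    seeds <- round(stats::runif(6, 1, 2^30))
    background <- generate_texture_field(sz, cp$NWM, seeds[1])
    f_dnawm <- generate_texture_field(sz, cp$dNAWM, seeds[2])
    f_non <- generate_texture_field(sz, cp$non_dNAWM, seeds[3])
    boost <- cp$dNAWM$lesion_intensity_boost
    baseline <- paint(background, dnawm, f_dnawm)
    baseline <- paint(baseline, non_dnawm_mask, f_non)
    baseline[geom$baseline] <- f_dnawm[geom$baseline] + boost
    followup_bg <- generate_texture_field(sz, cp$NWM, seeds[4])
    f_lesion <- generate_texture_field(sz, cp$dNAWM, seeds[5])
    followup <- followup_bg
    followup[geom$followup] <- f_lesion[geom$followup] + boost
    metadata <- list(
      age = max(60, round(stats::rnorm(1, 76.6, 7.7))),
      sex = sample(c("F", "M"), 1, prob = c(0.451, 0.549)),
      interval_days = max(366, round(stats::rlnorm(1, log(615), 0.35))),
      fazekas = sample(1:6, 1, prob = c(4, 12, 13, 7, 10, 5))
    )
    structure(
      list(
        subject_id = subject_id, group = "case",
        baseline = baseline, followup = followup,
        masks = list(
          WMH_baseline = roi_mask(geom$baseline, "WMH_baseline", subject_id),
          WMH_followup = roi_mask(geom$followup, "WMH_followup", subject_id),
          dNAWM = roi_mask(dnawm, "dNAWM", subject_id),
          non_dNAWM = roi_mask(non_dnawm_mask, "non_dNAWM", subject_id)
        ),
        metadata = metadata
      ),
      class = "subject_record"
    )
  })
}

#' Generate one control subject
#'
#' Control white matter stays normal at both time points. The `NWM` ROI is an
#' annulus drawn by the same geometric process as the cases' developing
#' region, at a matching periventricular location, textured with the control
#' parameters.
#'
#' @inheritParams generate_case_subject
#' @return A `subject_record` with one `NWM` mask.
#' @export
generate_control_subject <- function(spec, seed, subject_id = "control_1") {
  with_local_seed(seed, {
    cp <- jitter_class_params(spec$class_params, spec$subject_variation)
    geom <- draw_lesion_geometry(spec)
    nwm <- geom$followup & !geom$baseline
    sz <- spec$image_size
    seeds <- round(stats::runif(3, 1, 2^30))
    baseline <- generate_texture_field(sz, cp$NWM, seeds[1])
    baseline <- paint(baseline, nwm,
                      generate_texture_field(sz, cp$NWM, seeds[2]))
    followup <- generate_texture_field(sz, cp$NWM, seeds[3])
    metadata <- list(
      age = max(60, round(stats::rnorm(1, 74.8, 5.5))),
      sex = sample(c("F", "M"), 1, prob = c(0.431, 0.569)),
      interval_days = max(366, round(stats::rlnorm(1, log(581), 0.3))),
      fazekas = 0L
    )
    structure(
      list(
        subject_id = subject_id, group = "control",
        baseline = baseline, followup = followup,
        masks = list(NWM = roi_mask(nwm, "NWM", subject_id)),
        metadata = metadata
      ),
      class = "subject_record"
    )
  })
}

#' Generate a full longitudinal cohort
#'
#' `n_cases` case subjects (each contributing `dNAWM` and `non_dNAWM` ROIs)
#' and `n_controls` control subjects (one `NWM` ROI each); with the default
#' 51 + 51 design this yields 153 analysis ROIs. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort`: `subjects` (list of `subject_record`)
#'   and the `spec`.
#' @export
generate_cohort <- function(spec) {
  subjects <- vector("list", spec$n_cases + spec$n_controls)
  for (i in seq_len(spec$n_cases)) {
    subjects[[i]] <- generate_case_subject(
      spec, derive_seed(spec$seed, i, stream = 1L),
      sprintf("case_%03d", i)
    )
  }
  for (i in seq_len(spec$n_controls)) {
    subjects[[spec$n_cases + i]] <- generate_control_subject(
      spec, derive_seed(spec$seed, i, stream = 2L),
      sprintf("control_%03d", i)
    )
  }
  structure(list(subjects = subjects, spec = spec), class = "cohort")
}

#' Generate a null cohort (no tissue-class effect)
#'
#' Identical to [generate_cohort()] except all three ROI classes share one
#' set of texture parameters, so any downstream class discrimination is pure
#' type-I error. Used as the calibration harness for the selection and
#' evaluation statistics.
#'
#' @param spec a [cohort_spec()].
#' @param shared_params the single [texture_params()] used for every class;
#'   defaults to the spec's `NWM` parameters (the lesion intensity boost is
#'   retained so the masks remain constructible).
#' @return A `cohort`.
#' @export
generate_null_cohort <- function(spec, shared_params = NULL) {
  shared <- shared_params %||% spec$class_params$NWM
  boost <- spec$class_params$dNAWM$lesion_intensity_boost
  shared_lesion <- shared
  shared_lesion$lesion_intensity_boost <- boost
  null_spec <- spec
  null_spec$class_params <- list(
    NWM = shared, non_dNAWM = shared, dNAWM = shared_lesion
  )
  generate_cohort(null_spec)
}

#' Extract the feature matrix of a cohort
#'
#' Runs [extract_battery()] on every analysis ROI (cases: `dNAWM` and
#' `non_dNAWM` on the baseline image; controls: `NWM`).
#'
#' @param cohort a `cohort`.
#' @param config a [battery_config()].
#' @return A data.frame: `subject_id`, `group`, `roi_label`, then one column
#'   per feature.
#' @export
extract_cohort_features <- function(cohort, config = battery_config()) {
  rows <- list()
  for (s in cohort$subjects) {
    labs <- if (s$group == "case") c("dNAWM", "non_dNAWM") else "NWM"
    for (lab in labs) {
      fv <- extract_battery(s$baseline, s$masks[[lab]], config)
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = s$subject_id, group = s$group, roi_label = lab),
        as.list(fv)
      )
    }
  }
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' Images and masks are written as single-slice NIfTI volumes (identity
#' affine scaled by the pixel spacing); ROI labels are carried in the
#' manifest CSV, not in NIfTI headers.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param pixel_spacing in-plane spacing in mm.
#' @return Invisibly, the manifest data.frame (also written to
#'   `manifest.csv`).
#' @export
write_cohort <- function(cohort, dir, pixel_spacing = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    base_path <- file.path(dir, sprintf("%s_baseline.nii.gz", s$subject_id))
    fu_path <- file.path(dir, sprintf("%s_followup.nii.gz", s$subject_id))
    RNifti::writeNifti(nifti_slice(s$baseline, pixel_spacing), base_path)
    RNifti::writeNifti(nifti_slice(s$followup, pixel_spacing), fu_path)
    for (lab in names(s$masks)) {
      mpath <- file.path(dir, sprintf("%s_mask_%s.nii.gz", s$subject_id, lab))
      RNifti::writeNifti(
        nifti_slice(s$masks[[lab]]$pixels * 1L, pixel_spacing), mpath
      )
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, roi_label = lab,
        image = basename(base_path), followup = basename(fu_path),
        mask = basename(mpath),
        age = s$metadata$age, sex = s$metadata$sex,
        interval_days = s$metadata$interval_days,
        fazekas = s$metadata$fazekas,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

nifti_slice <- function(mat, pixel_spacing = 1) {
  arr <- array(mat, dim = c(dim(mat), 1L))
  RNifti::asNifti(arr, pixdim = c(pixel_spacing, pixel_spacing, 1))
}
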