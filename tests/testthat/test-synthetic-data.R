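test_that("texture fields are deterministic with the requested moments", {
  p <- texture_params(noise_sd = 10)
  f1 <- generate_texture_field(c(64, 64), p, seed = 5)
  f2 <- generate_texture_field(c(64, 64), p, seed = 5)
  expect_identical(f1, f2)
  expect_false(identical(
    f1, generate_texture_field(c(64, 64), p, seed = 6)
  ))
  # degenerate noise: constant image at the mean
  f0 <- generate_texture_field(c(32, 32), texture_params(noise_sd = 0), 1)
  expect_true(all(f0 == 500))
  # empirical moments over several seeds
  for (s in c(11, 12, 13)) {
    f <- generate_texture_field(c(256, 256), p, seed = s)
    expect_equal(mean(f), 500, tolerance = 1e-6)
    expect_lt(abs(sd(f) - 10) / 10, 0.1)
  }
  expect_error(generate_texture_field(c(8, 8), p, 1),
               class = "nawmrad_invalid_argument")
  expect_error(texture_params(correlation_length = 0),
               class = "nawmrad_invalid_argument")
})

test_that("case subjects have nested lesions and valid annulus ROIs", {
  spec <- small_cohort_spec(seed = 4)
  for (s in 1:5) {
    subj <- generate_case_subject(spec, seed = 100 + s)
    base <- subj$masks$WMH_baseline$pixels
    fu <- subj$masks$WMH_followup$pixels
    expect_true(all(fu[base]))          # containment
    expect_gt(sum(fu), sum(base))       # strict superset
    ann <- subj$masks$dNAWM$pixels
    expect_identical(sum(ann), sum(fu) - sum(base)) # set-difference count
    expect_gte(sum(ann), spec$roi_min_pixels)
    expect_gte(sum(subj$masks$non_dNAWM$pixels), spec$roi_min_pixels)
    expect_identical(dim(subj$baseline), dim(subj$followup))
  }
})

test_that("default-size ROIs satisfy the 100-pixel rule", {
  spec <- cohort_spec(n_cases = 3, n_controls = 2, seed = 9)
  coh <- generate_cohort(spec)
  for (subj in coh$subjects) {
    for (m in subj$masks) {
      if (m$label %in% c("dNAWM", "non_dNAWM", "NWM")) {
        expect_true(validate_roi(m, 100)$pass)
      }
    }
  }
})

test_that("cohort bookkeeping: ROI counts and determinism", {
  spec <- small_cohort_spec(seed = 2, n = 2)
  coh <- generate_cohort(spec)
  f <- extract_cohort_features(coh, battery_config(
    offsets = 1, feature_groups = "histogram", min_pixels = 50
  ))
  expect_identical(nrow(f), 2L * 2L + 2L) # 2 ROIs per case + 1 per control
  expect_identical(sum(f$roi_label == "dNAWM"), 2L)
  # single-subject cohort gives 3 ROIs
  f1 <- extract_cohort_features(
    generate_cohort(small_cohort_spec(seed = 3, n = 1)),
    battery_config(offsets = 1, feature_groups = "histogram", min_pixels = 50)
  )
  expect_identical(nrow(f1), 3L)
  # identical specs give identical downstream feature matrices
  f2 <- extract_cohort_features(generate_cohort(small_cohort_spec(seed = 2, n = 2)),
                                battery_config(offsets = 1,
                                               feature_groups = "histogram",
                                               min_pixels = 50))
  expect_identical(f, f2)
})

test_that("null cohorts with dNAWM-equal shared params match case texture", {
  spec <- small_cohort_spec(seed = 6, n = 2)
  shared <- spec$class_params$dNAWM
  null_spec_cohort <- generate_null_cohort(spec, shared_params = shared)
  # all-classes-shared: the dNAWM ROI texture is generated by the same
  # parameter set as in the signal cohort
  s_null <- null_spec_cohort$subjects[[1]]
  expect_identical(s_null$group, "case")
  # and the null cohort remains deterministic
  again <- generate_null_cohort(spec, shared_params = shared)
  expect_identical(s_null$baseline, again$subjects[[1]]$baseline)
})

test_that("generation failure surfaces as a diagnostic condition", {
  spec <- cohort_spec(n_cases = 1, n_controls = 1, image_size = c(96, 96),
                      roi_min_pixels = 5000, seed = 1)
  expect_error(generate_case_subject(spec, 1),
               class = "nawmrad_generation_failure")
})

test_that("written cohorts round-trip through NIfTI with a manifest", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_cohort_spec(seed = 8, n = 1))
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(nrow(man), 4L + 1L) # 4 case masks + 1 control mask
  img <- as.array(RNifti::readNifti(file.path(dir, man$image[1])))
  expect_equal(dim(img)[1:2], dim(coh$subjects[[1]]$baseline))
  expect_equal(as.vector(img), as.vector(coh$subjects[[1]]$baseline),
               tolerance = 1e-6)
})
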