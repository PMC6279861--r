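test_that("battery is deterministic and matches its manifest", {
  set.seed(77)
  img <- matrix(runif(900, 0, 100), 30, 30)
  msk <- matrix(FALSE, 30, 30); msk[5:26, 5:26] <- TRUE
  cfg <- battery_config()
  fv1 <- extract_battery(img, msk, cfg)
  fv2 <- extract_battery(img, msk, cfg)
  expect_identical(fv1, fv2)
  man <- battery_manifest(cfg)
  expect_identical(names(fv1), man$feature)
  # 13 histogram + 5 form + (10 glcm + 11 rlm) * 6 variants * 3 offsets
  expect_identical(nrow(man), 13L + 5L + 21L * 18L)
})

test_that("battery contains the published selected-feature names", {
  man <- battery_manifest(battery_config())$feature
  published <- c(
    "Uniformity", "stdDeviation",
    "InverseDifferenceMoment_AllDirection_offset7",
    "InverseDifferenceMoment_angle90_offset4",
    "InverseDifferenceMoment_angle135_offset7",
    "Correlation_AllDirection_offset4_SD",
    "SumEntropy_AllDirection_offset1",
    "DifferenceEntropy_AllDirection_offset1",
    "ShortRunLowGreyLevelEmphasis_AllDirection_offset1_SD",
    "ShortRunEmphasis_angle90_offset7",
    "GreyLevelNonuniformity_angle90_offset1",
    "ShortRunEmphasis_AllDirection_offset7",
    "LongRunHighGreyLevelEmphasis_AllDirection_offset7",
    "ShortRunEmphasis_angle135_offset4",
    "ShortRunEmphasis_AllDirection_offset4_SD",
    "LongRunHighGreyLevelEmphasis_angle135_offset7",
    "ShortRunHighGreyLevelEmphasis_AllDirection_offset4_SD",
    "LongRunHighGreyLevelEmphasis_angle0_offset7"
  )
  expect_true(all(published %in% man))
})

test_that("constant ROI reaches the homogeneity limits", {
  img <- matrix(42, 24, 24)
  msk <- matrix(FALSE, 24, 24); msk[3:22, 3:22] <- TRUE
  fv <- extract_battery(img, msk)
  expect_equal(fv[["Uniformity"]], 1)
  expect_equal(fv[["InverseDifferenceMoment_AllDirection_offset7"]], 1)
  expect_equal(fv[["entropy"]], 0)
})

test_that("undersized ROIs are rejected, AllDirection equals per-angle mean", {
  img <- matrix(runif(400), 20, 20)
  msk <- matrix(FALSE, 20, 20); msk[1:5, 1:5] <- TRUE
  expect_error(extract_battery(img, msk), class = "nawmrad_invalid_argument")
  msk[1:12, 1:12] <- TRUE
  fv <- extract_battery(img, msk)
  per_angle <- fv[sprintf("Contrast_angle%d_offset1", c(0, 45, 90, 135))]
  expect_equal(unname(fv[["Contrast_AllDirection_offset1"]]),
               mean(per_angle))
  expect_equal(unname(fv[["Contrast_AllDirection_offset1_SD"]]),
               sqrt(mean((per_angle - mean(per_angle))^2)))
})

test_that("feature bounds hold on random patches", {
  for (i in 1:10) {
    q <- NULL
    set.seed(400 + i)
    img <- matrix(runif(625, 0, 50), 25, 25)
    msk <- matrix(runif(625) < 0.85, 25, 25)
    if (sum(msk) < 120) next
    fv <- extract_battery(img, msk)
    expect_gt(fv[["Uniformity"]], 0); expect_lte(fv[["Uniformity"]], 1)
    for (d in c(1, 4, 7)) {
      idm <- fv[[sprintf("InverseDifferenceMoment_AllDirection_offset%d", d)]]
      sre <- fv[[sprintf("ShortRunEmphasis_AllDirection_offset%d", d)]]
      rp <- fv[[sprintf("RunPercentage_AllDirection_offset%d", d)]]
      expect_gt(idm, 0); expect_lte(idm, 1)
      expect_gt(sre, 0); expect_lte(sre, 1)
      expect_gt(rp, 0);  expect_lte(rp, 1)
    }
  }
})

test_that("homogeneity features fall as texture heterogeneity rises", {
  # increasing gray-level dispersion (the generator's heterogeneity axis)
  msk <- matrix(TRUE, 40, 40)
  ws <- c(0, 0.25, 0.5, 0.75)
  u <- idm <- numeric(length(ws))
  for (k in seq_along(ws)) {
    us <- idms <- numeric(0)
    for (s in 1:12) {
      p <- texture_params(noise_sd = 30, correlation_length = 2.5,
                          dispersion = ws[k])
      f <- generate_texture_field(c(40, 40), p, seed = 9000 + s)
      fv <- extract_battery(f, msk, battery_config(
        offsets = 7, feature_groups = c("histogram", "glcm"),
        min_pixels = 50
      ))
      us <- c(us, fv[["Uniformity"]])
      idms <- c(idms, fv[["InverseDifferenceMoment_AllDirection_offset7"]])
    }
    u[k] <- mean(us); idm[k] <- mean(idms)
  }
  expect_true(all(diff(u) < 0))
  expect_true(all(diff(idm) < 0))
})
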