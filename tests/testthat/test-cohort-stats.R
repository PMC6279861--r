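test_that("published 2x2 risk-factor tables reproduce their chi-squares", {
  counts <- clinical_cohort_counts()
  printed <- c(female = 0.040, hypertension = 3.151, diabetes = 3.303,
               hyperlipidemia = 1.700, smoking = 1.038, drinking = 0.189,
               atrial_fibrillation = 0.505)
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    got <- chi_square_2x2(r$case_pos, r$case_neg, r$control_pos, r$control_neg)
    expect_equal(round(got$statistic, 3),
                 unname(printed[r$characteristic]),
                 info = r$characteristic)
  }
})

test_that("chi-square is invariant under row and column swaps, 0 for equality", {
  a <- chi_square_2x2(41, 10, 33, 18)
  swapped <- chi_square_2x2(matrix(c(18, 33, 10, 41), 2, byrow = TRUE))
  expect_equal(a$statistic, swapped$statistic, tolerance = 1e-12)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chi_square_2x2(5, 0, 7, 0),
               class = "nawmrad_invalid_argument")
})

test_that("chi-square matches the observed-vs-expected summation oracle", {
  set.seed(19)
  for (i in 1:15) {
    m <- matrix(rpois(4, 20) + 1, 2)
    exp_ <- outer(rowSums(m), colSums(m)) / sum(m)
    ref <- sum((m - exp_)^2 / exp_)
    expect_equal(chi_square_2x2(m)$statistic, ref, tolerance = 1e-10)
  }
})

test_that("t-test from printed summaries agrees with the published age row", {
  r <- t_test_two_sample(list(n = 51, mean = 76.61, sd = 7.72),
                         list(n = 51, mean = 74.82, sd = 5.47))
  # computed from the rounded summaries; the printed 1.347 used raw data
  expect_equal(r$t, 1.35, tolerance = 0.01)
  expect_equal(r$p_value, 0.18, tolerance = 0.01)
  # identical summaries: t = 0, p = 1
  same <- t_test_two_sample(list(n = 10, mean = 5, sd = 1),
                            list(n = 10, mean = 5, sd = 1))
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
})

test_that("t-test raw-sample mode equals summary mode and stats::t.test", {
  set.seed(23)
  x <- rnorm(20, 1); y <- rnorm(25)
  raw <- t_test_two_sample(x, y)
  summ <- t_test_two_sample(list(n = 20, mean = mean(x), sd = sd(x)),
                            list(n = 25, mean = mean(y), sd = sd(y)))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$p_value, ref$p.value, tolerance = 1e-12)
  w <- t_test_two_sample(x, y, pooled = FALSE)
  refw <- t.test(x, y)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
})

test_that("Mann-Whitney U follows the min convention and the pair oracle", {
  dom <- mann_whitney_u(11:18, 1:8)        # full dominance
  expect_equal(dom$U, 0)
  expect_equal(dom$U_x, 64)
  eq <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$p_value, 1, tolerance = 1e-9)
  set.seed(29)
  x <- sample(1:10, 8, replace = TRUE); y <- sample(1:10, 8, replace = TRUE)
  got <- mann_whitney_u(x, y)
  # exhaustive pairwise comparison count
  ux <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(got$U_x, ux)
  expect_equal(got$U, min(ux, 64 - ux))
})

test_that("synthetic cohort baseline table carries the expected tests", {
  coh <- generate_cohort(cohort_spec(n_cases = 25, n_controls = 25,
                                     image_size = c(64, 64),
                                     roi_min_pixels = 60, seed = 31))
  tab <- cohort_table(coh)
  expect_identical(tab$characteristic,
                   c("female", "age", "interval_days", "fazekas_median"))
  expect_true(all(is.finite(tab$statistic[1:3])))
  expect_true(all(tab$p_value[1:3] >= 0 & tab$p_value[1:3] <= 1))
})
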