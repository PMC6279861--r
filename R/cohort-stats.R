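#' Pearson chi-square test of a 2x2 contingency table
#'
#' `statistic = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, 1 degree of
#' freedom. The Yates continuity correction is off by default, the
#' convention that reproduces case-control risk-factor tables computed on
#' raw counts.
#'
#' @param a,b,c,d cell counts: case-positive, case-negative,
#'   control-positive, control-negative. Alternatively `a` may be a 2x2
#'   matrix or length-4 vector.
#' @param correction apply the Yates continuity correction.
#' @return A list with `statistic`, `df`, and `p_value`.
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           correction = FALSE) {
  if (is.matrix(a)) {
    m <- a
  } else if (length(a) == 4L) {
    m <- matrix(as.numeric(a), 2, byrow = TRUE)
  } else {
    m <- matrix(as.numeric(c(a, b, c, d)), 2, byrow = TRUE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop_invalid("cell counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_invalid("all table marginals must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correction))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-sample t-test from raw samples or summary statistics
#'
#' Student's pooled-variance t-test (default) or Welch's test, accepting
#' either raw numeric vectors or `(n, mean, sd)` summaries - the latter is
#' how published group summaries are re-tested.
#'
#' @param x,y numeric vectors, or lists/named vectors with elements `n`,
#'   `mean`, `sd`.
#' @param pooled pooled-variance Student's t (default) vs Welch.
#' @return A list with `t`, `df`, and `p_value`.
#' @export
t_test_two_sample <- function(x, y, pooled = TRUE) {
  summarize <- function(z) {
    if (is.list(z) || !is.null(names(z))) {
      list(n = as.numeric(z[["n"]]), mean = as.numeric(z[["mean"]]),
           sd = as.numeric(z[["sd"]]))
    } else {
      list(n = length(z), mean = mean(z), sd = stats::sd(z))
    }
  }
  sx <- summarize(x); sy <- summarize(y)
  if (sx$n < 2 || sy$n < 2) stop_invalid("need n >= 2 per group")
  if (sx$sd == 0 && sy$sd == 0) {
    if (sx$mean == sy$mean) return(list(t = 0, df = sx$n + sy$n - 2, p_value = 1))
    stop_invalid("zero variance in both groups")
  }
  if (pooled) {
    sp2 <- ((sx$n - 1) * sx$sd^2 + (sy$n - 1) * sy$sd^2) / (sx$n + sy$n - 2)
    se <- sqrt(sp2 * (1 / sx$n + 1 / sy$n))
    df <- sx$n + sy$n - 2
  } else {
    v1 <- sx$sd^2 / sx$n; v2 <- sy$sd^2 / sy$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (sx$n - 1) + v2^2 / (sy$n - 1))
  }
  t <- (sx$mean - sy$mean) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistics with a tie-corrected two-sided normal
#' approximation. The headline `U` follows the `min(U_x, U_y)` convention
#' (0 when one sample completely dominates the other); both one-sided U
#' statistics are also returned since software conventions differ.
#'
#' @param x,y numeric samples.
#' @return A list with `U` (min convention), `U_x`, `U_y`, and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop_invalid("need >= 1 observation per group")
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  )
  list(U = min(ux, uy), U_x = ux, U_y = uy, p_value = p)
}

#' Baseline-characteristics table for a synthetic cohort
#'
#' Summarizes case vs control demographics the way clinical baseline tables
#' do: sex by chi-square, age by pooled t-test, scan interval by
#' Mann-Whitney, plus descriptive Fazekas medians.
#'
#' @param cohort a `cohort` from [generate_cohort()], or its metadata
#'   data.frame with columns `group`, `age`, `sex`, `interval_days`,
#'   `fazekas`.
#' @return A data.frame with one row per characteristic: summaries per
#'   group, the test statistic, and the p-value.
#' @export
cohort_table <- function(cohort) {
  meta <- if (inherits(cohort, "cohort")) {
    do.call(rbind, lapply(cohort$subjects, function(s) {
      data.frame(group = s$group, age = s$metadata$age, sex = s$metadata$sex,
                 interval_days = s$metadata$interval_days,
                 fazekas = s$metadata$fazekas, stringsAsFactors = FALSE)
    }))
  } else {
    as.data.frame(cohort)
  }
  case <- meta[meta$group == "case", ]
  ctrl <- meta[meta$group == "control", ]
  fm_case <- sum(case$sex == "F"); fm_ctrl <- sum(ctrl$sex == "F")
  sex <- chi_square_2x2(fm_case, nrow(case) - fm_case,
                        fm_ctrl, nrow(ctrl) - fm_ctrl)
  age <- t_test_two_sample(case$age, ctrl$age)
  intv <- mann_whitney_u(case$interval_days, ctrl$interval_days)
  fmt_iqr <- function(z) {
    q <- stats::quantile(z, c(.25, .5, .75))
    sprintf("%.0f (%.0f, %.0f)", q[2], q[1], q[3])
  }
  data.frame(
    characteristic = c("female", "age", "interval_days", "fazekas_median"),
    case = c(
      sprintf("%d (%.2f%%)", fm_case, 100 * fm_case / nrow(case)),
      sprintf("%.2f +/- %.2f", mean(case$age), stats::sd(case$age)),
      fmt_iqr(case$interval_days),
      fmt_iqr(case$fazekas)
    ),
    control = c(
      sprintf("%d (%.2f%%)", fm_ctrl, 100 * fm_ctrl / nrow(ctrl)),
      sprintf("%.2f +/- %.2f", mean(ctrl$age), stats::sd(ctrl$age)),
      fmt_iqr(ctrl$interval_days),
      fmt_iqr(ctrl$fazekas)
    ),
    statistic = c(sex$statistic, age$t, intv$U, NA),
    p_value = c(sex$p_value, age$p_value, intv$p_value, NA),
    stringsAsFactors = FALSE
  )
}

#' Clinical risk-factor counts of the motivating case-control cohort
#'
#' Published 2x2 counts (case-positive, case-negative, control-positive,
#' control-negative; 51 subjects per group) for the seven binary baseline
#' characteristics of the motivating clinical cohort, shipped so the
#' contingency statistics can be recomputed with [chi_square_2x2()].
#'
#' @return A data.frame with columns `characteristic`, `case_pos`,
#'   `case_neg`, `control_pos`, `control_neg`.
#' @export
clinical_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_characteristics.csv",
                      package = "nawmrad", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
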