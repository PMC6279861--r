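#' ROC curve, AUC with confidence interval, and Youden operating point
#'
#' Builds the empirical ROC curve and computes the trapezoidal AUC (equal to
#' the normalized Mann-Whitney U statistic with half credit for ties), a 95%
#' confidence interval (DeLong by default, stratified bootstrap as the
#' alternative), and the operating point maximizing the Youden index
#' (sensitivity + specificity - 1), ties resolved toward the lower
#' threshold.
#'
#' @param probs numeric scores or probabilities.
#' @param labels binary class vector; the second factor level is positive.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf confidence level (default 0.95).
#' @param boot_n bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed seed for the bootstrap.
#' @return A list of class `roc_result`: `auc`, `auc_ci`, `thresholds`,
#'   `sensitivities`, `specificities`, and `operating_point`.
#' @export
roc_auc <- function(probs, labels, ci_method = c("delong", "bootstrap"),
                    conf = 0.95, boot_n = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop_invalid("both classes must be present")
  r <- pROC::roc(response = g, predictor = as.numeric(probs),
                 levels = levels(g), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(r, conf.level = conf, method = "delong"))
  } else {
    with_local_seed(seed, as.numeric(pROC::ci.auc(
      r, conf.level = conf, method = "bootstrap",
      boot.n = boot_n, progress = "none"
    )))
  }
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"), transpose = FALSE)
  youden <- co$sensitivity + co$specificity - 1
  best <- which(youden == max(youden))
  best <- best[which.min(co$threshold[best])]
  structure(
    list(
      auc = auc, auc_ci = c(low = ci[1], high = ci[3]),
      thresholds = co$threshold, sensitivities = co$sensitivity,
      specificities = co$specificity,
      operating_point = c(
        threshold = co$threshold[best],
        sensitivity = co$sensitivity[best],
        specificity = co$specificity[best]
      )
    ),
    class = "roc_result"
  )
}

#' Hosmer-Lemeshow calibration test
#'
#' Deciles-of-risk goodness-of-fit test: samples are partitioned by
#' quantiles of the predicted probability (ties kept together), and the
#' statistic sums `(O - E)^2 / (E (1 - E / n_g))` over groups, which equals
#' the observed-vs-expected chi-square over both outcome columns. Groups
#' whose expected event count is 0 are merged with their neighbor. The
#' p-value uses `groups - 2` degrees of freedom, the reference distribution
#' for probabilities fitted by a logistic model.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcome (second factor level = event).
#' @param groups number of risk groups (default 10).
#' @return A list of class `hl_result`: `statistic`, `df`, `p_value`, and
#'   the per-group observed/expected `table`.
#' @export
hosmer_lemeshow <- function(probs, labels, groups = 10) {
  y <- as.integer(factor(labels)) - 1L
  n <- length(y)
  if (n < groups) stop_invalid("need at least `groups` observations")
  qs <- stats::quantile(probs, probs = seq(0, 1, length.out = groups + 1),
                        names = FALSE)
  brk <- unique(qs)
  if (length(brk) < 3) brk <- c(-Inf, mean(range(probs)), Inf)
  grp <- cut(probs, breaks = brk, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(table(grp)),
    observed = as.vector(tapply(y, grp, sum)),
    expected = as.vector(tapply(probs, grp, sum))
  )
  tab <- tab[tab$n > 0, , drop = FALSE]
  # merge groups with degenerate expected counts into their lower neighbor
  i <- 2L
  while (i <= nrow(tab)) {
    if (tab$expected[i] <= 0 || tab$expected[i] >= tab$n[i]) {
      tab$n[i - 1] <- tab$n[i - 1] + tab$n[i]
      tab$observed[i - 1] <- tab$observed[i - 1] + tab$observed[i]
      tab$expected[i - 1] <- tab$expected[i - 1] + tab$expected[i]
      tab <- tab[-i, , drop = FALSE]
      message("merged a degenerate risk group with its neighbor")
    } else {
      i <- i + 1L
    }
  }
  if (tab$expected[1] <= 0 && nrow(tab) > 1) {
    tab$n[2] <- tab$n[2] + tab$n[1]
    tab$observed[2] <- tab$observed[2] + tab$observed[1]
    tab$expected[2] <- tab$expected[2] + tab$expected[1]
    tab <- tab[-1, , drop = FALSE]
  }
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- nrow(tab) - 2L
  structure(
    list(
      statistic = stat, df = df,
      p_value = stats::pchisq(stat, df, lower.tail = FALSE),
      table = tab
    ),
    class = "hl_result"
  )
}

#' Intraclass correlation coefficient, two-way random, absolute agreement
#'
#' ICC(2,1) (single measures) from the two-way random-effects ANOVA
#' decomposition of a subjects x raters matrix, with the F-distribution
#' confidence interval of McGraw and Wong. This is the conventional form for
#' inter- and intra-observer agreement of repeated feature measurements.
#'
#' @param ratings numeric matrix, subjects in rows, raters/occasions in
#'   columns (>= 2 raters, >= 5 subjects).
#' @param conf confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci`, the mean squares, and
#'   a `degenerate` flag (zero between-subject variance).
#' @export
icc_agreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop_invalid("need >= 2 raters")
  if (n < 5) stop_invalid("need >= 5 subjects")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= mse) {
    return(structure(
      list(icc = 0, ci = c(low = NA_real_, high = NA_real_),
           msr = msr, msc = msc, mse = mse, degenerate = TRUE),
      class = "icc_result"
    ))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (icc >= 1 - 1e-12) {
    return(structure(
      list(icc = 1, ci = c(low = 1, high = 1),
           msr = msr, msc = msc, mse = mse, degenerate = FALSE),
      class = "icc_result"
    ))
  }
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(
    list(icc = icc, ci = c(low = lower, high = upper),
         msr = msr, msc = msc, mse = mse, degenerate = FALSE),
    class = "icc_result"
  )
}
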