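#' Stage 1: univariate ANOVA + Mann-Whitney filter
#'
#' Keeps features whose class difference is significant under both the
#' two-group one-way ANOVA (equivalent to the pooled t-test for two groups)
#' and the two-sided Mann-Whitney U test (normal approximation with tie
#' correction). The conservative "both tests" combination is the default; a
#' union mode is available. Constant features (tests undefined) are excluded
#' with a warning. No multiple-testing correction is applied by default,
#' matching a single p <= alpha criterion; Benjamini-Hochberg is available.
#'
#' @param x numeric matrix or data.frame of features (samples x features).
#' @param labels binary class vector (two levels).
#' @param alpha significance level (default 0.05).
#' @param mode `"both"` (pass both tests) or `"either"`.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Character vector of surviving feature names, with a `report`
#'   attribute (data.frame of per-feature p-values).
#' @export
univariate_filter <- function(x, labels, alpha = 0.05,
                              mode = c("both", "either"), adjust = "none") {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop_invalid("exactly two classes are required")
  if (min(table(g)) < 2L) stop_invalid("need >= 2 samples per class")
  i1 <- g == levels(g)[1]
  p_anova <- p_mw <- rep(NA_real_, ncol(x))
  dropped <- logical(ncol(x))
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    if (anyNA(v) || stats::sd(v) == 0 ||
        (stats::sd(v[i1]) == 0 && stats::sd(v[!i1]) == 0)) {
      dropped[k] <- TRUE
      next
    }
    p_anova[k] <- stats::oneway.test(v ~ g, var.equal = TRUE)$p.value
    p_mw[k] <- suppressWarnings(
      stats::wilcox.test(v[i1], v[!i1], exact = FALSE, correct = FALSE)$p.value
    )
  }
  if (any(dropped)) {
    warning(sprintf(
      "%d constant/degenerate feature(s) excluded from the univariate filter",
      sum(dropped)
    ))
  }
  pa <- stats::p.adjust(p_anova, method = adjust)
  pm <- stats::p.adjust(p_mw, method = adjust)
  keep <- if (mode == "both") {
    !dropped & pa <= alpha & pm <= alpha
  } else {
    !dropped & (pa <= alpha | pm <= alpha)
  }
  keep[is.na(keep)] <- FALSE
  out <- colnames(x)[keep]
  attr(out, "report") <- data.frame(
    feature = colnames(x), p_anova = p_anova, p_mw = p_mw,
    dropped = dropped, kept = keep, stringsAsFactors = FALSE
  )
  out
}

#' Stage 2: Spearman redundancy pruning
#'
#' Iteratively removes one member of the most-correlated feature pair until
#' no pair exceeds `rho_max` in absolute Spearman correlation. Within the
#' offending pair, the member with the larger mean absolute correlation
#' against all other remaining features is dropped; ties are broken by the
#' larger univariate p-value (when supplied) and then by reverse
#' lexicographic name, making the procedure deterministic.
#'
#' @param x numeric matrix/data.frame restricted to stage-1 survivors.
#' @param rho_max absolute Spearman correlation threshold (default 0.9).
#' @param priority optional named numeric vector of univariate p-values used
#'   for tie-breaking (smaller p = kept preferentially).
#' @return Character vector of surviving feature names.
#' @export
redundancy_filter <- function(x, rho_max = 0.9, priority = NULL) {
  x <- as.matrix(x)
  feats <- colnames(x)
  if (length(feats) < 2L) return(feats)
  rho <- abs(stats::cor(x, method = "spearman"))
  diag(rho) <- 0
  keep <- feats
  while (length(keep) >= 2L) {
    sub <- rho[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= rho_max) break
    # most-correlated pair; deterministic pick among ties
    hits <- which(sub == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_names <- cbind(keep[hits[, 1]], keep[hits[, 2]])
    ord <- order(pair_names[, 1], pair_names[, 2])
    pair <- pair_names[ord[1], ]
    mean_rho <- rowMeans(sub[pair, , drop = FALSE])
    drop <- if (mean_rho[1] > mean_rho[2]) {
      pair[1]
    } else if (mean_rho[2] > mean_rho[1]) {
      pair[2]
    } else if (!is.null(priority) && all(pair %in% names(priority)) &&
               priority[pair[1]] != priority[pair[2]]) {
      pair[which.max(priority[pair])]
    } else {
      max(pair) # reverse lexicographic: keep the smaller name
    }
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Stage 3: LASSO-penalized logistic selection
#'
#' Fits the L1-penalized logistic regression path on internally standardized
#' training features (zero mean, unit SD) and picks the penalty by
#' stratified n-fold cross-validated binomial deviance at the minimum-mean
#' rule (the one-standard-error rule is available). Returns the features
#' with nonzero coefficients at the chosen penalty.
#'
#' @param x numeric matrix of training features (stage-2 survivors).
#' @param labels binary class vector.
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @return List with `features`, `weights` (nonzero coefficients on the
#'   standardized scale), `lambda`, and the `cv` object.
#' @export
lasso_select <- function(x, labels, n_folds = 10, seed = 1,
                         lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  y <- as.integer(factor(labels)) - 1L
  if (min(table(y)) < n_folds) {
    stop_invalid("need at least `n_folds` samples per class")
  }
  xs <- scale(x)
  foldid <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  cv <- glmnet::cv.glmnet(
    xs, y, family = "binomial", type.measure = "deviance",
    foldid = foldid, standardize = FALSE
  )
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  nz <- co[co != 0]
  if (length(nz) == 0L) {
    warning("LASSO selected no feature at the chosen penalty")
  }
  list(features = names(nz), weights = nz, lambda = lam, cv = cv)
}

#' Run the three-stage feature-selection cascade
#'
#' Applies, on the training rows only, the univariate ANOVA + Mann-Whitney
#' filter, Spearman redundancy pruning, and LASSO-penalized logistic
#' selection in sequence. Test rows never influence any stage. Survivors are
#' nested: stage 3 is a subset of stage 2 is a subset of stage 1.
#'
#' @param x numeric matrix/data.frame (all samples x features).
#' @param labels binary class vector aligned with `x` rows.
#' @param train logical vector marking training rows.
#' @param alpha stage-1 significance level.
#' @param rho_max stage-2 Spearman threshold.
#' @param n_folds stage-3 cross-validation folds.
#' @param seed stage-3 fold seed.
#' @param mode stage-1 combination rule.
#' @param lambda_rule stage-3 penalty rule.
#' @return A list of class `selection_result`: `stage1`, `stage2`, `stage3`
#'   survivor name vectors, `lasso_lambda`, `nonzero_weights`, and a
#'   `report` with the stage-1 p-values.
#' @export
run_cascade <- function(x, labels, train = rep(TRUE, length(labels)),
                        alpha = 0.05, rho_max = 0.9, n_folds = 10, seed = 1,
                        mode = "both", lambda_rule = "min") {
  x <- as.matrix(x)
  # rows or columns with missing values never enter the cascade
  bad_col <- colSums(is.na(x)) > 0
  if (any(bad_col)) {
    warning(sprintf("%d feature(s) with missing values excluded", sum(bad_col)))
    x <- x[, !bad_col, drop = FALSE]
  }
  xt <- x[train, , drop = FALSE]
  yt <- labels[train]
  s1 <- univariate_filter(xt, yt, alpha = alpha, mode = mode)
  report <- attr(s1, "report")
  s1 <- as.character(s1)
  if (length(s1) == 0L) {
    return(structure(
      list(stage1 = character(0), stage2 = character(0),
           stage3 = character(0), lasso_lambda = NA_real_,
           nonzero_weights = numeric(0), report = report),
      class = "selection_result"
    ))
  }
  prio <- stats::setNames(
    pmax(report$p_anova, report$p_mw, na.rm = TRUE), report$feature
  )
  s2 <- redundancy_filter(xt[, s1, drop = FALSE], rho_max = rho_max,
                          priority = prio[s1])
  if (length(s2) >= 1L && min(table(yt)) >= n_folds) {
    las <- lasso_select(xt[, s2, drop = FALSE], yt, n_folds = n_folds,
                        seed = seed, lambda_rule = lambda_rule)
    s3 <- las$features
    lam <- las$lambda
    w <- las$weights
  } else {
    s3 <- character(0); lam <- NA_real_; w <- numeric(0)
  }
  stopifnot(all(s3 %in% s2), all(s2 %in% s1))
  structure(
    list(stage1 = s1, stage2 = s2, stage3 = s3, lasso_lambda = lam,
         nonzero_weights = w, report = report),
    class = "selection_result"
  )
}
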