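#' Stratified train/test split
#'
#' Randomly assigns samples to training and test sets with per-class
#' largest-remainder (half-up) rounding, so a balanced 51 + 51 design at the
#' 7:3 proportion yields exactly 72 training and 30 test samples.
#'
#' @param labels class vector (any number of classes when `stratify`).
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @param stratify stratify by class (default `TRUE`).
#' @return Logical vector, `TRUE` for training rows.
#' @export
split_train_test <- function(labels, train_fraction = 0.7, seed = 1,
                             stratify = TRUE) {
  if (train_fraction < 0 || train_fraction > 1) {
    stop_invalid("`train_fraction` must be in [0, 1]")
  }
  g <- factor(labels)
  if (stratify && any(table(g) < 2L)) {
    stop_invalid("every class needs >= 2 samples for a stratified split")
  }
  n <- length(labels)
  is_train <- logical(n)
  with_local_seed(seed, {
    if (stratify) {
      for (lev in levels(g)) {
        idx <- which(g == lev)
        k <- floor(train_fraction * length(idx) + 0.5)
        k <- min(length(idx), k)
        is_train[sample(idx, k)] <- TRUE
      }
    } else {
      k <- floor(train_fraction * n + 0.5)
      is_train[sample.int(n, min(n, k))] <- TRUE
    }
  })
  is_train
}

#' Fit an unpenalized multivariable logistic model
#'
#' Maximum-likelihood logistic regression on the selected features, with
#' internal standardization (training mean and SD, reused verbatim at
#' prediction time). Complete or quasi-complete separation is detected and
#' flagged with a warning (coefficients are unstable); non-convergence is an
#' error.
#'
#' @param x numeric matrix/data.frame of training features.
#' @param labels binary class vector; the second factor level is the
#'   positive class.
#' @param features feature names to use (default: all columns of `x`).
#' @param standardize standardize features before fitting (default `TRUE`).
#' @return An object of class `nawm_logistic`: `intercept`, `weights` (on
#'   the standardized scale), `center`, `scale`, `features`, `separation`
#'   flag, fitted `train_probs`, and `n_train`.
#' @export
fit_logistic <- function(x, labels, features = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  features <- features %||% colnames(x)
  x <- x[, features, drop = FALSE]
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop_invalid("two classes are required")
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- stats::setNames(rep(0, ncol(x)), features)
    scl <- stats::setNames(rep(1, ncol(x)), features)
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  dat <- data.frame(y = y, xs, check.names = FALSE)
  fit <- stats::glm(
    y ~ ., data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  )
  if (!fit$converged) {
    stop(errorCondition("logistic fit did not converge",
                        class = c("nawmrad_nonconvergence", "nawmrad_error")))
  }
  p <- stats::fitted(fit)
  separation <- all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
  if (separation) {
    warning("complete separation detected; coefficients are unstable")
  }
  co <- stats::coef(fit)
  structure(
    list(
      intercept = unname(co[1]),
      weights = stats::setNames(unname(co[-1]), features),
      center = stats::setNames(unname(ctr), features),
      scale = stats::setNames(unname(scl), features),
      features = features, separation = separation,
      train_probs = unname(p), n_train = length(y),
      positive_level = levels(factor(labels))[2]
    ),
    class = "nawm_logistic"
  )
}

#' Predict class probability from a fitted logistic model
#'
#' Applies the training standardization statistics and the logistic link:
#' `1 / (1 + exp(-(intercept + sum(w * z))))`.
#'
#' @param model a `nawm_logistic`.
#' @param newdata named numeric vector, matrix or data.frame holding every
#'   model feature.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_prob <- function(model, newdata) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  missing <- setdiff(model$features, colnames(newdata))
  if (length(missing) > 0) {
    stop_invalid(sprintf("missing model feature(s): %s",
                         paste(missing, collapse = ", ")))
  }
  z <- sweep(sweep(newdata[, model$features, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  eta <- model$intercept + drop(z %*% model$weights)
  stats::plogis(eta)
}
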