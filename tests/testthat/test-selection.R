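make_signal_matrix <- function(n = 72, p_noise = 20, seed = 1,
                               delta = 2, n_signal = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * (p_noise + n_signal)), n)
  colnames(x) <- c(sprintf("signal%02d", seq_len(n_signal)),
                   sprintf("noise%02d", seq_len(p_noise)))
  for (k in seq_len(n_signal)) x[, k] <- x[, k] + delta * y
  list(x = x, y = y)
}

test_that("univariate filter keeps separated features, drops flat ones", {
  d <- make_signal_matrix(n = 72, p_noise = 10, delta = 8)
  x <- cbind(d$x, flat = rep(3, 72))
  expect_warning(kept <- univariate_filter(x, d$y), "constant")
  expect_true("signal01" %in% kept)
  expect_false("flat" %in% kept)
  rep_ <- attr(kept, "report")
  # disjoint class supports: both tests deeply significant
  expect_lt(rep_$p_anova[rep_$feature == "signal01"], 1e-6)
  expect_lt(rep_$p_mw[rep_$feature == "signal01"], 1e-6)
})

test_that("identically distributed feature across classes is dropped", {
  set.seed(7)
  y <- rep(0:1, each = 20)
  x <- cbind(same = rep(seq_len(20), 2)) # identical values in both classes
  expect_length(univariate_filter(x, y), 0)
})

test_that("stage-1 pass rate on null features calibrates to alpha", {
  set.seed(123)
  n_feat <- 300
  rates <- numeric(4)
  for (r in 1:4) {
    y <- rep(0:1, each = 30)
    x <- matrix(rnorm(60 * n_feat), 60, dimnames = list(NULL, paste0("f", 1:n_feat)))
    rates[r] <- length(univariate_filter(x, y)) / n_feat
  }
  n_tests <- 4 * n_feat
  band <- qbinom(c(0.005, 0.995), n_tests, 0.05) / n_tests
  expect_gte(mean(rates), band[1])
  expect_lte(mean(rates), band[2])
})

test_that("redundancy filter removes duplicates and respects the threshold", {
  set.seed(11)
  a <- rnorm(50)
  x <- cbind(a1 = a, a2 = a, b = rnorm(50))
  kept <- redundancy_filter(x, rho_max = 0.9)
  expect_length(kept, 2)
  expect_true("b" %in% kept)
  expect_length(intersect(kept, c("a1", "a2")), 1)
  # all pairwise below the threshold: identity
  x2 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_identical(redundancy_filter(x2, rho_max = 0.9), letters[1:4])
})

test_that("redundancy filter matches a greedy enumeration oracle", {
  greedy_oracle <- function(x, rho_max) {
    rho <- abs(cor(x, method = "spearman")); diag(rho) <- 0
    keep <- colnames(x)
    repeat {
      sub <- rho[keep, keep, drop = FALSE]
      if (length(keep) < 2 || max(sub) <= rho_max) break
      hit <- which(sub == max(sub), arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      pn <- cbind(keep[hit[, 1]], keep[hit[, 2]])
      pn <- pn[order(pn[, 1], pn[, 2])[1], ]
      mr <- rowMeans(sub[pn, , drop = FALSE])
      drop <- if (mr[1] > mr[2]) pn[1] else if (mr[2] > mr[1]) pn[2] else max(pn)
      keep <- setdiff(keep, drop)
    }
    keep
  }
  set.seed(17)
  for (i in 1:10) {
    base <- rnorm(40)
    x <- cbind(
      v = base, w = base + rnorm(40, 0, 0.1), y = base + rnorm(40, 0, 0.2),
      z = rnorm(40), u = rnorm(40)
    )
    expect_identical(redundancy_filter(x, rho_max = 0.8),
                     greedy_oracle(x, 0.8))
  }
})

test_that("LASSO recovers a planted signal among noise features", {
  hits <- 0
  for (s in 1:10) {
    d <- make_signal_matrix(n = 72, p_noise = 30, seed = 100 + s, delta = 3)
    sel <- lasso_select(d$x, d$y, seed = s)
    if ("signal01" %in% sel$features) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("LASSO selection is deterministic and shrinks to empty at huge penalty", {
  d <- make_signal_matrix(seed = 5)
  s1 <- lasso_select(d$x, d$y, seed = 42)
  s2 <- lasso_select(d$x, d$y, seed = 42)
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$weights, s2$weights)
  # penalty-dominance limit: all coefficients zero at very large lambda
  fit <- glmnet::glmnet(scale(d$x), d$y, family = "binomial",
                        standardize = FALSE)
  co <- as.matrix(coef(fit, s = 1e6))[-1, 1]
  expect_true(all(co == 0))
})

test_that("cascade nests stages and uses training rows only", {
  d <- make_signal_matrix(n = 100, p_noise = 25, seed = 3, delta = 2.5,
                          n_signal = 3)
  train <- rep(c(TRUE, FALSE), times = c(70, 30))
  sel <- run_cascade(d$x, d$y, train = train, seed = 1)
  expect_true(all(sel$stage3 %in% sel$stage2))
  expect_true(all(sel$stage2 %in% sel$stage1))
  # leakage check: perturbing test rows must not change the selection
  x2 <- d$x
  x2[!train, ] <- x2[sample(which(!train)), sample(ncol(x2))]
  sel2 <- run_cascade(x2, d$y, train = train, seed = 1)
  expect_identical(sel$stage1, sel2$stage1)
  expect_identical(sel$stage2, sel2$stage2)
  expect_identical(sel$stage3, sel2$stage3)
  expect_identical(sel$nonzero_weights, sel2$nonzero_weights)
})

test_that("cascade recovers planted informative features most of the time", {
  hits <- 0
  for (s in 1:10) {
    d <- make_signal_matrix(n = 102, p_noise = 25, seed = 200 + s,
                            delta = 2.5, n_signal = 3)
    train <- split_train_test(d$y, seed = s)
    sel <- run_cascade(d$x, d$y, train = train, seed = s)
    planted <- sprintf("signal%02d", 1:3)
    if (all(planted %in% sel$stage3)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
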