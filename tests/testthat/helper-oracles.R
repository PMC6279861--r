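# Brute-force reference implementations, independent of the package's
# vectorized code paths. All operate on a dense bin grid (NA outside mask).

oracle_grid <- function(qpatch) {
  r <- qpatch$rows - min(qpatch$rows) + 1L
  c <- qpatch$cols - min(qpatch$cols) + 1L
  g <- matrix(NA_integer_, max(r), max(c))
  g[cbind(r, c)] <- qpatch$bins
  g
}

oracle_displacement <- function(angle, d) {
  switch(as.character(angle),
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d)
  )
}

# O(N^2)-style GLCM: loop over every pixel, look up its displaced partner.
oracle_glcm <- function(qpatch, angle, d, symmetric = TRUE) {
  g <- oracle_grid(qpatch)
  dd <- oracle_displacement(angle, d)
  ng <- qpatch$ng
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(g))) {
    for (c in seq_len(ncol(g))) {
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nrow(g) || c2 < 1 || c2 > ncol(g)) next
      a <- g[r, c]; b <- g[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Run-length oracle: walk each stride-d subsequence pixel by pixel.
oracle_rlm <- function(qpatch, angle, d) {
  g <- oracle_grid(qpatch)
  nr <- nrow(g); nc <- ncol(g)
  step <- oracle_displacement(angle, 1)
  # starting points: cells with no in-grid predecessor along the direction
  runs <- list()
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      pr <- r0 - step[1]; pc <- c0 - step[2]
      if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next
      # full line from (r0, c0); then its d interleaved subsequences
      line <- integer(0)
      r <- r0; c <- c0
      while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
        line <- c(line, ifelse(is.na(g[r, c]), 0L, g[r, c]))
        r <- r + step[1]; c <- c + step[2]
      }
      for (p in seq_len(min(d, length(line)))) {
        sub <- line[seq(p, length(line), by = d)]
        cur <- 0L; len <- 0L
        for (v in c(sub, -1L)) {
          if (v == cur && v > 0L) {
            len <- len + 1L
          } else {
            if (cur > 0L) runs[[length(runs) + 1L]] <- c(cur, len)
            cur <- v; len <- 1L
          }
        }
      }
    }
  }
  if (length(runs) == 0) return(matrix(0, qpatch$ng, 1))
  m <- do.call(rbind, runs)
  counts <- matrix(0, qpatch$ng, max(m[, 2]))
  for (i in seq_len(nrow(m))) {
    counts[m[i, 1], m[i, 2]] <- counts[m[i, 1], m[i, 2]] + 1
  }
  counts
}

# Element-wise GLCM feature recomputation (plain double loops).
oracle_glcm_features <- function(P, log_base = 2) {
  ng <- nrow(P)
  energy <- entropy <- idm <- contrast <- 0
  sumav <- shade <- prom <- 0
  mux <- muy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    mux <- mux + i * P[i, j]; muy <- muy + j * P[i, j]
  }
  sx2 <- sy2 <- cov <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log(p, log_base)
    idm <- idm + p / (1 + (i - j)^2)
    contrast <- contrast + (i - j)^2 * p
    sx2 <- sx2 + (i - mux)^2 * p
    sy2 <- sy2 + (j - muy)^2 * p
    cov <- cov + (i - mux) * (j - muy) * p
    shade <- shade + (i + j - mux - muy)^3 * p
    prom <- prom + (i + j - mux - muy)^4 * p
  }
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  se <- de <- sa <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log(psum[k], log_base)
  }
  for (k in 1:ng) if (pdif[k] > 0) de <- de - pdif[k] * log(pdif[k], log_base)
  corr <- if (sx2 * sy2 > 0) cov / sqrt(sx2 * sy2) else 0
  c(Energy = energy, Entropy = entropy, InverseDifferenceMoment = idm,
    Contrast = contrast, Correlation = corr, SumAverage = sa,
    SumEntropy = se, DifferenceEntropy = de, ClusterShade = shade,
    ClusterProminence = prom)
}

oracle_rlm_features <- function(counts, np) {
  ng <- nrow(counts); rmax <- ncol(counts)
  nr <- sum(counts)
  acc <- stats::setNames(rep(0, 11), c(
    "ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
    "RunLengthNonuniformity", "RunPercentage", "LowGreyLevelRunEmphasis",
    "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
    "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
    "LongRunHighGreyLevelEmphasis"
  ))
  for (i in 1:ng) for (l in 1:rmax) {
    r <- counts[i, l]
    if (r == 0) next
    acc["ShortRunEmphasis"] <- acc["ShortRunEmphasis"] + r / l^2
    acc["LongRunEmphasis"] <- acc["LongRunEmphasis"] + r * l^2
    acc["LowGreyLevelRunEmphasis"] <- acc["LowGreyLevelRunEmphasis"] + r / i^2
    acc["HighGreyLevelRunEmphasis"] <- acc["HighGreyLevelRunEmphasis"] + r * i^2
    acc["ShortRunLowGreyLevelEmphasis"] <-
      acc["ShortRunLowGreyLevelEmphasis"] + r / (i^2 * l^2)
    acc["ShortRunHighGreyLevelEmphasis"] <-
      acc["ShortRunHighGreyLevelEmphasis"] + r * i^2 / l^2
    acc["LongRunLowGreyLevelEmphasis"] <-
      acc["LongRunLowGreyLevelEmphasis"] + r * l^2 / i^2
    acc["LongRunHighGreyLevelEmphasis"] <-
      acc["LongRunHighGreyLevelEmphasis"] + r * i^2 * l^2
  }
  for (i in 1:ng) {
    acc["GreyLevelNonuniformity"] <-
      acc["GreyLevelNonuniformity"] + sum(counts[i, ])^2
  }
  for (l in 1:rmax) {
    acc["RunLengthNonuniformity"] <-
      acc["RunLengthNonuniformity"] + sum(counts[, l])^2
  }
  acc <- acc / nr
  acc["RunPercentage"] <- nr / np
  acc
}

# Pair-counting AUC: U / (n1 n2) with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# Random masked patch for oracle-equivalence sweeps.
random_qpatch <- function(seed, max_dim = 12, ng = 8) {
  set.seed(seed)
  nr <- sample(4:max_dim, 1); nc <- sample(4:max_dim, 1)
  img <- matrix(stats::runif(nr * nc, 0, 100), nr, nc)
  msk <- matrix(stats::runif(nr * nc) < 0.75, nr, nc)
  if (sum(msk) < 4) msk[sample(nr * nc, 6)] <- TRUE
  q <- quantize(extract_patch(img, msk), ng = sample(2:ng, 1))
  q
}

small_cohort_spec <- function(seed = 1, n = 3) {
  cohort_spec(n_cases = n, n_controls = n, image_size = c(64, 64),
              roi_min_pixels = 60, seed = seed)
}
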