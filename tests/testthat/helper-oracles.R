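# Independent brute-force oracles, coded from the definitions alone.
# These deliberately avoid the package's vectorized implementations.

oracle_entropy <- function(values, bins = 64) {
  values <- values[is.finite(values)]
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(0)
  counts <- rep(0, bins)
  for (v in values) {
    b <- floor((v - lo) / (hi - lo) * bins) + 1
    if (b > bins) b <- bins
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / length(values)
      h <- h - p * log2(p)
    }
  }
  h
}

oracle_rms_norm <- function(values, duration_s) {
  s <- 0
  for (v in values) s <- s + v * v
  sqrt(s / length(values)) / duration_s
}

oracle_jerkiness <- function(values, duration_s) {
  d <- c()
  for (i in 2:length(values)) {
    dv <- values[i] - values[i - 1]
    if (dv != 0) d <- c(d, dv)
  }
  if (length(d) < 2) return(0)
  changes <- 0
  for (i in 2:length(d)) {
    if (sign(d[i]) != sign(d[i - 1])) changes <- changes + 1
  }
  changes / duration_s
}

# closed-form OLS slope via the normal equations
oracle_ols_slope <- function(y, x) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

oracle_coef_var <- function(values) {
  m <- mean(values)
  sqrt(sum((values - m)^2) / length(values)) / m
}

# ICC(3,k) from the two-way ANOVA decomposition written out longhand
# using aov() as the independent mean-squares engine
oracle_icc_3k <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(
    y = as.vector(ratings),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(y ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / msr
}

# Mann-Whitney U by literal pair counting (+1/2 per tie)
oracle_mwu <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) {
    if (a > b) u <- u + 1
    else if (a == b) u <- u + 0.5
  }
  u
}

# literal reading of the three impact-detection criteria: every local
# maximum, height > frac*max, steep rise before / fall after within the
# half-refractory window, refractory resolved keeping higher peaks
oracle_impacts <- function(svm, rate = 250, peak_frac = 0.2,
                           diff_frac = 0.2, min_sep = 0.166) {
  n <- length(svm)
  refrac <- ceiling(min_sep * rate)
  if (n <= refrac) return(integer(0))
  d <- diff(svm)
  height <- peak_frac * max(svm)
  up <- diff_frac * max(d); dn <- diff_frac * min(d)
  half <- max(1, floor(refrac / 2))
  cand <- c()
  for (i in 2:(n - 1)) {
    if (svm[i] > svm[i - 1] && svm[i] >= svm[i + 1] && svm[i] > height) {
      pre <- d[max(1, i - half):(i - 1)]
      post <- d[i:min(n - 1, i + half - 1)]
      if (any(pre > up) && any(post < dn)) cand <- c(cand, i)
    }
  }
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-svm[cand], cand)]
  kept <- c()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= refrac)) kept <- c(kept, i)
  }
  sort(kept)
}

# block-level hit counting: a true block is recalled when a detected block
# matches both boundaries within tol seconds
match_truth_blocks <- function(det, truth, rate = 250, tol = 1.25) {
  hit <- logical(nrow(truth))
  used <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(det))) {
      if (used[j]) next
      ds <- (det$start[j] - 1) / rate
      de <- (det$end[j] - 1) / rate
      if (abs(ds - truth$start[i]) <= tol && abs(de - truth$end[i]) <= tol) {
        hit[i] <- TRUE; used[j] <- TRUE; break
      }
    }
  }
  list(recall_hits = sum(hit), matched_det = sum(used))
}
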