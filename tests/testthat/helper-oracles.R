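# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# assignments of the rank vector.
oracle_wilcoxon_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(1.0)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  min(1, 2 * mean(w_plus <= w_obs))
}

# Batch ordinary least squares per voxel: returns contrast estimate and t.
oracle_batch_t <- function(X, Y, contrast) {
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  fitted <- X %*% beta
  df <- nrow(X) - qr(X)$rank
  sigma2 <- colSums((Y - fitted)^2) / df
  cxx <- drop(t(contrast) %*% XtXinv %*% contrast)
  cb <- drop(t(contrast) %*% beta)
  list(beta = cb, t = cb / sqrt(pmax(sigma2, 1e-12) * cxx), df = df)
}

# Per-TR hit counting by explicit looping.
oracle_classify <- function(s, cued_level, hit_rule = "met_or_exceeded",
                            hit_fraction = 0.5) {
  lo <- c(10, 40, 70)[cued_level]
  hi <- c(40, 70, Inf)[cued_level]
  n_hit <- 0L
  for (v in s) {
    hit <- if (hit_rule == "met_or_exceeded") v >= lo else (v >= lo && v < hi)
    if (hit) n_hit <- n_hit + 1L
  }
  list(n_hit = n_hit, success = n_hit >= ceiling(hit_fraction * length(s)))
}

# Occupancy / distance summaries by explicit looping.
oracle_metrics <- function(s, cued_level) {
  lo <- c(10, 40, 70)[cued_level]
  hi <- c(40, 70, Inf)[cued_level]
  d <- numeric(length(s))
  for (i in seq_along(s)) {
    v <- s[i]
    d[i] <- if (v >= lo && v < hi) 0 else min(abs(v - lo), abs(v - hi))
  }
  list(occupancy = sum(d == 0) / length(d), dist_median = median(d),
       dist_sd = sd(d))
}
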