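# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct summation, exhaustive enumeration, and
# closed-form geometry.

# Pearson statistic by direct O/E summation.
chi2_direct <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

wcss_of_partition <- function(X, assign) {
  s <- 0
  for (g in unique(assign)) {
    pts <- X[assign == g, , drop = FALSE]
    ctr <- colMeans(pts)
    s <- s + sum(sweep(pts, 2, ctr)^2)
  }
  s
}

# Global k-means optimum by exhaustive enumeration of all set partitions
# into exactly k non-empty groups (restricted-growth strings). Feasible
# for n <= 9, k <= 3.
best_partition_wcss <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  assign <- integer(n)
  rec <- function(i, maxg) {
    if (i > n) {
      if (maxg == k) best <<- min(best, wcss_of_partition(X, assign))
      return(invisible(NULL))
    }
    for (g in seq_len(min(maxg + 1L, k))) {
      assign[i] <<- g
      rec(i + 1L, max(maxg, g))
    }
  }
  rec(1L, 0L)
  best
}

# One-sample KS distance against a normal with sample mean/SD,
# D = sup |F_hat - Phi|, computed from first principles.
ks_D_direct <- function(x) {
  x <- sort(x)
  n <- length(x)
  z <- pnorm(x, mean(x), sd(x))
  max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1) / n))
}

# Distance-to-chord elbow pick computed directly (min-max normalized).
elbow_direct <- function(kv, wv) {
  x <- (kv - min(kv)) / (max(kv) - min(kv))
  y <- (wv - min(wv)) / (max(wv) - min(wv))
  m <- length(x)
  dx <- x[m] - x[1]; dy <- y[m] - y[1]
  d <- abs(dy * x - dx * y + x[m] * y[1] - y[m] * x[1]) / sqrt(dx^2 + dy^2)
  kv[which.max(d)]
}

# Published contingency counts (muscle rows in canonical order).
published_counts <- function() {
  m <- rbind(c(14, 12, 0, 0),
             c(0, 26, 0, 0),
             c(25, 1, 0, 0),
             c(0, 0, 0, 26),
             c(2, 24, 0, 0),
             c(19, 6, 0, 1),
             c(0, 0, 26, 0))
  dimnames(m) <- list(muscle = pifm_muscles(),
                      cluster = paste0("cluster", 1:4))
  m
}
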