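# Run code with a private RNG stream; the caller's .Random.seed survives.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Z-score a feature matrix
#'
#' Centers and scales each column to mean 0 and SD 1 using the sample SD
#' (n - 1 denominator, the convention of mainstream statistics packages).
#' The raw-scale means and SDs are retained so centroids can be mapped
#' back to cm^2 / cm.
#'
#' @param raw Numeric matrix (or data.frame) of raw features, n x p,
#'   typically columns (PCSA, FL); n >= 2.
#' @param sd_denom `"n-1"` (default, sample SD) or `"n"` (population SD).
#' @return List of class `pifm_features`: `X` (z-scored matrix),
#'   `column_means`, `column_sds`.
#' @export
zscore_features <- function(raw, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  X <- as.matrix(raw)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 samples to z-score", call. = FALSE)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (sd_denom == "n") sds <- sds * sqrt((nrow(X) - 1) / nrow(X))
  if (any(sds == 0)) {
    stop("zero-variance column(s): cannot z-score", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
  structure(list(X = Z, column_means = mu, column_sds = sds),
            class = "pifm_features")
}

# Squared Euclidean distances, n x k, between rows of X and rows of C.
dist2_matrix <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first centre uniform, each next with prob
# proportional to the squared distance to the nearest chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- dist2_matrix(X, X[centers[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, dist2_matrix(X, X[centers[j], , drop = FALSE])[, 1])
    }
  }
  X[centers, , drop = FALSE]
}

# One Lloyd run from given initial centroids. Converges when assignments
# stop changing or the WCSS improvement drops below tol; empty clusters
# are repaired by relocating the point farthest from its centroid.
lloyd_run <- function(X, centroids, max_iter = 300L, tol = 1e-10) {
  n <- nrow(X)
  k <- nrow(centroids)
  assign_prev <- integer(n)
  wcss_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_matrix(X, centroids)
    assignments <- max.col(-d2, ties.method = "first")
    # empty-cluster repair
    repeat {
      sizes <- tabulate(assignments, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      nearest <- d2[cbind(seq_len(n), assignments)]
      donor <- which.max(nearest)
      assignments[donor] <- empty[1]
      d2[donor, ] <- Inf
      d2[donor, empty[1]] <- 0
    }
    centroids <- rowsum(X, assignments) / tabulate(assignments, nbins = k)
    wcss <- sum((X - centroids[assignments, , drop = FALSE])^2)
    if (identical(assignments, assign_prev) ||
        (wcss_prev - wcss) < tol || iter >= max_iter) {
      return(list(assignments = assignments, centroids = centroids,
                  wcss = wcss, n_iter = iter))
    }
    assign_prev <- assignments
    wcss_prev <- wcss
  }
}

#' Seeded multi-restart k-means (Lloyd's algorithm, k-means++ seeding)
#'
#' Runs Lloyd's algorithm from `n_restarts` independent k-means++
#' initializations and returns the solution with the smallest
#' within-cluster sum of squares (WCSS). Restart r uses the RNG stream
#' seeded with `seed + r`, so the result is fully reproducible from
#' `(X, k, n_restarts, seed)` and individual restarts can be replayed.
#' Clusters in the returned result are re-indexed by descending first
#' feature (PCSA) centroid, ties broken by ascending second feature, so
#' cluster 1 is always the largest-PCSA group.
#'
#' @param X Numeric matrix, n x p (typically z-scored, p = 2).
#' @param k Number of clusters, 1 <= k <= n.
#' @param n_restarts Independent initializations (default 50).
#' @param seed Integer seed governing all restarts.
#' @param extra_inits Optional list of k x p matrices used as additional
#'   deterministic initializations (e.g. warm starts).
#' @return Object of class `pifm_kmeans`: `k`, `assignments` (1-based),
#'   `centroids`, `wcss`, `n_iter`, `seed`, `n_restarts`.
#' @export
pifm_kmeans <- function(X, k, n_restarts = 50L, seed = 1L,
                        extra_inits = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seed + r, kmeanspp_init(X, k))
    run <- lloyd_run(X, init)
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }
  for (init in extra_inits) {
    if (!is.matrix(init) || nrow(init) != k || ncol(init) != ncol(X)) next
    run <- lloyd_run(X, init)
    if (run$wcss < best$wcss) best <- run
  }
  ord <- order(-best$centroids[, 1],
               best$centroids[, min(2L, ncol(X))])
  relabel <- match(seq_len(k), ord)
  structure(
    list(k = as.integer(k),
         assignments = relabel[best$assignments],
         centroids = best$centroids[ord, , drop = FALSE],
         wcss = best$wcss,
         n_iter = best$n_iter,
         seed = as.integer(seed),
         n_restarts = as.integer(n_restarts)),
    class = "pifm_kmeans"
  )
}

#' @export
print.pifm_kmeans <- function(x, ...) {
  cat("k-means solution: k =", x$k, " WCSS =", format(x$wcss, digits = 6),
      "\ncluster sizes:", tabulate(x$assignments, nbins = x$k), "\n")
  invisible(x)
}

#' Within-cluster sum-of-squares curve over k
#'
#' Computes the multi-restart k-means WCSS at each k = 1..k_max. To
#' guarantee a monotone non-increasing curve, the best (k-1)-solution is
#' warm-started as an extra initialization at k (its centroids plus the
#' sample farthest from its assigned centroid).
#'
#' @param X Numeric matrix, n x p.
#' @param k_max Largest k (>= 2, <= n).
#' @param n_restarts Restarts per k.
#' @param seed Integer seed.
#' @return Object of class `pifm_wcss_curve`: data.frame `(k, wcss)` in
#'   `$curve` plus the per-k fits in `$fits`.
#' @export
wcss_curve <- function(X, k_max = 10L, n_restarts = 50L, seed = 1L) {
  X <- as.matrix(X)
  if (k_max < 2L) stop("k_max must be >= 2", call. = FALSE)
  if (k_max > nrow(X)) stop("k_max exceeds the number of samples",
                            call. = FALSE)
  fits <- vector("list", k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    extra <- NULL
    if (!is.null(prev)) {
      far <- which.max(rowSums(
        (X - prev$centroids[prev$assignments, , drop = FALSE])^2))
      extra <- list(rbind(prev$centroids, X[far, , drop = FALSE]))
    }
    fits[[k]] <- pifm_kmeans(X, k, n_restarts = n_restarts,
                             seed = seed + 1000L * k, extra_inits = extra)
    prev <- fits[[k]]
  }
  structure(
    list(curve = data.frame(k = seq_len(k_max),
                            wcss = vapply(fits, `[[`, 0, "wcss")),
         fits = fits),
    class = "pifm_wcss_curve"
  )
}

#' @export
print.pifm_wcss_curve <- function(x, ...) {
  print(x$curve)
  invisible(x)
}

#' Elbow-method selection of the number of clusters
#'
#' Normalizes both axes of the WCSS-vs-k curve to [0, 1] and returns the k
#' with the maximal perpendicular distance from the chord joining the
#' curve's endpoints (the knee of the curve). Ties are broken toward the
#' smallest k (parsimony).
#'
#' @param curve A `pifm_wcss_curve`, or a data.frame with columns
#'   `k, wcss` (>= 3 points).
#' @return Selected k (integer).
#' @export
#' @examples
#' select_k_elbow(data.frame(k = 1:5, wcss = c(100, 20, 18, 16, 14))) # 2
select_k_elbow <- function(curve) {
  if (inherits(curve, "pifm_wcss_curve")) curve <- curve$curve
  if (!all(c("k", "wcss") %in% names(curve))) {
    stop("curve needs columns k and wcss", call. = FALSE)
  }
  m <- nrow(curve)
  if (m < 3L) stop("need at least 3 points on the WCSS curve", call. = FALSE)
  x <- (curve$k - min(curve$k)) / (max(curve$k) - min(curve$k))
  span <- max(curve$wcss) - min(curve$wcss)
  y <- if (span > 0) (curve$wcss - min(curve$wcss)) / span else rep(0, m)
  # perpendicular distance from (x, y) to the chord (x1,y1)-(xm,ym)
  dx <- x[m] - x[1]
  dy <- y[m] - y[1]
  d <- abs(dy * x - dx * y + x[m] * y[1] - y[m] * x[1]) / sqrt(dx^2 + dy^2)
  best <- which(d >= max(d) - 1e-12)
  as.integer(curve$k[min(best)])
}

#' Map z-space centroids back to the raw feature scale
#'
#' @param centroids k x p matrix in z-space.
#' @param features The `pifm_features` object whose constants defined the
#'   z-transform.
#' @return k x p matrix in raw units.
#' @export
unscale_centroids <- function(centroids, features) {
  stopifnot(inherits(features, "pifm_features"))
  sweep(sweep(centroids, 2, features$column_sds, "*"),
        2, features$column_means, "+")
}
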