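#' Muscle-by-cluster contingency table
#'
#' Counts, for every muscle (rows, fixed canonical order) and every
#' cluster (columns), how many participants' samples of that muscle fell
#' in that cluster.
#'
#' @param assignments data.frame `(participant, muscle, cluster)` with
#'   1-based cluster labels.
#' @param k Number of clusters (columns); labels must not exceed it.
#' @return Integer matrix, muscles x k, with dimnames; attribute
#'   `n_samples` holds the grand total.
#' @export
build_contingency <- function(assignments, k) {
  need <- c("participant", "muscle", "cluster")
  missing_cols <- setdiff(need, names(assignments))
  if (length(missing_cols) > 0L) {
    stop("assignments missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_muscle(assignments$muscle, several.ok = TRUE)
  key <- paste(assignments$participant, assignments$muscle)
  if (anyDuplicated(key)) {
    stop("duplicated (participant, muscle) assignment(s)", call. = FALSE)
  }
  cl <- assignments$cluster
  if (any(cl < 1L | cl > k) || any(cl != round(cl))) {
    stop("cluster labels must be integers in 1..k", call. = FALSE)
  }
  muscles_present <- intersect(pifm_muscles(), unique(assignments$muscle))
  counts <- table(factor(assignments$muscle, levels = muscles_present),
                  factor(cl, levels = seq_len(k)))
  out <- matrix(as.integer(counts), nrow = length(muscles_present),
                dimnames = list(muscle = muscles_present,
                                cluster = paste0("cluster", seq_len(k))))
  attr(out, "n_samples") <- sum(out)
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Tests independence of muscle identity and cluster membership with the
#' Pearson statistic, no continuity correction. Empty clusters (all-zero
#' columns) are dropped with a warning before testing; an all-zero row is
#' an error.
#'
#' @param counts Integer matrix of counts (muscles x clusters).
#' @return List: `chi2`, `df`, `p_value`, `expected`, `dropped_clusters`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dropped <- which(colSums(counts) == 0)
  if (length(dropped) > 0L) {
    warning("dropping empty cluster column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
  }
  if (any(rowSums(counts) == 0)) {
    stop("contingency table has an all-zero row", call. = FALSE)
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least a 2 x 2 table after dropping empty clusters",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       expected = ct$expected,
       dropped_clusters = dropped)
}

#' Bonferroni-corrected pairwise cluster-frequency comparisons
#'
#' For each muscle, compares its membership frequencies between every pair
#' of clusters that both contain samples of that muscle, with a two-sided
#' exact binomial test of equal allocation applied to
#' `(count_a, count_a + count_b)`. P-values are Bonferroni-corrected
#' within each muscle's family of compared pairs (m = number of occupied
#' cluster pairs for that muscle); a muscle confined to a single cluster
#' yields no comparisons.
#'
#' @param counts Contingency matrix from [build_contingency()].
#' @param alpha Significance level after correction (default 0.05).
#' @return data.frame: `muscle, cluster_a, cluster_b, count_a, count_b,
#'   p_raw, p_adjusted, significant`.
#' @export
pairwise_cluster_comparisons <- function(counts, alpha = 0.05) {
  counts <- as.matrix(counts)
  muscles <- rownames(counts)
  if (is.null(muscles)) muscles <- paste0("row", seq_len(nrow(counts)))
  res <- list()
  for (i in seq_len(nrow(counts))) {
    occupied <- which(counts[i, ] > 0)
    if (length(occupied) < 2L) next
    pairs <- utils::combn(occupied, 2L)
    m <- ncol(pairs)
    for (j in seq_len(m)) {
      a <- pairs[1, j]; b <- pairs[2, j]
      ca <- counts[i, a]; cb <- counts[i, b]
      p_raw <- stats::binom.test(ca, ca + cb, p = 0.5)$p.value
      res[[length(res) + 1L]] <- data.frame(
        muscle = muscles[i], cluster_a = a, cluster_b = b,
        count_a = as.integer(ca), count_b = as.integer(cb),
        p_raw = p_raw, p_adjusted = min(1, p_raw * m),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L) {
    return(data.frame(muscle = character(), cluster_a = integer(),
                      cluster_b = integer(), count_a = integer(),
                      count_b = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample, with the Lilliefors correction for the
#' estimated parameters. Requires n >= 5 (the Lilliefors p-value
#' approximation is not defined below that).
#'
#' @param values Numeric vector, n >= 5, no missing values.
#' @return List: `statistic` (D), `p_value`.
#' @export
normality_screen <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  if (length(values) < 5L) {
    stop("normality screen needs at least 5 observations", call. = FALSE)
  }
  lt <- nortest::lillie.test(values)
  list(statistic = unname(lt$statistic), p_value = unname(lt$p.value))
}

#' Normality screen per muscle and feature
#'
#' @param estimates data.frame `(participant, muscle, est_fl_cm,
#'   est_pcsa_cm2)`.
#' @return data.frame `(muscle, feature, statistic, p_value)`.
#' @export
normality_screen_cohort <- function(estimates) {
  feats <- c(est_pcsa_cm2 = "pcsa", est_fl_cm = "fl")
  out <- list()
  for (m in intersect(pifm_muscles(), unique(estimates$muscle))) {
    for (col in names(feats)) {
      scr <- normality_screen(estimates[estimates$muscle == m, col])
      out[[length(out) + 1L]] <- data.frame(
        muscle = m, feature = feats[[col]],
        statistic = scr$statistic, p_value = scr$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# z-score -> ordinal size label; FL collapses the lowest two bins.
size_label <- function(z, lowest_two_distinct = TRUE) {
  if (z <= -1.5) if (lowest_two_distinct) "extremely small" else "short"
  else if (z <= -0.5) if (lowest_two_distinct) "small" else "short"
  else if (z < 0.5) "moderate"
  else if (lowest_two_distinct) "large" else "long"
}

#' Qualitative morphological profiles of clusters
#'
#' Maps each cluster's z-space centroid to ordinal labels: PCSA in
#' \{extremely small, small, moderate, large\} (cuts at -1.5, -0.5, +0.5)
#' and fiber length in \{short, moderate, long\} (cuts at -0.5, +0.5), and
#' renders a one-line narrative per cluster.
#'
#' @param centroids k x 2 matrix of z-space centroids, columns
#'   (z_pcsa, z_fl), rows in reporting order.
#' @return data.frame `(cluster, pcsa_label, fl_label, narrative)`.
#' @export
profile_clusters <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 2L) stop("centroids must be k x 2", call. = FALSE)
  if (nrow(centroids) < 2L) stop("need k >= 2 clusters", call. = FALSE)
  pcsa_label <- vapply(centroids[, 1], size_label, "", TRUE)
  fl_label <- vapply(centroids[, 2], size_label, "", FALSE)
  data.frame(
    cluster = seq_len(nrow(centroids)),
    pcsa_label = pcsa_label,
    fl_label = fl_label,
    narrative = sprintf("Cluster %d: %s PCSA and %s fiber length",
                        seq_len(nrow(centroids)), pcsa_label, fl_label),
    stringsAsFactors = FALSE
  )
}
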