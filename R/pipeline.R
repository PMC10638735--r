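#' Per-muscle mean and SD summary of a morphometry or estimates table
#'
#' @param records data.frame with a `muscle` column plus numeric
#'   measurement columns (e.g. `volume_cm3, length_cm` or
#'   `est_fl_cm, est_pcsa_cm2`).
#' @return data.frame: one row per muscle, `<col>_mean` and `<col>_sd`
#'   for each measurement column.
#' @export
summarize_morphometry <- function(records) {
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                      c("cluster"))
  muscles <- intersect(pifm_muscles(), unique(records$muscle))
  out <- do.call(rbind, lapply(muscles, function(m) {
    sub <- records[records$muscle == m, , drop = FALSE]
    row <- data.frame(muscle = m, stringsAsFactors = FALSE)
    for (col in num_cols) {
      row[[paste0(col, "_mean")]] <- mean(sub[[col]])
      row[[paste0(col, "_sd")]] <- stats::sd(sub[[col]])
    }
    row
  }))
  rownames(out) <- NULL
  out
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Orchestrates: cohort input (synthetic generation or a morphometry
#' table) -> fiber-length/PCSA estimation -> z-scoring -> elbow-method
#' model selection -> k-means -> contingency table, chi-square,
#' Bonferroni-corrected pairwise post-hoc comparisons, normality screen
#' and qualitative cluster profiles. Deterministic given the
#' configuration and seed.
#'
#' @param morphometry Optional data.frame `(participant, muscle,
#'   volume_cm3, length_cm)`. If NULL, a synthetic cohort is generated.
#' @param spec Cohort specification for synthetic mode (default:
#'   26 participants, shipped marginals).
#' @param reference Cadaveric reference table.
#' @param k Number of clusters, or `"elbow"` (default) to select it from
#'   the WCSS curve.
#' @param k_max Largest k scanned by the elbow rule.
#' @param n_restarts k-means restarts.
#' @param seed Integer seed (governs synthetic generation and k-means).
#' @param alpha Post-hoc significance level.
#' @param out_dir Optional directory; when given, all intermediate CSVs
#'   and the JSON report are written there.
#' @return Object of class `pifm_report`: a list with `morphometry`,
#'   `estimates`, `summary_morphometry`, `summary_estimates`, `features`,
#'   `wcss`, `k`, `k_mode`, `clustering`, `assignments`, `contingency`,
#'   `chi_square`, `posthoc`, `normality`, `profiles`, `n_samples`,
#'   `seed`, `config`.
#' @export
run_pipeline <- function(morphometry = NULL, spec = cohort_spec(),
                         reference = load_reference(), k = "elbow",
                         k_max = 10L, n_restarts = 50L, seed = 1L,
                         alpha = 0.05, out_dir = NULL) {
  config <- list(mode = if (is.null(morphometry)) "synthetic" else "table",
                 k = k, k_max = k_max, n_restarts = n_restarts,
                 alpha = alpha, seed = seed)
  if (is.null(morphometry)) {
    morphometry <- pipeline_stage("generate", generate_cohort(spec, seed))
  }
  estimates <- pipeline_stage("estimate",
                              estimate_cohort(morphometry, reference))
  features <- pipeline_stage("zscore", zscore_features(
    as.matrix(estimates[, c("est_pcsa_cm2", "est_fl_cm")])))
  colnames(features$X) <- c("z_pcsa", "z_fl")

  curve <- NULL
  if (identical(k, "elbow")) {
    curve <- pipeline_stage("elbow",
                            wcss_curve(features$X, k_max = k_max,
                                       n_restarts = n_restarts, seed = seed))
    k_sel <- select_k_elbow(curve)
    fit <- curve$fits[[k_sel]]
  } else {
    k_sel <- as.integer(k)
    fit <- pipeline_stage("kmeans",
                          pifm_kmeans(features$X, k_sel,
                                      n_restarts = n_restarts, seed = seed))
  }

  assignments <- data.frame(participant = estimates$participant,
                            muscle = estimates$muscle,
                            cluster = fit$assignments,
                            stringsAsFactors = FALSE)
  contingency <- pipeline_stage("stats",
                                build_contingency(assignments, k_sel))
  chi <- pipeline_stage("stats", pearson_chi_square(contingency))
  posthoc <- pipeline_stage("stats",
                            pairwise_cluster_comparisons(contingency, alpha))
  normality <- pipeline_stage("stats", normality_screen_cohort(estimates))
  profiles <- if (k_sel >= 2L) profile_clusters(fit$centroids) else NULL

  report <- structure(
    list(morphometry = morphometry,
         estimates = estimates,
         summary_morphometry = summarize_morphometry(morphometry),
         summary_estimates = summarize_morphometry(estimates),
         features = features,
         wcss = if (is.null(curve)) NULL else curve$curve,
         k = k_sel,
         k_mode = if (identical(k, "elbow")) "elbow" else "fixed",
         clustering = fit,
         assignments = assignments,
         contingency = contingency,
         chi_square = chi,
         posthoc = posthoc,
         normality = normality,
         profiles = profiles,
         n_samples = nrow(estimates),
         seed = as.integer(seed),
         config = config),
    class = "pifm_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pifm_report <- function(x, ...) {
  cat("PIFM classification report\n",
      "  samples: ", x$n_samples, " (",
      length(unique(x$morphometry$participant)), " participants x ",
      length(unique(x$morphometry$muscle)), " muscles)\n",
      "  k = ", x$k, " (", x$k_mode, "), WCSS = ",
      format(x$clustering$wcss, digits = 5), "\n",
      "  chi-square: ", format(x$chi_square$chi2, digits = 6),
      " on ", x$chi_square$df, " df, p = ",
      format(x$chi_square$p_value, digits = 3), "\n", sep = "")
  cat("  contingency table:\n")
  print(x$contingency)
  if (!is.null(x$profiles)) {
    for (s in x$profiles$narrative) cat("  ", s, "\n", sep = "")
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits morphometry, estimates, assignments, centroids (z and raw
#' scale), WCSS curve, contingency, post-hoc and normality CSVs plus a
#' machine-readable JSON report. Row order is bit-stable (canonical
#' muscle order, lexical participants).
#'
#' @param report A `pifm_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pifm_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  emit(report$morphometry, "morphometry.csv")
  emit(report$estimates, "estimates.csv")
  emit(report$assignments, "assignments.csv")
  cent <- as.data.frame(report$clustering$centroids)
  names(cent) <- c("z_pcsa", "z_fl")
  raw <- unscale_centroids(report$clustering$centroids, report$features)
  cent$raw_pcsa_cm2 <- raw[, 1]
  cent$raw_fl_cm <- raw[, 2]
  cent <- cbind(cluster = seq_len(nrow(cent)), cent)
  emit(cent, "centroids.csv")
  if (!is.null(report$wcss)) emit(report$wcss, "wcss_curve.csv")
  cont <- cbind(data.frame(muscle = rownames(report$contingency)),
                as.data.frame(unclass(report$contingency)))
  emit(cont, "contingency.csv")
  emit(report$posthoc, "posthoc.csv")
  emit(report$normality, "normality.csv")

  json <- list(
    n_samples = report$n_samples,
    k = report$k,
    k_mode = report$k_mode,
    wcss = report$clustering$wcss,
    chi_square = report$chi_square[c("chi2", "df", "p_value")],
    cluster_sizes = as.integer(colSums(report$contingency)),
    profiles = report$profiles,
    summary_morphometry = report$summary_morphometry,
    summary_estimates = report$summary_estimates,
    seed = report$seed,
    config = report$config,
    version = as.character(utils::packageVersion("pifmclass"))
  )
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths[[length(paths) + 1L]] <- jp
  invisible(unlist(paths))
}
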