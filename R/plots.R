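#' Elbow plot of the WCSS curve
#'
#' @param curve A `pifm_wcss_curve` or a data.frame `(k, wcss)`.
#' @param k_selected Optional k to highlight.
#' @return A ggplot object.
#' @export
plot_elbow <- function(curve, k_selected = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (inherits(curve, "pifm_wcss_curve")) curve <- curve$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = k, y = wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
  if (!is.null(k_selected)) {
    p <- p + ggplot2::geom_vline(xintercept = k_selected, linetype = 2)
  }
  p
}

#' Scatter plot of the clustered (PCSA, FL) feature space
#'
#' @param report A `pifm_report` from [run_pipeline()].
#' @param space `"raw"` (cm^2 / cm, default) or `"z"`.
#' @return A ggplot object; points shaped by muscle, coloured by cluster,
#'   centroids marked.
#' @export
plot_clusters <- function(report, space = c("raw", "z")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  space <- match.arg(space)
  stopifnot(inherits(report, "pifm_report"))
  df <- data.frame(
    muscle = muscle_factor(report$estimates$muscle),
    cluster = factor(report$assignments$cluster),
    pcsa = report$estimates$est_pcsa_cm2,
    fl = report$estimates$est_fl_cm
  )
  cent <- report$clustering$centroids
  labs <- c(x = "estimated PCSA (cm²)", y = "estimated FL (cm)")
  if (space == "z") {
    df$pcsa <- report$features$X[, 1]
    df$fl <- report$features$X[, 2]
    labs <- c(x = "z-scored PCSA", y = "z-scored FL")
  } else {
    cent <- unscale_centroids(cent, report$features)
  }
  cent_df <- data.frame(pcsa = cent[, 1], fl = cent[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = pcsa, y = fl)) +
    ggplot2::geom_point(ggplot2::aes(colour = cluster,
                                     shape = muscle), size = 2) +
    ggplot2::geom_point(data = cent_df, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::scale_shape_manual(values = c(16, 18, 8, 25, 3, 17, 15)) +
    ggplot2::labs(x = labs[["x"]], y = labs[["y"]]) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("k", "wcss", "cluster", "muscle", "pcsa", "fl"))
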