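#' Default per-muscle morphometry distribution parameters
#'
#' Per-muscle means and SDs of muscle volume (cm^3) and length (cm) for a
#' healthy young adult male cohort, used as the synthetic generator's
#' default marginals.
#'
#' @return data.frame `(muscle, volume_mean_cm3, volume_sd_cm3,
#'   length_mean_cm, length_sd_cm)`.
#' @export
cohort_defaults <- function() {
  path <- system.file("extdata", "cohort_defaults.csv",
                      package = "pifmclass", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Specification of a synthetic morphometry cohort
#'
#' @param n_participants Number of participants (>= 2; default 26).
#' @param params Per-muscle marginal parameters, a data.frame shaped like
#'   [cohort_defaults()] (the default).
#' @param participant_correlation Correlation rho in [0, 1) between each
#'   measurement and the participant's latent body-size factor (Gaussian
#'   copula); default 0.5.
#' @param distribution Marginal family: `"truncated-normal"` (truncated
#'   at 0; default) or `"log-normal"` (moment-matched).
#' @return Object of class `pifm_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 26L,
                        params = cohort_defaults(),
                        participant_correlation = 0.5,
                        distribution = c("truncated-normal", "log-normal")) {
  distribution <- match.arg(distribution)
  if (n_participants < 2L) stop("need n_participants >= 2", call. = FALSE)
  need <- c("muscle", "volume_mean_cm3", "volume_sd_cm3",
            "length_mean_cm", "length_sd_cm")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols) > 0L) {
    stop("params missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_muscle(params$muscle, several.ok = TRUE)
  vals <- unlist(params[, setdiff(need, "muscle")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all means and SDs must be positive", call. = FALSE)
  }
  rho <- participant_correlation
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("participant_correlation must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 params = params, rho = rho,
                 distribution = distribution),
            class = "pifm_cohort_spec")
}

# Inverse CDF of a normal(mean, sd) truncated to (0, Inf).
qtruncnorm0 <- function(p, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + p * (1 - p0), mean, sd)
}

# Moment-matched log-normal quantile.
qlnorm_mm <- function(p, mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  stats::qlnorm(p, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic morphometry cohort
#'
#' Each participant carries a latent standard-normal body-size factor `u`.
#' Every measurement (volume and length of each muscle) gets a standard
#' normal score `z = rho * u + sqrt(1 - rho^2) * eps` with independent
#' residuals `eps`, so each measurement correlates `rho` with the latent
#' factor (and `rho^2` with any other measurement of the same
#' participant). Scores are mapped through the Gaussian copula to the
#' target marginal: a normal(mean, sd) truncated at 0 (default) or a
#' moment-matched log-normal. Reproducible given the seed.
#'
#' @param spec A `pifm_cohort_spec` (default: 26 participants with the
#'   shipped marginals).
#' @param seed Integer seed.
#' @return data.frame `(participant, muscle, volume_cm3, length_cm)`,
#'   participants `P01...`, muscles in canonical order within participant.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "pifm_cohort_spec"))
  n <- spec$n_participants
  pm <- spec$params
  n_m <- nrow(pm)
  qfun <- switch(spec$distribution,
                 "truncated-normal" = qtruncnorm0,
                 "log-normal" = qlnorm_mm)
  with_seed(seed, {
    u <- stats::rnorm(n)
    draw <- function(mean, sd) {
      eps <- stats::rnorm(n)
      z <- spec$rho * u + sqrt(1 - spec$rho^2) * eps
      qfun(stats::pnorm(z), mean, sd)
    }
    rows <- lapply(seq_len(n_m), function(i) {
      data.frame(
        participant = sprintf("P%02d", seq_len(n)),
        muscle = pm$muscle[i],
        volume_cm3 = draw(pm$volume_mean_cm3[i], pm$volume_sd_cm3[i]),
        length_cm = draw(pm$length_mean_cm[i], pm$length_sd_cm[i]),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$participant, muscle_factor(out$muscle)), ]
    rownames(out) <- NULL
    out
  })
}

#' Voxelized elliptic-cylinder phantom stack with analytic ground truth
#'
#' Builds a segmented label stack from elliptic-cylinder primitives (one
#' per muscle) whose analytic volume (`pi * a * b * extent`) and length
#' are known in closed form, for validating the morphometry estimators.
#' A pixel belongs to a cylinder if its centre lies inside the ellipse.
#'
#' @param muscles data.frame with columns `muscle, center_row_cm,
#'   center_col_cm, radius_row_cm, radius_col_cm, first_slice, n_slices`
#'   (slice indices 0-based). May be empty.
#' @param n_slices Total slices in the stack.
#' @param grid_cm In-plane field of view (cm), square.
#' @param slice_thickness_cm Slice thickness (cm).
#' @param in_plane_pixel_cm Pixel size (cm).
#' @return List: `stack` (a `pifm_stack`, or NULL for an empty spec) and
#'   `truth` data.frame `(muscle, volume_cm3, length_cm)`.
#' @export
generate_label_stack <- function(muscles, n_slices = 30L, grid_cm = 6,
                                 slice_thickness_cm = 0.35,
                                 in_plane_pixel_cm = 0.05) {
  n_px <- max(1L, round(grid_cm / in_plane_pixel_cm))
  if (nrow(muscles) == 0L) {
    return(list(stack = NULL,
                truth = data.frame(muscle = character(),
                                   volume_cm3 = numeric(),
                                   length_cm = numeric())))
  }
  validate_muscle(muscles$muscle, several.ok = TRUE)
  centres <- (seq_len(n_px) - 0.5) * in_plane_pixel_cm
  labels <- array(0L, dim = c(n_slices, n_px, n_px))
  label_map <- stats::setNames(seq_len(nrow(muscles)), muscles$muscle)
  masks <- list()
  for (i in seq_len(nrow(muscles))) {
    g <- muscles[i, ]
    inside <- outer(((centres - g$center_row_cm) / g$radius_row_cm)^2,
                    ((centres - g$center_col_cm) / g$radius_col_cm)^2,
                    "+") <= 1
    slices <- g$first_slice + seq_len(g$n_slices) - 1L
    if (any(slices < 0L) || any(slices >= n_slices)) {
      stop("cylinder for ", g$muscle, " exceeds the stack extent",
           call. = FALSE)
    }
    for (j in seq_len(i - 1L)) {
      if (any(masks[[j]]$inside & inside) &&
          length(intersect(masks[[j]]$slices, slices)) > 0L) {
        stop("overlapping muscle primitives: ", muscles$muscle[j], " and ",
             g$muscle, call. = FALSE)
      }
    }
    masks[[i]] <- list(inside = inside, slices = slices)
    for (s in slices) {
      plane <- labels[s + 1L, , ]
      plane[inside] <- i
      labels[s + 1L, , ] <- plane
    }
  }
  truth <- data.frame(
    muscle = muscles$muscle,
    volume_cm3 = pi * muscles$radius_row_cm * muscles$radius_col_cm *
      muscles$n_slices * slice_thickness_cm,
    length_cm = muscles$n_slices * slice_thickness_cm,
    stringsAsFactors = FALSE
  )
  list(stack = segmented_stack(labels, slice_thickness_cm,
                               in_plane_pixel_cm, label_map),
       truth = truth)
}
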