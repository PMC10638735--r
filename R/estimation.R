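#' Estimated muscle fiber length
#'
#' Scales the whole-muscle length measured in vivo by the cadaveric
#' fiber-length-to-muscle-length ratio:
#' `FL (cm) = muscle length (cm) x ratio`. Kept at full precision; any
#' rounding is left to presentation.
#'
#' @param muscle_length_cm Muscle length in cm (> 0). Vectorized.
#' @param fl_to_length_ratio Dimensionless ratio in (0, 1]. Vectorized.
#' @return Estimated fiber length in cm.
#' @export
#' @examples
#' estimate_fiber_length(9.20, 0.47) # 4.324
estimate_fiber_length <- function(muscle_length_cm, fl_to_length_ratio) {
  if (any(!is.finite(muscle_length_cm)) || any(muscle_length_cm <= 0)) {
    stop("muscle_length_cm must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(fl_to_length_ratio)) ||
      any(fl_to_length_ratio <= 0 | fl_to_length_ratio > 1)) {
    stop("fl_to_length_ratio must lie in (0, 1]", call. = FALSE)
  }
  muscle_length_cm * fl_to_length_ratio
}

#' Estimated physiological cross-sectional area
#'
#' `PCSA (cm^2) = volume (cm^3) x cos(pennation) / estimated FL (cm)`.
#' Pennation is given in degrees (the unit the cadaveric tables print) and
#' converted to radians only inside the cosine.
#'
#' @param volume_cm3 Muscle volume in cm^3 (> 0). Vectorized.
#' @param pennation_deg Pennation angle in degrees, in [0, 90). Vectorized.
#' @param est_fl_cm Estimated fiber length in cm (> 0). Vectorized.
#' @return Estimated PCSA in cm^2.
#' @export
#' @examples
#' estimate_pcsa(10, 0, 2) # 5
estimate_pcsa <- function(volume_cm3, pennation_deg, est_fl_cm) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0)) {
    stop("volume_cm3 must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(pennation_deg)) ||
      any(pennation_deg < 0 | pennation_deg >= 90)) {
    stop("pennation_deg must lie in [0, 90)", call. = FALSE)
  }
  if (any(!is.finite(est_fl_cm)) || any(est_fl_cm <= 0)) {
    stop("est_fl_cm must be finite and > 0", call. = FALSE)
  }
  volume_cm3 * cos(pennation_deg * pi / 180) / est_fl_cm
}

#' Architecture estimates for a morphometry cohort
#'
#' Applies the fiber-length and PCSA equations to every
#' (participant, muscle) record, using the muscle-level cadaveric
#' parameters from the reference table. Cadaveric constants are applied
#' uniformly across participants; per-sample overrides for sensitivity
#' analyses can be injected via optional `ratio` / `pennation_deg` columns
#' in `morphometry`.
#'
#' @param morphometry data.frame `(participant, muscle, volume_cm3,
#'   length_cm)`.
#' @param reference Reference table from [load_reference()].
#' @return data.frame `(participant, muscle, est_fl_cm, est_pcsa_cm2)`,
#'   one row per input record, input order preserved.
#' @export
estimate_cohort <- function(morphometry, reference = load_reference()) {
  need <- c("participant", "muscle", "volume_cm3", "length_cm")
  missing_cols <- setdiff(need, names(morphometry))
  if (length(missing_cols) > 0L) {
    stop("morphometry missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(morphometry) == 0L) {
    return(data.frame(participant = character(), muscle = character(),
                      est_fl_cm = numeric(), est_pcsa_cm2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  validate_muscle(morphometry$muscle, several.ok = TRUE)
  key <- paste(morphometry$participant, morphometry$muscle)
  if (anyDuplicated(key)) {
    stop("duplicated (participant, muscle) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  n_muscle <- tapply(morphometry$muscle, morphometry$participant,
                     function(m) length(unique(m)))
  if (any(n_muscle < length(pifm_muscles()))) {
    warning("partial cohort: some participants lack one or more of the ",
            length(pifm_muscles()), " muscles", call. = FALSE)
  }
  ref <- reference_summary(reference)
  idx <- match(morphometry$muscle, ref$muscle)
  ratio <- if ("ratio" %in% names(morphometry)) {
    morphometry$ratio
  } else {
    ref$ratio[idx]
  }
  theta <- if ("pennation_deg" %in% names(morphometry)) {
    morphometry$pennation_deg
  } else {
    ref$pennation_deg[idx]
  }
  est_fl <- estimate_fiber_length(morphometry$length_cm, ratio)
  est_pcsa <- estimate_pcsa(morphometry$volume_cm3, theta, est_fl)
  data.frame(
    participant = morphometry$participant,
    muscle = morphometry$muscle,
    est_fl_cm = est_fl,
    est_pcsa_cm2 = est_pcsa,
    stringsAsFactors = FALSE
  )
}
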