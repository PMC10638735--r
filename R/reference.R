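#' Cadaveric architecture reference for the plantar intrinsic foot muscles
#'
#' Loads the per-muscle (and per-head) cadaveric architecture parameters:
#' the fiber-length-to-muscle-length ratio, the cadaveric fiber length, and
#' the pennation angle. The shipped defaults are the classical cadaveric
#' values for the seven large plantar intrinsic foot muscles; alternative
#' reference tables with the same columns can be supplied.
#'
#' The table has one `head == "all"` row per muscle carrying the printed
#' muscle-level values, plus one row per muscular head for the multi-head
#' muscles (FDB, FHB, QP). Muscle-level parameters used in estimation are
#' derived by [get_reference()].
#'
#' @param path Path to a reference CSV with columns
#'   `muscle, head, fl_to_length_ratio, cadaveric_fl_cm, pennation_deg,
#'   source`. Default: the table shipped with the package.
#' @return A data.frame with the columns above, validated.
#' @export
#' @examples
#' ref <- load_reference()
#' subset(ref, muscle == "QP")
load_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cadaveric_reference.csv",
                        package = "pifmclass", mustWork = TRUE)
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("muscle", "head", "fl_to_length_ratio",
                "cadaveric_fl_cm", "pennation_deg")
  missing_cols <- setdiff(required, names(ref))
  if (length(missing_cols) > 0L) {
    stop("reference table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_muscle(ref$muscle, several.ok = TRUE)
  absent <- setdiff(pifm_muscles(), ref$muscle)
  if (length(absent) > 0L) {
    stop("reference table lacks muscle(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ratio <- ref$fl_to_length_ratio
  if (any(!is.na(ratio) & (ratio <= 0 | ratio > 1))) {
    stop("fl_to_length_ratio values must lie in (0, 1]", call. = FALSE)
  }
  theta <- ref$pennation_deg
  if (any(!is.na(theta) & (theta < 0 | theta >= 90))) {
    stop("pennation_deg values must lie in [0, 90)", call. = FALSE)
  }
  fl <- ref$cadaveric_fl_cm
  if (any(!is.na(fl) & fl <= 0)) {
    stop("cadaveric_fl_cm values must be positive", call. = FALSE)
  }
  ref
}

#' Average architecture parameters across muscular heads
#'
#' Unweighted arithmetic mean at full precision. Used to collapse per-head
#' fiber-length-to-muscle-length ratios (or angles) to one muscle-level
#' value; no head-size weighting is applied and no intermediate rounding
#' is performed.
#'
#' @param values Numeric vector of finite per-head values (non-empty).
#' @return The arithmetic mean.
#' @export
#' @examples
#' average_heads(c(0.50, 0.44)) # quadratus plantae heads -> 0.47
#' average_heads(c(0.29, 0.26)) # flexor hallucis brevis heads -> 0.275
average_heads <- function(values) {
  if (length(values) == 0L) {
    stop("cannot average an empty set of head values", call. = FALSE)
  }
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("head values must be finite", call. = FALSE)
  }
  mean(values)
}

#' Muscle-level architecture parameters for one muscle
#'
#' Resolves the muscle-level fiber-length-to-muscle-length ratio and
#' pennation angle used by the estimation equations:
#' \itemize{
#'   \item ratio: the unweighted mean of the per-head ratios when every
#'     head carries one ([average_heads()], kept at full precision), or the
#'     printed muscle-level value when the head list is incomplete (FDB: the
#'     5th-toe head has no printed ratio) or the muscle has a single head;
#'   \item pennation: always the muscle-level value (`head == "all"` row).
#' }
#'
#' @param muscle One muscle code (see [pifm_muscles()]).
#' @param reference Reference table from [load_reference()].
#' @return A list with `ratio`, `pennation_deg`, `cadaveric_fl_cm`,
#'   `n_heads`.
#' @export
#' @examples
#' get_reference("ADDH_TH") # ratio 0.82, pennation 13.30
#' get_reference("FHB")$ratio # 0.275, the full-precision head mean
get_reference <- function(muscle, reference = load_reference()) {
  muscle <- validate_muscle(muscle)
  rows <- reference[reference$muscle == muscle, , drop = FALSE]
  muscle_row <- rows[rows$head == "all", , drop = FALSE]
  if (nrow(muscle_row) != 1L) {
    stop("reference table needs exactly one 'all' row for ", muscle,
         call. = FALSE)
  }
  head_rows <- rows[rows$head != "all", , drop = FALSE]
  if (nrow(head_rows) == 0L || anyNA(head_rows$fl_to_length_ratio)) {
    ratio <- muscle_row$fl_to_length_ratio
  } else {
    ratio <- average_heads(head_rows$fl_to_length_ratio)
  }
  if (is.na(ratio)) {
    stop("no usable fl_to_length_ratio for ", muscle, call. = FALSE)
  }
  list(
    ratio = ratio,
    pennation_deg = muscle_row$pennation_deg,
    cadaveric_fl_cm = muscle_row$cadaveric_fl_cm,
    n_heads = max(1L, nrow(head_rows))
  )
}

#' Muscle-level reference parameters for all muscles
#'
#' @param reference Reference table from [load_reference()].
#' @return data.frame with one row per muscle: `muscle, ratio,
#'   pennation_deg, cadaveric_fl_cm, n_heads`.
#' @export
reference_summary <- function(reference = load_reference()) {
  out <- do.call(rbind, lapply(pifm_muscles(), function(m) {
    p <- get_reference(m, reference)
    data.frame(muscle = m, ratio = p$ratio,
               pennation_deg = p$pennation_deg,
               cadaveric_fl_cm = p$cadaveric_fl_cm,
               n_heads = p$n_heads, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
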