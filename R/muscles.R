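#' The seven plantar intrinsic foot muscles handled by the package
#'
#' Returns the fixed, ordered vector of muscle codes: abductor hallucis
#' (ABDH), abductor digiti minimi (ABDM), adductor hallucis oblique head
#' (ADDH_OH), adductor hallucis transverse head (ADDH_TH), flexor digitorum
#' brevis (FDB), flexor hallucis brevis (FHB) and quadratus plantae (QP).
#' The three small plantar muscles (lumbricals, flexor digiti minimi,
#' plantar interossei) are outside the package's scope.
#'
#' This ordering is used everywhere a fixed muscle order matters
#' (contingency-table rows, CSV outputs, cohort generation).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' pifm_muscles()
pifm_muscles <- function() {
  c("ABDH", "ABDM", "ADDH_OH", "ADDH_TH", "FDB", "FHB", "QP")
}

#' Validate muscle codes
#'
#' @param muscle Character vector of candidate codes.
#' @param several.ok Allow more than one code?
#' @return The validated code(s), invisibly usable downstream.
#' @keywords internal
validate_muscle <- function(muscle, several.ok = FALSE) {
  if (!several.ok && length(muscle) != 1L) {
    stop("exactly one muscle code expected", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(muscle)), pifm_muscles())
  if (length(bad) > 0L) {
    stop(
      "unknown muscle code(s): ", paste(bad, collapse = ", "),
      " (valid: ", paste(pifm_muscles(), collapse = ", "), ")",
      call. = FALSE
    )
  }
  as.character(muscle)
}

# Muscle factor in canonical order; keeps CSV/contingency ordering stable.
muscle_factor <- function(muscle) {
  factor(as.character(muscle), levels = pifm_muscles())
}
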