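#' Construct a segmented label stack
#'
#' A segmented stack is the package's in-memory form of a muscle label map:
#' a 3-D integer array indexed (slice, row, col), slices ordered proximal
#' to distal, 0 = background, with positive codes mapped to muscle codes.
#' All geometry is in cm.
#'
#' @param labels 3-D integer array (slice x row x col).
#' @param slice_thickness_cm Slice thickness in cm (> 0); slices are
#'   contiguous (zero gap).
#' @param in_plane_pixel_cm In-plane pixel edge length in cm (> 0);
#'   pixels are square.
#' @param label_map Named integer vector mapping label codes to muscle
#'   codes, e.g. `c(ABDH = 1, QP = 2)`.
#' @param ml_axis Which in-plane axis runs medial to lateral; `"col"`
#'   (default) or `"row"`. Used only for the transverse-head in-plane
#'   length rule.
#' @return Object of class `pifm_stack`.
#' @export
segmented_stack <- function(labels, slice_thickness_cm, in_plane_pixel_cm,
                            label_map, ml_axis = c("col", "row")) {
  ml_axis <- match.arg(ml_axis)
  if (length(dim(labels)) != 3L) {
    stop("labels must be a 3-D array (slice x row x col)", call. = FALSE)
  }
  if (any(labels != round(labels))) {
    stop("labels must be integer-valued", call. = FALSE)
  }
  if (!is.numeric(slice_thickness_cm) || slice_thickness_cm <= 0) {
    stop("slice_thickness_cm must be > 0", call. = FALSE)
  }
  if (!is.numeric(in_plane_pixel_cm) || in_plane_pixel_cm <= 0) {
    stop("in_plane_pixel_cm must be > 0", call. = FALSE)
  }
  if (is.null(names(label_map)) || any(names(label_map) == "")) {
    stop("label_map must be a named vector (names = muscle codes)",
         call. = FALSE)
  }
  validate_muscle(names(label_map), several.ok = TRUE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unmapped <- setdiff(present, label_map)
  if (length(unmapped) > 0L) {
    stop("label code(s) not in label_map: ",
         paste(sort(unmapped), collapse = ", "), call. = FALSE)
  }
  structure(
    list(labels = labels,
         slice_thickness_cm = as.numeric(slice_thickness_cm),
         in_plane_pixel_cm = as.numeric(in_plane_pixel_cm),
         label_map = label_map,
         ml_axis = ml_axis),
    class = "pifm_stack"
  )
}

#' @export
print.pifm_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat("Segmented label stack:", d[1], "slices x", d[2], "x", d[3],
      "pixels\n  slice thickness", x$slice_thickness_cm,
      "cm, pixel", x$in_plane_pixel_cm, "cm\n  muscles:",
      paste(names(x$label_map), collapse = ", "), "\n")
  invisible(x)
}

#' Per-slice anatomical cross-sectional areas from a label stack
#'
#' For every slice and every muscle in the stack's label map, the ACSA is
#' the labelled pixel count times the squared pixel edge length. Slices in
#' which a muscle does not appear are recorded with ACSA 0, so the table
#' always covers the full slice range for every mapped muscle.
#'
#' @param stack A `pifm_stack`.
#' @return data.frame `(slice_index, muscle, acsa_cm2)`; `slice_index` is
#'   0-based, proximal to distal.
#' @export
extract_acsa <- function(stack) {
  stopifnot(inherits(stack, "pifm_stack"))
  n_slice <- dim(stack$labels)[1]
  px_area <- stack$in_plane_pixel_cm^2
  muscles <- names(stack$label_map)
  out <- expand.grid(slice_index = seq_len(n_slice) - 1L,
                     muscle = muscles,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flat <- matrix(stack$labels, nrow = n_slice)  # slice x (row*col)
  counts <- vapply(stack$label_map, function(code) {
    rowSums(flat == code)
  }, numeric(n_slice))
  out$acsa_cm2 <- as.vector(counts[cbind(out$slice_index + 1L,
                                         match(out$muscle, muscles))])
  out$acsa_cm2 <- out$acsa_cm2 * px_area
  out[order(match(out$muscle, muscles), out$slice_index), , drop = FALSE]
}

#' Muscle volume from per-slice ACSAs
#'
#' Volume is the sum of all measured ACSAs for the muscle multiplied by the
#' slice thickness (contiguous slices, zero gap).
#'
#' @param acsa ACSA table as from [extract_acsa()] or [read_acsa_csv()].
#' @param muscle One muscle code.
#' @param slice_thickness_cm Slice thickness in cm.
#' @return Volume in cm^3.
#' @export
compute_volume <- function(acsa, muscle, slice_thickness_cm) {
  muscle <- validate_muscle(muscle)
  a <- acsa$acsa_cm2[acsa$muscle == muscle]
  if (length(a) == 0L || all(a <= 0)) {
    stop("muscle ", muscle, " has no positive ACSA in the table",
         call. = FALSE)
  }
  sum(a) * slice_thickness_cm
}

#' Muscle length from slice visibility (or in-plane extent)
#'
#' For every muscle except the adductor hallucis transverse head, length is
#' the proximal-to-distal extent: the inclusive count of slices in which
#' the muscle is visible (ACSA > 0) times the slice thickness, so a muscle
#' visible in a single slice has length one slice thickness. The
#' transverse head runs orthogonally to the scan axis, so its length is the
#' medial-to-lateral in-plane extent: the inclusive pixel-column span over
#' all slices where it appears, times the pixel size; this route requires
#' the label stack.
#'
#' @param acsa ACSA table.
#' @param muscle One muscle code.
#' @param slice_thickness_cm Slice thickness in cm.
#' @param stack The `pifm_stack`; required for `ADDH_TH` (and ignored
#'   otherwise) unless `in_plane = FALSE`.
#' @param in_plane Use the in-plane medial-to-lateral rule? Default: TRUE
#'   exactly for `ADDH_TH`.
#' @return Length in cm.
#' @export
compute_length <- function(acsa, muscle, slice_thickness_cm,
                           stack = NULL, in_plane = identical(muscle, "ADDH_TH")) {
  muscle <- validate_muscle(muscle)
  rows <- acsa[acsa$muscle == muscle, , drop = FALSE]
  visible <- rows$slice_index[rows$acsa_cm2 > 0]
  if (length(visible) == 0L) {
    stop("muscle ", muscle, " is not visible in any slice", call. = FALSE)
  }
  if (!in_plane) {
    return((max(visible) - min(visible) + 1) * slice_thickness_cm)
  }
  if (is.null(stack)) {
    stop("the in-plane (medial-to-lateral) length rule for ", muscle,
         " requires the label stack", call. = FALSE)
  }
  code <- stack$label_map[[muscle]]
  hit <- which(stack$labels == code, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    stop("muscle ", muscle, " is not present in the stack", call. = FALSE)
  }
  axis_idx <- if (stack$ml_axis == "col") hit[, 3] else hit[, 2]
  (max(axis_idx) - min(axis_idx) + 1) * stack$in_plane_pixel_cm
}

#' Full morphometry (volume and length) for every muscle in a stack
#'
#' @param stack A `pifm_stack`.
#' @param participant_id Participant label for the output rows.
#' @return data.frame `(participant, muscle, volume_cm3, length_cm)`.
#' @export
compute_morphometry <- function(stack, participant_id = "P01") {
  acsa <- extract_acsa(stack)
  muscles <- names(stack$label_map)
  out <- do.call(rbind, lapply(muscles, function(m) {
    data.frame(
      participant = participant_id,
      muscle = m,
      volume_cm3 = compute_volume(acsa, m, stack$slice_thickness_cm),
      length_cm = compute_length(acsa, m, stack$slice_thickness_cm,
                                 stack = stack),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Read a NIfTI integer label volume as a segmented stack
#'
#' The NIfTI voxel dimensions (mm) are converted to cm at this boundary.
#' The first array axis is taken as the slice (proximal-to-distal) axis by
#' default; use `slice_axis` if the acquisition stored slices last, as is
#' common for transverse stacks.
#'
#' @param path Path to a `.nii`/`.nii.gz` file with integer labels.
#' @param label_map Named integer vector mapping codes to muscle codes.
#' @param slice_axis Which array axis indexes slices (1, 2 or 3).
#' @param ml_axis Medial-lateral in-plane axis, `"col"` or `"row"`, in the
#'   returned (slice, row, col) frame.
#' @return A `pifm_stack`.
#' @export
read_label_stack <- function(path, label_map, slice_axis = 3L,
                             ml_axis = c("col", "row")) {
  ml_axis <- match.arg(ml_axis)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3-D label volume, got ", length(dim(arr)),
         " dimensions", call. = FALSE)
  }
  if (any(arr != round(arr))) {
    stop("label volume contains non-integer values; expected an integer ",
         "label map", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("NIfTI header lacks positive voxel dimensions", call. = FALSE)
  }
  units <- tryCatch(RNifti::pixunits(img), error = function(e) "mm")
  # unknown spatial units are treated as mm, the de-facto NIfTI standard
  to_cm <- if (any(units == "m")) 100 else 0.1
  perm <- c(slice_axis, setdiff(1:3, slice_axis))
  arr <- aperm(arr, perm)
  thickness_cm <- pd[slice_axis] * to_cm
  in_plane <- pd[setdiff(1:3, slice_axis)] * to_cm
  if (abs(in_plane[1] - in_plane[2]) > 1e-8) {
    stop("anisotropic in-plane pixels are not supported", call. = FALSE)
  }
  segmented_stack(arr, thickness_cm, in_plane[1], label_map,
                  ml_axis = ml_axis)
}

#' Read a per-slice ACSA table from CSV
#'
#' The CSV route bypasses pixel counting: areas were measured upstream
#' (e.g. by manual tracing) and are consumed as-is. Columns:
#' `slice_index, muscle, acsa_cm2` (an optional `participant` column is
#' preserved).
#'
#' @param path CSV path.
#' @return data.frame usable wherever an ACSA table is expected.
#' @export
read_acsa_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_index", "muscle", "acsa_cm2")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("ACSA CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_muscle(tab$muscle, several.ok = TRUE)
  if (any(!is.finite(tab$acsa_cm2)) || any(tab$acsa_cm2 < 0)) {
    stop("acsa_cm2 must be finite and non-negative", call. = FALSE)
  }
  tab
}
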