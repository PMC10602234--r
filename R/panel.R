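#' Bead panel definition
#'
#' A bead panel describes one SAB assay: the assay class, the ordered list of
#' bead specificities (allele strings such as `"A*29:01"` or
#' `"DPA1*02:01-DPB1*01:01"`), and which bead identifiers are positive or
#' negative control beads.
#'
#' @param assay_class `"I"` or `"II"`.
#' @param specificities Character vector of unique bead identifiers, in panel
#'   order.
#' @param control_ids Character vector of control-bead identifiers; must be a
#'   subset of the declared identifiers. At least one non-control specificity
#'   must remain.
#' @return An object of class `sab_panel`.
#' @export
bead_panel <- function(assay_class, specificities, control_ids = character(0)) {
  assay_class <- match.arg(as.character(assay_class), c("I", "II"))
  specificities <- as.character(specificities)
  control_ids <- as.character(control_ids)
  if (anyDuplicated(specificities))
    stop("bead panel specificities must be unique")
  if (!all(control_ids %in% specificities))
    stop("control_ids must be a subset of the declared bead identifiers")
  if (length(setdiff(specificities, control_ids)) < 1L)
    stop("panel must contain at least one non-control specificity")
  structure(
    list(assay_class = assay_class,
         specificities = specificities,
         control_ids = control_ids),
    class = "sab_panel")
}

#' @export
print.sab_panel <- function(x, ...) {
  cat(sprintf("<sab_panel> class %s: %d beads (%d controls)\n",
              x$assay_class, length(x$specificities), length(x$control_ids)))
  invisible(x)
}

#' One serum draw's bead-to-MFI map
#'
#' @param sample_id,patient_id Opaque identifier strings.
#' @param draw_index Integer >= 0 giving the chronological order of the draw
#'   within the patient.
#' @param assay_class `"I"` or `"II"`.
#' @param mfi Named numeric vector, one finite non-negative normalized MFI per
#'   bead identifier.
#' @return An object of class `sab_profile`.
#' @export
sample_profile <- function(sample_id, patient_id, draw_index, assay_class, mfi) {
  assay_class <- match.arg(as.character(assay_class), c("I", "II"))
  draw_index <- as.integer(draw_index)
  if (is.na(draw_index) || draw_index < 0L)
    stop("draw_index must be a non-negative integer")
  mfi <- unlist(mfi)
  if (length(mfi) == 0L || is.null(names(mfi)) || any(names(mfi) == ""))
    stop("mfi must be a non-empty named vector of bead values")
  if (anyDuplicated(names(mfi)))
    stop("duplicate bead identifiers in mfi")
  storage.mode(mfi) <- "double"
  if (any(!is.finite(mfi)) || any(mfi < 0))
    stop("MFI values must be finite and >= 0")
  structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         draw_index = draw_index,
         assay_class = assay_class,
         mfi = mfi),
    class = "sab_profile")
}

#' @export
print.sab_profile <- function(x, ...) {
  cat(sprintf("<sab_profile> %s (patient %s, draw %d, class %s): %d beads, max MFI %.1f\n",
              x$sample_id, x$patient_id, x$draw_index, x$assay_class,
              length(x$mfi), max(x$mfi)))
  invisible(x)
}

#' Assemble one patient's chronological sample history
#'
#' Selects the samples of one patient on one assay class, orders them by draw
#' index and computes the set of beads present in every sample. Bead sets can
#' drift between kit lots; beads missing from any sample are dropped from the
#' common set with a warning, because the distance computation needs a shared
#' coordinate system.
#'
#' @param samples List of [sample_profile()] objects.
#' @param patient_id Patient to select.
#' @param assay_class `"I"` or `"II"`.
#' @param panel Optional [bead_panel()]; when given, `common_beads` is
#'   reported in panel order, otherwise in the order of the earliest sample.
#' @param min_common_beads Minimum size of the common bead set below which a
#'   warning is emitted (default 50).
#' @return An object of class `sab_history` with fields `patient_id`,
#'   `assay_class`, `samples` (chronological) and `common_beads`.
#' @export
build_history <- function(samples, patient_id, assay_class,
                          panel = NULL, min_common_beads = 50L) {
  assay_class <- match.arg(as.character(assay_class), c("I", "II"))
  keep <- vapply(samples, function(s)
    s$patient_id == patient_id && s$assay_class == assay_class, logical(1))
  sel <- samples[keep]
  if (length(sel) == 0L)
    stop(sprintf("no samples found for patient '%s' on class %s",
                 patient_id, assay_class))
  ord <- order(vapply(sel, function(s) s$draw_index, integer(1)))
  sel <- sel[ord]
  draws <- vapply(sel, function(s) s$draw_index, integer(1))
  if (anyDuplicated(draws))
    stop(sprintf("duplicate draw_index for patient '%s'", patient_id))
  bead_sets <- lapply(sel, function(s) names(s$mfi))
  common <- Reduce(intersect, bead_sets)
  if (length(common) == 0L)
    stop(sprintf("no common beads across samples of patient '%s'", patient_id))
  ref_order <- if (!is.null(panel)) panel$specificities else bead_sets[[1L]]
  common <- ref_order[ref_order %in% common]
  dropped <- setdiff(unique(unlist(bead_sets)), common)
  if (length(dropped) > 0L)
    warning(sprintf("patient '%s': %d bead(s) absent from some samples dropped from common set: %s",
                    patient_id, length(dropped),
                    paste(head(dropped, 10L), collapse = ", ")),
            call. = FALSE)
  if (length(common) < min_common_beads)
    warning(sprintf("patient '%s': only %d common beads (minimum %d requested)",
                    patient_id, length(common), min_common_beads),
            call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id),
         assay_class = assay_class,
         samples = sel,
         common_beads = common),
    class = "sab_history")
}

#' @export
print.sab_history <- function(x, ...) {
  cat(sprintf("<sab_history> patient %s, class %s: %d samples, %d common beads\n",
              x$patient_id, x$assay_class, length(x$samples),
              length(x$common_beads)))
  invisible(x)
}

# History as a numeric matrix: rows = samples (chronological), cols = common beads.
history_matrix <- function(history, bead_ids = history$common_beads) {
  m <- t(vapply(history$samples, function(s) unname(s$mfi[bead_ids]),
                numeric(length(bead_ids))))
  rownames(m) <- vapply(history$samples, function(s) s$sample_id, character(1))
  colnames(m) <- bead_ids
  m
}
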