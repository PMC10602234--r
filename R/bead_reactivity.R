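#' Select low-reactivity samples for the bead scan
#'
#' The over-reactivity scan isolates nonspecific bead behaviour, so only
#' samples whose bead signals are all at background qualify. A sample is
#' kept when its maximum bead MFI satisfies the comparison against the
#' cutoff: `strict_less` (`max < cutoff`, e.g. the archive-wide inclusion at
#' 1000) or `less_equal` (`max <= cutoff`, e.g. a pilot inclusion at 1200).
#' Control beads should be stripped beforehand ([strip_controls_and_qc()]).
#'
#' @param samples List of [sample_profile()] objects.
#' @param cutoff Positive MFI cutoff.
#' @param mode `"strict_less"` or `"less_equal"`.
#' @return Filtered list of profiles, input order preserved.
#' @export
select_low_reactivity_samples <- function(samples, cutoff = 1000,
                                          mode = c("strict_less", "less_equal")) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  keep <- vapply(samples, function(s) {
    m <- max(s$mfi)
    if (mode == "strict_less") m < cutoff else m <= cutoff
  }, logical(1))
  samples[keep]
}

#' Rank beads by PC-plane distance ratio (transposed PCA)
#'
#' Over-reactive beads show elevated nonspecific variance across
#' low-reactivity sera. The MFI matrix is transposed relative to sample
#' screening: rows are beads (observations) and columns are samples
#' (variables), so [pca_scores()]'s column centering removes each sample's
#' background shift. For each bead the mean Euclidean distance to every
#' other bead in PC score space is computed; a bead's distance ratio is its
#' mean distance divided by the grand mean over all beads (self-inclusive,
#' so the ratios average to exactly 1). Beads are ranked by descending
#' ratio, ties broken by bead identifier.
#'
#' If every bead has an identical profile the score space is degenerate and
#' all ratios are defined as 1.
#'
#' @param samples List of >= 3 [sample_profile()] objects (typically from
#'   [select_low_reactivity_samples()]).
#' @param panel Optional [bead_panel()] used only to record the assay class.
#' @param n_components Number of PCs for the score plane (default 2).
#' @param epsilon Degeneracy tolerance on the grand-mean distance.
#' @return An object of class `sab_bead_report`: list with `assay_class`,
#'   `n_samples_used`, `degenerate`, `rows` (data frame `rank, bead,
#'   mean_ed, distance_ratio`) and `ed_matrix` (bead-pair Euclidean
#'   distances in score space).
#' @export
bead_distance_ratios <- function(samples, panel = NULL, n_components = 2L,
                                 epsilon = 1e-9) {
  if (length(samples) < 3L)
    stop(sprintf("bead scan needs at least 3 samples, got %d", length(samples)))
  bead_sets <- lapply(samples, function(s) names(s$mfi))
  beads <- Reduce(intersect, bead_sets)
  if (length(beads) < 3L)
    stop(sprintf("bead scan needs at least 3 common beads, got %d", length(beads)))
  # rows = beads, columns = samples
  m <- vapply(samples, function(s) unname(s$mfi[beads]), numeric(length(beads)))
  rownames(m) <- beads
  colnames(m) <- vapply(samples, function(s) s$sample_id, character(1))
  k <- min(n_components, nrow(m) - 1L, ncol(m))
  sc <- pca_scores(m, k)
  dmat <- as.matrix(dist(sc$scores))
  mean_ed <- rowSums(dmat) / (nrow(dmat) - 1L)
  grand <- mean(mean_ed)
  degenerate <- sc$degenerate || grand <= epsilon
  ratio <- if (degenerate) rep(1, length(beads)) else mean_ed / grand
  ord <- order(-ratio, beads, method = "radix")
  rows <- data.frame(rank = seq_along(beads),
                     bead = beads[ord],
                     mean_ed = unname(mean_ed[ord]),
                     distance_ratio = unname(ratio[ord]),
                     stringsAsFactors = FALSE)
  structure(
    list(assay_class = if (!is.null(panel)) panel$assay_class
                       else samples[[1L]]$assay_class,
         n_samples_used = length(samples),
         degenerate = degenerate,
         rows = rows,
         ed_matrix = dmat),
    class = "sab_bead_report")
}

#' @export
print.sab_bead_report <- function(x, ...) {
  cat(sprintf("<sab_bead_report> class %s: %d beads over %d samples%s\n",
              x$assay_class, nrow(x$rows), x$n_samples_used,
              if (x$degenerate) " (degenerate)" else ""))
  print(head(x$rows, 8L), row.names = FALSE)
  invisible(x)
}
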