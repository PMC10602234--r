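#' Screening configuration
#'
#' @param ratio_threshold Distance-ratio threshold at or above which a sample
#'   is flagged (default 1.4, the ROC-calibrated operating point).
#' @param reactivity_cutoff MFI positivity cutoff (default 1000); samples
#'   with every bead below it are discarded as non-reactive.
#' @param min_historic Minimum number of historic samples needed to evaluate
#'   an index sample (default 2 — below that no historic pair exists).
#' @param n_components Number of principal components for the score space
#'   (default 2; capped at the rank of each patient's matrix).
#' @param epsilon Degeneracy tolerance for mean distances (default 1e-9).
#' @return An object of class `sab_flag_config`.
#' @export
flag_config <- function(ratio_threshold = 1.4, reactivity_cutoff = 1000,
                        min_historic = 2L, n_components = 2L,
                        epsilon = 1e-9) {
  stopifnot(ratio_threshold > 0, reactivity_cutoff > 0,
            min_historic >= 2L, n_components >= 1L, epsilon > 0)
  structure(
    list(ratio_threshold = ratio_threshold,
         reactivity_cutoff = reactivity_cutoff,
         min_historic = as.integer(min_historic),
         n_components = as.integer(n_components),
         epsilon = epsilon),
    class = "sab_flag_config")
}

#' Is a sample non-reactive?
#'
#' A sample is non-reactive when every bead MFI is strictly below the assay
#' positivity cutoff; such samples carry no pattern to compare and are
#' discarded from screening (a value exactly at the cutoff counts as
#' reactive).
#'
#' @param sample A [sample_profile()].
#' @param cutoff MFI positivity cutoff (default 1000).
#' @return Logical scalar.
#' @export
is_nonreactive <- function(sample, cutoff = 1000) {
  if (length(sample$mfi) == 0L) stop("sample has no bead values")
  all(sample$mfi < cutoff)
}

#' Euclidean distance ratio in score space
#'
#' The screening statistic: the mean Euclidean distance from the index
#' sample's score row to each historic score row, divided by the mean
#' pairwise distance among the historic rows. If both means are numerically
#' zero the ratio is defined as 1 (degenerate history, index
#' indistinguishable); if only the denominator is zero the ratio is `Inf`
#' (identical history, deviant index).
#'
#' @param index_scores Numeric score row of the sample of interest.
#' @param historic_scores Matrix (>= 2 rows) or list of score rows of the
#'   historic samples, same dimension as `index_scores`.
#' @param epsilon Degeneracy tolerance on the mean distances.
#' @return List with `numerator_mean_ed`, `denominator_mean_ed`,
#'   `distance_ratio` and `degenerate`.
#' @export
distance_ratio <- function(index_scores, historic_scores, epsilon = 1e-9) {
  if (is.list(historic_scores))
    historic_scores <- do.call(rbind, historic_scores)
  historic_scores <- as.matrix(historic_scores)
  h <- nrow(historic_scores)
  if (h < 2L) stop("at least 2 historic score rows are required")
  index_scores <- as.numeric(index_scores)
  if (length(index_scores) != ncol(historic_scores))
    stop("index and historic score rows must have the same dimension")
  num <- mean(apply(historic_scores, 1L, euclidean_distance, b = index_scores))
  den <- mean(dist(historic_scores))
  if (den <= epsilon) {
    if (num <= epsilon)
      return(list(numerator_mean_ed = num, denominator_mean_ed = den,
                  distance_ratio = 1, degenerate = TRUE))
    return(list(numerator_mean_ed = num, denominator_mean_ed = den,
                distance_ratio = Inf, degenerate = FALSE))
  }
  list(numerator_mean_ed = num, denominator_mean_ed = den,
       distance_ratio = num / den, degenerate = FALSE)
}

flag_result <- function(sample_id, patient_id, n_historic, reason,
                        numerator = NA_real_, denominator = NA_real_,
                        dr = NA_real_, threshold = NA_real_) {
  structure(
    list(sample_id = sample_id,
         patient_id = patient_id,
         n_historic = n_historic,
         numerator_mean_ed = numerator,
         denominator_mean_ed = denominator,
         distance_ratio = dr,
         threshold = threshold,
         flagged = identical(reason, "above_threshold"),
         reason = reason),
    class = "sab_flag_result")
}

#' @export
print.sab_flag_result <- function(x, ...) {
  cat(sprintf("<sab_flag_result> %s: DR = %s vs threshold %s -> %s (%s)\n",
              x$sample_id,
              if (is.na(x$distance_ratio)) "NA" else sprintf("%.3f", x$distance_ratio),
              if (is.na(x$threshold)) "NA" else sprintf("%.2f", x$threshold),
              if (x$flagged) "FLAGGED" else "not flagged", x$reason))
  invisible(x)
}

#' Flag an index sample against a patient's history
#'
#' The core screening pipeline for one sample: (1) a non-reactive index
#' (every bead below the positivity cutoff) is discarded; (2) the MFI matrix
#' over the history's common beads is assembled, historic samples plus the
#' index as rows; (3) PC scores are computed jointly on all rows
#' ([pca_scores()], components capped at the matrix rank); (4) the Euclidean
#' distance ratio of the index versus the historic samples is computed; (5)
#' the sample is flagged when the ratio is at or above the threshold
#' (inclusive).
#'
#' Too few historic samples is a reportable outcome, not an error: the
#' result carries reason `insufficient_history` so batch runs continue.
#'
#' @param history A [build_history()] result containing the index sample.
#' @param index_sample_id Sample to evaluate; the remaining samples act as
#'   the historic reference.
#' @param config A [flag_config()].
#' @return An object of class `sab_flag_result` with fields `sample_id`,
#'   `patient_id`, `n_historic`, `numerator_mean_ed`, `denominator_mean_ed`,
#'   `distance_ratio`, `threshold`, `flagged` and `reason` (one of
#'   `above_threshold`, `below_threshold`, `nonreactive_discarded`,
#'   `insufficient_history`, `degenerate_history`).
#' @export
flag_sample <- function(history, index_sample_id, config = flag_config()) {
  stopifnot(inherits(history, "sab_history"))
  ids <- vapply(history$samples, function(s) s$sample_id, character(1))
  pos <- match(index_sample_id, ids)
  if (is.na(pos))
    stop(sprintf("index sample '%s' not found in history of patient '%s'",
                 index_sample_id, history$patient_id))
  index <- history$samples[[pos]]
  historic <- history$samples[-pos]
  if (is_nonreactive(index, config$reactivity_cutoff))
    return(flag_result(index$sample_id, history$patient_id, length(historic),
                       "nonreactive_discarded",
                       threshold = config$ratio_threshold))
  if (length(historic) < config$min_historic)
    return(flag_result(index$sample_id, history$patient_id, length(historic),
                       "insufficient_history",
                       threshold = config$ratio_threshold))
  m <- rbind(
    t(vapply(historic, function(s) unname(s$mfi[history$common_beads]),
             numeric(length(history$common_beads)))),
    unname(index$mfi[history$common_beads]))
  rownames(m) <- c(vapply(historic, function(s) s$sample_id, character(1)),
                   index$sample_id)
  k <- min(config$n_components, nrow(m) - 1L, ncol(m))
  sc <- pca_scores(m, k)
  n_hist <- length(historic)
  dr <- distance_ratio(sc$scores[n_hist + 1L, ],
                       sc$scores[seq_len(n_hist), , drop = FALSE],
                       config$epsilon)
  reason <- if (dr$degenerate) "degenerate_history"
            else if (dr$distance_ratio >= config$ratio_threshold) "above_threshold"
            else "below_threshold"
  flag_result(index$sample_id, history$patient_id, n_hist, reason,
              dr$numerator_mean_ed, dr$denominator_mean_ed,
              dr$distance_ratio, config$ratio_threshold)
}

#' Leave-one-out distance-ratio profile of a history
#'
#' Computes, in a single joint PC space over all of a patient's samples, the
#' distance ratio of each sample treated in turn as the sample of interest
#' against the remaining samples. This fold-difference profile is the
#' per-sample statistic used for cohort comparisons and as the negative
#' class in threshold calibration.
#'
#' @param history A [build_history()] result with at least 3 samples.
#' @param config A [flag_config()].
#' @return Named numeric vector: sample_id -> distance ratio.
#' @export
fold_difference_profile <- function(history, config = flag_config()) {
  stopifnot(inherits(history, "sab_history"))
  n <- length(history$samples)
  if (n < 3L)
    stop("leave-one-out profile needs at least 3 samples")
  m <- history_matrix(history)
  k <- min(config$n_components, n - 1L, ncol(m))
  sc <- pca_scores(m, k)
  out <- vapply(seq_len(n), function(i) {
    distance_ratio(sc$scores[i, ], sc$scores[-i, , drop = FALSE],
                   config$epsilon)$distance_ratio
  }, numeric(1))
  names(out) <- vapply(history$samples, function(s) s$sample_id, character(1))
  out
}

#' Flag results as a report table
#'
#' @param results List of `sab_flag_result` objects (or a single one).
#' @param assay_class Optional assay class recorded in the table.
#' @return Data frame with one row per result, columns `sample_id`,
#'   `patient_id`, `assay_class`, `n_historic`, `numerator_mean_ed`,
#'   `denominator_mean_ed`, `distance_ratio`, `threshold`, `flagged`,
#'   `reason`.
#' @export
flag_report <- function(results, assay_class = NA_character_) {
  if (inherits(results, "sab_flag_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, patient_id = r$patient_id,
               assay_class = assay_class, n_historic = r$n_historic,
               numerator_mean_ed = r$numerator_mean_ed,
               denominator_mean_ed = r$denominator_mean_ed,
               distance_ratio = r$distance_ratio, threshold = r$threshold,
               flagged = r$flagged, reason = r$reason,
               stringsAsFactors = FALSE)))
}
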