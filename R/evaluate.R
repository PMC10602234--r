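#' Flag every index sample of a simulated study
#'
#' Runs [flag_sample()] on each patient's index draw and joins the result
#' with the simulation truth labels.
#'
#' @param sim A [simulate_study()] result.
#' @param config A [flag_config()].
#' @return Data frame: one row per index sample with the flag result fields
#'   plus `cohort` and `label`.
#' @export
evaluate_screening <- function(sim, config = flag_config()) {
  rows <- lapply(sim$patients, function(p) {
    idx <- p$truth$sample_id[p$truth$is_index]
    res <- flag_sample(p$history, idx, config)
    cbind(flag_report(res, p$history$assay_class),
          cohort = p$cohort,
          label = p$truth$label[p$truth$is_index],
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screening sensitivity and specificity over repeated simulated studies
#'
#' Aggregates index-sample flags over `n_seeds` independent replicates of a
#' study design. Sensitivity is the fraction of evaluated event index
#' samples flagged; specificity is the fraction of evaluated stable-cohort
#' index samples not flagged (and is also reported for the sensitized
#' cohort). Non-reactive or insufficient-history index samples are excluded
#' from the denominators, mirroring the screening workflow's discard rule.
#'
#' @param study A [study_config()].
#' @param n_seeds Number of replicate studies.
#' @param base_seed Seed from which per-replicate seeds are derived.
#' @param config A [flag_config()].
#' @return List with `sensitivity`, `specificity_stable`,
#'   `specificity_sensitized`, per-event-type sensitivities, counts `n_*`,
#'   and the pooled per-sample data frame `details`.
#' @export
screening_performance <- function(study = study_config(), n_seeds = 200L,
                                  base_seed = 1L, config = flag_config()) {
  seeds <- derive_seeds(base_seed, n_seeds)
  details <- do.call(rbind, lapply(seq_len(n_seeds), function(i) {
    df <- evaluate_screening(simulate_study(study, seed = seeds[i]), config)
    df$replicate <- i
    df
  }))
  evaluated <- details[!details$reason %in%
                         c("nonreactive_discarded", "insufficient_history"), ]
  ev <- evaluated[evaluated$cohort == "event", ]
  st <- evaluated[evaluated$cohort == "stable", ]
  se <- evaluated[evaluated$cohort == "sensitized", ]
  sens_by_type <- vapply(split(ev$flagged, ev$label), mean, numeric(1))
  list(sensitivity = mean(ev$flagged),
       specificity_stable = mean(!st$flagged),
       specificity_sensitized = if (nrow(se) > 0L) mean(!se$flagged) else NA_real_,
       sensitivity_by_event = sens_by_type,
       n_event = nrow(ev), n_stable = nrow(st), n_sensitized = nrow(se),
       details = details)
}

#' Labelled distance-ratio batch for threshold calibration
#'
#' Builds one calibration batch from a simulated study: positives are the
#' index-sample distance ratios of event patients ([flag_sample()]);
#' negatives are the leave-one-out distance ratios
#' ([fold_difference_profile()]) of every control-cohort patient's samples,
#' mirroring a design where stable and sensitized cohorts supply the
#' negative class.
#'
#' @param sim A [simulate_study()] result.
#' @param config A [flag_config()].
#' @return List with numeric vectors `pos` and `neg`.
#' @export
dr_batch <- function(sim, config = flag_config()) {
  pos <- c(); neg <- c()
  for (p in sim$patients) {
    if (p$cohort == "event") {
      idx <- p$truth$sample_id[p$truth$is_index]
      res <- flag_sample(p$history, idx, config)
      if (!is.na(res$distance_ratio)) pos <- c(pos, res$distance_ratio)
    } else {
      neg <- c(neg, unname(fold_difference_profile(p$history, config)))
    }
  }
  list(pos = pos, neg = neg)
}

#' Threshold-calibration recovery across train/test batch pairs
#'
#' For each replicate, two independent study batches are simulated; the ROC
#' optimal threshold is selected on the training batch and applied to the
#' held-out batch, and the Youden J achieved out-of-sample is compared with
#' the training J. Small gaps indicate the calibrated threshold transfers.
#'
#' @param study A [study_config()] used for both batches (default: a
#'   12-event / 12-control batch, a realistic single-run scale).
#' @param n_seeds Number of train/test replicates.
#' @param base_seed Seed from which batch seeds are derived.
#' @param config A [flag_config()].
#' @return List with `median_abs_j_gap`, `median_threshold`, `median_auc`
#'   and the per-replicate data frame `details` (`threshold, auc, train_j,
#'   test_j, j_gap`).
#' @export
calibration_recovery <- function(study = study_config(n_event = 12L,
                                                      n_stable = 8L,
                                                      n_sensitized = 4L),
                                 n_seeds = 200L, base_seed = 1L,
                                 config = flag_config()) {
  seeds <- derive_seeds(base_seed, 2L * n_seeds)
  details <- do.call(rbind, lapply(seq_len(n_seeds), function(i) {
    train <- dr_batch(simulate_study(study, seed = seeds[2L * i - 1L]), config)
    test <- dr_batch(simulate_study(study, seed = seeds[2L * i]), config)
    roc <- roc_auc(train$neg, train$pos)
    t_opt <- roc$optimal_threshold
    test_j <- mean(test$pos >= t_opt) + mean(test$neg < t_opt) - 1
    data.frame(threshold = t_opt, auc = roc$auc,
               train_j = roc$youden_j_at_optimum, test_j = test_j,
               j_gap = abs(roc$youden_j_at_optimum - test_j))
  }))
  list(median_abs_j_gap = median(details$j_gap),
       median_threshold = median(details$threshold),
       median_auc = median(details$auc),
       details = details)
}
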