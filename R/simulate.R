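#' Simulation configuration for one synthetic patient
#'
#' The generator emulates a longitudinal SAB history: a latent per-bead
#' profile (a random subset of beads carries positive reactivity, the rest
#' sit at lognormal background), observed through multiplicative lognormal
#' draw-to-draw noise with a fixed coefficient of variation. After the
#' stable historic draws one index draw is emitted, with an optional event
#' applied:
#'
#' * `none` — the index is one more stable draw.
#' * `new_specificity` — `n_new_beads` previously-background beads jump to
#'   `new_mfi` (a de-novo antibody pattern).
#' * `inflation` — every historically positive bead's latent mean is
#'   multiplied by `1 + inflation_pct/100`; the default percentage range
#'   119.67–243.33 spans observed at-least-2-fold MFI rises on reactive
#'   specificities.
#' * `prozone_like` — pattern distortion: the top half of the positive beads
#'   (by latent MFI) is suppressed to 20% and the bottom half elevated
#'   2-fold, a speculative stand-in for complement-mediated prozone
#'   interference.
#'
#' @param seed Integer RNG seed (the generator is fully deterministic per
#'   seed).
#' @param n_beads Panel size (default 96).
#' @param background_mfi_mean Median background MFI (default 150).
#' @param background_log_sd Lognormal sd (log scale) of the per-bead
#'   background level (default 0.5).
#' @param positive_mfi_range Range the latent means of positive beads are
#'   drawn from, default `c(2000, 15000)`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   draw noise (default 0.15; 0 gives identical draws).
#' @param n_historic Number of stable draws before the index draw (default 5).
#' @param n_positive_range Range for the number of positive beads, default
#'   `c(2, 8)`; use `c(0, 0)` for a non-reactive patient.
#' @param event List describing the index event: `type` plus, as applicable,
#'   `n_new_beads`, `new_mfi` (scalar or range), `inflation_factor` (scalar;
#'   overrides `inflation_pct_range`), `inflation_pct_range`.
#' @param assay_class,patient_id Metadata for the emitted profiles.
#' @param mfi_digits Decimal places MFI values are rounded to (default 2,
#'   matching the CSV writers).
#' @return An object of class `sab_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_beads = 96L, background_mfi_mean = 150,
                       background_log_sd = 0.5,
                       positive_mfi_range = c(2000, 15000),
                       noise_cv = 0.15, n_historic = 5L,
                       n_positive_range = c(2L, 8L),
                       event = list(type = "none"),
                       assay_class = "I", patient_id = "P001",
                       mfi_digits = 2L) {
  event$type <- match.arg(event$type %||% "none",
                          c("none", "new_specificity", "inflation", "prozone_like"))
  stopifnot(n_beads >= 3L, background_mfi_mean > 0, background_log_sd >= 0,
            length(positive_mfi_range) == 2L, all(positive_mfi_range > 0),
            noise_cv >= 0, n_historic >= 1L,
            length(n_positive_range) == 2L, all(n_positive_range >= 0),
            n_positive_range[1] <= n_positive_range[2])
  if (event$type == "new_specificity") {
    event$n_new_beads <- as.integer(event$n_new_beads %||% 1L)
    event$new_mfi <- event$new_mfi %||% c(3000, 10000)
    stopifnot(event$n_new_beads >= 1L, all(event$new_mfi >= 1000))
  }
  if (event$type == "inflation") {
    event$inflation_pct_range <- event$inflation_pct_range %||% c(119.67, 243.33)
    if (!is.null(event$inflation_factor))
      stopifnot(event$inflation_factor > 1)
  }
  structure(
    list(seed = as.integer(seed), n_beads = as.integer(n_beads),
         background_mfi_mean = background_mfi_mean,
         background_log_sd = background_log_sd,
         positive_mfi_range = positive_mfi_range,
         noise_cv = noise_cv, n_historic = as.integer(n_historic),
         n_positive_range = as.integer(n_positive_range),
         event = event, assay_class = assay_class,
         patient_id = patient_id, mfi_digits = as.integer(mfi_digits)),
    class = "sab_sim_config")
}

# Allele-style bead names for a synthetic panel.
synthetic_bead_names <- function(n, assay_class = "I") {
  loci <- if (assay_class == "I") c("A", "B", "C")
          else c("DRB1", "DQB1", "DPB1")
  sprintf("%s*%02d:%02d",
          loci[((seq_len(n) - 1L) %% length(loci)) + 1L],
          ((seq_len(n) - 1L) %/% length(loci)) + 1L,
          ((seq_len(n) - 1L) %% 4L) + 1L)
}

# One multiplicative lognormal noise matrix with mean 1 and CV = cv.
noise_matrix <- function(nr, nc, cv) {
  if (cv == 0) return(matrix(1, nr, nc))
  s <- sqrt(log(1 + cv^2))
  matrix(rlnorm(nr * nc, meanlog = -s^2 / 2, sdlog = s), nr, nc)
}

#' Simulate one patient's longitudinal SAB history
#'
#' See [sim_config()] for the generative model. The per-sample truth labels
#' are `stable` for historic draws, `nonreactive` for all draws of a patient
#' without positive beads, and `dsa_like` / `inflation` / `prozone_like` for
#' the index draw according to the event.
#'
#' @param config A [sim_config()].
#' @return List with `history` (a `sab_history`), `truth` (data frame
#'   `sample_id, label` plus per-bead `bead_truth`), and `latent` (the
#'   latent means, positive beads and realized event parameters).
#' @export
simulate_patient <- function(config = sim_config()) {
  stopifnot(inherits(config, "sab_sim_config"))
  local_seed(config$seed, {
    beads <- synthetic_bead_names(config$n_beads, config$assay_class)
    n_pos <- if (config$n_positive_range[1] == config$n_positive_range[2])
      config$n_positive_range[1]
    else sample(config$n_positive_range[1]:config$n_positive_range[2], 1L)
    pos_beads <- if (n_pos > 0L) sort(sample(beads, n_pos)) else character(0)
    latent <- rlnorm(config$n_beads, meanlog = log(config$background_mfi_mean),
                     sdlog = config$background_log_sd)
    names(latent) <- beads
    latent[pos_beads] <- runif(n_pos, config$positive_mfi_range[1],
                               config$positive_mfi_range[2])

    ev <- config$event
    index_latent <- latent
    realized <- list(type = ev$type)
    if (ev$type == "new_specificity") {
      bg_beads <- setdiff(beads, pos_beads)
      if (length(bg_beads) < ev$n_new_beads)
        stop("not enough background beads for the new-specificity event")
      new_beads <- sort(sample(bg_beads, ev$n_new_beads))
      new_mfi <- if (length(ev$new_mfi) == 2L)
        runif(ev$n_new_beads, ev$new_mfi[1], ev$new_mfi[2]) else
        rep(ev$new_mfi, ev$n_new_beads)
      index_latent[new_beads] <- new_mfi
      realized$new_beads <- new_beads
      realized$new_mfi <- new_mfi
    } else if (ev$type == "inflation") {
      factor <- ev$inflation_factor %||%
        (1 + runif(1L, ev$inflation_pct_range[1], ev$inflation_pct_range[2]) / 100)
      index_latent[pos_beads] <- latent[pos_beads] * factor
      realized$inflation_factor <- factor
    } else if (ev$type == "prozone_like" && n_pos > 0L) {
      ord <- pos_beads[order(-latent[pos_beads])]
      top <- ord[seq_len(ceiling(n_pos / 2))]
      bottom <- setdiff(ord, top)
      index_latent[top] <- latent[top] * 0.2
      index_latent[bottom] <- latent[bottom] * 2
      realized$suppressed <- top
      realized$elevated <- bottom
    }

    n_draws <- config$n_historic + 1L
    noise <- noise_matrix(config$n_beads, n_draws, config$noise_cv)
    values <- cbind(latent * noise[, seq_len(config$n_historic), drop = FALSE],
                    index_latent * noise[, n_draws])
    values <- round(values, config$mfi_digits)

    samples <- lapply(seq_len(n_draws), function(j) {
      mfi <- values[, j]
      names(mfi) <- beads
      sample_profile(sprintf("%s_T%02d", config$patient_id, j - 1L),
                     config$patient_id, j - 1L, config$assay_class, mfi)
    })
    history <- structure(
      list(patient_id = config$patient_id, assay_class = config$assay_class,
           samples = samples, common_beads = beads),
      class = "sab_history")

    base_label <- if (n_pos == 0L) "nonreactive" else "stable"
    index_label <- if (n_pos == 0L && ev$type == "none") "nonreactive"
      else switch(ev$type, none = "stable", new_specificity = "dsa_like",
                  inflation = "inflation", prozone_like = "prozone_like")
    truth <- data.frame(
      sample_id = vapply(samples, function(s) s$sample_id, character(1)),
      label = c(rep(base_label, config$n_historic), index_label),
      is_index = c(rep(FALSE, config$n_historic), TRUE),
      stringsAsFactors = FALSE)
    bead_truth <- data.frame(bead = beads,
                             positive = beads %in% pos_beads,
                             stringsAsFactors = FALSE)
    list(history = history, truth = truth, bead_truth = bead_truth,
         latent = list(means = latent, index_means = index_latent,
                       positive_beads = pos_beads, event = realized))
  })
}

#' Inject over-reactive behaviour into selected beads
#'
#' Emulates beads with inflated nonspecific variance in a low-reactivity
#' archive: each targeted bead's deviation from its per-bead median (across
#' samples) is scaled by `sd_multiplier`, and with probability `spike_prob`
#' per sample the value is raised to at least `spike_mfi` (a sporadic
#' nonspecific spike). Values are clamped to `[0, max_mfi]` so an archive
#' built below a reactivity cutoff stays below it. Non-targeted beads are
#' untouched; `sd_multiplier = 1` with `spike_prob = 0` is the identity.
#'
#' @param samples List of [sample_profile()] objects (low-reactivity).
#' @param bead_ids Beads to perturb; must exist in every sample.
#' @param sd_multiplier Linear scaling of deviations from the bead median.
#' @param spike_prob Per-sample probability of a spike.
#' @param spike_mfi Spike floor value (keep below the archive cutoff).
#' @param max_mfi Upper clamp (default `Inf`).
#' @param seed Optional RNG seed for the spike draws.
#' @param mfi_digits Decimal rounding of perturbed values.
#' @return List with `samples` (perturbed) and `bead_truth` (data frame
#'   `bead, overreactive`).
#' @export
inject_overreactive_beads <- function(samples, bead_ids, sd_multiplier = 5,
                                      spike_prob = 0, spike_mfi = 900,
                                      max_mfi = Inf, seed = NULL,
                                      mfi_digits = 2L) {
  stopifnot(length(samples) > 0L, sd_multiplier > 0, spike_prob >= 0,
            spike_prob <= 1, spike_mfi >= 0)
  all_beads <- names(samples[[1L]]$mfi)
  unknown <- setdiff(bead_ids, Reduce(intersect, lapply(samples, function(s) names(s$mfi))))
  if (length(unknown) > 0L)
    stop(sprintf("unknown bead(s): %s", paste(unknown, collapse = ", ")))
  run <- function() {
    vals <- vapply(samples, function(s) unname(s$mfi[bead_ids]),
                   numeric(length(bead_ids)))
    vals <- matrix(vals, nrow = length(bead_ids))
    med <- apply(vals, 1L, median)
    new_vals <- pmax(med + sd_multiplier * (vals - med), 0)
    if (spike_prob > 0) {
      spike <- matrix(runif(length(new_vals)) < spike_prob, nrow = nrow(new_vals))
      new_vals[spike] <- pmax(new_vals[spike], spike_mfi)
    }
    new_vals <- round(pmin(new_vals, max_mfi), mfi_digits)
    out <- lapply(seq_along(samples), function(j) {
      s <- samples[[j]]
      s$mfi[bead_ids] <- new_vals[, j]
      s
    })
    list(samples = out,
         bead_truth = data.frame(bead = all_beads,
                                 overreactive = all_beads %in% bead_ids,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Simulate a low-reactivity sample archive with over-reactive beads
#'
#' Generates `n_samples` background-only serum profiles (every bead below
#' `cutoff`; values that would land at or above it are redrawn) and then
#' injects `n_overreactive` beads with [inject_overreactive_beads()],
#' clamped just below the cutoff so the whole archive qualifies for the
#' bead scan.
#'
#' @param seed RNG seed.
#' @param n_samples,n_beads Archive dimensions (defaults 300 x 96).
#' @param n_overreactive Number of over-reactive beads injected (default 2).
#' @param sd_multiplier,spike_prob,spike_mfi Passed to
#'   [inject_overreactive_beads()].
#' @param cutoff Low-reactivity cutoff (default 1000, mode strict-less).
#' @param background_mfi_mean,background_log_sd Background model as in
#'   [sim_config()].
#' @param assay_class Assay class of the synthetic panel.
#' @return List with `samples`, `panel`, `target_beads`, `bead_truth`.
#' @export
simulate_low_reactivity_archive <- function(seed = 1L, n_samples = 300L,
                                            n_beads = 96L, n_overreactive = 2L,
                                            sd_multiplier = 5, spike_prob = 0.1,
                                            spike_mfi = 900, cutoff = 1000,
                                            background_mfi_mean = 150,
                                            background_log_sd = 0.5,
                                            assay_class = "II") {
  stopifnot(n_samples >= 3L, n_beads >= 3L, n_overreactive >= 0L,
            n_overreactive <= n_beads, cutoff > 0, spike_mfi < cutoff)
  local_seed(seed, {
    beads <- synthetic_bead_names(n_beads, assay_class)
    vals <- matrix(rlnorm(n_beads * n_samples,
                          meanlog = log(background_mfi_mean),
                          sdlog = background_log_sd),
                   n_beads, n_samples)
    # truncate the background below the cutoff by per-value redraw
    bad <- which(vals >= cutoff)
    while (length(bad) > 0L) {
      vals[bad] <- rlnorm(length(bad), meanlog = log(background_mfi_mean),
                          sdlog = background_log_sd)
      bad <- which(vals >= cutoff)
    }
    vals <- round(vals, 2L)
    samples <- lapply(seq_len(n_samples), function(j) {
      mfi <- vals[, j]
      names(mfi) <- beads
      sample_profile(sprintf("AR%04d", j), sprintf("ARP%04d", j), 0L,
                     assay_class, mfi)
    })
    targets <- if (n_overreactive > 0L) sort(sample(beads, n_overreactive))
               else character(0)
    inj <- if (n_overreactive > 0L)
      inject_overreactive_beads(samples, targets, sd_multiplier, spike_prob,
                                spike_mfi, max_mfi = cutoff - 0.01)
    else list(samples = samples,
              bead_truth = data.frame(bead = beads, overreactive = FALSE,
                                      stringsAsFactors = FALSE))
    list(samples = inj$samples,
         panel = bead_panel(assay_class, beads),
         target_beads = targets,
         bead_truth = inj$bead_truth)
  })
}

#' Study design for a synthetic screening cohort
#'
#' Default cohort sizes mirror the screening study design the method was
#' characterized on: 25 patients with an index event (alternating de-novo
#' new-specificity and at-least-2-fold inflation events), 20 stable
#' moderately reactive control patients, and 13 highly sensitized control
#' patients, each with 5 historic draws plus one index draw on a 96-bead
#' panel with 15% draw-to-draw CV.
#'
#' @param n_event,n_stable,n_sensitized Patients per cohort.
#' @param n_historic,n_beads,noise_cv,assay_class As in [sim_config()].
#' @param new_mfi_range MFI range of injected new specificities.
#' @param n_new_beads_range Range of the number of new beads per event.
#' @param inflation_pct_range Percent-increase range of inflation events.
#' @param positive_range_stable,positive_range_event Positive-bead count
#'   ranges of stable/event patients.
#' @param positive_range_sensitized Positive-bead count range of sensitized
#'   patients.
#' @return An object of class `sab_study_config`.
#' @export
study_config <- function(n_event = 25L, n_stable = 20L, n_sensitized = 13L,
                         n_historic = 5L, n_beads = 96L, noise_cv = 0.15,
                         assay_class = "I",
                         new_mfi_range = c(3000, 10000),
                         n_new_beads_range = c(1L, 2L),
                         inflation_pct_range = c(119.67, 243.33),
                         positive_range_stable = c(2L, 8L),
                         positive_range_event = c(2L, 8L),
                         positive_range_sensitized = c(30L, 60L)) {
  structure(
    list(n_event = as.integer(n_event), n_stable = as.integer(n_stable),
         n_sensitized = as.integer(n_sensitized),
         n_historic = as.integer(n_historic), n_beads = as.integer(n_beads),
         noise_cv = noise_cv, assay_class = assay_class,
         new_mfi_range = new_mfi_range,
         n_new_beads_range = as.integer(n_new_beads_range),
         inflation_pct_range = inflation_pct_range,
         positive_range_stable = as.integer(positive_range_stable),
         positive_range_event = as.integer(positive_range_event),
         positive_range_sensitized = as.integer(positive_range_sensitized)),
    class = "sab_study_config")
}

#' Simulate a full synthetic screening study
#'
#' Generates every patient of a [study_config()] design, deterministically
#' from `seed`. Event patients alternate between new-specificity and
#' inflation events. Optionally writes the dataset as a wide-dialect CSV
#' (round-trippable through [read_samples_csv()]) plus a truth-table CSV;
#' outputs are byte-identical across reruns with the same seed.
#'
#' @param study A [study_config()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory; `samples.csv` and `truth.csv`
#'   are written there.
#' @return List with `patients` (per-patient [simulate_patient()] results,
#'   named by patient id), `samples` (flat list of profiles), `panel`,
#'   `truth` (data frame `sample_id, patient_id, cohort, label, is_index`),
#'   `study`, `seed` and, when written, `files`.
#' @export
simulate_study <- function(study = study_config(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(study, "sab_study_config"))
  n_total <- study$n_event + study$n_stable + study$n_sensitized
  seeds <- derive_seeds(seed, n_total + 1L)
  specs <- list()
  if (study$n_event > 0L)
    specs <- c(specs, lapply(seq_len(study$n_event), function(i) {
      type <- if (i %% 2L == 1L) "new_specificity" else "inflation"
      ev <- if (type == "new_specificity")
        list(type = type,
             n_new_beads = study$n_new_beads_range[1] +
               (i %/% 2L) %% (study$n_new_beads_range[2] - study$n_new_beads_range[1] + 1L),
             new_mfi = study$new_mfi_range)
      else list(type = type, inflation_pct_range = study$inflation_pct_range)
      list(patient_id = sprintf("EVT%03d", i), cohort = "event", event = ev,
           n_positive_range = study$positive_range_event)
    }))
  if (study$n_stable > 0L)
    specs <- c(specs, lapply(seq_len(study$n_stable), function(i)
      list(patient_id = sprintf("STB%03d", i), cohort = "stable",
           event = list(type = "none"),
           n_positive_range = study$positive_range_stable)))
  if (study$n_sensitized > 0L)
    specs <- c(specs, lapply(seq_len(study$n_sensitized), function(i)
      list(patient_id = sprintf("SEN%03d", i), cohort = "sensitized",
           event = list(type = "none"),
           n_positive_range = study$positive_range_sensitized)))

  patients <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    cfg <- sim_config(seed = seeds[i], n_beads = study$n_beads,
                      noise_cv = study$noise_cv,
                      n_historic = study$n_historic,
                      n_positive_range = sp$n_positive_range,
                      event = sp$event, assay_class = study$assay_class,
                      patient_id = sp$patient_id)
    out <- simulate_patient(cfg)
    out$cohort <- sp$cohort
    out
  })
  names(patients) <- vapply(specs, function(sp) sp$patient_id, character(1))

  samples <- unlist(lapply(patients, function(p) p$history$samples),
                    recursive = FALSE, use.names = FALSE)
  truth <- if (length(patients) > 0L)
    do.call(rbind, lapply(patients, function(p)
      cbind(p$truth,
            patient_id = p$history$patient_id, cohort = p$cohort,
            stringsAsFactors = FALSE)))
  else data.frame(sample_id = character(0), label = character(0),
                  is_index = logical(0), patient_id = character(0),
                  cohort = character(0), stringsAsFactors = FALSE)
  truth <- truth[, c("sample_id", "patient_id", "cohort", "label", "is_index")]
  rownames(truth) <- NULL
  panel <- bead_panel(study$assay_class,
                      synthetic_bead_names(study$n_beads, study$assay_class))
  result <- list(patients = patients, samples = samples, panel = panel,
                 truth = truth, study = study, seed = seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    sample_file <- file.path(out_dir, "samples.csv")
    truth_file <- file.path(out_dir, "truth.csv")
    write_samples_csv(samples, panel, sample_file, dialect = "wide")
    write_table_csv(truth, truth_file)
    result$files <- c(samples = sample_file, truth = truth_file)
  }
  result
}

# Deterministic CSV writer for plain data frames (RFC 4180, LF, no rownames).
write_table_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.10g", col)
    else csv_quote(as.character(col))
  })
  lines <- c(paste(csv_quote(colnames(df)), collapse = ","),
             if (nrow(df) > 0L) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
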