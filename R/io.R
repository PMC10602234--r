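#' Read SAB MFI tables from CSV
#'
#' Two documented dialects are supported. The *wide* dialect has one row per
#' sample: header columns `sample_id, patient_id, draw_index, assay_class`
#' followed by one column per bead identifier; an empty cell means the bead
#' was absent from that sample's panel lot. The *long* dialect has columns
#' `sample_id, patient_id, draw_index, assay_class, bead, mfi`, one row per
#' (sample, bead). Files are UTF-8, RFC 4180 quoted, decimal point `.`,
#' header row mandatory. All samples in one file must share an assay class.
#'
#' @param path Path to the CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param control_ids Bead identifiers to record as control beads on the
#'   returned panel (they are not removed here; see
#'   [strip_controls_and_qc()]).
#' @return A list with `samples` (list of [sample_profile()]) and `panel`
#'   ([bead_panel()] inferred from the file).
#' @export
read_samples_csv <- function(path, dialect = c("wide", "long"),
                             control_ids = character(0)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (dialect == "wide") read_wide(df, path, control_ids)
  else read_long(df, path, control_ids)
}

required_meta_cols <- c("sample_id", "patient_id", "draw_index", "assay_class")

check_columns <- function(df, needed, path) {
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
}

parse_mfi <- function(values, rows, path, what) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) | out < 0)
  if (length(bad) > 0L)
    stop(sprintf("%s: negative or non-numeric MFI for %s at data row %d (value '%s')",
                 path, what, rows[bad[1L]], values[bad[1L]]))
  out
}

single_class <- function(classes, path) {
  cls <- unique(classes)
  if (length(cls) != 1L)
    stop(sprintf("%s: mixed assay classes in one file (%s)",
                 path, paste(cls, collapse = ", ")))
  cls
}

read_wide <- function(df, path, control_ids) {
  check_columns(df, required_meta_cols, path)
  beads <- setdiff(colnames(df), required_meta_cols)
  if (length(beads) == 0L)
    stop(sprintf("%s: wide file contains no bead columns", path))
  if (anyDuplicated(colnames(df)))
    stop(sprintf("%s: duplicate column names", path))
  cls <- single_class(df$assay_class, path)
  samples <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- as.character(df[i, beads])
    present <- !is.na(vals) & vals != ""
    if (!any(present))
      stop(sprintf("%s: sample '%s' has no bead values", path, df$sample_id[i]))
    mfi <- parse_mfi(vals[present], rep(i, sum(present)), path,
                     sprintf("sample '%s'", df$sample_id[i]))
    names(mfi) <- beads[present]
    samples[[i]] <- sample_profile(df$sample_id[i], df$patient_id[i],
                                   df$draw_index[i], cls, mfi)
  }
  check_unique_samples(samples, path)
  list(samples = samples,
       panel = bead_panel(cls, beads, intersect(control_ids, beads)))
}

read_long <- function(df, path, control_ids) {
  check_columns(df, c(required_meta_cols, "bead", "mfi"), path)
  cls <- single_class(df$assay_class, path)
  key <- paste(df$sample_id, df$bead, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("%s: duplicate record for sample '%s', bead '%s' at data row %d",
                 path, df$sample_id[d], df$bead[d], d))
  }
  mfi_all <- parse_mfi(df$mfi, seq_len(nrow(df)), path, "long record")
  beads <- unique(df$bead)
  sample_ids <- unique(df$sample_id)
  samples <- lapply(sample_ids, function(sid) {
    rows <- df$sample_id == sid
    mfi <- mfi_all[rows]
    names(mfi) <- df$bead[rows]
    sample_profile(sid, df$patient_id[rows][1L], df$draw_index[rows][1L],
                   cls, mfi)
  })
  check_unique_samples(samples, path)
  list(samples = samples,
       panel = bead_panel(cls, beads, intersect(control_ids, beads)))
}

check_unique_samples <- function(samples, path) {
  ids <- vapply(samples, function(s) paste(s$patient_id, s$sample_id, sep = "\r"),
                character(1))
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate (patient_id, sample_id)", path))
  invisible(TRUE)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

format_mfi <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)

#' Write SAB MFI tables to CSV
#'
#' Inverse of [read_samples_csv()]. MFI values are written at a fixed decimal
#' precision (`digits`, default 2); a write/read cycle is the identity on
#' values already rounded to that precision. Output is byte-deterministic for
#' a given input.
#'
#' @param samples List of [sample_profile()] objects (one assay class).
#' @param panel [bead_panel()] supplying the bead column order for the wide
#'   dialect.
#' @param path Output file path.
#' @param dialect `"wide"` or `"long"`.
#' @param digits Decimal places written for MFI values.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, panel, path,
                              dialect = c("wide", "long"), digits = 2L) {
  dialect <- match.arg(dialect)
  beads <- panel$specificities
  lines <- if (dialect == "wide") {
    header <- paste(csv_quote(c(required_meta_cols, beads)), collapse = ",")
    rows <- vapply(samples, function(s) {
      vals <- character(length(beads))
      present <- beads %in% names(s$mfi)
      vals[present] <- format_mfi(s$mfi[beads[present]], digits)
      paste(c(csv_quote(c(s$sample_id, s$patient_id)),
              as.character(s$draw_index), s$assay_class, vals),
            collapse = ",")
    }, character(1))
    c(header, rows)
  } else {
    header <- paste(c(required_meta_cols, "bead", "mfi"), collapse = ",")
    rows <- unlist(lapply(samples, function(s) {
      paste(csv_quote(s$sample_id), csv_quote(s$patient_id), s$draw_index,
            s$assay_class, csv_quote(names(s$mfi)),
            format_mfi(unname(s$mfi), digits), sep = ",")
    }))
    c(header, rows)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Remove QC samples and control beads
#'
#' Drops samples whose `sample_id` matches the QC pattern (the laboratory
#' convention for kit quality-control sera) and removes the panel's control
#' beads from the remaining profiles. Retained bead values are never altered
#' and input order is preserved.
#'
#' @param samples List of [sample_profile()] objects.
#' @param panel [bead_panel()] whose `control_ids` are removed.
#' @param qc_pattern Regular expression matched against `sample_id`
#'   (default: identifiers starting with `"QC"`).
#' @return Filtered list of profiles (possibly empty).
#' @export
strip_controls_and_qc <- function(samples, panel, qc_pattern = "^QC") {
  keep <- !grepl(qc_pattern, vapply(samples, function(s) s$sample_id, character(1)))
  lapply(samples[keep], function(s) {
    retained <- setdiff(names(s$mfi), panel$control_ids)
    if (length(retained) == 0L)
      stop(sprintf("sample '%s' has no non-control beads", s$sample_id))
    sample_profile(s$sample_id, s$patient_id, s$draw_index, s$assay_class,
                   s$mfi[retained])
  })
}

#' Deidentify samples with a reversible key file
#'
#' Replaces patient and sample identifiers with sequential study numbers and
#' writes the reversible mapping to a separate key CSV, mirroring a blinded
#' review workflow. Identifier content never enters any computation; this is
#' plumbing only.
#'
#' @param samples List of [sample_profile()] objects.
#' @param key_path Optional path for the key CSV
#'   (`study_sample_id, sample_id, study_patient_id, patient_id`).
#' @return List with `samples` (relabelled) and `key` (data frame).
#' @export
deidentify_samples <- function(samples, key_path = NULL) {
  sample_ids <- vapply(samples, function(s) s$sample_id, character(1))
  patient_ids <- vapply(samples, function(s) s$patient_id, character(1))
  pat_map <- sprintf("PT%03d", seq_along(unique(patient_ids)))
  names(pat_map) <- unique(patient_ids)
  samp_map <- sprintf("SMP%04d", seq_along(sample_ids))
  names(samp_map) <- sample_ids
  key <- data.frame(study_sample_id = unname(samp_map[sample_ids]),
                    sample_id = sample_ids,
                    study_patient_id = unname(pat_map[patient_ids]),
                    patient_id = patient_ids,
                    stringsAsFactors = FALSE)
  relabelled <- lapply(samples, function(s)
    sample_profile(samp_map[[s$sample_id]], pat_map[[s$patient_id]],
                   s$draw_index, s$assay_class, s$mfi))
  if (!is.null(key_path))
    write.csv(key, key_path, row.names = FALSE, quote = TRUE)
  list(samples = relabelled, key = key)
}
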