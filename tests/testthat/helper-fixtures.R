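# In-code fixtures shared across test files.

make_profile <- function(sample_id, mfi, patient_id = "P1", draw = 0L,
                         assay_class = "I") {
  sample_profile(sample_id, patient_id, draw, assay_class, mfi)
}

# A patient history directly from a numeric matrix: rows = draws, cols = beads.
history_from_matrix <- function(m, patient_id = "P1", assay_class = "I",
                                beads = NULL) {
  beads <- beads %||% colnames(m) %||% paste0("b", seq_len(ncol(m)))
  samples <- lapply(seq_len(nrow(m)), function(i) {
    mfi <- m[i, ]
    names(mfi) <- beads
    sample_profile(sprintf("%s_T%02d", patient_id, i - 1L), patient_id,
                   i - 1L, assay_class, mfi)
  })
  build_history(samples, patient_id, assay_class, min_common_beads = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equilateral triangle with unit side; centroid at (0.5, sqrt(3)/6).
triangle_historic <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))

rand_matrix <- function(n, p) matrix(rnorm(n * p), n, p)

# Independent seed streams for simulation-property tests.
derive_test_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Sign-normalize loading columns the way the package documents: the entry of
# largest absolute value (ties -> lowest index) is made non-negative.
normalize_signs <- function(loadings) {
  for (j in seq_len(ncol(loadings))) {
    v <- loadings[, j]
    if (v[which.max(abs(v))] < 0) loadings[, j] <- -v
  }
  loadings
}
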