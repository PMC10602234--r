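test_that("wide dialect round-trips, including an all-zero matrix", {
  beads <- c("A*01:01", "B*07:02", "C*04:01")
  samples <- list(make_profile("s1", setNames(c(0, 0, 0), beads)),
                  make_profile("s2", setNames(c(0, 0, 0), beads), draw = 1L))
  panel <- bead_panel("I", beads)
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(samples, panel, path, "wide")
  back <- read_samples_csv(path, "wide")
  expect_length(back$samples, 2L)
  expect_equal(back$panel$specificities, beads)
  for (i in 1:2) {
    expect_equal(back$samples[[i]]$mfi, samples[[i]]$mfi)
    expect_equal(back$samples[[i]]$sample_id, samples[[i]]$sample_id)
    expect_equal(back$samples[[i]]$draw_index, samples[[i]]$draw_index)
  }
})

test_that("long dialect transcribes records directly and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,draw_index,assay_class,bead,mfi",
               "s1,P1,0,I,b1,100",
               "s1,P1,0,I,b2,2000"), path)
  ds <- read_samples_csv(path, "long")
  expect_length(ds$samples, 1L)
  expect_equal(ds$samples[[1]]$mfi, c(b1 = 100, b2 = 2000))

  out <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(ds$samples, ds$panel, out, "long")
  again <- read_samples_csv(out, "long")
  expect_equal(again$samples[[1]]$mfi, ds$samples[[1]]$mfi)
})

test_that("a generated 10x96 dataset round-trips profile-by-profile in both dialects", {
  sim <- simulate_study(study_config(n_event = 0L, n_stable = 2L,
                                     n_sensitized = 0L, n_historic = 4L),
                        seed = 101)
  expect_length(sim$samples, 10L)
  for (dialect in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_samples_csv(sim$samples, sim$panel, path, dialect)
    back <- read_samples_csv(path, dialect)
    expect_length(back$samples, length(sim$samples))
    for (i in seq_along(sim$samples)) {
      expect_equal(back$samples[[i]]$mfi, sim$samples[[i]]$mfi)
      expect_equal(back$samples[[i]]$patient_id, sim$samples[[i]]$patient_id)
    }
  }
})

test_that("format errors are reported with the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,patient_id,assay_class,b1", "s1,P1,I,100"), path)
  expect_error(read_samples_csv(path, "wide"), "draw_index")

  writeLines(c("sample_id,patient_id,draw_index,assay_class,b1,b2",
               "s1,P1,0,I,100,-5"), path)
  expect_error(read_samples_csv(path, "wide"), "row 1")

  writeLines(c("sample_id,patient_id,draw_index,assay_class,bead,mfi",
               "s1,P1,0,I,b1,100",
               "s1,P1,0,I,b1,200"), path)
  expect_error(read_samples_csv(path, "long"), "duplicate")

  writeLines(c("sample_id,patient_id,draw_index,assay_class,bead,mfi",
               "s1,P1,0,I,b1,abc"), path)
  expect_error(read_samples_csv(path, "long"), "non-numeric")
})

test_that("strip_controls_and_qc drops QC samples and control beads, leaving values intact", {
  beads <- c("PC", "NC", "b1")
  panel <- bead_panel("I", beads, control_ids = c("PC", "NC"))
  samples <- list(
    make_profile("QC1", c(PC = 21000, NC = 40, b1 = 100)),
    make_profile("P1s", c(PC = 20000, NC = 50, b1 = 300)))
  out <- strip_controls_and_qc(samples, panel)
  expect_length(out, 1L)
  expect_equal(out[[1]]$sample_id, "P1s")
  expect_equal(out[[1]]$mfi, c(b1 = 300))
})

test_that("QC filtering keeps exactly the non-QC samples of a batch", {
  beads <- paste0("b", 1:4)
  panel <- bead_panel("I", beads)
  mk <- function(id) make_profile(id, setNames(runif(4, 0, 500), beads),
                                  patient_id = id)
  samples <- c(lapply(sprintf("S%03d", 1:95), mk),
               lapply(sprintf("QC%d", 1:5), mk))
  out <- strip_controls_and_qc(samples, panel)
  expect_length(out, 95L)
  expect_equal(vapply(out, function(s) s$sample_id, character(1)),
               sprintf("S%03d", 1:95))
})

test_that("build_history sorts draws, intersects bead sets and warns on lot drift", {
  s1 <- make_profile("a", c(b1 = 1, b2 = 2, b3 = 3), draw = 1L)
  s2 <- make_profile("b", c(b2 = 4, b3 = 5, b4 = 6), draw = 0L)
  h <- NULL
  expect_warning(
    h <- build_history(list(s1, s2), "P1", "I", min_common_beads = 1L),
    "dropped")
  expect_equal(h$common_beads, c("b2", "b3"))
  expect_equal(vapply(h$samples, function(s) s$sample_id, character(1)),
               c("b", "a"))

  # identical bead sets: nothing dropped, no drift warning
  t1 <- make_profile("x", setNames(runif(96, 0, 100), paste0("b", 1:96)))
  t2 <- make_profile("y", setNames(runif(96, 0, 100), paste0("b", 1:96)), draw = 1L)
  h2 <- build_history(list(t1, t2), "P1", "I")
  expect_length(h2$common_beads, 96L)
})

test_that("build_history is independent of input sample order", {
  set.seed(5)
  profs <- lapply(0:3, function(d)
    make_profile(paste0("s", d), setNames(runif(5, 0, 100), paste0("b", 1:5)),
                 draw = d))
  h1 <- build_history(profs, "P1", "I", min_common_beads = 1L)
  h2 <- build_history(rev(profs), "P1", "I", min_common_beads = 1L)
  expect_equal(h1$common_beads, h2$common_beads)
  expect_equal(vapply(h1$samples, function(s) s$sample_id, character(1)),
               vapply(h2$samples, function(s) s$sample_id, character(1)))
})

test_that("build_history errors on empty selections and empty intersections", {
  s1 <- make_profile("a", c(b1 = 1))
  expect_error(build_history(list(s1), "P9", "I"), "no samples")
  s2 <- make_profile("b", c(b2 = 1), draw = 1L)
  expect_error(build_history(list(s1, s2), "P1", "I"), "no common beads")
})

test_that("two-lot synthetic history keeps the shared beads with a warning", {
  beads_a <- paste0("b", 1:96)
  beads_b <- c(paste0("b", 3:96), "x1", "x2", "x3", "x4")  # 94 shared
  s1 <- make_profile("a", setNames(runif(96, 0, 100), beads_a))
  s2 <- make_profile("b", setNames(runif(98, 0, 100), beads_b), draw = 1L)
  h <- NULL
  expect_warning(h <- build_history(list(s1, s2), "P1", "I"), "dropped")
  expect_length(h$common_beads, 94L)
})

test_that("deidentification is reversible through the key file", {
  samples <- list(make_profile("lab-123", c(b1 = 1), patient_id = "MRN9"),
                  make_profile("lab-456", c(b1 = 2), patient_id = "MRN9"))
  key_path <- withr::local_tempfile(fileext = ".csv")
  d <- deidentify_samples(samples, key_path)
  expect_true(file.exists(key_path))
  expect_equal(d$samples[[1]]$sample_id, "SMP0001")
  expect_equal(d$samples[[2]]$patient_id, d$samples[[1]]$patient_id)
  key <- read.csv(key_path, stringsAsFactors = FALSE)
  expect_equal(key$sample_id[key$study_sample_id == "SMP0002"], "lab-456")
  # values untouched
  expect_equal(d$samples[[2]]$mfi, samples[[2]]$mfi)
})
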