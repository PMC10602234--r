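test_that("non-reactivity is strict: a bead exactly at the cutoff counts as reactive", {
  beads <- paste0("b", 1:5)
  zero <- make_profile("s0", setNames(rep(0, 5), beads))
  expect_true(is_nonreactive(zero, 1000))
  at_cutoff <- make_profile("s1", setNames(c(1000, 0, 0, 0, 0), beads))
  expect_false(is_nonreactive(at_cutoff, 1000))
  near <- make_profile("s2", setNames(c(999.9, 500, 10, 0, 3), beads))
  expect_true(is_nonreactive(near, 1000))
  expect_equal(is_nonreactive(near, 1000), max(near$mfi) < 1000)
})

test_that("distance_ratio reproduces the equilateral-triangle geometry", {
  centroid <- c(0.5, sqrt(3) / 6)
  dr <- distance_ratio(centroid, triangle_historic)
  expect_equal(dr$denominator_mean_ed, 1, tolerance = 1e-12)
  expect_equal(dr$numerator_mean_ed, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(dr$distance_ratio, 1 / sqrt(3), tolerance = 1e-12)
  expect_false(dr$degenerate)

  # index on a vertex: distances (0, 1, 1) -> DR = 2/3
  dr2 <- distance_ratio(c(0, 0), triangle_historic)
  expect_equal(dr2$numerator_mean_ed, 2 / 3, tolerance = 1e-12)
  expect_equal(dr2$distance_ratio, 2 / 3, tolerance = 1e-12)
})

test_that("degenerate geometries follow the documented ratio rules", {
  same <- rbind(c(1, 1), c(1, 1), c(1, 1))
  dr <- distance_ratio(c(1, 1), same)
  expect_equal(dr$distance_ratio, 1)
  expect_true(dr$degenerate)

  dr_inf <- distance_ratio(c(5, 5), same)
  expect_identical(dr_inf$distance_ratio, Inf)
  expect_false(dr_inf$degenerate)

  expect_error(distance_ratio(c(0, 0), rbind(c(1, 1))), "2 historic")
  expect_error(distance_ratio(c(0, 0, 0), same), "dimension")
})

test_that("flag_sample handles degenerate, insufficient and nonreactive cases", {
  m <- matrix(rep(c(2000, 150, 80), each = 4), 4, 3)
  h <- history_from_matrix(m)
  res <- flag_sample(h, "P1_T03")
  expect_equal(res$reason, "degenerate_history")
  expect_equal(res$distance_ratio, 1)
  expect_false(res$flagged)

  h2 <- history_from_matrix(matrix(c(2000, 2100, 150, 160, 80, 90), 2, 3))
  res2 <- flag_sample(h2, "P1_T01")
  expect_equal(res2$reason, "insufficient_history")
  expect_false(res2$flagged)
  expect_true(is.na(res2$distance_ratio))

  m3 <- rbind(c(2000, 150, 80), c(2100, 160, 90), c(1900, 140, 70),
              c(500, 100, 60))
  res3 <- flag_sample(history_from_matrix(m3), "P1_T03")
  expect_equal(res3$reason, "nonreactive_discarded")
  expect_false(res3$flagged)

  expect_error(flag_sample(h, "nope"), "not found")
})

test_that("an identical history with a deviant index yields an infinite ratio and a flag", {
  m <- rbind(c(2000, 150), c(2000, 150), c(2000, 150), c(9000, 150))
  res <- flag_sample(history_from_matrix(m), "P1_T03")
  expect_identical(res$distance_ratio, Inf)
  expect_true(res$flagged)
  expect_equal(res$reason, "above_threshold")
})

test_that("ratio is invariant to bead offsets, global scale and historic order", {
  set.seed(21)
  base <- matrix(runif(5 * 8, 0, 3000), 5, 8)
  h <- history_from_matrix(base)
  ref <- flag_sample(h, "P1_T04")$distance_ratio

  shifted <- sweep(base, 2L, runif(8, 0, 500), "+")
  expect_equal(flag_sample(history_from_matrix(shifted), "P1_T04")$distance_ratio,
               ref, tolerance = 1e-9)

  expect_equal(flag_sample(history_from_matrix(base * 3.7), "P1_T04")$distance_ratio,
               ref, tolerance = 1e-9)

  perm <- base[c(3, 1, 4, 2, 5), ]
  h_perm <- history_from_matrix(perm)
  # index row 5 of base is now draw 4 still last: same index sample
  expect_equal(flag_sample(h_perm, "P1_T04")$distance_ratio, ref,
               tolerance = 1e-9)
})

test_that("raising the threshold never converts a non-flagged sample to flagged", {
  set.seed(33)
  for (i in 1:10) {
    m <- matrix(runif(5 * 6, 0, 5000), 5, 6)
    h <- history_from_matrix(m)
    low <- flag_sample(h, "P1_T04", flag_config(ratio_threshold = 1.1))
    high <- flag_sample(h, "P1_T04", flag_config(ratio_threshold = 2.0))
    expect_true(low$flagged >= high$flagged)
    expect_equal(low$distance_ratio, high$distance_ratio)
  }
})

test_that("flagging is inclusive at the threshold", {
  # rig a history whose DR is exactly 1 and flag at threshold 1
  m <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  m <- m + 100
  h <- history_from_matrix(m)
  res <- flag_sample(h, "P1_T03", flag_config(ratio_threshold = 1))
  expect_equal(res$distance_ratio, 1, tolerance = 1e-12)
  expect_true(res$flagged)
})

test_that("leave-one-out profile: identical samples and square corners both give DR 1", {
  m_same <- matrix(rep(c(1500, 200, 90), each = 3), 3, 3)
  prof <- fold_difference_profile(history_from_matrix(m_same))
  expect_equal(unname(prof), rep(1, 3))

  square <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)) + 50
  prof2 <- fold_difference_profile(history_from_matrix(square))
  expect_equal(unname(prof2), rep(1, 4), tolerance = 1e-12)

  expect_error(fold_difference_profile(history_from_matrix(m_same[1:2, ])),
               "at least 3")
})

test_that("an injected new specificity is flagged and dominates the LOO profile", {
  flagged <- 0L; top <- 0L
  seeds <- derive_test_seeds(515, 30)
  for (s in seeds) {
    p <- simulate_patient(sim_config(seed = s,
                                     event = list(type = "new_specificity",
                                                  n_new_beads = 1L,
                                                  new_mfi = 8000)))
    idx <- p$truth$sample_id[p$truth$is_index]
    res <- flag_sample(p$history, idx)
    flagged <- flagged + res$flagged
    prof <- fold_difference_profile(p$history)
    top <- top + (names(which.max(prof)) == idx)
  }
  expect_gte(flagged / 30, 0.9)
  expect_gte(top / 30, 0.9)
})

test_that("a stable sixth draw usually stays under the 1.4 threshold", {
  seeds <- derive_test_seeds(616, 30)
  drs <- vapply(seeds, function(s) {
    p <- simulate_patient(sim_config(seed = s))
    flag_sample(p$history, p$truth$sample_id[p$truth$is_index])$distance_ratio
  }, numeric(1))
  expect_lt(median(drs), 1.4)
})
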