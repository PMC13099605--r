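test_that("empirical ladder interpolates between the anchors", {
  lad <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
  expect_equal(lad$step_kDa, (602.09 - 548.08) / 8)
  expect_equal(lad$step_kDa, 6.75125)
  expect_equal(unname(lad$rungs[1L]), 548.08)
  expect_equal(unname(lad$rungs[9L]), 602.09)
  # linearity: constant step
  expect_equal(unique(round(diff(lad$rungs), 10)), 6.75125)
})

test_that("theoretical ladder uses per-subunit masses and rejects degeneracy", {
  lad <- build_ladder(mass_a_kDa = 22.48, mass_b_kDa = 15.62,
                      core_mass_kDa = 423.12)
  expect_equal(lad$step_kDa, 6.86)
  expect_equal(unname(lad$rungs[1L]), 423.12 + 8 * 15.62)
  expect_error(build_ladder(mass_a_kDa = 15.62, mass_b_kDa = 15.62,
                            core_mass_kDa = 423.12), "degenerate")
  expect_error(build_ladder(anchor_low_kDa = 602, anchor_high_kDa = 548),
               "exceed")
  expect_error(build_ladder(anchor_low_kDa = 548), "either")
})

test_that("peaks are assigned to the nearest rung with residuals", {
  lad <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
  # a peak exactly on rung 3
  on_rung <- data.frame(mass_kDa = unname(lad$rungs[4L]))
  a <- assign_peaks(on_rung, lad)
  expect_identical(a$k, 3L)
  expect_equal(a$residual_kDa, 0)
  expect_true(a$within_tolerance)

  # the four printed heterogeneous masses resolve to four stoichiometries
  peaks <- data.frame(mass_kDa = c(561.63, 586.39, 575.16, 581.91))
  a4 <- assign_peaks(peaks, lad)
  expect_identical(attr(a4, "n_distinct"), 4L)
  expect_identical(a4$k[1L], 2L)                 # 561.63 -> two substitutions
  expect_equal(a4$residual_kDa[1L], 561.63 - (548.08 + 2 * 6.75125),
               tolerance = 1e-9)
  expect_lt(abs(a4$residual_kDa[1L]), 0.06)
  expect_identical(a4$ratio[1L], "6:2")
  # the between-rung peak is reported with its residual, not forced
  expect_false(a4$within_tolerance[2L])
  expect_gt(abs(a4$residual_kDa[2L]), 1)
})

test_that("assignment is permutation invariant and tolerates empty input", {
  lad <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
  peaks <- data.frame(mass_kDa = c(561.63, 586.39, 575.16, 581.91))
  perm <- peaks[c(3, 1, 4, 2), , drop = FALSE]
  a1 <- assign_peaks(peaks, lad)
  a2 <- assign_peaks(perm, lad)
  expect_identical(sort(a1$k), sort(a2$k))
  expect_identical(attr(a1, "n_distinct"), attr(a2, "n_distinct"))

  a0 <- assign_peaks(data.frame(mass_kDa = numeric(0)), lad)
  expect_identical(nrow(a0), 0L)
  expect_identical(attr(a0, "n_distinct"), 0L)
})

test_that("equidistant peaks break ties toward lower k with a warning", {
  lad <- build_ladder(anchor_low_kDa = 100, anchor_high_kDa = 180)  # step 10
  expect_warning(a <- assign_peaks(data.frame(mass_kDa = 115), lad),
                 "tie")
  expect_identical(a$k, 1L)
})

test_that("empirical and theoretical ladders agree on the printed masses", {
  emp <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
  theo <- build_ladder(mass_a_kDa = 22.48, mass_b_kDa = 15.62,
                       core_mass_kDa = 548.08 - 8 * 15.62)
  peaks <- data.frame(mass_kDa = c(561.63, 586.39, 575.16, 581.91))
  expect_identical(assign_peaks(peaks, emp)$k, assign_peaks(peaks, theo)$k)
})

test_that("assignment is exact when mass error is below step/6", {
  lad <- build_ladder(mass_a_kDa = 22.48, mass_b_kDa = 15.62,
                      core_mass_kDa = 423.12)
  counts <- dbinom(0:8, 8, 0.5)
  pk <- simulate_ms_peaks(counts, 22.48, 15.62, 423.12,
                          mass_sd_kDa = lad$step_kDa / 10, seed = 9)
  a <- assign_peaks(pk, lad)
  # generator labels its peaks with the true k
  expect_identical(a$k, pk$k)
  expect_true(all(abs(a$residual_kDa) < lad$step_kDa / 2))
})

test_that("denatured peaks verify subunit presence", {
  peaks <- data.frame(mass_kDa = c(15.63, 22.47))
  rep1 <- verify_subunit_presence(
    peaks, c(SSu_A = 22.48, SSu_B = 15.62), tolerance_kDa = 0.05)
  expect_true(all(rep1$present))
  expect_equal(rep1$matched_kDa[rep1$species == "SSu_A"], 22.47)

  # one species absent
  rep2 <- verify_subunit_presence(
    data.frame(mass_kDa = 15.62), c(SSu_A = 22.48, SSu_B = 15.62))
  expect_identical(rep2$present, c(FALSE, TRUE))

  # simulator round trip: peak masses derived from the generator species
  pk <- simulate_ms_peaks(c(1, rep(0, 7), 1), 22.48, 15.62, 423.12)
  sub_masses <- c(heavy = 423.12 + 8 * 22.48, light = 423.12 + 8 * 15.62)
  rep3 <- verify_subunit_presence(pk, sub_masses, tolerance_kDa = 0.01)
  expect_true(all(rep3$present))
})
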