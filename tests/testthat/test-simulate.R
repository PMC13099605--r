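test_that("assembly simulation matches the binomial model", {
  # degenerate skew
  pool <- simulate_assembly(1, n_holoenzymes = 500, seed = 1)
  expect_true(all(pool$k == 8L))

  # heterogeneous fraction within 3 binomial SE of 127/128 at n = 1e5
  pool <- simulate_assembly(0.5, n_holoenzymes = 1e5, seed = 2)
  p_het <- 127 / 128
  se <- sqrt(p_het * (1 - p_het) / 1e5)
  expect_lt(abs(mean(pool$k > 0 & pool$k < 8) - p_het), 3 * se)

  # chi-square goodness of fit against Binomial(8, 0.3)
  pool <- simulate_assembly(0.3, n_holoenzymes = 1e5, seed = 3)
  obs <- tabulate(pool$k + 1L, 9L)
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = dbinom(0:8, 8, 0.3)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("preference simulation matches the exact chain distribution", {
  pool <- simulate_assembly(0.5, alpha = 4, n_holoenzymes = 1e5, seed = 4)
  hom <- mean(pool$k %in% c(0L, 8L))
  expect_gt(hom, 2 / 256)   # well above the independent-sites value
  want <- brute_force_chain_pmf(0.5, 4)
  p_hom <- want[1L] + want[9L]
  expect_lt(abs(hom - p_hom), 3 * sqrt(p_hom * (1 - p_hom) / 1e5))
  # full distribution consistent with the exact chain pmf
  obs <- tabulate(pool$k + 1L, 9L)
  gof <- suppressWarnings(stats::chisq.test(obs, p = want))
  expect_gt(gof$p.value, 1e-4)
})

test_that("simulators are seed-deterministic", {
  expect_identical(simulate_assembly(0.4, alpha = 2, seed = 9),
                   simulate_assembly(0.4, alpha = 2, seed = 9))
  pool <- simulate_assembly(0.5, n_holoenzymes = 200, seed = 1)
  expect_identical(
    simulate_purification(pool, densitometry_cv = 0.1, seed = 5),
    simulate_purification(pool, densitometry_cv = 0.1, seed = 5))
  cnt <- dbinom(0:8, 8, 0.5)
  expect_identical(
    simulate_ms_peaks(cnt, 22.48, 15.62, 423.12, mass_sd_kDa = 0.1, seed = 3),
    simulate_ms_peaks(cnt, 22.48, 15.62, 423.12, mass_sd_kDa = 0.1, seed = 3))
  expect_identical(simulate_kinetic_data(seed = 11),
                   simulate_kinetic_data(seed = 11))
})

test_that("lossless noise-free purification conserves amounts exactly", {
  # 60% heterogeneous by construction
  pool <- manual_pool(c(150, 0, 0, 0, 600, 0, 0, 0, 250))
  rec <- simulate_purification(pool, e_his = 1, e_strep = 1)
  get <- function(st, ab)
    rec$intensity[rec$stage == st & rec$antibody == ab]
  # post-strep survivors / soluble = heterogeneous fraction
  expect_equal(get("post_strep", "anti_strep") / 1000, 0.60)
  expect_equal(attr(rec, "truth")$heterogeneous_fraction, 0.60)

  # constant efficiency thins His-tagged signal by exactly e
  rec2 <- simulate_purification(pool, e_his = 0.8, e_strep = 1)
  expect_equal(rec2$intensity[rec2$stage == "post_his" &
                                rec2$antibody == "anti_his"],
               0.8 * (600 + 250))
})

test_that("per-tag retention matches its closed form", {
  # closed form at m = 8 matching tags
  pool <- manual_pool(c(0, 0, 0, 0, 0, 0, 0, 0, 4000))   # all k = 8
  rec <- simulate_purification(pool, efficiency_mode = "per_tag", q = 0.25,
                               stochastic = TRUE, seed = 6)
  p_keep <- 1 - 0.75^8
  kept <- rec$intensity[rec$stage == "post_his" &
                          rec$antibody == "anti_his"] / 4000
  expect_lt(abs(kept - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / 4000))
  # deterministic thinning hits the closed form exactly
  rec2 <- simulate_purification(pool, efficiency_mode = "per_tag", q = 0.25)
  expect_equal(rec2$intensity[rec2$stage == "post_his" &
                                rec2$antibody == "anti_his"],
               4000 * p_keep)
})

test_that("noise conservation: lognormal band noise has unit mean", {
  pool <- manual_pool(c(0, 0, 0, 0, 1000, 0, 0, 0, 0))
  set.seed(8)
  ints <- replicate(400, {
    r <- simulate_purification(pool, e_his = 1, e_strep = 1,
                               densitometry_cv = 0.2)
    r$intensity[r$stage == "soluble" & r$antibody == "anti_his"]
  })
  expect_lt(abs(mean(ints) / 1000 - 1), 3 * 0.2 / sqrt(400))
})

test_that("simulated MS peaks follow the mass ladder and detection floor", {
  cnt <- c(rep(0, 8), 123)   # all mass at k = 8
  pk <- simulate_ms_peaks(cnt, 22.48, 15.62, 423.12)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mass_kDa, 423.12 + 8 * 22.48)

  # binomial abundances with floor 0.05 keep only k = 2..6
  pk2 <- simulate_ms_peaks(dbinom(0:8, 8, 0.5), 22.48, 15.62, 423.12,
                           detection_floor = 0.05)
  expect_identical(pk2$k, 2:6)
})

test_that("kinetic simulators hit their noise-free identities", {
  d <- simulate_mm_rates(2, 0.5, substrate_mM = 0.5, n_replicates = 1, cv = 0)
  expect_equal(d$rate, 1)    # v(S = K) = V/2

  r <- simulate_recovery(0.3, v_final = 2, time_min = 1 / 0.3,
                         n_replicates = 1, cv = 0)
  expect_equal(r$activity / 2, 1 - exp(-1))

  m <- simulate_melt(55, temperature_C = 55, base = 0.2, top = 1.2)
  expect_equal(m$signal, 0.7)    # midpoint at Tm
})

test_that("simulator parameter validation rejects bad inputs", {
  expect_error(simulate_assembly(1.5), "probability")
  expect_error(simulate_assembly(0.5, alpha = -1), "> 0")
  expect_error(simulate_ms_peaks(dbinom(0:8, 8, 0.5), -1, 15, 400), "> 0")
  expect_error(simulate_mm_rates(0, 0.5), "> 0")
  expect_error(simulate_melt(-5), "> 0")
})
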