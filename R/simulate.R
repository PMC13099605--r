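#' Simulate assembly of two SSu species into L8S8 holoenzymes
#'
#' Draws a pool of holoenzymes, each with `k` = number of His-tagged SSus
#' among its `n_sites` sites. With `alpha = 1` sites are independent and
#' `k ~ Binomial(n_sites, skew_p)`. With `alpha != 1` each holoenzyme's
#' sites are filled sequentially and the odds of repeating the species that
#' filled the previous site are multiplied by `alpha`, matching
#' [stoichiometry_pmf()] exactly.
#'
#' @param skew_p His-skew: per-site probability of the His-tagged species.
#' @param alpha preference multiplier (1 = independent sites).
#' @param n_holoenzymes pool size (>= 1).
#' @param n_sites SSu sites per holoenzyme (8 for L8S8).
#' @param seed integer seed for reproducibility, or NULL.
#' @return A data.frame with columns `holoenzyme` (index), `k` (His-tagged
#'   SSu count, 0..`n_sites`), `n_his_tags` (= `k`) and `n_strep_tags`
#'   (= `n_sites - k`), plus attributes `skew_p`, `alpha`,
#'   `heterogeneous_fraction` (empirical fraction with `0 < k < n_sites`).
#' @export
simulate_assembly <- function(skew_p, alpha = 1, n_holoenzymes = 10000L,
                              n_sites = 8L, seed = NULL) {
  check_prob(skew_p, "skew_p")
  check_pos(alpha, "alpha")
  n_holoenzymes <- as.integer(n_holoenzymes)
  if (n_holoenzymes < 1L) stop("'n_holoenzymes' must be >= 1", call. = FALSE)
  check_seed(seed)

  if (alpha == 1) {
    k <- stats::rbinom(n_holoenzymes, n_sites, skew_p)
  } else {
    p_hh <- alpha * skew_p / (alpha * skew_p + (1 - skew_p))
    p_hs <- skew_p / (skew_p + alpha * (1 - skew_p))
    last_his <- stats::runif(n_holoenzymes) < skew_p
    k <- as.integer(last_his)
    for (site in seq_len(n_sites - 1L)) {
      p_his <- ifelse(last_his, p_hh, p_hs)
      last_his <- stats::runif(n_holoenzymes) < p_his
      k <- k + as.integer(last_his)
    }
  }
  out <- data.frame(holoenzyme = seq_len(n_holoenzymes), k = k,
                    n_his_tags = k, n_strep_tags = n_sites - k)
  attr(out, "skew_p") <- skew_p
  attr(out, "alpha") <- alpha
  attr(out, "n_sites") <- n_sites
  attr(out, "heterogeneous_fraction") <- mean(k > 0L & k < n_sites)
  out
}

# retention probability of one holoenzyme at a column, given m matching tags
retention_prob <- function(m, mode, e, q) {
  if (mode == "constant") ifelse(m > 0L, e, 0) else 1 - (1 - q)^m
}

#' Simulate tandem affinity purification with western-blot readout
#'
#' Passes a simulated holoenzyme pool through a His-affinity column and then
#' a Strep-affinity column, and reports band intensities for each stage
#' (`soluble`, `post_his`, `post_strep`) probed with each antibody
#' (`anti_his`, `anti_strep`), the readout tracked during tandem
#' purification experiments.
#'
#' Column capture follows one of two efficiency models. Under
#' `efficiency_mode = "constant"` a holoenzyme with at least one matching
#' tag is retained with fixed probability (`e_his`, `e_strep`). Under
#' `"per_tag"` retention depends on tag count: a holoenzyme with `m`
#' matching tags is retained with probability `1 - (1 - q)^m`, the failure
#' mode under which the downstream corrected estimator is known to
#' underestimate heterogeneity. By default retention is applied as
#' deterministic expected-count thinning (each holoenzyme carries a weight
#' multiplied by its retention probability), so that noise-free runs satisfy
#' conservation identities exactly; `stochastic = TRUE` draws per-holoenzyme
#' Bernoulli outcomes instead.
#'
#' Band intensity at a stage is the retained holoenzyme count with at least
#' one matching tag (`signal_mode = "per_holoenzyme"`, what a native-PAGE
#' band reports) or the retained matching-tag count (`"per_tag"`, what an
#' epitope-proportional blot reports), times the antibody gain, times
#' multiplicative lognormal noise of coefficient of variation
#' `densitometry_cv`.
#'
#' @param holoenzymes data.frame from [simulate_assembly()].
#' @param e_his,e_strep constant-mode capture efficiencies in (0, 1].
#' @param efficiency_mode `"constant"` or `"per_tag"`.
#' @param q per-tag capture probability used when
#'   `efficiency_mode = "per_tag"`.
#' @param signal_mode `"per_holoenzyme"` or `"per_tag"`.
#' @param densitometry_cv coefficient of variation of the lognormal band
#'   noise (0 = noise-free).
#' @param gain_his,gain_strep antibody gains (free positive scalars).
#' @param replicate_id label stored in the `replicate` column.
#' @param stochastic logical; draw Bernoulli retention instead of
#'   expected-count thinning.
#' @param seed integer seed or NULL.
#' @return A data.frame with columns `replicate`, `stage`, `antibody`,
#'   `intensity` (6 rows), with attributes `truth` (a list holding the true
#'   heterogeneous fraction of the soluble pool and the stage-wise retained
#'   weights) for use in estimator validation.
#' @export
simulate_purification <- function(holoenzymes,
                                  e_his = 0.8, e_strep = 0.8,
                                  efficiency_mode = c("constant", "per_tag"),
                                  q = 0.3,
                                  signal_mode = c("per_holoenzyme", "per_tag"),
                                  densitometry_cv = 0,
                                  gain_his = 1, gain_strep = 1,
                                  replicate_id = "r1",
                                  stochastic = FALSE, seed = NULL) {
  efficiency_mode <- match.arg(efficiency_mode)
  signal_mode <- match.arg(signal_mode)
  if (!all(c("n_his_tags", "n_strep_tags") %in% names(holoenzymes)))
    stop("'holoenzymes' must come from simulate_assembly()", call. = FALSE)
  check_prob(e_his, "e_his"); check_prob(e_strep, "e_strep")
  check_prob(q, "q")
  check_pos(densitometry_cv, "densitometry_cv", strict = FALSE)
  check_pos(gain_his, "gain_his"); check_pos(gain_strep, "gain_strep")
  check_seed(seed)

  m_his <- holoenzymes$n_his_tags
  m_strep <- holoenzymes$n_strep_tags
  n <- length(m_his)

  w_sol <- rep(1, n)
  p_keep_his <- retention_prob(m_his, efficiency_mode, e_his, q)
  p_keep_strep <- retention_prob(m_strep, efficiency_mode, e_strep, q)
  if (stochastic) {
    w_his <- w_sol * (stats::runif(n) < p_keep_his)
    w_strep <- w_his * (stats::runif(n) < p_keep_strep)
  } else {
    w_his <- w_sol * p_keep_his
    w_strep <- w_his * p_keep_strep
  }

  signal <- function(w, m) {
    if (signal_mode == "per_holoenzyme") sum(w[m > 0L]) else sum(w * m)
  }
  stages <- list(soluble = w_sol, post_his = w_his, post_strep = w_strep)
  out <- expand.grid(stage = names(stages),
                     antibody = c("anti_his", "anti_strep"),
                     stringsAsFactors = FALSE)
  out$intensity <- mapply(function(st, ab) {
    w <- stages[[st]]
    if (ab == "anti_his") gain_his * signal(w, m_his)
    else gain_strep * signal(w, m_strep)
  }, out$stage, out$antibody)
  out$intensity <- out$intensity * rlnorm_cv(nrow(out), densitometry_cv)
  out <- data.frame(replicate = replicate_id, out, row.names = NULL)

  attr(out, "truth") <- list(
    heterogeneous_fraction = mean(m_his > 0L & m_strep > 0L),
    n_holoenzymes = n,
    retained = vapply(stages, sum, numeric(1)),
    efficiency_mode = efficiency_mode, signal_mode = signal_mode
  )
  out
}

#' Simulate deconvoluted native-MS peaks for a stoichiometry distribution
#'
#' One neutral-mass peak per represented stoichiometry `k`, at
#' `core_mass_kDa + k * mass_a_kDa + (n_sites - k) * mass_b_kDa` plus
#' Gaussian mass error; relative intensity is the abundance fraction.
#' Peaks below the detection floor (relative abundance) are suppressed.
#'
#' @param counts abundances over `k = 0..n_sites` (length `n_sites + 1`
#'   numeric, e.g. a pmf or holoenzyme counts).
#' @param mass_a_kDa,mass_b_kDa average masses (kDa) of the two SSu species;
#'   `k` counts copies of species A.
#' @param core_mass_kDa mass of the invariant core (L8 plus any constant
#'   components), kDa.
#' @param mass_sd_kDa SD of Gaussian mass error per peak, kDa.
#' @param detection_floor minimum relative abundance reported, in [0, 1).
#' @param n_sites number of SSu sites.
#' @param seed integer seed or NULL.
#' @return data.frame with columns `k`, `mass_kDa`, `rel_intensity`
#'   (fractions of total abundance), only rows above the floor.
#' @export
simulate_ms_peaks <- function(counts, mass_a_kDa, mass_b_kDa, core_mass_kDa,
                              mass_sd_kDa = 0, detection_floor = 0,
                              n_sites = 8L, seed = NULL) {
  if (length(counts) != n_sites + 1L || any(counts < 0))
    stop("'counts' must be a nonnegative vector over k = 0..n_sites",
         call. = FALSE)
  check_pos(mass_a_kDa, "mass_a_kDa"); check_pos(mass_b_kDa, "mass_b_kDa")
  check_pos(core_mass_kDa, "core_mass_kDa")
  check_pos(mass_sd_kDa, "mass_sd_kDa", strict = FALSE)
  if (detection_floor < 0 || detection_floor >= 1)
    stop("'detection_floor' must be in [0, 1)", call. = FALSE)
  check_seed(seed)

  k <- 0:n_sites
  rel <- counts / sum(counts)
  mass <- core_mass_kDa + k * mass_a_kDa + (n_sites - k) * mass_b_kDa +
    stats::rnorm(n_sites + 1L, 0, mass_sd_kDa)
  keep <- rel >= detection_floor & rel > 0
  data.frame(k = k[keep], mass_kDa = mass[keep], rel_intensity = rel[keep],
             row.names = NULL)
}

#' Simulate Michaelis-Menten rate measurements
#'
#' @param v_max,km maximum rate and Michaelis constant (mM).
#' @param substrate_mM substrate concentrations assayed.
#' @param n_replicates replicates per concentration series.
#' @param cv relative Gaussian noise on rates (0 = noise-free).
#' @param temperature_C assay temperature recorded in the output.
#' @param seed integer seed or NULL.
#' @return data.frame: `replicate`, `substrate_mM`, `rate`, `temperature_C`.
#' @export
simulate_mm_rates <- function(v_max, km,
                              substrate_mM = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                              n_replicates = 5L, cv = 0.05,
                              temperature_C = 25, seed = NULL) {
  check_pos(v_max, "v_max"); check_pos(km, "km")
  check_pos(cv, "cv", strict = FALSE)
  check_seed(seed)
  d <- expand.grid(replicate = paste0("r", seq_len(n_replicates)),
                   substrate_mM = substrate_mM, stringsAsFactors = FALSE)
  v <- v_max * d$substrate_mM / (km + d$substrate_mM)
  d$rate <- v * (1 + stats::rnorm(nrow(d), 0, cv))
  d$temperature_C <- temperature_C
  d[order(d$replicate, d$substrate_mM), , drop = FALSE]
}

#' Simulate first-order activity-recovery time courses
#'
#' Activity of inhibitor-bound enzyme recovering as the inhibitor is slowly
#' released: `v(t) = v_final * (1 - exp(-k_obs * t))`.
#'
#' @param k_obs first-order recovery rate constant (min^-1).
#' @param v_final plateau activity.
#' @param time_min sampling times (min).
#' @param n_replicates number of replicate courses.
#' @param cv relative Gaussian noise (applied to `v_final` scale).
#' @param seed integer seed or NULL.
#' @return data.frame: `replicate`, `time_min`, `activity`.
#' @export
simulate_recovery <- function(k_obs, v_final = 1,
                              time_min = seq(0.5, 10, by = 0.5),
                              n_replicates = 5L, cv = 0.05, seed = NULL) {
  check_pos(k_obs, "k_obs"); check_pos(v_final, "v_final")
  check_pos(cv, "cv", strict = FALSE)
  check_seed(seed)
  d <- expand.grid(replicate = paste0("r", seq_len(n_replicates)),
                   time_min = time_min, stringsAsFactors = FALSE)
  mu <- v_final * (1 - exp(-k_obs * d$time_min))
  d$activity <- mu + stats::rnorm(nrow(d), 0, cv * v_final)
  d[order(d$replicate, d$time_min), , drop = FALSE]
}

#' Simulate a thermal melt curve (Boltzmann sigmoid)
#'
#' `signal(T) = base + (top - base) / (1 + exp((tm_C - T) / slope_C))`,
#' the two-state unfolding readout of a thermal shift assay.
#'
#' @param tm_C melting temperature (deg C).
#' @param slope_C transition width parameter (deg C).
#' @param base,top pre- and post-transition signal levels.
#' @param temperature_C temperatures sampled.
#' @param sd additive Gaussian noise SD on the signal.
#' @param seed integer seed or NULL.
#' @return data.frame: `temperature_C`, `signal`.
#' @export
simulate_melt <- function(tm_C, slope_C = 2, base = 0, top = 1,
                          temperature_C = seq(25, 85, by = 1),
                          sd = 0, seed = NULL) {
  check_pos(tm_C, "tm_C"); check_pos(slope_C, "slope_C")
  check_pos(sd, "sd", strict = FALSE)
  check_seed(seed)
  mu <- base + (top - base) / (1 + exp((tm_C - temperature_C) / slope_C))
  data.frame(temperature_C = temperature_C,
             signal = mu + stats::rnorm(length(temperature_C), 0, sd))
}

#' Simulate a full kinetic fixture set
#'
#' Convenience wrapper bundling [simulate_mm_rates()] at two temperatures,
#' [simulate_recovery()] and [simulate_melt()] with one seed, mirroring a
#' complete kinetic characterisation of one Rubisco variant.
#'
#' @param v_max_25,v_max_35 maximum carboxylation rates at 25 and 35 deg C.
#' @param km Michaelis constant for RuBP (mM).
#' @param k_obs recovery rate constant (min^-1).
#' @param tm_C melting temperature (deg C).
#' @param n_replicates replicates for the rate and recovery designs.
#' @param cv relative noise level.
#' @param seed integer seed or NULL.
#' @return list with elements `rates` (both temperatures), `recovery`,
#'   `melt`, and `params` echoing the generating values.
#' @export
simulate_kinetic_data <- function(v_max_25 = 2, v_max_35 = 4, km = 0.5,
                                  k_obs = 0.3, tm_C = 55,
                                  n_replicates = 5L, cv = 0.05, seed = NULL) {
  check_seed(seed)
  rates <- rbind(
    simulate_mm_rates(v_max_25, km, n_replicates = n_replicates, cv = cv,
                      temperature_C = 25),
    simulate_mm_rates(v_max_35, km, n_replicates = n_replicates, cv = cv,
                      temperature_C = 35)
  )
  recovery <- simulate_recovery(k_obs, n_replicates = n_replicates, cv = cv)
  melt <- simulate_melt(tm_C, sd = cv * 0.2)
  list(rates = rates, recovery = recovery, melt = melt,
       params = list(v_max_25 = v_max_25, v_max_35 = v_max_35, km = km,
                     k_obs = k_obs, tm_C = tm_C))
}
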