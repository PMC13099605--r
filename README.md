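# ssuhet

Quantifying small-subunit (SSu) heterogeneity in L8S8 Form I Rubisco from
tandem affinity-purification experiments, with the downstream mass-spectrometry,
kinetic and stability analyses that characterise the resulting holoenzymes.

Rubisco carries eight small subunits, and plants express several SSu
isoforms at once. When a His-tagged and a Strep-tagged SSu are co-expressed,
holoenzymes incorporating both survive consecutive His-then-Strep affinity
capture — but imperfect column efficiency means the surviving fraction
understates the truth. This package is for researchers running or reanalysing
such experiments: it implements the assembly model, the corrected estimator,
its simulation-based validation, and the companion analyses.

## What it computes

**Assembly model.** With His-skew *p* (the probability a site is filled by
the His-tagged species) and independent sites, the His-tag count *k* per
holoenzyme is Binomial(8, *p*); the heterogeneous fraction is
1 − *p*⁸ − (1 − *p*)⁸ (= 127/128 at *p* = 0.5, leaving ≤ 0.8% homogeneous).
A sequential-preference extension multiplies the odds of repeating the
previous species by α and is invertible from a measured heterogeneity
(`fit_preference_alpha`).

**Corrected heterogeneity estimator.** Column efficiencies from stage
ratios (ê_His = anti-His post-His / soluble; ê_Strep = anti-Strep
post-Strep / post-His), dual-tagged amount back-projected as
anti-Strep(post-Strep)/(ê_His·ê_Strep), total by inclusion–exclusion;
measured heterogeneity and His-skew per replicate, then summarised
(`fit_heterogeneity`). A simulation study (`run_validation_study`) shows
the estimator is unbiased under constant capture efficiency and
systematically underestimates when capture scales with tag count.

**Native-MS stoichiometry.** A nine-rung mass ladder between the all-light
and all-heavy holoenzyme masses (empirically anchored or theoretical);
nearest-rung assignment with residual reporting (`build_ladder`,
`assign_peaks`).

**Kinetics and stability.** Per-replicate Michaelis–Menten fits
(V_Cmax, K_m), two-point Arrhenius activation energy, slow-binding
inhibitor-release recovery (k_obs), Boltzmann melt with two-state van't
Hoff energetics (T_m, ΔG°_unfolding). Group statistics: one-sample t test,
one-way ANOVA + Tukey HSD with a compact letter display.

Simulators for every input (`simulate_assembly`, `simulate_purification`,
`simulate_ms_peaks`, `simulate_kinetic_data`) make the whole pipeline
testable without laboratory data.

## Worked example

Simulate six replicates of a tandem-purification experiment in which
assembly actually *prefers* homogeneity (α = 4), then quantify:

```r
library(ssuhet)
set.seed(11)
records <- do.call(rbind, lapply(1:6, function(r) {
  pool <- simulate_assembly(skew_p = 0.5, alpha = 4, n_holoenzymes = 50000)
  simulate_purification(pool, e_his = 0.8, e_strep = 0.9,
                        densitometry_cv = 0.02,
                        replicate_id = paste0("r", r))
}))
fit <- fit_heterogeneity(records)
fit
#> Tandem-purification heterogeneity fit (n = 6 replicates)
#>   His-skew:               0.5 +/- 0.009
#>   measured heterogeneity: 0.801 +/- 0.044
#>   predicted (binomial):   0.992
#>   predicted > measured (paired t, p = 0.00013)
```

The His-skew is even (0.50), so the independent-sites model predicts 99.2%
heterogeneity; the corrected measurement recovers ~0.80 — the estimator sees
through the lossy columns (true efficiencies 0.8/0.9 are re-estimated from
the stage ratios) and the paired test flags the shortfall against the
binomial prediction. Inverting the preference model recovers the simulated
departure from independence:

```r
fit_preference_alpha(fit$measured$mean, fit$skew$p_hat)$alpha
#> [1] 3.85737
```

Assigning the deconvoluted native masses of a GB1-shifted heterogeneous
sample to the ladder anchored on its homogeneous endpoints:

```r
ladder <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
assign_peaks(data.frame(mass_kDa = c(561.63, 586.39, 575.16, 581.91)), ladder)
#> Native-MS stoichiometry assignment: 4 peak(s), 4 distinct stoichiometries
#>  mass_kDa rel_intensity k ratio theoretical_kDa residual_kDa within_tolerance
#>    561.63            NA 2   6:2          561.58        0.048             TRUE
#>    586.39            NA 6   2:6          588.59       -2.198            FALSE
#>    575.16            NA 4   4:4          575.08        0.075             TRUE
#>    581.91            NA 5   3:5          581.84        0.074             TRUE
#> tolerance: 1.688 kDa
```

Four distinct SSu stoichiometries; one peak sits between rungs and is
flagged by its residual rather than silently forced.

See `vignettes/ssu-heterogeneity.Rmd` for the models, assumptions, and
design decisions.

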