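---
title: "Quantifying small-subunit heterogeneity in L8S8 Rubisco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying small-subunit heterogeneity in L8S8 Rubisco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssuhet)
```

## The problem

Form I Rubisco is an L8S8 hexadecamer: eight large subunits and eight small
subunits (SSus). Plants carry several *rbcS* genes, so the SSu pool is a
mixture of isoforms, and a single holoenzyme can in principle carry more
than one isoform — an *SSu-heterogeneous* holoenzyme. Tandem affinity
purification makes this measurable: co-express a His-tagged and a
Strep-tagged SSu, capture on a His column and then a Strep column, and only
holoenzymes carrying both tags survive both steps. Two practical
complications drive everything in this package:

1. columns are not perfectly efficient, so some dual-tagged Rubisco is lost
   and the surviving fraction underestimates heterogeneity unless
   corrected; and
2. the expected amount of heterogeneity depends on how evenly the two SSus
   incorporate, which must itself be estimated from the data (the
   *His-skew*).

## The assembly model

Let $p$ be the His-skew: the probability that any one of the $n = 8$ SSu
sites is filled by the His-tagged species. If sites fill independently, the
number $k$ of His-tagged SSus per holoenzyme is binomial,

$$\Pr(k) = \binom{8}{k} p^k (1-p)^{8-k},$$

and the heterogeneous fraction is $1 - p^8 - (1-p)^8$. At even
incorporation ($p = 0.5$) this is $127/128 \approx 0.992$; the homogeneous
remainder is $1/128 \approx 0.78\%$ — the model predicts that essentially
all Rubisco should be heterogeneous when both SSus incorporate evenly.

```{r}
predicted_heterogeneity(0.5)
100 * homogeneous_fraction(0.5)
```

Measured heterogeneity falling short of this prediction suggests SSu
binding events are not independent. To make that idea quantitative the
package includes a one-parameter departure from independence: sites fill
sequentially and the *odds* of repeating the species that filled the
previous site are multiplied by $\alpha$ ($\alpha = 1$ recovers the
binomial; $\alpha > 1$ favours homogeneity). The pmf is computed exactly by
forward recursion over (site, count, last species) — equivalent to summing
all $2^8$ fill orders — and `fit_preference_alpha()` inverts the model by
monotone root finding on $\log \alpha$ (tolerance $10^{-8}$, default
bracket $[10^{-3}, 10^3]$). This chain is deliberately the simplest
consistent parameterisation: "previous species" means the immediately
preceding fill, and the first site fills with probability $p$. It is an
interpretive extension, not a mechanism claim. Targets outside the
attainable range return an explicit no-solution result rather than a
clamped $\alpha$.

```{r}
stoichiometry_pmf(0.5, alpha = 4)
fit_preference_alpha(measured_het = 0.65, p = 0.5)$alpha
```

## The corrected heterogeneity estimator

The experiment tracks band intensity at three stages (soluble input, after
the His column, after the Strep column) with two antibodies (anti-His,
anti-Strep). Column efficiencies are estimated per replicate from stage
ratios,

$$\hat e_\mathrm{His} = \frac{I_\mathrm{aHis}(\mathrm{post His})}{I_\mathrm{aHis}(\mathrm{soluble})},
\qquad
\hat e_\mathrm{Strep} = \frac{I_\mathrm{aStrep}(\mathrm{post Strep})}{I_\mathrm{aStrep}(\mathrm{post His})},$$

each a survival fraction of signal the column should retain entirely.
Ratios above 1 (possible under noise) are capped at 1 with a warning. The
dual-tagged amount is back-projected to the input scale,
$\hat a_\mathrm{het} = I_\mathrm{aStrep}(\mathrm{post Strep}) / (\hat e_\mathrm{His}\,\hat e_\mathrm{Strep})$,
and the total initial amount uses inclusion–exclusion,
$\hat a_\mathrm{tot} = a_\mathrm{His} + a_\mathrm{Strep} - \hat a_\mathrm{het}$,
exact when every holoenzyme carries at least one tag (true for dual-tagged
constructs). Measured heterogeneity is $\hat a_\mathrm{het} / \hat a_\mathrm{tot}$
per replicate, summarised as mean ± SD; estimation is always
replicate-first, then summarised.

**Two estimands, two signal models.** A subtlety worth stating plainly:
what a band intensity is proportional to decides which estimator is
unbiased for what.

- If intensity counts *holoenzymes* containing at least one matching tag
  (a native-PAGE band), the corrected heterogeneity estimator recovers the
  true heterogeneous holoenzyme fraction exactly in the noise-free limit.
- If intensity counts *epitopes* (signal proportional to tag count), the
  His-skew $\hat p = a_\mathrm{His} / (a_\mathrm{His} + a_\mathrm{Strep})$
  recovers the per-site incorporation probability $p$ exactly — each SSu
  contributes one unit of signal once, so no inclusion–exclusion is
  applied in the skew denominator.

The simulator implements both (`signal_mode`), the default being
`per_holoenzyme`; the package computes both quantities from the same
records, and the validation study quantifies what happens when the
assumptions are violated.

## Validation by simulation

`run_validation_study()` re-creates the simulation logic used to validate
the correction: simulate holoenzyme pools, push them through tandem capture
under a known efficiency model, add multiplicative lognormal densitometry
noise, and compare estimate with truth.

```{r, eval = FALSE}
run_validation_study(skews = c(0.4, 0.5, 0.6), noise_cvs = 0,
                     n_holoenzymes = 1e5, seed = 1)
```

Two regimes matter:

- **Constant efficiency** (a holoenzyme with any matching tag is captured
  with fixed probability): the estimator is unbiased; noise-free bias is
  zero to floating-point precision, and |bias| < 0.01 at the experimental
  design size (10^5 holoenzymes, 6 replicates).
- **Tag-count-dependent efficiency** (retention $1 - (1-q)^m$ for $m$
  matching tags): the estimator *underestimates* in every cell. The stage
  ratio $\hat e$ is dominated by tag-rich holoenzymes, which are captured
  more efficiently than the tag-poor heterogeneous ones the correction is
  meant to rescue, so the back-projection under-corrects.

The systematic per-tag bias is small at near-even skews (order 0.1–1% when
truth is near 99%), so resolving its *sign* requires the noise-free,
large-pool design; with realistic densitometry noise (CV 5–10%) on single
band intensities, cell-level sampling error dwarfs it. The default study
grid includes noisy cells for coverage of estimator variance, while the
directional bias checks run noise-free.

**What the generator does and does not emulate.** It reproduces the
statistical structure the estimators assume: binomial or
preference-chain assembly, per-column capture (deterministic expected-count
thinning by default, so conservation identities hold exactly; Bernoulli
draws optionally), positive multiplicative band noise, Gaussian mass error
and detection floors for MS peaks, and noise-free-identifiable kinetic
curves. It does not emulate gel images, antibody saturation or
non-linearity of densitometry, incomplete tag accessibility, untagged
endogenous SSus (the in-planta three-species case is out of scope), or
charge-state effects in MS. Passing tests therefore demonstrate estimator
correctness under the stated model, not robustness to every laboratory
artifact.

## Native-MS stoichiometry assignment

With one SSu enlarged by a GB1 fusion (15.62 → 22.48 kDa per subunit),
each substitution shifts the holoenzyme mass by a fixed step, and the nine
possible stoichiometries form a mass ladder. `build_ladder()` supports an
*empirical* mode anchored on the measured masses of the two homogeneous
holoenzymes (preferred: native masses carry adducts that sequence masses
miss) and a *theoretical* mode from per-subunit masses plus a core mass.
The two modes disagree by ~0.11 kDa per step for the masses above, which
is why both exist.

`assign_peaks()` assigns each deconvoluted peak to the nearest rung, ties
broken toward lower substitution count with a warning, and reports the
residual against a tolerance (default step/4). Residual reporting is a
design decision: a peak that falls between rungs is flagged, never silently
forced to a stoichiometry. Assignment is provably unambiguous whenever mass
error stays below half a step; the test suite checks exactness for
simulated error SD below step/6.

```{r}
ladder <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
assign_peaks(data.frame(mass_kDa = c(561.63, 586.39, 575.16, 581.91)),
             ladder)
```

## Kinetic and stability fits

All nonlinear fits use Levenberg–Marquardt least squares with positivity
box constraints; temperatures are converted to kelvin internally.

- **Michaelis–Menten** (`fit_michaelis_menten()`): $v = V S / (K + S)$
  fitted per replicate (starting values from a Hanes–Woolf linearisation),
  then summarised — matching the per-replicate protocol of rate assays with
  $n = 5$ replicates over six substrate concentrations. Non-converged
  replicates are flagged and excluded from the summary with a warning.
- **Activation energy** (`activation_energy()`): two-point Arrhenius,
  $E_a = R \ln(v_2/v_1) / (1/T_1 - 1/T_2)$, applied to replicate-paired
  $V_{C\max}$ values by default (means are also accepted — both orderings
  are supported since published protocols differ).
- **Activity recovery** (`fit_recovery()`): release of a slow-binding
  inhibitor. Both standard forms are implemented —
  $v(t) = v_f (1 - e^{-k_{obs} t})$ (default, for instantaneous-rate
  readouts over a ~10 min course) and the integrated product form
  $P(t) = v_s t - (v_s/k_{obs})(1 - e^{-k_{obs} t})$ — selectable because
  the underlying rate law is standard but the reported observable varies.
  A flat trace leaves $k_{obs}$ unidentifiable and is flagged, not fitted.
- **Thermal melts** (`fit_melt()`): Boltzmann sigmoid for $T_m$ and
  width, then a two-state van't Hoff analysis:
  $\Delta H_{vH} = R T_m^2 / s$ with $s$ the fitted width, and
  $\Delta G(T) = \Delta H (1 - T/T_m) + \Delta C_p (T - T_m - T\ln(T/T_m))$
  extrapolated to a reference temperature (default 25 °C,
  $\Delta C_p = 0$ unless configured). This is a standard reconstruction of
  a melt-to-energetics protocol; with $\Delta C_p = 0$ the extrapolation is
  constant-enthalpy, and $\Delta G(T_m) = 0$ by construction. A transition
  amplitude under five residual SDs is reported as "no transition".

```{r}
fit <- fit_michaelis_menten(simulate_mm_rates(2, 0.5, cv = 0, seed = 1))
coef(fit)
activation_energy(1, 2, 25, 35)   # rate doubling over 10 K
```

## Group statistics

`one_sample_t()` (two-sided, e.g. His-skew against 0.5) and
`anova_tukey_cld()` — classical equal-variance one-way ANOVA, Tukey HSD on
the studentized range, and a compact letter display built by
insert-and-absorb so that two groups share a letter iff their adjusted
difference is not significant. Letters are assigned in descending order of
group mean (the conventional choice). Group labels may not contain `-`,
which delimits pairwise comparison names.

## Numerical choices and limitations

- Problem sizes: validation and round-trip tests use pools of $10^4$–$10^5$
  holoenzymes and 5–6 replicates, the scale at which the experimental
  design operates and at which the directional bias is resolvable.
- The efficiency correction reconstructs a stage-ratio protocol from the
  tracked-intensity description; the exact published formula lives in
  supplementary material not reproduced here. All formula choices are
  isolated in `estimate_efficiencies()` / `correct_amounts()`.
- Cross-antibody calibration defaults to 1 (both signals normalised to a
  shared standard); it is exposed as `calibration` because blot gains are
  instrument-specific.
- The preference chain is one of many possible non-independence models; a
  fitted $\alpha$ summarises the deviation, it does not identify a
  mechanism. Spatial arrangement of SSus on the holoenzyme is out of scope.
- Lognormal noise is used for densitometry (positive, multiplicative);
  detection floors for MS peaks are relative-abundance thresholds on
  deconvoluted neutral masses — raw spectra are never simulated.
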