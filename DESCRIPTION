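Package: ssuhet
Title: Small-Subunit Heterogeneity in L8S8 Rubisco
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies small-subunit (SSu) heterogeneity in hexadecameric
    (L8S8) Form I Rubisco from tandem affinity-purification experiments.
    Implements the binomial (and sequential-preference) model of SSu
    incorporation at a given His-skew, a column-efficiency-corrected
    estimator of the heterogeneous fraction from stage-tracked western-blot
    intensities, assignment of deconvoluted native mass-spectrometry peaks
    to SSu stoichiometries via a theoretical or empirically anchored mass
    ladder, and the downstream kinetic and stability fits
    (Michaelis-Menten, two-point Arrhenius activation energy, slow-binding
    inhibitor-release recovery, and two-state thermal melt analysis),
    together with the group-comparison statistics (one-sample t test,
    one-way ANOVA with Tukey HSD and compact letter display) and a
    simulation framework for validating the estimators.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
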