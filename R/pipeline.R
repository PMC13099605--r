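# End-to-end orchestration: the estimator-validation simulation study and
# the consolidated analysis workflow over the module CSV dialects.

read_input <- function(x) {
  if (is.character(x) && length(x) == 1L) utils::read.csv(x) else x
}

#' Validation study of the heterogeneity estimator
#'
#' Re-creates the simulation used to validate the column-efficiency
#' correction: over a grid of His-skews, efficiency models (constant versus
#' tag-count-dependent) and densitometry noise levels, pools of holoenzymes
#' are simulated, pushed through tandem purification, quantified with
#' [fit_heterogeneity()], and the bias of measured against true
#' heterogeneity is tabulated. Constant-efficiency cells are expected to be
#' (near-)unbiased; tag-count-dependent cells underestimate, because the
#' single per-column efficiency ratio is dominated by holoenzymes rich in
#' matching tags while heterogeneous holoenzymes carry fewer.
#'
#' @param skews His-skew values simulated.
#' @param efficiency_modes subset of `c("constant", "per_tag")`.
#' @param noise_cvs densitometry coefficients of variation.
#' @param n_holoenzymes pool size per replicate.
#' @param n_replicates replicates per cell.
#' @param e_his,e_strep constant-mode efficiencies.
#' @param q per-tag capture probability.
#' @param seed integer seed.
#' @return Object of class `"validation_study"`: data.frame with one row
#'   per grid cell (`skew`, `efficiency_mode`, `noise_cv`, `truth`,
#'   `estimate`, `bias`, `sd`, `n_replicates`).
#' @export
run_validation_study <- function(skews = c(0.4, 0.5, 0.6),
                                 efficiency_modes = c("constant", "per_tag"),
                                 noise_cvs = c(0, 0.05, 0.1),
                                 n_holoenzymes = 20000L, n_replicates = 6L,
                                 e_his = 0.8, e_strep = 0.9, q = 0.3,
                                 seed = NULL) {
  check_seed(seed)
  grid <- expand.grid(skew = skews, efficiency_mode = efficiency_modes,
                      noise_cv = noise_cvs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    recs <- list(); truths <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      pool <- simulate_assembly(g$skew, n_holoenzymes = n_holoenzymes)
      rec <- simulate_purification(
        pool, e_his = e_his, e_strep = e_strep,
        efficiency_mode = g$efficiency_mode, q = q,
        densitometry_cv = g$noise_cv, replicate_id = paste0("r", r))
      truths[r] <- attr(rec, "truth")$heterogeneous_fraction
      recs[[r]] <- rec
    }
    fit <- fit_heterogeneity(do.call(rbind, recs))
    est <- fit$measured$mean
    data.frame(g, truth = mean(truths), estimate = est,
               bias = est - mean(truths), sd = fit$measured$sd,
               n_replicates = n_replicates)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("validation_study", "data.frame")
  out
}

#' @export
print.validation_study <- function(x, digits = 4, ...) {
  cat("Heterogeneity-estimator validation study\n")
  df <- as.data.frame(x)
  for (cn in c("truth", "estimate", "bias", "sd"))
    df[[cn]] <- round(df[[cn]], digits)
  print(df, row.names = FALSE)
  neg <- df$bias[df$efficiency_mode == "per_tag"]
  if (length(neg))
    cat("per_tag cells underestimating: ", sum(neg < 0), "/", length(neg),
        "\n", sep = "")
  invisible(x)
}

#' Run the consolidated analysis workflow
#'
#' Runs every analysis stage for which an input is supplied — tandem
#' purification quantification, native/denatured-MS stoichiometry, kinetic
#' and stability fits, and group statistics — and returns one consolidated
#' report. Missing inputs skip their stage with a message rather than
#' failing. Inputs may be data.frames or paths to CSVs in the module
#' dialects (see the individual functions for the column layouts).
#'
#' @param purification purification records (`replicate`, `stage`,
#'   `antibody`, `intensity`).
#' @param native_peaks native-MS peak list (`mass_kDa`, `rel_intensity`).
#' @param denatured_peaks denatured-MS peak list (`mass_kDa`).
#' @param ladder a `"mass_ladder"`, or NULL to skip assignment.
#' @param expected_subunit_masses_kDa named vector for
#'   [verify_subunit_presence()].
#' @param mm_rates rate table (`replicate`, `substrate_mM`, `rate`,
#'   optionally `temperature_C`; fitted per temperature).
#' @param recovery recovery table (`replicate`, `time_min`, `activity`).
#' @param melt melt curve (`temperature_C`, `signal`).
#' @param group_values,group_labels observations and labels for
#'   [anova_tukey_cld()].
#' @param calibration antibody gain ratio for the purification stage.
#' @param out_dir if non-NULL, per-stage CSVs and a Markdown summary
#'   (`report.md`) are written there.
#' @return Object of class `"workflow_report"`: list of per-stage results
#'   (`heterogeneity`, `stoichiometry`, `subunit_presence`, `mm`,
#'   `arrhenius`, `recovery`, `melt`, `stats`), NULL where skipped.
#' @export
run_paper_workflow <- function(purification = NULL, native_peaks = NULL,
                               denatured_peaks = NULL, ladder = NULL,
                               expected_subunit_masses_kDa = NULL,
                               mm_rates = NULL, recovery = NULL, melt = NULL,
                               group_values = NULL, group_labels = NULL,
                               calibration = 1, out_dir = NULL) {
  report <- list()
  skip <- function(stage)
    message("stage '", stage, "': input missing, skipped")

  if (!is.null(purification)) {
    report$heterogeneity <-
      fit_heterogeneity(read_input(purification), calibration = calibration)
  } else skip("heterogeneity")

  if (!is.null(native_peaks) && !is.null(ladder)) {
    report$stoichiometry <- assign_peaks(read_input(native_peaks), ladder)
  } else skip("stoichiometry")

  if (!is.null(denatured_peaks) && !is.null(expected_subunit_masses_kDa)) {
    report$subunit_presence <- verify_subunit_presence(
      read_input(denatured_peaks), expected_subunit_masses_kDa)
  } else skip("subunit_presence")

  if (!is.null(mm_rates)) {
    rates <- read_input(mm_rates)
    if (!"temperature_C" %in% names(rates)) rates$temperature_C <- NA_real_
    fits <- lapply(split(rates, rates$temperature_C),
                   fit_michaelis_menten)
    report$mm <- fits
    if (length(fits) == 2L) {
      t12 <- as.numeric(names(fits))
      # pair per-replicate V_Cmax values across the two temperatures
      f1 <- fits[[1L]]$fits; f2 <- fits[[2L]]$fits
      common <- intersect(f1$replicate[f1$converged],
                          f2$replicate[f2$converged])
      ea <- activation_energy(
        f1$v_cmax[match(common, f1$replicate)],
        f2$v_cmax[match(common, f2$replicate)], t12[1L], t12[2L])
      report$arrhenius <- list(per_replicate = stats::setNames(ea, common),
                               mean = mean(ea), sd = stats::sd(ea),
                               t1_C = t12[1L], t2_C = t12[2L])
    }
  } else skip("mm")

  if (!is.null(recovery)) {
    report$recovery <- fit_recovery(read_input(recovery))
  } else skip("recovery")

  if (!is.null(melt)) {
    report$melt <- fit_melt(read_input(melt))
  } else skip("melt")

  if (!is.null(group_values) && !is.null(group_labels)) {
    report$stats <- anova_tukey_cld(group_values, group_labels)
  } else skip("stats")

  class(report) <- "workflow_report"
  if (!is.null(out_dir)) write_workflow_report(report, out_dir)
  report
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("Consolidated analysis report\n")
  cat("  stages run: ", paste(names(x), collapse = ", "), "\n\n", sep = "")
  for (nm in names(x)) {
    cat("== ", nm, " ==\n", sep = "")
    obj <- x[[nm]]
    if (nm == "arrhenius") {
      cat("E_a: ", format(round(obj$mean, 2)), " +/- ",
          format(round(obj$sd, 2)), " kJ/mol (",
          obj$t1_C, " -> ", obj$t2_C, " degC)\n", sep = "")
    } else if (nm == "mm") {
      for (tn in names(obj)) { cat("at ", tn, " degC:\n", sep = ""); print(obj[[tn]]) }
    } else print(obj)
    cat("\n")
  }
  invisible(x)
}

write_workflow_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Consolidated analysis report", "")
  if (!is.null(report$heterogeneity)) {
    h <- report$heterogeneity
    utils::write.csv(h$corrected,
                     file.path(out_dir, "corrected_amounts.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## Heterogeneity", "",
               paste0("- His-skew: ", round(h$skew$p_hat, 4), " +/- ",
                      round(h$skew$sd, 4)),
               paste0("- measured heterogeneity: ",
                      round(h$measured$mean, 4), " +/- ",
                      round(h$measured$sd, 4)),
               paste0("- predicted heterogeneity: ",
                      round(mean(h$comparison$predicted), 4)),
               paste0("- ", h$comparison$direction), "")
  }
  if (!is.null(report$stoichiometry)) {
    utils::write.csv(as.data.frame(report$stoichiometry),
                     file.path(out_dir, "stoichiometry_assignments.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## Native-MS stoichiometry", "",
               paste0("- distinct stoichiometries: ",
                      attr(report$stoichiometry, "n_distinct")), "")
  }
  if (!is.null(report$mm)) {
    mm <- do.call(rbind, lapply(names(report$mm), function(tn)
      data.frame(temperature_C = tn, report$mm[[tn]]$fits)))
    utils::write.csv(mm, file.path(out_dir, "mm_fits.csv"),
                     row.names = FALSE)
    lines <- c(lines, "## Michaelis-Menten", "",
               vapply(names(report$mm), function(tn)
                 paste0("- ", tn, " degC: V_Cmax = ",
                        round(report$mm[[tn]]$v_cmax, 4), ", K_m = ",
                        round(report$mm[[tn]]$km_rubp, 4), " mM"),
                 character(1)), "")
  }
  if (!is.null(report$arrhenius))
    lines <- c(lines, paste0("- E_a: ", round(report$arrhenius$mean, 2),
                             " kJ/mol"), "")
  if (!is.null(report$recovery))
    lines <- c(lines, "## Recovery", "",
               paste0("- k_obs: ", round(report$recovery$k_obs, 4),
                      " min^-1"), "")
  if (!is.null(report$melt))
    lines <- c(lines, "## Melt", "",
               paste0("- Tm: ", round(report$melt$tm_C, 2), " degC; ",
                      "dG_unfold(", report$melt$ref_temp_C, " degC) = ",
                      round(report$melt$dG_unfold, 2), " kJ/mol"), "")
  if (!is.null(report$stats)) {
    utils::write.csv(report$stats$tukey,
                     file.path(out_dir, "tukey.csv"), row.names = FALSE)
    lines <- c(lines, "## Group comparison", "",
               paste0("- ", names(report$stats$letters), ": ",
                      report$stats$letters), "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
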