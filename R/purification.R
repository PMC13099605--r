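# Column-efficiency-corrected quantification of SSu heterogeneity from
# stage-tracked western-blot intensities.
#
# Record layout (one row per replicate x stage x antibody):
#   replicate, stage in {soluble, post_his, post_strep},
#   antibody in {anti_his, anti_strep}, intensity >= 0.

.STAGES <- c("soluble", "post_his", "post_strep")
.ANTIBODIES <- c("anti_his", "anti_strep")

validate_purification_records <- function(records) {
  need <- c("replicate", "stage", "antibody", "intensity")
  if (!all(need %in% names(records)))
    stop("purification records need columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  records <- records[records$stage %in% .STAGES &
                       records$antibody %in% .ANTIBODIES, , drop = FALSE]
  if (any(records$intensity < 0, na.rm = TRUE))
    stop("intensities must be nonnegative", call. = FALSE)
  key <- interaction(records$replicate, records$stage, records$antibody)
  if (anyDuplicated(key))
    stop("duplicate (replicate, stage, antibody) rows", call. = FALSE)
  records
}

# intensity for one replicate at (stage, antibody); NA if absent
get_intensity <- function(rec, stage, antibody) {
  i <- rec$stage == stage & rec$antibody == antibody
  if (!any(i)) NA_real_ else rec$intensity[i][1L]
}

#' Estimate His- and Strep-column capture efficiencies per replicate
#'
#' The His-column efficiency is the fraction of His-tagged signal surviving
#' the His column, `anti_his(post_his) / anti_his(soluble)`; the
#' Strep-column efficiency is `anti_strep(post_strep) / anti_strep(post_his)`
#' (the Strep column acts on the His-column survivors). Ratios above 1 —
#' possible under densitometry noise — are capped at 1 with a warning when
#' `cap = TRUE`. Replicates with a zero or missing denominator are excluded
#' and listed in the `excluded` attribute.
#'
#' @param records purification record data.frame (see
#'   [simulate_purification()] for the layout).
#' @param cap logical; cap ratios above 1 at 1.
#' @return data.frame with columns `replicate`, `e_his`, `e_strep`,
#'   `capped_his`, `capped_strep`; attribute `excluded` is a character
#'   vector of replicate ids dropped, with reasons as names.
#' @export
estimate_efficiencies <- function(records, cap = TRUE) {
  records <- validate_purification_records(records)
  reps <- unique(records$replicate)
  rows <- list(); excluded <- character(0)
  for (r in reps) {
    rec <- records[records$replicate == r, , drop = FALSE]
    his_sol <- get_intensity(rec, "soluble", "anti_his")
    his_post <- get_intensity(rec, "post_his", "anti_his")
    strep_post_his <- get_intensity(rec, "post_his", "anti_strep")
    strep_post_strep <- get_intensity(rec, "post_strep", "anti_strep")
    bad <- c(
      if (is.na(his_sol) || his_sol == 0) "anti_his soluble zero or missing",
      if (is.na(his_post)) "anti_his post_his missing",
      if (is.na(strep_post_his) || strep_post_his == 0)
        "anti_strep post_his zero or missing",
      if (is.na(strep_post_strep)) "anti_strep post_strep missing"
    )
    if (length(bad)) {
      excluded <- c(excluded, stats::setNames(as.character(r),
                                              paste(bad, collapse = "; ")))
      next
    }
    e_his <- his_post / his_sol
    e_strep <- strep_post_strep / strep_post_his
    capped_his <- capped_strep <- FALSE
    if (cap && e_his > 1) { e_his <- 1; capped_his <- TRUE }
    if (cap && e_strep > 1) { e_strep <- 1; capped_strep <- TRUE }
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = r, e_his = e_his, e_strep = e_strep,
      capped_his = capped_his, capped_strep = capped_strep)
  }
  if (!length(rows))
    stop("no replicate had the stages required to estimate efficiencies",
         call. = FALSE)
  out <- do.call(rbind, rows)
  if (any(out$capped_his | out$capped_strep))
    warning("efficiency ratio(s) > 1 capped at 1 (densitometry noise)",
            call. = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Correct stage intensities for column losses
#'
#' Back-projects the signal surviving tandem His-then-Strep capture to the
#' input scale: the dual-tagged (heterogeneous) amount is
#' `anti_strep(post_strep) / (e_his * e_strep)`, the His-containing initial
#' amount is `anti_his(soluble)` and the Strep-containing initial amount is
#' `anti_strep(soluble)`, all expressed on the anti-His gain scale by
#' dividing anti-Strep intensities by `calibration` (the anti-Strep/anti-His
#' gain ratio, 1 when both blots are normalised to a shared standard). The
#' total initial amount uses inclusion-exclusion,
#' `a_his + a_strep - a_hetero`, exact when every holoenzyme carries at
#' least one tag (true for dual-tagged SSu constructs). A replicate whose
#' dual amount exceeds either single-tag amount (impossible without noise)
#' is retained but flagged.
#'
#' @param records purification record data.frame.
#' @param efficiencies data.frame from [estimate_efficiencies()].
#' @param calibration anti-Strep/anti-His antibody gain ratio.
#' @return data.frame with columns `replicate`, `e_his`, `e_strep`,
#'   `a_his_initial`, `a_strep_initial`, `a_hetero`, `a_total_initial`,
#'   `consistent`.
#' @export
correct_amounts <- function(records, efficiencies = NULL, calibration = 1) {
  records <- validate_purification_records(records)
  if (is.null(efficiencies)) efficiencies <- estimate_efficiencies(records)
  check_pos(calibration, "calibration")
  if (any(efficiencies$e_his <= 0 | efficiencies$e_his > 1) ||
      any(efficiencies$e_strep <= 0 | efficiencies$e_strep > 1))
    stop("efficiencies must be in (0, 1]", call. = FALSE)

  rows <- lapply(seq_len(nrow(efficiencies)), function(i) {
    r <- efficiencies$replicate[i]
    rec <- records[records$replicate == r, , drop = FALSE]
    a_his <- get_intensity(rec, "soluble", "anti_his")
    a_strep <- get_intensity(rec, "soluble", "anti_strep") / calibration
    a_het <- get_intensity(rec, "post_strep", "anti_strep") /
      (efficiencies$e_his[i] * efficiencies$e_strep[i] * calibration)
    data.frame(replicate = r,
               e_his = efficiencies$e_his[i],
               e_strep = efficiencies$e_strep[i],
               a_his_initial = a_his, a_strep_initial = a_strep,
               a_hetero = a_het,
               a_total_initial = a_his + a_strep - a_het,
               consistent = a_het <= min(a_his, a_strep))
  })
  out <- do.call(rbind, rows)
  if (any(!out$consistent))
    warning(sum(!out$consistent),
            " replicate(s) with a_hetero > min(single-tag amounts); ",
            "flagged, retained", call. = FALSE)
  out
}

#' His-skew from corrected amounts
#'
#' The His-skew quantifies the evenness of His- and Strep-tagged SSu
#' incorporation: the His-attributable fraction of the total initial
#' Rubisco signal, `a_his_initial / (a_his_initial + a_strep_initial)`,
#' computed per replicate and averaged. When band intensity is
#' epitope-proportional (signal scales with tag count) each SSu contributes
#' one unit of signal exactly once, the denominator is the total
#' incorporated-SSu signal, and the ratio estimates the per-site
#' incorporation probability `p` of the binomial assembly model.
#'
#' @param corrected data.frame from [correct_amounts()].
#' @return An object of class `"skew_estimate"`: list with `p_hat` (mean),
#'   `per_replicate` (named numeric), `sd`, `n_replicates`.
#' @export
his_skew <- function(corrected) {
  denom <- corrected$a_his_initial + corrected$a_strep_initial
  if (any(denom <= 0))
    stop("zero or negative total initial amount", call. = FALSE)
  per <- stats::setNames(
    pmin(1, pmax(0, corrected$a_his_initial / denom)),
    corrected$replicate)
  structure(list(p_hat = mean(per), per_replicate = per,
                 sd = stats::sd(per), n_replicates = length(per)),
            class = "skew_estimate")
}

#' @export
print.skew_estimate <- function(x, digits = 3, ...) {
  cat("His-skew: ", format(round(x$p_hat, digits)), " +/- ",
      format(round(x$sd, digits)), " (n = ", x$n_replicates, ")\n", sep = "")
  invisible(x)
}

#' Measured heterogeneous fraction from corrected amounts
#'
#' The efficiency-corrected fraction of holoenzymes surviving consecutive
#' His-then-Strep capture, `a_hetero / a_total_initial`, per replicate with
#' a mean +/- SD summary.
#'
#' @param corrected data.frame from [correct_amounts()].
#' @return list with `per_replicate` (named numeric), `mean`, `sd`, `n`.
#' @export
measured_heterogeneity <- function(corrected) {
  if (any(corrected$a_total_initial <= 0))
    stop("zero or negative total initial amount", call. = FALSE)
  per <- stats::setNames(corrected$a_hetero / corrected$a_total_initial,
                         corrected$replicate)
  list(per_replicate = per, mean = mean(per), sd = stats::sd(per),
       n = length(per))
}

#' Compare measured with model-predicted heterogeneity
#'
#' Pairs each replicate's measured heterogeneous fraction with the
#' independent-sites prediction `1 - p^8 - (1 - p)^8` evaluated at that
#' replicate's His-skew, and tests the mean difference with a paired t test.
#' A measured value below prediction is the signature of either
#' tag-count-dependent column losses or non-independent SSu binding.
#'
#' @param skew `"skew_estimate"` from [his_skew()].
#' @param measured list from [measured_heterogeneity()].
#' @param n_sites number of SSu sites.
#' @param alpha significance cutoff for the direction flag.
#' @return list with per-replicate `predicted`, `measured`, `difference`
#'   (predicted - measured), the paired `t` statistic and `p_value`,
#'   `direction` (`"predicted > measured"`, `"predicted < measured"` or
#'   `"no significant difference"`).
#' @export
compare_measured_vs_predicted <- function(skew, measured, n_sites = 8L,
                                          alpha = 0.05) {
  reps <- names(skew$per_replicate)
  if (!setequal(reps, names(measured$per_replicate)))
    stop("replicate sets of skew and measured heterogeneity differ",
         call. = FALSE)
  meas <- measured$per_replicate[reps]
  pred <- predicted_heterogeneity(skew$per_replicate, n_sites = n_sites)
  diff <- pred - meas
  tt <- if (length(diff) >= 2L && stats::sd(diff) > 0)
    tryCatch(stats::t.test(pred, meas, paired = TRUE),
             error = function(e) NULL) else NULL
  p_value <- if (is.null(tt)) NA_real_ else tt$p.value
  direction <- if (!is.na(p_value) && p_value < alpha) {
    if (mean(diff) > 0) "predicted > measured" else "predicted < measured"
  } else "no significant difference"
  list(predicted = stats::setNames(pred, reps), measured = meas,
       difference = stats::setNames(diff, reps),
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p_value = p_value, direction = direction)
}

#' Fit the heterogeneity estimator to a tandem-purification experiment
#'
#' One-call interface to the full quantification: per-replicate column
#' efficiencies ([estimate_efficiencies()]), corrected amounts
#' ([correct_amounts()]), His-skew ([his_skew()]), measured heterogeneity
#' ([measured_heterogeneity()]) and the comparison with the binomial
#' prediction ([compare_measured_vs_predicted()]).
#'
#' @param records purification record data.frame with columns `replicate`,
#'   `stage`, `antibody`, `intensity`.
#' @param calibration anti-Strep/anti-His antibody gain ratio.
#' @param cap_efficiency cap efficiency ratios above 1 at 1.
#' @param n_sites number of SSu sites (8 for L8S8).
#' @return An object of class `"het_fit"` with components `efficiencies`,
#'   `corrected`, `skew`, `measured`, `comparison`, `n_sites`, `call`.
#' @examples
#' pool <- simulate_assembly(0.5, n_holoenzymes = 5000, seed = 1)
#' recs <- simulate_purification(pool, e_his = 0.8, e_strep = 0.9, seed = 2)
#' fit <- fit_heterogeneity(recs)
#' coef(fit)
#' @export
fit_heterogeneity <- function(records, calibration = 1,
                              cap_efficiency = TRUE, n_sites = 8L) {
  eff <- estimate_efficiencies(records, cap = cap_efficiency)
  corrected <- correct_amounts(records, eff, calibration = calibration)
  skew <- his_skew(corrected)
  measured <- measured_heterogeneity(corrected)
  comparison <- compare_measured_vs_predicted(skew, measured,
                                              n_sites = n_sites)
  structure(list(efficiencies = eff, corrected = corrected, skew = skew,
                 measured = measured, comparison = comparison,
                 n_sites = n_sites, call = match.call()),
            class = "het_fit")
}

#' @export
print.het_fit <- function(x, digits = 3, ...) {
  cat("Tandem-purification heterogeneity fit (n = ",
      x$measured$n, " replicates)\n", sep = "")
  cat("  His-skew:               ", format(round(x$skew$p_hat, digits)),
      " +/- ", format(round(x$skew$sd, digits)), "\n", sep = "")
  cat("  measured heterogeneity: ", format(round(x$measured$mean, digits)),
      " +/- ", format(round(x$measured$sd, digits)), "\n", sep = "")
  cat("  predicted (binomial):   ",
      format(round(mean(x$comparison$predicted), digits)), "\n", sep = "")
  cat("  ", x$comparison$direction,
      if (!is.na(x$comparison$p_value))
        paste0(" (paired t, p = ", format.pval(x$comparison$p_value,
                                               digits = 2), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.het_fit <- function(object, ...) {
  s <- list(
    coef = coef(object),
    efficiencies = object$efficiencies,
    per_replicate = data.frame(
      replicate = names(object$measured$per_replicate),
      skew = unname(object$skew$per_replicate),
      measured = unname(object$measured$per_replicate),
      predicted = unname(object$comparison$predicted)),
    comparison = object$comparison)
  class(s) <- "summary.het_fit"
  s
}

#' @export
print.summary.het_fit <- function(x, digits = 3, ...) {
  cat("Per-replicate estimates:\n")
  print(cbind(x$per_replicate[1L],
              round(x$per_replicate[-1L], digits)), row.names = FALSE)
  cat("\nColumn efficiencies:\n")
  print(cbind(x$efficiencies[1L], round(x$efficiencies[2:3], digits)),
        row.names = FALSE)
  cat("\n", x$comparison$direction, "\n", sep = "")
  invisible(x)
}

#' @export
coef.het_fit <- function(object, ...) {
  c(his_skew = object$skew$p_hat,
    measured_heterogeneity = object$measured$mean,
    predicted_heterogeneity = mean(object$comparison$predicted),
    e_his = mean(object$efficiencies$e_his),
    e_strep = mean(object$efficiencies$e_strep))
}

#' @export
plot.het_fit <- function(x, ...) {
  vals <- rbind(measured = x$measured$per_replicate,
                predicted = x$comparison$predicted)
  mids <- graphics::barplot(rowMeans(vals), ylim = c(0, 1),
                            ylab = "heterogeneous fraction",
                            col = c("grey70", "grey35"), ...)
  graphics::points(rep(mids[1L], ncol(vals)), vals[1L, ], pch = 1)
  graphics::points(rep(mids[2L], ncol(vals)), vals[2L, ], pch = 1)
  invisible(x)
}
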