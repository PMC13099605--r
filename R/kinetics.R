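# Kinetic and stability fits: Michaelis-Menten, two-point Arrhenius,
# slow-binding inhibitor-release recovery, and two-state thermal melts.
# All nonlinear fits use Levenberg-Marquardt least squares with box
# constraints (minpack.lm); temperatures are taken in Celsius and
# converted to kelvin internally.

# Hanes-Woolf linearisation S/v = S/V + K/V for starting values
mm_start <- function(s, v) {
  ok <- v > 0 & s > 0
  if (sum(ok) >= 2L) {
    fit <- stats::lm(I(s[ok] / v[ok]) ~ s[ok])
    V0 <- 1 / stats::coef(fit)[2L]
    K0 <- stats::coef(fit)[1L] * V0
    if (is.finite(V0) && is.finite(K0) && V0 > 0 && K0 > 0)
      return(c(v_cmax = unname(V0), km = unname(K0)))
  }
  c(v_cmax = max(v, na.rm = TRUE), km = stats::median(s))
}

#' Fit Michaelis-Menten kinetics per replicate
#'
#' Nonlinear least squares of `v = V * S / (K + S)` fitted independently to
#' each replicate's rate-versus-substrate series, with starting values from
#' a Hanes-Woolf linearisation and positivity enforced by box constraints.
#' Per-replicate parameter estimates are then summarised (mean +/- SD), and
#' the mean-parameter "average model" is the curve reported by
#' [predict.mm_fit()].
#'
#' @param data data.frame with columns `replicate`, `substrate_mM`, `rate`
#'   (and optionally `temperature_C`, ignored here; fit temperatures
#'   separately).
#' @return Object of class `"mm_fit"`: list with `fits` (data.frame of
#'   per-replicate `v_cmax`, `km_rubp`, standard errors, `converged`),
#'   `v_cmax`, `km_rubp` (means over converged fits), `sd` (named),
#'   `n_converged`, `data`, `call`.
#' @examples
#' d <- simulate_mm_rates(2, 0.5, cv = 0, seed = 1)
#' fit <- fit_michaelis_menten(d)
#' coef(fit)
#' @export
fit_michaelis_menten <- function(data) {
  need <- c("replicate", "substrate_mM", "rate")
  if (!all(need %in% names(data)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (all(data$rate == 0)) stop("all rates are zero", call. = FALSE)

  rows <- lapply(split(data, data$replicate), function(d) {
    out <- data.frame(replicate = d$replicate[1L], v_cmax = NA_real_,
                      km_rubp = NA_real_, se_v_cmax = NA_real_,
                      se_km = NA_real_, converged = FALSE)
    if (length(unique(d$substrate_mM)) < 3L) return(out)
    start <- mm_start(d$substrate_mM, d$rate)
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ v_cmax * substrate_mM / (km + substrate_mM),
                        data = d,
                        start = list(v_cmax = start[["v_cmax"]],
                                     km = start[["km"]]),
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) c(NA_real_, NA_real_))
      out$v_cmax <- cf[["v_cmax"]]; out$km_rubp <- cf[["km"]]
      out$se_v_cmax <- se[1L]; out$se_km <- se[2L]
      out$converged <- TRUE
    }
    out
  })
  fits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- fits$converged
  if (!any(ok)) stop("no replicate fit converged", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " replicate fit(s) failed; excluded from summary",
            call. = FALSE)
  structure(list(
    fits = fits,
    v_cmax = mean(fits$v_cmax[ok]), km_rubp = mean(fits$km_rubp[ok]),
    sd = c(v_cmax = stats::sd(fits$v_cmax[ok]),
           km_rubp = stats::sd(fits$km_rubp[ok])),
    n_converged = sum(ok), data = data, call = match.call()),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat("Michaelis-Menten fit (", x$n_converged, " replicate(s))\n", sep = "")
  cat("  V_Cmax:   ", format(round(x$v_cmax, digits)), " +/- ",
      format(round(x$sd[["v_cmax"]], digits)), "\n", sep = "")
  cat("  K_m^RuBP: ", format(round(x$km_rubp, digits)), " +/- ",
      format(round(x$sd[["km_rubp"]], digits)), " mM\n", sep = "")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(v_cmax = object$v_cmax, km_rubp = object$km_rubp)
}

#' @export
summary.mm_fit <- function(object, ...) {
  cat("Per-replicate Michaelis-Menten fits:\n")
  print(object$fits, row.names = FALSE)
  invisible(object$fits)
}

#' Predicted rates from the average Michaelis-Menten model
#'
#' @param object an `"mm_fit"`.
#' @param newdata data.frame with a `substrate_mM` column (defaults to the
#'   fitted substrate range).
#' @param ... unused.
#' @return numeric vector of rates.
#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$substrate_mM else newdata$substrate_mM
  object$v_cmax * s / (object$km_rubp + s)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$data$substrate_mM, x$data$rate,
                 xlab = "[RuBP] (mM)", ylab = "rate", ...)
  s <- seq(0, max(x$data$substrate_mM), length.out = 200)
  graphics::lines(s, x$v_cmax * s / (x$km_rubp + s))
  invisible(x)
}

#' Two-point Arrhenius activation energy
#'
#' `E_a = R * ln(v2 / v1) / (1/T1 - 1/T2)` with temperatures in kelvin,
#' the activation energy implied by rates measured at two temperatures.
#' Vectorised over replicate pairs: pass per-replicate rate vectors for a
#' paired estimate, or single means.
#'
#' @param v1,v2 rates at `t1_C` and `t2_C` (positive; recycled pairwise).
#' @param t1_C,t2_C assay temperatures (deg C); must differ.
#' @return Activation energy in kJ/mol (vector if inputs are vectors).
#' @examples
#' activation_energy(1, 2, 25, 35)  # doubling over 10 K: ~52.9 kJ/mol
#' @export
activation_energy <- function(v1, v2, t1_C = 25, t2_C = 35) {
  check_pos(v1, "v1"); check_pos(v2, "v2")
  if (t1_C == t2_C) stop("temperatures must differ", call. = FALSE)
  T1 <- celsius_to_kelvin(t1_C); T2 <- celsius_to_kelvin(t2_C)
  .R_GAS * log(v2 / v1) / (1 / T1 - 1 / T2)
}

#' Fit activity-recovery (slow-binding inhibitor release) time courses
#'
#' Recovery of activity as a slow-binding inhibitor is released, fitted per
#' replicate. Two standard forms are available:
#' \describe{
#'   \item{`"rate"` (default)}{instantaneous activity
#'     `v(t) = v_final * (1 - exp(-k_obs * t))`, for data reported as
#'     activity per time point.}
#'   \item{`"product"`}{integrated product accumulation
#'     `P(t) = v_s * t - (v_s / k_obs) * (1 - exp(-k_obs * t))`, for
#'     cumulative progress curves.}
#' }
#' A trace with no usable time dependence (constant activity) leaves
#' `k_obs` unidentifiable and is flagged rather than fitted.
#'
#' @param data data.frame with columns `replicate`, `time_min`, `activity`.
#' @param model `"rate"` or `"product"`.
#' @return Object of class `"recovery_fit"`: list with `fits`
#'   (per-replicate `k_obs`, `v_final`, SEs, `converged`), `k_obs` (mean
#'   over converged fits), `sd`, `n_converged`, `model`, `data`.
#' @examples
#' d <- simulate_recovery(0.3, cv = 0, seed = 1)
#' fit_recovery(d)
#' @export
fit_recovery <- function(data, model = c("rate", "product")) {
  model <- match.arg(model)
  need <- c("replicate", "time_min", "activity")
  if (!all(need %in% names(data)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)

  rows <- lapply(split(data, data$replicate), function(d) {
    out <- data.frame(replicate = d$replicate[1L], k_obs = NA_real_,
                      v_final = NA_real_, se_k_obs = NA_real_,
                      converged = FALSE)
    if (length(unique(d$time_min)) < 4L) return(out)
    # a flat trace carries no information on k_obs
    if (stats::sd(d$activity) < 1e-12 * max(1, abs(mean(d$activity))))
      return(out)
    v0 <- max(abs(d$activity))
    start <- list(k_obs = 1 / max(stats::median(d$time_min), 1e-6),
                  v_final = v0)
    form <- if (model == "rate")
      activity ~ v_final * (1 - exp(-k_obs * time_min))
    else
      activity ~ v_final * time_min - (v_final / k_obs) *
        (1 - exp(-k_obs * time_min))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = start,
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) c(NA_real_, NA_real_))
      out$k_obs <- cf[["k_obs"]]; out$v_final <- cf[["v_final"]]
      out$se_k_obs <- se[1L]; out$converged <- TRUE
    }
    out
  })
  fits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- fits$converged
  if (!any(ok)) stop("no recovery fit converged or identifiable",
                     call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " replicate trace(s) flagged (degenerate or ",
            "non-converged); excluded from summary", call. = FALSE)
  structure(list(fits = fits, k_obs = mean(fits$k_obs[ok]),
                 sd = stats::sd(fits$k_obs[ok]), n_converged = sum(ok),
                 model = model, data = data, call = match.call()),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, digits = 4, ...) {
  cat("Activity-recovery fit (", x$model, " form, ", x$n_converged,
      " replicate(s))\n", sep = "")
  cat("  k_obs: ", format(round(x$k_obs, digits)), " +/- ",
      format(round(x$sd, digits)), " min^-1\n", sep = "")
  invisible(x)
}

#' @export
coef.recovery_fit <- function(object, ...) {
  c(k_obs = object$k_obs,
    v_final = mean(object$fits$v_final[object$fits$converged]))
}

#' @export
predict.recovery_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min else newdata$time_min
  cf <- coef(object)
  if (object$model == "rate")
    cf[["v_final"]] * (1 - exp(-cf[["k_obs"]] * t))
  else
    cf[["v_final"]] * t - (cf[["v_final"]] / cf[["k_obs"]]) *
      (1 - exp(-cf[["k_obs"]] * t))
}

#' Fit a thermal melt curve and two-state unfolding energetics
#'
#' Boltzmann sigmoid fit
#' `signal(T) = base + (top - base) / (1 + exp((tm - T) / slope))`
#' for the melting temperature, followed by a two-state van't Hoff
#' analysis: the unfolded fraction is `f(T) = K / (1 + K)` with
#' `ln K = -(dH/R) * (1/T - 1/Tm)`, which links the transition width to
#' the van't Hoff enthalpy, `dH_vH = R * Tm^2 / slope` (temperatures in
#' kelvin). The Gibbs free energy of unfolding is extrapolated to a
#' reference temperature with
#' `dG(T) = dH * (1 - T/Tm) + dCp * (T - Tm - T * ln(T/Tm))`; by
#' definition `dG(Tm) = 0`. With the default `dCp = 0` this is the
#' constant-enthalpy two-state extrapolation.
#'
#' @param data data.frame with columns `temperature_C`, `signal`.
#' @param ref_temp_C reference temperature for `dG_unfold` (deg C).
#' @param dCp heat-capacity change of unfolding (kJ/mol/K), default 0.
#' @return Object of class `"melt_fit"`: list with `tm_C`, `slope_C`,
#'   `base`, `top`, `dH_vH` (kJ/mol), `dG_unfold` (kJ/mol at
#'   `ref_temp_C`), `ref_temp_C`, `converged`, `data`. A curve with no
#'   detectable transition errors out.
#' @examples
#' d <- simulate_melt(55)
#' fit_melt(d)
#' @export
fit_melt <- function(data, ref_temp_C = 25, dCp = 0) {
  need <- c("temperature_C", "signal")
  if (!all(need %in% names(data)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  rng <- range(data$signal)
  if (diff(rng) <= 0) stop("no transition detected (flat signal)",
                           call. = FALSE)
  mid <- mean(rng)
  tm0 <- data$temperature_C[which.min(abs(data$signal - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ base + (top - base) / (1 + exp((tm - temperature_C) / slope)),
      data = data,
      start = list(base = rng[1L], top = rng[2L], tm = tm0, slope = 2),
      lower = c(-Inf, -Inf, min(data$temperature_C), 1e-6),
      upper = c(Inf, Inf, max(data$temperature_C), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("no transition detected (melt fit did not converge)",
         call. = FALSE)
  cf <- stats::coef(fit)
  amplitude <- abs(cf[["top"]] - cf[["base"]])
  resid_sd <- stats::sd(stats::residuals(fit))
  if (amplitude < 5 * resid_sd)
    stop("no transition detected (amplitude indistinguishable from noise)",
         call. = FALSE)
  tm_K <- celsius_to_kelvin(cf[["tm"]])
  dH <- .R_GAS * tm_K^2 / cf[["slope"]]   # kJ/mol; slope in K == deg C width
  Tref <- celsius_to_kelvin(ref_temp_C)
  dG <- dH * (1 - Tref / tm_K) + dCp * (Tref - tm_K - Tref * log(Tref / tm_K))
  structure(list(tm_C = unname(cf[["tm"]]), slope_C = unname(cf[["slope"]]),
                 base = unname(cf[["base"]]), top = unname(cf[["top"]]),
                 dH_vH = unname(dH), dG_unfold = unname(dG),
                 ref_temp_C = ref_temp_C, dCp = dCp,
                 converged = TRUE, data = data, call = match.call()),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, digits = 3, ...) {
  cat("Thermal melt fit (two-state)\n")
  cat("  Tm:          ", format(round(x$tm_C, digits)), " degC\n", sep = "")
  cat("  dH_vH:       ", format(round(x$dH_vH, 1)), " kJ/mol\n", sep = "")
  cat("  dG_unfold(", x$ref_temp_C, " degC): ",
      format(round(x$dG_unfold, digits)), " kJ/mol\n", sep = "")
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm_C = object$tm_C, slope_C = object$slope_C, dH_vH = object$dH_vH,
    dG_unfold = object$dG_unfold)
}

#' Gibbs free energy of unfolding at an arbitrary temperature
#'
#' @param object a `"melt_fit"`.
#' @param newdata data.frame with a `temperature_C` column (defaults to the
#'   fit's reference temperature).
#' @param ... unused.
#' @return `dG_unfold` in kJ/mol at the requested temperatures (0 at Tm).
#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  t_C <- if (is.null(newdata)) object$ref_temp_C else newdata$temperature_C
  Tq <- celsius_to_kelvin(t_C)
  tm_K <- celsius_to_kelvin(object$tm_C)
  object$dH_vH * (1 - Tq / tm_K) +
    object$dCp * (Tq - tm_K - Tq * log(Tq / tm_K))
}
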