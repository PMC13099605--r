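# Native-MS stoichiometry assignment: a 9-rung mass ladder spanning the
# all-light to all-heavy holoenzyme, and nearest-rung peak assignment.

#' Build a stoichiometry mass ladder
#'
#' Theoretical masses of an L8S8 holoenzyme carrying `k = 0..n_sites`
#' copies of SSu species A (the heavier species) and `n_sites - k` of
#' species B. Two modes:
#' \describe{
#'   \item{empirical}{anchored on the measured masses of the two
#'     homogeneous holoenzymes (`anchor_low_kDa` = all-B,
#'     `anchor_high_kDa` = all-A); `rung_k = low + k * (high - low) / 8`.
#'     Preferred for native-MS data, whose masses carry adducts absent from
#'     sequence masses.}
#'   \item{theoretical}{from per-subunit masses and an invariant core:
#'     `rung_k = core + k * mass_a + (8 - k) * mass_b`.}
#' }
#'
#' @param anchor_low_kDa,anchor_high_kDa measured masses (kDa) of the
#'   homogeneous all-B and all-A holoenzymes (empirical mode).
#' @param mass_a_kDa,mass_b_kDa per-subunit average masses (kDa) with
#'   `mass_a_kDa > mass_b_kDa` (theoretical mode).
#' @param core_mass_kDa invariant core mass (theoretical mode).
#' @param n_sites number of substitutable sites.
#' @return Object of class `"mass_ladder"`: list with `rungs` (named
#'   numeric, `"0"` ... `"8"`), `step_kDa`, `mode`, `n_sites`.
#' @examples
#' build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
#' build_ladder(mass_a_kDa = 22.48, mass_b_kDa = 15.62, core_mass_kDa = 423)
#' @export
build_ladder <- function(anchor_low_kDa = NULL, anchor_high_kDa = NULL,
                         mass_a_kDa = NULL, mass_b_kDa = NULL,
                         core_mass_kDa = NULL, n_sites = 8L) {
  empirical <- !is.null(anchor_low_kDa) && !is.null(anchor_high_kDa)
  theoretical <- !is.null(mass_a_kDa) && !is.null(mass_b_kDa) &&
    !is.null(core_mass_kDa)
  if (empirical == theoretical)
    stop("give either both anchors (empirical mode) or both subunit ",
         "masses plus a core mass (theoretical mode)", call. = FALSE)
  k <- 0:n_sites
  if (empirical) {
    check_pos(anchor_low_kDa, "anchor_low_kDa")
    if (anchor_high_kDa <= anchor_low_kDa)
      stop("'anchor_high_kDa' must exceed 'anchor_low_kDa'", call. = FALSE)
    step <- (anchor_high_kDa - anchor_low_kDa) / n_sites
    rungs <- anchor_low_kDa + k * step
    mode <- "empirical"
  } else {
    check_pos(mass_a_kDa, "mass_a_kDa"); check_pos(mass_b_kDa, "mass_b_kDa")
    check_pos(core_mass_kDa, "core_mass_kDa")
    step <- mass_a_kDa - mass_b_kDa
    if (step <= 0)
      stop("degenerate ladder: 'mass_a_kDa' must exceed 'mass_b_kDa'",
           call. = FALSE)
    rungs <- core_mass_kDa + k * mass_a_kDa + (n_sites - k) * mass_b_kDa
    mode <- "theoretical"
  }
  structure(list(rungs = stats::setNames(rungs, k), step_kDa = step,
                 mode = mode, n_sites = n_sites),
            class = "mass_ladder")
}

#' @export
print.mass_ladder <- function(x, digits = 2, ...) {
  cat("Stoichiometry mass ladder (", x$mode, " mode), step ",
      format(round(x$step_kDa, 4)), " kDa\n", sep = "")
  print(round(x$rungs, digits))
  invisible(x)
}

#' Assign deconvoluted native-MS peaks to SSu stoichiometries
#'
#' Each peak is assigned to the nearest ladder rung (ties broken toward
#' lower `k`, with a warning). The residual is reported and flagged against
#' a tolerance (default a quarter of the ladder step), so ambiguous peaks
#' are visible rather than silently forced onto a rung.
#'
#' @param peaks data.frame with columns `mass_kDa` and (optionally)
#'   `rel_intensity`.
#' @param ladder a `"mass_ladder"` from [build_ladder()].
#' @param tolerance_kDa flag threshold on `|residual|`; default
#'   `ladder$step_kDa / 4`.
#' @return Object of class `"stoich_assignment"`: data.frame with columns
#'   `mass_kDa`, `rel_intensity`, `k` (copies of species A),
#'   `ratio` (label `"(n-k):k"`, species B count first), `theoretical_kDa`,
#'   `residual_kDa`, `within_tolerance`; attributes `n_distinct` (number of
#'   distinct assigned stoichiometries) and `tolerance_kDa`. Empty input
#'   gives an empty assignment, not an error.
#' @examples
#' lad <- build_ladder(anchor_low_kDa = 548.08, anchor_high_kDa = 602.09)
#' assign_peaks(data.frame(mass_kDa = c(561.63, 575.16, 581.91, 586.39)), lad)
#' @export
assign_peaks <- function(peaks, ladder, tolerance_kDa = NULL) {
  stopifnot(inherits(ladder, "mass_ladder"))
  if (is.null(tolerance_kDa)) tolerance_kDa <- ladder$step_kDa / 4
  if (nrow(peaks) > 0L && !"rel_intensity" %in% names(peaks))
    peaks$rel_intensity <- NA_real_
  if (nrow(peaks) == 0L) {
    out <- data.frame(mass_kDa = numeric(0), rel_intensity = numeric(0),
                      k = integer(0), ratio = character(0),
                      theoretical_kDa = numeric(0),
                      residual_kDa = numeric(0),
                      within_tolerance = logical(0))
  } else {
    check_pos(peaks$mass_kDa, "mass_kDa")
    res <- lapply(peaks$mass_kDa, function(m) {
      d <- abs(m - ladder$rungs)
      near <- which(d == min(d))
      if (length(near) > 1L)
        warning("peak at ", format(m), " kDa equidistant from rungs; ",
                "tie broken toward lower k", call. = FALSE)
      k <- unname(near[1L]) - 1L
      c(k = k, theo = unname(ladder$rungs[near[1L]]))
    })
    k <- vapply(res, `[[`, numeric(1), "k")
    theo <- vapply(res, `[[`, numeric(1), "theo")
    out <- data.frame(
      mass_kDa = peaks$mass_kDa, rel_intensity = peaks$rel_intensity,
      k = as.integer(k),
      ratio = paste0(ladder$n_sites - as.integer(k), ":", as.integer(k)),
      theoretical_kDa = theo, residual_kDa = peaks$mass_kDa - theo,
      within_tolerance = abs(peaks$mass_kDa - theo) <= tolerance_kDa)
  }
  attr(out, "n_distinct") <- length(unique(out$k))
  attr(out, "tolerance_kDa") <- tolerance_kDa
  class(out) <- c("stoich_assignment", "data.frame")
  out
}

#' @export
print.stoich_assignment <- function(x, digits = 2, ...) {
  cat("Native-MS stoichiometry assignment: ", nrow(x), " peak(s), ",
      attr(x, "n_distinct"), " distinct stoichiometries\n", sep = "")
  df <- as.data.frame(x)
  df$mass_kDa <- round(df$mass_kDa, digits)
  df$theoretical_kDa <- round(df$theoretical_kDa, digits)
  df$residual_kDa <- round(df$residual_kDa, digits + 1)
  print(df, row.names = FALSE)
  cat("tolerance: ", format(round(attr(x, "tolerance_kDa"), 3)),
      " kDa\n", sep = "")
  invisible(x)
}

#' Verify subunit presence from denatured-MS peaks
#'
#' Matches each expected SSu species mass against a denatured peak list and
#' reports whether a peak lies within tolerance — the denatured-MS check
#' that both SSu species are present before interpreting native masses as
#' heterogeneity.
#'
#' @param peaks data.frame with column `mass_kDa` (denatured peak list).
#' @param expected_masses_kDa named numeric vector of expected subunit
#'   masses (names = species labels).
#' @param tolerance_kDa match tolerance (kDa).
#' @return data.frame: `species`, `expected_kDa`, `matched_kDa` (NA if
#'   none), `residual_kDa`, `present`.
#' @export
verify_subunit_presence <- function(peaks, expected_masses_kDa,
                                    tolerance_kDa = 0.05) {
  check_pos(expected_masses_kDa, "expected_masses_kDa")
  check_pos(tolerance_kDa, "tolerance_kDa")
  species <- names(expected_masses_kDa)
  if (is.null(species)) species <- paste0("species_", seq_along(expected_masses_kDa))
  rows <- lapply(seq_along(expected_masses_kDa), function(i) {
    exp_m <- expected_masses_kDa[i]
    if (nrow(peaks) == 0L) {
      matched <- NA_real_
    } else {
      d <- abs(peaks$mass_kDa - exp_m)
      matched <- peaks$mass_kDa[which.min(d)]
      if (min(d) > tolerance_kDa) matched <- NA_real_
    }
    data.frame(species = species[i], expected_kDa = unname(exp_m),
               matched_kDa = matched,
               residual_kDa = if (is.na(matched)) NA_real_ else
                 matched - unname(exp_m),
               present = !is.na(matched))
  })
  do.call(rbind, rows)
}
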