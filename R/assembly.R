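#' Stoichiometry distribution of a two-species L8S8 holoenzyme
#'
#' Probability mass function of `k`, the number of His-tagged small subunits
#' (SSus) among the eight SSu sites of an L8S8 holoenzyme, when sites are
#' filled from a pool containing a His-tagged and a Strep-tagged species.
#'
#' With `alpha = 1` every site is filled independently and the distribution
#' is Binomial(`n_sites`, `p`). With `alpha != 1` sites are filled
#' sequentially and the odds of repeating the species that filled the
#' immediately preceding site are multiplied by `alpha` (`alpha > 1` favours
#' runs of the same species and hence homogeneity; `alpha < 1` favours
#' alternation). The first site is His-tagged with probability `p`. The pmf
#' is computed exactly by a forward recursion over (site, count, last
#' species), equivalent to summing over all `2^n_sites` ordered fill
#' sequences.
#'
#' @param p His-skew: probability that a site is filled by the His-tagged
#'   species, in `[0, 1]`.
#' @param alpha preference multiplier on the odds of repeating the previous
#'   species; `1` means independent sites. Must be `> 0`.
#' @param n_sites number of SSu sites; 8 for L8S8 Rubisco.
#' @return An object of class `"stoich_pmf"`: a list with elements `pmf`
#'   (numeric vector of length `n_sites + 1`, named `"0"` ... `"8"`),
#'   `model` (`"binomial"` or `"preference"`), `p`, `alpha`, `n_sites`.
#' @examples
#' stoichiometry_pmf(0.5)                 # Binomial(8, 0.5)
#' stoichiometry_pmf(0.5, alpha = 4)      # homogeneity-favouring chain
#' @seealso [predicted_heterogeneity()], [fit_preference_alpha()]
#' @export
stoichiometry_pmf <- function(p, alpha = 1, n_sites = 8L) {
  check_prob(p, "p")
  check_pos(alpha, "alpha")
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("'n_sites' must be >= 1", call. = FALSE)

  if (alpha == 1) {
    pmf <- stats::dbinom(0:n_sites, n_sites, p)
    model <- "binomial"
  } else {
    # state[s, k + 1]: probability of k His sites so far with last species
    # s (1 = His, 2 = Strep), after filling the current site
    state <- matrix(0, 2L, n_sites + 1L)
    state[1L, 2L] <- p
    state[2L, 1L] <- 1 - p
    p_his_after_his <- alpha * p / (alpha * p + (1 - p))
    p_his_after_strep <- p / (p + alpha * (1 - p))
    if (n_sites > 1L) {
      for (site in 2:n_sites) {
        nxt <- matrix(0, 2L, n_sites + 1L)
        idx <- 1:n_sites
        nxt[1L, idx + 1L] <- state[1L, idx] * p_his_after_his +
          state[2L, idx] * p_his_after_strep
        nxt[2L, idx] <- state[1L, idx] * (1 - p_his_after_his) +
          state[2L, idx] * (1 - p_his_after_strep)
        state <- nxt
      }
    }
    pmf <- colSums(state)
    model <- "preference"
  }
  names(pmf) <- 0:n_sites
  structure(
    list(pmf = pmf, model = model, p = p, alpha = alpha, n_sites = n_sites),
    class = "stoich_pmf"
  )
}

#' @export
print.stoich_pmf <- function(x, digits = 4, ...) {
  cat("SSu stoichiometry distribution (", x$model, " model)\n", sep = "")
  cat("  His-skew p = ", format(x$p), ", alpha = ", format(x$alpha),
      ", sites = ", x$n_sites, "\n", sep = "")
  print(round(x$pmf, digits))
  cat("heterogeneous fraction (1 <= k <= ", x$n_sites - 1L, "): ",
      format(1 - x$pmf[1L] - x$pmf[x$n_sites + 1L], digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' Predicted fraction of SSu-heterogeneous holoenzymes
#'
#' Probability that a holoenzyme carries both SSu species, i.e.
#' `P(1 <= k <= n_sites - 1)` under the assembly model of
#' [stoichiometry_pmf()]. For independent sites (`alpha = 1`) this is the
#' closed form `1 - p^n - (1 - p)^n`.
#'
#' @inheritParams stoichiometry_pmf
#' @return Probability in `[0, 1]`. Vectorised over `p` and `alpha`
#'   (recycled to a common length).
#' @examples
#' predicted_heterogeneity(0.5)       # 127/128
#' predicted_heterogeneity(0.6)       # 1 - 0.6^8 - 0.4^8
#' @export
predicted_heterogeneity <- function(p, alpha = 1, n_sites = 8L) {
  check_prob(p, "p")
  check_pos(alpha, "alpha")
  n <- max(length(p), length(alpha))
  p <- rep_len(p, n); alpha <- rep_len(alpha, n)
  vapply(seq_len(n), function(i) {
    if (alpha[i] == 1) return(1 - p[i]^n_sites - (1 - p[i])^n_sites)
    d <- stoichiometry_pmf(p[i], alpha[i], n_sites)$pmf
    unname(1 - d[1L] - d[length(d)])
  }, numeric(1))
}

#' Predicted fraction of SSu-homogeneous holoenzymes
#'
#' Complement of [predicted_heterogeneity()]: `P(k = 0) + P(k = n_sites)`.
#' At even incorporation (`p = 0.5`, independent sites) this is
#' `2 * (1/2)^8 = 1/128`, under 1 percent of the holoenzyme pool.
#'
#' @inheritParams stoichiometry_pmf
#' @return Probability in `[0, 1]`. Vectorised over `p`.
#' @export
homogeneous_fraction <- function(p, alpha = 1, n_sites = 8L) {
  1 - predicted_heterogeneity(p, alpha, n_sites)
}

#' Solve for the preference multiplier matching an observed heterogeneity
#'
#' Finds `alpha` such that `predicted_heterogeneity(p, alpha)` equals a
#' measured heterogeneous fraction, by monotone 1-D root finding on
#' `log(alpha)` over `[1e-3, 1e3]`. Heterogeneity decreases monotonically
#' in `alpha` (stronger preference for repeating a species concentrates
#' mass at k = 0 and k = 8), so a solution, when it exists in the bracket,
#' is unique. A target outside the attainable range yields an explicit
#' no-solution result rather than a clamped value.
#'
#' @param measured_het observed heterogeneous fraction, strictly in (0, 1).
#' @param p His-skew.
#' @param n_sites number of SSu sites.
#' @param interval search interval for `alpha`.
#' @param tol absolute tolerance on `alpha` for the root finder.
#' @return A list with `alpha` (NA if no solution), `solution` (logical),
#'   `achieved` (forward-evaluated heterogeneity at the returned alpha),
#'   and `range` (attainable heterogeneity over the interval).
#' @export
fit_preference_alpha <- function(measured_het, p, n_sites = 8L,
                                 interval = c(1e-3, 1e3), tol = 1e-8) {
  if (!is.numeric(measured_het) || length(measured_het) != 1L ||
      measured_het <= 0 || measured_het >= 1)
    stop("'measured_het' must be a single value strictly in (0, 1)",
         call. = FALSE)
  check_prob(p, "p")
  f <- function(log_a)
    predicted_heterogeneity(p, exp(log_a), n_sites) - measured_het
  lo <- f(log(interval[1L]))
  hi <- f(log(interval[2L]))
  rng <- sort(c(lo, hi)) + measured_het
  if (lo * hi > 0) {
    return(list(alpha = NA_real_, solution = FALSE, achieved = NA_real_,
                range = rng))
  }
  root <- stats::uniroot(f, lower = log(interval[1L]),
                         upper = log(interval[2L]), tol = tol)
  alpha <- exp(root$root)
  list(alpha = alpha, solution = TRUE,
       achieved = predicted_heterogeneity(p, alpha, n_sites), range = rng)
}
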