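# Group-comparison procedures used for the figure-level statistics:
# one-sample t test against an even-incorporation null, one-way ANOVA with
# Tukey HSD, and a compact letter display (CLD).

#' One-sample t test against a reference value
#'
#' Two-sided one-sample t test, as used to ask whether a His-skew differs
#' from 0.5 (even incorporation of the two SSu species).
#'
#' @param values numeric observations (n >= 2, nonzero variance).
#' @param mu0 null value (default 0.5).
#' @param alpha significance cutoff.
#' @return list: `t`, `df`, `p_value`, `significant`, `mean`, `mu0`.
#' @export
one_sample_t <- function(values, mu0 = 0.5, alpha = 0.05) {
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       mean = mean(values), mu0 = mu0)
}

# insert-and-absorb letter assignment: given group names ordered by
# descending mean and a matrix of significant pairs, return letters such
# that two groups share a letter iff they are NOT significantly different
cld_insert_absorb <- function(groups, sig_pairs) {
  cols <- list(groups)                      # start: one letter, all groups
  if (nrow(sig_pairs)) {
    for (i in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[i, 1L]; b <- sig_pairs[i, 2L]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)),
                        list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (j in seq_along(new_cols)) {
        for (l in seq_along(new_cols)) {
          if (j != l && keep[l] &&
              all(new_cols[[j]] %in% new_cols[[l]]) &&
              !(all(new_cols[[l]] %in% new_cols[[j]]) && j < l))
            keep[j] <- FALSE
        }
      }
      cols <- new_cols[keep]
    }
  }
  # letters ordered by the highest-mean member of each column
  first <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first)]
  letts <- stats::setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols))
    letts[cols[[j]]] <- paste0(letts[cols[[j]]], letters[j])
  letts
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical (equal-variance) one-way ANOVA followed by Tukey's honestly
#' significant difference test on the studentized-range distribution, and a
#' compact letter display built by the insert-and-absorb algorithm: two
#' groups share a letter if and only if their Tukey-adjusted difference is
#' not significant at `alpha`. Letters are assigned in order of descending
#' group mean.
#'
#' @param values numeric observations.
#' @param group group labels (coerced to factor), >= 2 groups, each with
#'   >= 2 values.
#' @param alpha significance cutoff.
#' @return Object of class `"anova_cld"`: list with `anova` (the ANOVA
#'   table), `f`, `p_value`, `tukey` (data.frame of pairwise differences,
#'   adjusted p values, significance), `letters` (named character, one per
#'   group, ordered by descending mean), `means`, `alpha`.
#' @examples
#' v <- c(rnorm(5, 0), rnorm(5, 0.5), rnorm(5, 10))
#' g <- rep(c("a", "b", "c"), each = 5)
#' anova_tukey_cld(v, g)
#' @export
anova_tukey_cld <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(grepl("-", levels(group), fixed = TRUE)))
    stop("group labels must not contain '-' (reserved in pairwise labels)",
         call. = FALSE)
  n_per <- table(group)
  if (any(n_per < 2L))
    stop("every group needs >= 2 values for variance-based tests",
         call. = FALSE)
  d <- data.frame(values = values, group = group)
  fit <- stats::aov(values ~ group, data = d)
  tab <- stats::anova(fit)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(
    comparison = rownames(hsd), diff = hsd[, "diff"],
    lwr = hsd[, "lwr"], upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
    significant = hsd[, "p adj"] < alpha, row.names = NULL)

  means <- sort(tapply(values, group, mean), decreasing = TRUE)
  ord_groups <- names(means)
  pairs <- do.call(rbind, strsplit(tukey$comparison[tukey$significant], "-",
                                   fixed = TRUE))
  if (is.null(pairs)) pairs <- matrix(character(0), ncol = 2L)
  letts <- cld_insert_absorb(ord_groups, pairs)

  structure(list(anova = tab, f = tab$`F value`[1L],
                 p_value = tab$`Pr(>F)`[1L], tukey = tukey,
                 letters = letts, means = means, alpha = alpha),
            class = "anova_cld")
}

#' @export
print.anova_cld <- function(x, digits = 3, ...) {
  cat("One-way ANOVA: F = ", format(round(x$f, digits)), ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  cat("Tukey HSD (alpha = ", x$alpha, ") letter display:\n", sep = "")
  print(data.frame(group = names(x$means),
                   mean = round(unname(x$means), digits),
                   letters = unname(x$letters[names(x$means)])),
        row.names = FALSE)
  invisible(x)
}
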