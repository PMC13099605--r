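# Independent oracles used across the suite.

# Exact pmf of the sequential-preference chain by brute-force enumeration
# of all 2^n ordered fill sequences (1 = His). Independent of the
# recursion used by stoichiometry_pmf().
brute_force_chain_pmf <- function(p, alpha, n_sites = 8L) {
  pmf <- numeric(n_sites + 1L)
  p_hh <- alpha * p / (alpha * p + (1 - p))
  p_hs <- p / (p + alpha * (1 - p))
  for (i in 0:(2^n_sites - 1L)) {
    bits <- as.integer(intToBits(i))[1:n_sites]
    pr <- if (bits[1L]) p else 1 - p
    for (s in 2:n_sites) {
      ph <- if (bits[s - 1L]) p_hh else p_hs
      pr <- pr * if (bits[s]) ph else 1 - ph
    }
    k <- sum(bits)
    pmf[k + 1L] <- pmf[k + 1L] + pr
  }
  pmf
}

# Build a multi-replicate purification record table from one pool.
sim_records <- function(pool, n_replicates = 3L, ...) {
  do.call(rbind, lapply(seq_len(n_replicates), function(r)
    simulate_purification(pool, replicate_id = paste0("r", r), ...)))
}

# A hand-built holoenzyme pool with exact composition (counts per k).
manual_pool <- function(counts, n_sites = 8L) {
  k <- rep(0:n_sites, counts)
  data.frame(holoenzyme = seq_along(k), k = k, n_his_tags = k,
             n_strep_tags = n_sites - k)
}

# Check the defining CLD property directly: two groups share a letter
# if and only if their pairwise comparison is not significant.
cld_matches_pairwise <- function(letters, tukey) {
  pairs <- strsplit(tukey$comparison, "-", fixed = TRUE)
  ok <- vapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    shared <- length(intersect(strsplit(letters[[a]], "")[[1L]],
                               strsplit(letters[[b]], "")[[1L]])) > 0L
    shared == !tukey$significant[i]
  }, logical(1))
  all(ok)
}
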