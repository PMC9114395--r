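# Independent oracles used by the tests. Deliberately written from first
# principles (direct summation, exhaustive enumeration, dense grids) rather
# than by calling package internals.

# Beta-binomial log density written directly from the definition, with the
# (mu, rho) parameterization alpha = mu(1-rho)/rho, beta = (1-mu)(1-rho)/rho.
oracle_dbetabinom_log <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# Grid-search maximum-likelihood rho with the pooled-mean plug-in, over a
# dense linear grid.
oracle_rho_grid <- function(alt, depth, n_grid = 10000L) {
  mu <- sum(alt) / sum(depth)
  mu <- min(max(mu, 1e-6), 1 - 1e-6)
  grid <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  ll <- numeric(n_grid)
  for (s in seq_along(alt)) {
    ll <- ll + oracle_dbetabinom_log(alt[s], depth[s], mu, grid)
  }
  grid[which.max(ll)]
}

# One-sided exact binomial tail by direct summation in log space.
oracle_binom_tail <- function(alt_sum, depth_sum, p0 = 0.5) {
  k <- 0:alt_sum
  sum(exp(lchoose(depth_sum, k) + k * log(p0) + (depth_sum - k) * log1p(-p0)))
}

# Brute-force zygote-rooted parsimony: minimum number of edge changes over
# all assignments of internal states (the sampled-crypt MRCA included) and all
# resolutions of ambiguous (NA) leaves. The zygote sits above the MRCA on a
# trunk edge with state 0, so an MRCA state of 1 costs one extra change.
# Exponential; for small trees only.
oracle_fitch <- function(tree, genotypes) {
  n <- tree$nleaf
  root <- n + 1L
  m <- length(tree$parent)
  internal_free <- (n + 1L):m
  edges <- cbind(child = setdiff(seq_len(m), root),
                 parent = tree$parent[setdiff(seq_len(m), root)])
  g <- genotypes[, tree$labels, drop = FALSE]
  vapply(seq_len(nrow(g)), function(r) {
    x <- g[r, ]
    amb <- which(is.na(x))
    best <- Inf
    n_amb <- length(amb)
    n_int <- length(internal_free)
    for (a in seq_len(2^n_amb) - 1L) {
      leaf_states <- x
      if (n_amb) leaf_states[amb] <- bitwAnd(a %/% 2^(seq_len(n_amb) - 1L), 1L)
      for (b in seq_len(2^n_int) - 1L) {
        states <- integer(m)
        states[seq_len(n)] <- leaf_states
        if (n_int) {
          states[internal_free] <- bitwAnd(b %/% 2^(seq_len(n_int) - 1L), 1L)
        }
        ch <- sum(states[edges[, "child"]] != states[edges[, "parent"]]) +
          (states[root] != 0L)  # trunk edge from the zygote
        if (ch < best) best <- ch
      }
    }
    as.integer(best)
  }, 0L)
}

# Reverse complement for strand-invariance checks.
oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

# Sorted leaf-label strings per branch of a ctree (keyed by character node
# id, plus "root" for the trunk). Used to compare variant placements across
# trees that share a topology but not a node numbering.
branch_leafset_strings <- function(tree) {
  ls <- ct_leafsets(tree)
  root <- tree$nleaf + 1L
  out <- vapply(seq_along(ls), function(v) {
    paste(sort(tree$labels[ls[[v]]]), collapse = ",")
  }, "")
  names(out) <- as.character(seq_along(ls))
  out["root"] <- paste(sort(tree$labels), collapse = ",")
  out[-root]
}

# Shared fixtures for cohort-level tests.
test_catalogues <- function() {
  list(sbs = synthetic_signatures(sbs96_labels(), 3, seed = 42),
       id = synthetic_signatures(id83_labels(), 2, seed = 43, prefix = "IDSIG"))
}

default_test_config <- function(seed = 1L, ...) {
  sim_config(n_crypts = 8, seed = seed,
             signature_activities = c(SIG1 = 6, SIG2 = 3, SIG3 = 1),
             id_signature_activities = c(IDSIG1 = 0.3, IDSIG2 = 0.1), ...)
}
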