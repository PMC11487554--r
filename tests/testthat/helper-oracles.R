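# Independent oracles, deliberately written with different algorithms than
# the package (recursive permutation generation, explicit loops) so the two
# routes share no code.

# all permutations of v, one per row, by head-recursion
oracle_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], oracle_perms(v[-i]))))
}

# exact two-sided Spearman p by brute-force enumeration over all n!
# permutations of y, rho recomputed with stats::cor each time
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  P <- oracle_perms(seq_along(y))
  rhos <- apply(P, 1L, function(p) stats::cor(rx, ry[p]))
  list(rho = rho_obs,
       p = mean(abs(rhos) >= abs(rho_obs) - 1e-9))
}

# tie-corrected normal-approximation Wilcoxon p, re-derived from the
# textbook formula with an explicit loop over the tie groups
oracle_wilcoxon_normal <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_along(a)])
  mu <- length(a) * (n + 1) / 2
  tie_sum <- 0
  for (val in unique(r)) {
    t <- sum(r == val)
    tie_sum <- tie_sum + (t^3 - t)
  }
  s2 <- length(a) * length(b) / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
  z <- w - mu
  z <- sign(z) * max(abs(z) - 0.5, 0)
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(s2)))
}

# small random normalized abundance table
rand_table <- function(n_taxa, n_samples, seed, rank = "species") {
  set.seed(seed)
  raw <- matrix(stats::rexp(n_taxa * n_samples), n_taxa, n_samples)
  raw[stats::runif(length(raw)) < 0.3] <- 0
  raw <- raw + 1e-6   # keep columns non-degenerate
  gen <- sprintf("Genus%02d", ((seq_len(n_taxa) - 1) %% 8) + 1)
  dimnames(raw) <- list(sprintf("%s species%03d", gen, seq_len(n_taxa)),
                        sprintf("S%03d", seq_len(n_samples)))
  normalize_to_relative(raw, rank = rank)
}

# roster over a subset of the given species names
rand_roster <- function(species, frac, seed, name = "rand") {
  set.seed(seed)
  keep <- sort(sample(seq_along(species), floor(frac * length(species))))
  biobank_roster(data.frame(strain_id = sprintf("R%04d", seq_along(keep)),
                            species = species[keep],
                            stringsAsFactors = FALSE), name = name)
}
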