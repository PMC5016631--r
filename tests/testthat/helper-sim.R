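# small fixture builders used across test files

# genotype table of n individuals drawn from Hardy-Weinberg at given
# per-locus frequency vectors
hwe_genotypes <- function(n, freqs, ids = paste0("i", seq_len(n))) {
  L <- length(freqs)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    al <- as.integer(names(freqs[[l]]))
    a1[, l] <- sample(al, n, TRUE, freqs[[l]])
    a2[, l] <- sample(al, n, TRUE, freqs[[l]])
  }
  genotype_table(ids, paste0("L", seq_len(L)), pmin(a1, a2), pmax(a1, a2))
}

# skewed microsatellite-like frequency list (one major + minor alleles)
msat_freqs <- function(n_loci = 10, n_alleles = 12) {
  lapply(seq_len(n_loci), function(l) {
    p <- rgamma(n_alleles, c(4, rep(0.3, n_alleles - 1)))
    p <- p / sum(p)
    stats::setNames(p, seq(102, by = 2, length.out = n_alleles))
  })
}

# uniform-frequency loci (for hand-checkable cases)
flat_freqs <- function(n_loci, k) {
  lapply(seq_len(n_loci), function(l)
    stats::setNames(rep(1 / k, k), seq_len(k)))
}

random_small_gt <- function(n, L, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hwe_genotypes(n, flat_freqs(L, k))
}
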