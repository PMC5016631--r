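# Independent second implementations used as oracles. These are written as
# direct, loop-heavy transcriptions of the textbook formulas and never share
# code with the package's estimators.

# Weir-Cockerham variance components for r populations, diploid data.
# gt: genotype_table; groups: list of id vectors. Returns list(a, b, c,
# theta, f) summed over loci and alleles.
oracle_wc <- function(gt, groups) {
  r <- length(groups)
  A <- 0; B <- 0; C <- 0
  for (l in seq_along(gt$locus_ids)) {
    alleles <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    idx <- lapply(groups, function(g) match(g, gt$individual_ids))
    n_i <- vapply(idx, function(ii) sum(!is.na(gt$a1[ii, l])), numeric(1))
    if (any(n_i == 0)) next
    nbar <- mean(n_i)
    if (r * nbar <= r || nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(idx, function(ii) {
        x1 <- gt$a1[ii, l]; x2 <- gt$a2[ii, l]
        ok <- !is.na(x1)
        sum((x1[ok] == al) + (x2[ok] == al)) / (2 * sum(ok))
      }, numeric(1))
      h_i <- vapply(idx, function(ii) {
        x1 <- gt$a1[ii, l]; x2 <- gt$a2[ii, l]
        ok <- !is.na(x1)
        sum(x1[ok] != x2[ok] & (x1[ok] == al | x2[ok] == al)) / sum(ok)
      }, numeric(1))
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  list(a = A, b = B, c = C, theta = A / (A + B + C), f = B / (B + C))
}

# single-population Weir-Cockerham f
oracle_f_single <- function(gt, ids) {
  Bp <- 0; C <- 0
  idx <- match(ids, gt$individual_ids)
  for (l in seq_along(gt$locus_ids)) {
    x1 <- gt$a1[idx, l]; x2 <- gt$a2[idx, l]
    ok <- !is.na(x1)
    n <- sum(ok)
    if (n < 2) next
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    for (al in alleles) {
      p <- sum((x1[ok] == al) + (x2[ok] == al)) / (2 * n)
      h <- sum(x1[ok] != x2[ok] & (x1[ok] == al | x2[ok] == al)) / n
      Bp <- Bp + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      C <- C + h / 2
    }
  }
  Bp / (Bp + C)
}

# exact Mann-Whitney P by literal enumeration of group assignments
oracle_mw_exact <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  combs <- utils::combn(n1 + n2, n1)
  ustat <- function(xx, yy) {
    sum(outer(xx, yy, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  u_obs <- ustat(x, y)
  u_all <- apply(combs, 2, function(ix) ustat(pooled[ix], pooled[-ix]))
  p_less <- mean(u_all <= u_obs + 1e-12)
  p_greater <- mean(u_all >= u_obs - 1e-12)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# Mantel permutation P by full enumeration of n! relabelings
oracle_mantel_enum <- function(G, D, alternative = "greater") {
  n <- nrow(G)
  lt <- lower.tri(G)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  r_obs <- stats::cor(G[lt], D[lt])
  rs <- vapply(perms(seq_len(n)), function(p)
    stats::cor(G[p, p][lt], D[lt]), numeric(1))
  switch(alternative,
         greater = mean(rs >= r_obs - 1e-12),
         less = mean(rs <= r_obs + 1e-12),
         two.sided = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# Holm flags by literal step-down
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
  }
  rej
}

# inclusion-exclusion variance partition from seven plain lm() fits
oracle_partition <- function(y, x1, x2, x3) {
  r2 <- function(...) summary(stats::lm(y ~ cbind(...)))$r.squared
  R1 <- r2(x1); R2 <- r2(x2); R3 <- r2(x3)
  R12 <- r2(x1, x2); R13 <- r2(x1, x3); R23 <- r2(x2, x3)
  R123 <- r2(x1, x2, x3)
  g <- R1 + R2 + R3 - R12 - R13 - R23 + R123
  c(a = R123 - R23, b = R123 - R13, c = R123 - R12,
    d = R1 + R2 - R12 - g, e = R1 + R3 - R13 - g, f = R2 + R3 - R23 - g,
    g = g, residual = 1 - R123)
}
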