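# Weir-Cockerham variance-components machinery.
#
# Genotypes are expanded once into per-allele column form so that permutation
# replicates reduce to a membership-matrix product:
#   dos  : n x C allele dosage (0/1/2; 0 for missing calls)
#   het  : n x C indicator that the individual is heterozygous AND carries
#          the column's allele
#   typed: n x L indicator that the call at the column's locus is present
# A set of permutations is then a 0/1 selection matrix S (n_perm x n) and all
# per-group counts are S %*% dos etc., evaluated in one BLAS call.

.geno_design <- function(gt) {
  n <- length(gt$individual_ids)
  L <- length(gt$locus_ids)
  cols <- vector("list", L)
  col_locus <- integer(0)
  for (l in seq_len(L)) {
    u <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    u <- u[!is.na(u)]
    if (!length(u)) next
    m <- matrix(0, n, length(u))
    h <- matrix(0, n, length(u))
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    for (k in seq_along(u)) {
      m[, k] <- (a1 == u[k]) + (a2 == u[k])
      h[, k] <- as.numeric(a1 != a2 & (a1 == u[k] | a2 == u[k]))
    }
    m[is.na(m)] <- 0; h[is.na(h)] <- 0
    cols[[l]] <- list(dos = m, het = h, alleles = u)
    col_locus <- c(col_locus, rep(l, length(u)))
  }
  keep <- !vapply(cols, is.null, logical(1))
  dos <- do.call(cbind, lapply(cols[keep], `[[`, "dos"))
  het <- do.call(cbind, lapply(cols[keep], `[[`, "het"))
  typed <- matrix(0, n, L)
  typed[, ] <- as.numeric(!is.na(gt$a1))
  list(dos = dos, het = het, typed = typed, col_locus = col_locus, n = n)
}

# Two-population Weir-Cockerham components, vectorised over permutation rows.
# c1,h1: n_perm x C count matrices for group 1; t1: n_perm x L typed counts.
# Returns list(theta = n_perm vector, a, b, c = n_perm x C component matrices).
.wc_pair <- function(c1, h1, t1, ctot, htot, ttot, col_locus) {
  c2 <- sweep(c1, 2, ctot, FUN = function(x, y) y - x)
  h2 <- sweep(h1, 2, htot, FUN = function(x, y) y - x)
  t2 <- sweep(t1, 2, ttot, FUN = function(x, y) y - x)
  N1 <- t1[, col_locus, drop = FALSE]
  N2 <- t2[, col_locus, drop = FALSE]
  valid <- N1 > 0 & N2 > 0 & (N1 + N2) > 2
  N1s <- pmax(N1, 1); N2s <- pmax(N2, 1)     # guarded; masked by `valid`
  p1 <- c1 / (2 * N1s); p2 <- c2 / (2 * N2s)
  nbar <- (N1 + N2) / 2
  nc <- 2 * N1 * N2 / pmax(N1 + N2, 1)
  pbar <- (c1 + c2) / (2 * pmax(N1 + N2, 1))
  s2 <- (N1 * (p1 - pbar)^2 + N2 * (p2 - pbar)^2) / pmax(nbar, 1)
  hbar <- (h1 + h2) / pmax(N1 + N2, 1)
  nbar1 <- pmax(nbar - 1, 0.5)
  a <- nbar / pmax(nc, 1e-12) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / nbar1)
  b <- nbar / nbar1 *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!valid] <- 0; b[!valid] <- 0; cc[!valid] <- 0
  den <- rowSums(a + b + cc)
  theta <- ifelse(abs(den) < 1e-300, NA_real_, rowSums(a) / den)
  list(theta = theta, a = a, b = b, c = cc)
}

# Haploid (haplotype-frequency) analogue: no within-individual level.
.wc_pair_haploid <- function(c1, ctot) {
  c2 <- sweep(c1, 2, ctot, FUN = function(x, y) y - x)
  N1 <- rowSums(c1); N2 <- rowSums(c2)
  valid <- N1 > 0 & N2 > 0 & (N1 + N2) > 2
  p1 <- c1 / pmax(N1, 1); p2 <- c2 / pmax(N2, 1)
  nbar <- (N1 + N2) / 2
  nc <- 2 * N1 * N2 / pmax(N1 + N2, 1)
  pbar <- (c1 + c2) / pmax(N1 + N2, 1)
  s2 <- (N1 * (p1 - pbar)^2 + N2 * (p2 - pbar)^2) / pmax(nbar, 1)
  nbar1 <- pmax(nbar - 1, 0.5)
  a <- nbar / pmax(nc, 1e-12) * (s2 - (pbar * (1 - pbar) - s2 / 2) / nbar1)
  b <- nbar / nbar1 * (pbar * (1 - pbar) - s2 / 2)
  a[!valid, ] <- 0; b[!valid, ] <- 0
  den <- rowSums(a + b)
  theta <- ifelse(abs(den) < 1e-300 | !valid, NA_real_, rowSums(a) / den)
  theta
}

.as_partition <- function(partition, ids) {
  if (is.null(names(partition))) {
    if (length(partition) != length(ids))
      stop("partition must be named by individual id or align with ids")
    names(partition) <- ids
  }
  part <- as.character(partition[ids])
  if (anyNA(part)) stop("partition misses some individuals")
  part
}

#' Multi-locus Weir-Cockerham theta between two subpopulations
#'
#' Computes the Weir-Cockerham (1984) estimator of F_ST from the per-locus,
#' per-allele variance components a (among populations), b (among individuals
#' within populations) and c (within individuals); theta = sum(a) /
#' sum(a + b + c) over all loci and alleles. Negative estimates are reported
#' as-is.
#'
#' @param gt a [genotype_table()].
#' @param partition named character vector (individual id -> group) taking
#'   exactly two values over the individuals of `gt`.
#' @return list with `theta` and the summed components `a`, `b`, `c`;
#'   `theta` is `NA` (flagged undefined) when every locus is monomorphic
#'   across both groups.
#' @export
wc_fst <- function(gt, partition) {
  part <- .as_partition(partition, gt$individual_ids)
  gl <- unique(part)
  if (length(gl) != 2) stop("wc_fst needs exactly two subpopulations")
  d <- .geno_design(gt)
  sel <- matrix(as.numeric(part == gl[1]), 1, d$n)
  res <- .wc_pair(sel %*% d$dos, sel %*% d$het, sel %*% d$typed,
                  colSums(d$dos), colSums(d$het), colSums(d$typed),
                  d$col_locus)
  list(theta = res$theta[1], a = sum(res$a), b = sum(res$b), c = sum(res$c))
}

#' Haplotype-frequency F_ST between two subpopulations
#'
#' Haplotypes are treated as alleles of one haploid locus; the estimator has
#' only among-group and within-group components.
#'
#' @param ht a [haplotype_table()] (or named integer haplotype vector).
#' @param partition named character vector (individual id -> group), two
#'   groups.
#' @return list with `theta` (`NA` when undefined).
#' @export
haplotype_fst <- function(ht, partition) {
  hap <- if (inherits(ht, "haplotype_table")) ht$haplotype_id else ht
  hap <- hap[!is.na(hap)]
  part <- .as_partition(partition, names(hap))
  gl <- unique(part)
  if (length(gl) != 2) stop("haplotype_fst needs exactly two subpopulations")
  K <- max(hap)
  Z <- matrix(0, length(hap), K)
  Z[cbind(seq_along(hap), hap)] <- 1
  sel <- matrix(as.numeric(part == gl[1]), 1, length(hap))
  theta <- .wc_pair_haploid(sel %*% Z, colSums(Z))
  list(theta = theta[1])
}

#' Within-group inbreeding coefficient (Weir-Cockerham f)
#'
#' Single-population reduction of the Weir-Cockerham components:
#' f = sum(b') / sum(b' + c) over loci and alleles, where b' is the
#' among-individual and c the within-individual component.
#'
#' @param gt a [genotype_table()].
#' @param ids individuals forming the group subset (default: all).
#' @return list with `f` (`NA` and `defined = FALSE` when the subset is
#'   monomorphic) and `n` (individuals used).
#' @export
fis <- function(gt, ids = gt$individual_ids) {
  if (length(ids) < 2) stop("F_IS needs at least 2 individuals")
  sub <- subset_genotypes(gt, ids)
  d <- .geno_design(sub)
  cnt <- colSums(d$dos); hets <- colSums(d$het); typ <- colSums(d$typed)
  N <- typ[d$col_locus]
  valid <- N > 1
  p <- cnt / (2 * pmax(N, 1))
  hbar <- hets / pmax(N, 1)
  bp <- N / pmax(N - 1, 0.5) * (p * (1 - p) - (2 * N - 1) / (4 * N) * hbar)
  cc <- hbar / 2
  bp[!valid] <- 0; cc[!valid] <- 0
  den <- sum(bp + cc)
  if (abs(den) < 1e-300) {
    return(list(f = NA_real_, defined = FALSE, n = length(ids)))
  }
  list(f = sum(bp) / den, defined = TRUE, n = length(ids))
}

#' Per-group F_IS table
#'
#' @param gt a [genotype_table()].
#' @param study a [study_frame()].
#' @param subset which individuals enter each group's estimate: all, adult
#'   females only, or offspring only.
#' @return data.frame `group_id`, `fis`, `n`, `defined` (class `fis_table`).
#' @export
fis_table <- function(gt, study,
                      subset = c("all", "adult_females", "offspring")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
                 all = rep(TRUE, nrow(study)),
                 adult_females = study$sex == "F" & study$age == "adult",
                 offspring = study$age == "offspring")
  st <- study[keep & study$individual_id %in% gt$individual_ids, ]
  groups <- unique(study$group_id)
  out <- data.frame(group_id = groups, fis = NA_real_, n = 0L,
                    defined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    ids <- st$individual_id[st$group_id == groups[i]]
    out$n[i] <- length(ids)
    if (length(ids) >= 2) {
      r <- fis(gt, ids)
      out$fis[i] <- r$f; out$defined[i] <- r$defined
    }
  }
  attr(out, "subset") <- subset
  class(out) <- c("fis_table", "data.frame")
  out
}

#' Pairwise F_ST matrix with permutation P-values
#'
#' For every pair of groups the observed Weir-Cockerham theta (diploid data)
#' or haplotype-frequency theta (haploid data) is computed, and its
#' significance assessed by `n_perm` random reassignments of whole
#' individuals (diploid) or single haplotypes (haploid) between the two
#' groups: P = (#\{theta_perm >= theta_obs\} + 1) / (n_perm + 1).
#'
#' @param data a [genotype_table()] or [haplotype_table()].
#' @param partition named character vector individual id -> group label.
#' @param n_perm number of permutations per pair.
#' @param seed integer seed (fixing it fixes every P-value).
#' @return object of class `fst_result`: list with `labels`, `theta` and
#'   `pvals` (symmetric matrices, zero/NA diagonal), `n_perm`. Pairs with a
#'   group of fewer than 2 members are flagged `NA`.
#' @export
pairwise_fst_matrix <- function(data, partition, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  diploid <- inherits(data, "genotype_table")
  if (diploid) {
    ids <- data$individual_ids
  } else {
    hap <- data$haplotype_id
    hap <- hap[!is.na(hap)]
    ids <- names(hap)
  }
  part <- .as_partition(partition, ids)
  labels <- unique(part)
  g <- length(labels)
  if (g < 2) stop("need at least two groups")
  theta <- matrix(NA_real_, g, g, dimnames = list(labels, labels))
  pv <- matrix(NA_real_, g, g, dimnames = list(labels, labels))
  diag(theta) <- 0
  if (diploid) d <- .geno_design(data) else {
    K <- max(hap)
    Z <- matrix(0, length(hap), K)
    Z[cbind(seq_along(hap), hap)] <- 1
  }
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    rows1 <- which(part == labels[i]); rows2 <- which(part == labels[j])
    n1 <- length(rows1); n <- n1 + length(rows2)
    if (n1 < 2 || length(rows2) < 2) next
    rows <- c(rows1, rows2)
    S <- matrix(0, n_perm + 1, n)
    S[1, seq_len(n1)] <- 1
    pick <- vapply(seq_len(n_perm), function(k) sample.int(n, n1),
                   integer(n1))
    S[cbind(rep(2:(n_perm + 1), each = n1), as.vector(pick))] <- 1
    if (diploid) {
      dos <- d$dos[rows, , drop = FALSE]
      het <- d$het[rows, , drop = FALSE]
      typ <- d$typed[rows, , drop = FALSE]
      th <- .wc_pair(S %*% dos, S %*% het, S %*% typ,
                     colSums(dos), colSums(het), colSums(typ),
                     d$col_locus)$theta
    } else {
      Zp <- Z[rows, , drop = FALSE]
      th <- .wc_pair_haploid(S %*% Zp, colSums(Zp))
    }
    obs <- th[1]
    if (is.na(obs)) next
    perm <- th[-1]
    perm <- perm[!is.na(perm)]
    p <- (sum(perm >= obs - 1e-12) + 1) / (length(perm) + 1)
    theta[i, j] <- theta[j, i] <- obs
    pv[i, j] <- pv[j, i] <- p
  }
  structure(list(labels = labels, theta = theta, pvals = pv, n_perm = n_perm),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("pairwise F_ST over", length(x$labels), "groups (", x$n_perm,
      "permutations )\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Relabel a partition to a coarser level
#'
#' Maps each individual's group label to its locality or region, so the same
#' pairwise machinery runs at any level of the sampling hierarchy.
#'
#' @param study a [study_frame()].
#' @param level `"group"`, `"locality"` or `"region"`.
#' @return named character vector individual id -> label at `level`.
#' @export
partition_at_level <- function(study, level = c("group", "locality", "region")) {
  level <- match.arg(level)
  col <- switch(level, group = "group_id", locality = "locality_id",
                region = "region_id")
  stats::setNames(study[[col]], study$individual_id)
}

#' Holm sequential-Bonferroni significance flags
#'
#' Step-down procedure: order the m P-values ascending and reject while
#' p_(i) <= alpha / (m - i + 1); once one test fails, all later tests fail.
#'
#' @param pvals numeric vector of P-values.
#' @param alpha family-wise error rate (default 0.05).
#' @return logical vector of rejections, in the original order; `NA` inputs
#'   yield `NA` flags and do not count toward m.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  out <- rep(NA, length(pvals))
  ok <- which(!is.na(pvals))
  m <- length(ok)
  if (!m) return(out)
  o <- ok[order(pvals[ok])]
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (pvals[o[i]] <= alpha / (m - i + 1)) rej[i] <- TRUE else break
  }
  out[o] <- rej
  out
}

#' Microsatellite diversity summary
#'
#' Per-locus unbiased expected heterozygosity
#' He = n/(n-1) * (1 - sum(p_i^2)) with n the number of non-missing allele
#' copies, averaged over loci; also mean observed alleles per locus and the
#' proportion of polymorphic loci.
#'
#' @param gt a [genotype_table()].
#' @return list `mean_alleles_per_locus`, `mean_expected_heterozygosity`,
#'   `proportion_polymorphic_loci`, and per-locus vectors `he`, `n_alleles`.
#'   All-missing loci are excluded with a warning.
#' @export
diversity_summary <- function(gt) {
  L <- length(gt$locus_ids)
  he <- rep(NA_real_, L); nal <- rep(NA_integer_, L)
  for (l in seq_len(L)) {
    al <- c(gt$a1[, l], gt$a2[, l])
    al <- al[!is.na(al)]
    if (!length(al)) next
    p <- as.numeric(table(al)) / length(al)
    nal[l] <- length(p)
    he[l] <- if (length(al) > 1)
      length(al) / (length(al) - 1) * (1 - sum(p^2)) else 0
  }
  if (anyNA(he)) warning("loci with no data excluded: ",
                         paste(gt$locus_ids[is.na(he)], collapse = ", "))
  ok <- !is.na(he)
  if (!any(ok)) stop("no locus with any non-missing call")
  list(mean_alleles_per_locus = mean(nal[ok]),
       mean_expected_heterozygosity = mean(he[ok]),
       proportion_polymorphic_loci = mean(nal[ok] > 1),
       he = stats::setNames(he, gt$locus_ids),
       n_alleles = stats::setNames(nal, gt$locus_ids))
}

#' Exact test of Hardy-Weinberg equilibrium at one locus
#'
#' Conditional on the observed allele counts: full enumeration of the
#' heterozygote-count distribution for biallelic loci, and Monte-Carlo
#' shuffling of the pooled allele vector (Guo-Thompson style) for more than
#' two alleles. The P-value sums the probabilities of all genotype arrays no
#' more probable than the observed one.
#'
#' @param gt a [genotype_table()].
#' @param locus locus id or index.
#' @param n_mc Monte-Carlo replicates for the multi-allelic path.
#' @param seed optional integer seed for the Monte-Carlo path.
#' @return list `p`, `method` (`"enumeration"` or `"monte-carlo"`),
#'   `n_alleles`. Monomorphic loci are flagged `defined = FALSE`.
#' @export
hwe_exact_test <- function(gt, locus, n_mc = 9999, seed = NULL) {
  l <- if (is.character(locus)) match(locus, gt$locus_ids) else locus
  a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  u <- sort(unique(c(a1, a2)))
  if (length(u) < 2)
    return(list(p = NA_real_, method = "none", n_alleles = length(u),
                defined = FALSE))
  n <- length(a1)
  if (length(u) == 2) {
    nA <- sum(a1 == u[1]) + sum(a2 == u[1])
    hobs <- sum(a1 != a2)
    hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    logw <- vapply(hs, function(h) {
      naa <- (nA - h) / 2; nbb <- (2 * n - nA - h) / 2
      h * log(2) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
    }, numeric(1))
    w <- exp(logw - max(logw))
    pr <- w / sum(w)
    pobs <- pr[match(hobs, hs)]
    p <- sum(pr[pr <= pobs * (1 + 1e-9)])
    return(list(p = p, method = "enumeration", n_alleles = 2, defined = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  score <- function(x1, x2) {
    g1 <- pmin(x1, x2); g2 <- pmax(x1, x2)
    tab <- table(paste(g1, g2))
    sum(g1 != g2) * log(2) - sum(lfactorial(as.numeric(tab)))
  }
  obs <- score(a1, a2)
  pool <- c(a1, a2)
  cnt <- 0L
  for (k in seq_len(n_mc)) {
    perm <- sample(pool)
    s <- score(perm[seq_len(n)], perm[n + seq_len(n)])
    if (s <= obs + 1e-9) cnt <- cnt + 1L
  }
  list(p = (cnt + 1) / (n_mc + 1), method = "monte-carlo",
       n_alleles = length(u), defined = TRUE)
}
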