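# Pseudo-group randomization null for social-group differentiation:
# draw artificial groups of fixed size from the pooled marker distribution,
# recompute the pairwise F_ST P-value distribution among them, and compare
# it to the observed distribution with a rank test.

#' Draw pseudo-groups of haplotypes from the pooled spectrum
#'
#' Samples `n_iter` multisets of `group_size` haplotypes i.i.d. with
#' replacement from the pooled haplotype frequency distribution (a frequency
#' table carries no individual identity, so with-replacement sampling is the
#' natural reading).
#'
#' @param spectrum named integer vector haplotype id -> pooled count.
#' @param group_size haplotypes per pseudo-group (must exceed 1).
#' @param n_iter number of pseudo-groups.
#' @param seed optional integer seed.
#' @return list of integer vectors of haplotype ids, length `n_iter`.
#' @export
draw_pseudo_groups_haploid <- function(spectrum, group_size, n_iter,
                                       seed = NULL) {
  if (group_size <= 1) stop("group_size must exceed 1")
  if (sum(spectrum) < group_size) stop("spectrum smaller than group_size")
  if (!is.null(seed)) set.seed(seed)
  ids <- as.integer(names(spectrum))
  pr <- spectrum / sum(spectrum)
  lapply(seq_len(n_iter),
         function(i) sample(ids, group_size, replace = TRUE, prob = pr))
}

#' Draw pseudo-groups of individuals from the pooled genotype set
#'
#' @param gt a [genotype_table()].
#' @param group_size individuals per pseudo-group (must exceed 1).
#' @param n_iter number of pseudo-groups.
#' @param replace sample individuals with replacement (default) or without.
#' @param seed optional integer seed.
#' @return list of character vectors of individual ids.
#' @export
draw_pseudo_groups_diploid <- function(gt, group_size, n_iter,
                                       replace = TRUE, seed = NULL) {
  if (group_size <= 1) stop("group_size must exceed 1")
  n <- length(gt$individual_ids)
  if (!replace && group_size > n)
    stop("group_size exceeds pool for without-replacement sampling")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_iter),
         function(i) sample(gt$individual_ids, group_size, replace = replace))
}

.pseudo_hap_table <- function(draws) {
  hap <- unlist(draws)
  hap <- match(hap, sort(unique(hap)))   # dense relabeling (F_ST-invariant)
  ids <- paste0("ps", rep(seq_along(draws), lengths(draws)), "_",
                unlist(lapply(lengths(draws), seq_len)))
  part <- stats::setNames(paste0("PG", rep(seq_along(draws), lengths(draws))),
                          ids)
  ht <- haplotype_table(ids, hap)
  list(ht = ht, partition = part)
}

.pseudo_geno_table <- function(gt, draws) {
  ids_all <- unlist(draws)
  new_ids <- paste0("ps", rep(seq_along(draws), lengths(draws)), "_",
                    unlist(lapply(lengths(draws), seq_len)))
  idx <- match(ids_all, gt$individual_ids)
  g <- genotype_table(new_ids, gt$locus_ids,
                      gt$a1[idx, , drop = FALSE], gt$a2[idx, , drop = FALSE])
  part <- stats::setNames(paste0("PG", rep(seq_along(draws), lengths(draws))),
                          new_ids)
  list(gt = g, partition = part)
}

#' Mann-Whitney U test
#'
#' U for sample `x` (number of (x, y) pairs with x below y, counting ties as
#' half). Exact P from the tie-free Wilcoxon distribution when there are no
#' ties and n1*n2 <= 400; otherwise a normal approximation with continuity
#' and tie correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of `x` relative to `y`).
#' @return list `U`, `P`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p_less <- stats::pwilcox(U, n1, n2)
    p_greater <- 1 - stats::pwilcox(U - 1, n1, n2)
    P <- switch(alternative,
                less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    return(list(U = U, P = P, method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tiecor <- sum(ties^3 - ties)
  sig2 <- n1 * n2 / 12 * ((n + 1) - tiecor / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, P = 1, method = "degenerate"))
  sig <- sqrt(sig2)
  z_less <- (U - mu + 0.5) / sig
  z_greater <- (U - mu - 0.5) / sig
  P <- switch(alternative,
              less = stats::pnorm(z_less),
              greater = 1 - stats::pnorm(z_greater),
              two.sided = min(1, 2 * min(stats::pnorm(z_less),
                                         1 - stats::pnorm(z_greater))))
  list(U = U, P = max(P, 1e-300), method = "normal")
}

#' Two-proportion Z test
#'
#' Pooled-proportion Z statistic for comparing k1/n1 against k2/n2, with the
#' two-sided normal P-value.
#'
#' @param k1,n1,k2,n2 successes and trials in the two samples.
#' @return list `Z`, `P`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("invalid counts")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  den <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  if (den <= 0 || p1 == p2) return(list(Z = 0, P = 1))
  Z <- (p1 - p2) / sqrt(den)
  list(Z = Z, P = 2 * stats::pnorm(-abs(Z)))
}

#' Pseudo-group randomization test of social-group differentiation
#'
#' Compares the observed distribution of pairwise F_ST permutation P-values
#' among the real social groups with the distribution obtained among
#' `n_iter` pseudo-groups of fixed size drawn from the pooled marker
#' distribution, using a Mann-Whitney U test. Excess small observed
#' P-values indicate group differentiation beyond random assortment.
#'
#' @param data a [genotype_table()] or [haplotype_table()].
#' @param real_partition named vector individual id -> real group.
#' @param group_size pseudo-group size (caller-supplied; e.g. the mean or
#'   modal real group size).
#' @param n_iter number of pseudo-groups; all `n_iter*(n_iter-1)/2` pairs
#'   are compared.
#' @param n_perm permutations per pairwise F_ST P-value.
#' @param seed integer seed; fixes every downstream number.
#' @param alternative passed to [mann_whitney_u()]; default two-sided.
#' @param replace with-replacement pseudo-group sampling for diploid data.
#' @return object of class `randomization_result`: `observed_pvals`,
#'   `permuted_pvals`, `mw_U`, `mw_P`, `group_size`, `n_iter`, `summary`
#'   (mean and sd of both distributions).
#' @export
randomization_test <- function(data, real_partition, group_size,
                               n_iter = 100, n_perm = 999, seed = NULL,
                               alternative = "two.sided", replace = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  haploid <- inherits(data, "haplotype_table")
  if (haploid && length(data$spectrum) < 2)
    stop("degenerate data: a single haplotype, test undefined")
  n_real <- length(unique(real_partition))
  if (n_real < 3) stop("need at least 3 real groups")
  obs <- pairwise_fst_matrix(data, real_partition, n_perm = n_perm)
  observed_pvals <- obs$pvals[upper.tri(obs$pvals)]
  observed_pvals <- observed_pvals[!is.na(observed_pvals)]
  if (haploid) {
    draws <- draw_pseudo_groups_haploid(data$spectrum, group_size, n_iter)
    ps <- .pseudo_hap_table(draws)
    perm_res <- pairwise_fst_matrix(ps$ht, ps$partition, n_perm = n_perm)
  } else {
    draws <- draw_pseudo_groups_diploid(data, group_size, n_iter,
                                        replace = replace)
    ps <- .pseudo_geno_table(data, draws)
    perm_res <- pairwise_fst_matrix(ps$gt, ps$partition, n_perm = n_perm)
  }
  permuted_pvals <- perm_res$pvals[upper.tri(perm_res$pvals)]
  permuted_pvals <- permuted_pvals[!is.na(permuted_pvals)]
  mw <- mann_whitney_u(observed_pvals, permuted_pvals,
                       alternative = alternative)
  structure(list(observed_pvals = observed_pvals,
                 permuted_pvals = permuted_pvals,
                 group_size = group_size, n_iter = n_iter,
                 mw_U = mw$U, mw_P = mw$P,
                 summary = c(observed_mean = mean(observed_pvals),
                             observed_sd = stats::sd(observed_pvals),
                             permuted_mean = mean(permuted_pvals),
                             permuted_sd = stats::sd(permuted_pvals))),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "pseudo-group randomization (size %d, %d iterations)\n", x$group_size,
    x$n_iter))
  cat(sprintf("observed P: %.3f +/- %.3f (%d pairs)\n", s["observed_mean"],
              s["observed_sd"], length(x$observed_pvals)))
  cat(sprintf("permuted P: %.3f +/- %.3f (%d pairs)\n", s["permuted_mean"],
              s["permuted_sd"], length(x$permuted_pvals)))
  cat(sprintf("Mann-Whitney U = %.0f, P = %.4g\n", x$mw_U, x$mw_P))
  invisible(x)
}
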