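# Likelihood-based pairwise relatedness, parentage LOD scores with simulated
# confidence, and paternal half-sib tests for codominant multi-allelic loci.
#
# All likelihoods share one genotyping-error model: with probability e an
# observed genotype is an independent Hardy-Weinberg draw instead of the
# true genotype.

#' Pooled allele frequencies per locus
#' @param gt a [genotype_table()].
#' @return list (per locus) of named numeric frequency vectors over the
#'   observed allele codes.
#' @export
allele_frequencies <- function(gt) {
  out <- vector("list", length(gt$locus_ids))
  names(out) <- gt$locus_ids
  for (l in seq_along(gt$locus_ids)) {
    al <- c(gt$a1[, l], gt$a2[, l])
    al <- al[!is.na(al)]
    tab <- table(al)
    out[[l]] <- stats::setNames(as.numeric(tab) / length(al), names(tab))
  }
  out
}

.freq <- function(fr, allele) {
  p <- fr[as.character(allele)]
  p[is.na(p)] <- 1e-6     # allele unseen in the reference sample
  unname(p)
}

.p_geno <- function(g, fr) {
  p1 <- .freq(fr, g[1]); p2 <- .freq(fr, g[2])
  if (g[1] == g[2]) p1 * p2 else 2 * p1 * p2
}

# P(gy | one allele of gx transmitted IBD, other allele random)
.t_one <- function(gy, gx, fr) {
  k <- function(i) {
    if (gy[1] == gy[2]) (i == gy[1]) * .freq(fr, gy[1])
    else (i == gy[1]) * .freq(fr, gy[2]) + (i == gy[2]) * .freq(fr, gy[1])
  }
  0.5 * k(gx[1]) + 0.5 * k(gx[2])
}

# joint IBD-state probabilities (P0, P1, P2) of an unordered genotype pair
.pair_state_probs <- function(gx, gy, fr) {
  px <- .p_geno(gx, fr)
  p0 <- px * .p_geno(gy, fr)
  p1 <- px * .t_one(gy, gx, fr)
  same <- identical(sort(gx), sort(gy))
  p2 <- if (same) px else 0
  c(p0, p1, p2)
}

.geno_of <- function(gt, id) {
  i <- match(id, gt$individual_ids)
  if (is.na(i)) stop("unknown individual id: ", id)
  rbind(gt$a1[i, ], gt$a2[i, ])   # 2 x L
}

# k-coefficient grid on the simplex (step 0.02), built once per session
.k_grid <- local({
  grid <- NULL
  function() {
    if (is.null(grid)) {
      k1 <- seq(0, 1, by = 0.02)
      g <- expand.grid(k1 = k1, k2 = k1)
      g <- g[g$k1 + g$k2 <= 1 + 1e-12, ]
      grid <<- cbind(k0 = 1 - g$k1 - g$k2, k1 = g$k1, k2 = g$k2)
    }
    grid
  }
})

.ml_k_from_probs <- function(P, e) {
  # P: n_loci x 3 matrix of (P0, P1, P2); returns the ML (k0,k1,k2)
  err <- (2 * e - e^2) * P[, 1]
  score <- function(K) {
    lik <- (1 - e)^2 * (K %*% t(P)) +
      matrix(err, nrow(K), length(err), byrow = TRUE)
    rowSums(log(pmax(lik, 1e-300)))
  }
  G <- .k_grid()
  ll <- score(G)
  best <- G[which.max(ll), ]
  # local refinement on a fine grid around the coarse optimum
  k1f <- seq(max(0, best["k1"] - 0.02), min(1, best["k1"] + 0.02), by = 0.002)
  k2f <- seq(max(0, best["k2"] - 0.02), min(1, best["k2"] + 0.02), by = 0.002)
  gf <- expand.grid(k1 = k1f, k2 = k2f)
  gf <- gf[gf$k1 + gf$k2 <= 1 + 1e-12, ]
  Gf <- cbind(k0 = 1 - gf$k1 - gf$k2, k1 = gf$k1, k2 = gf$k2)
  llf <- score(Gf)
  kk <- Gf[which.max(llf), ]
  list(k = kk, loglik = max(llf))
}

#' Maximum-likelihood pairwise relatedness
#'
#' Maximizes, over the IBD-coefficient simplex (k0, k1, k2), the product
#' over loci of k0*P0 + k1*P1 + k2*P2, where Ps are the joint genotype-pair
#' probabilities under 0/1/2 alleles shared identical by descent given the
#' reference allele frequencies. Search is a coarse simplex grid (step 0.02)
#' followed by fine-grid refinement; the estimator is deterministic.
#' Relatedness is r = k1/2 + k2.
#'
#' @param gt a [genotype_table()].
#' @param pair character vector of two individual ids.
#' @param allele_freqs per-locus frequency list (default: pooled from `gt`).
#' @param error_rate per-genotype error rate e (an erroneous genotype is a
#'   random Hardy-Weinberg draw).
#' @return list `k0`, `k1`, `k2`, `r`, `n_loci`.
#' @export
ml_relatedness <- function(gt, pair, allele_freqs = NULL, error_rate = 0.01) {
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  gx <- .geno_of(gt, pair[1]); gy <- .geno_of(gt, pair[2])
  use <- which(!is.na(gx[1, ]) & !is.na(gy[1, ]))
  if (!length(use)) stop("no locus typed in both individuals")
  P <- t(vapply(use, function(l) {
    .pair_state_probs(gx[, l], gy[, l], allele_freqs[[l]])
  }, numeric(3)))
  res <- .ml_k_from_probs(P, error_rate)
  k <- res$k
  list(k0 = unname(k["k0"]), k1 = unname(k["k1"]), k2 = unname(k["k2"]),
       r = unname(k["k1"] / 2 + k["k2"]), n_loci = length(use))
}

#' Mean pairwise ML relatedness within a set of individuals
#' @param gt a [genotype_table()].
#' @param ids individual ids (at least two).
#' @param allele_freqs per-locus frequency list (default pooled).
#' @param error_rate per-genotype error rate.
#' @return mean of r-hat over all pairs.
#' @export
mean_pairwise_relatedness <- function(gt, ids, allele_freqs = NULL,
                                      error_rate = 0.01) {
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  if (length(ids) < 2) stop("need at least two individuals")
  pairs <- utils::combn(ids, 2)
  mean(vapply(seq_len(ncol(pairs)), function(j) {
    ml_relatedness(gt, pairs[, j], allele_freqs, error_rate)$r
  }, numeric(1)))
}

# mendelian transition probability of unordered offspring genotype
.t_mendel <- function(go, gm, gf) {
  s <- 0
  for (am in gm) for (af in gf) {
    if (identical(sort(c(am, af)), sort(go))) s <- s + 0.25
  }
  s
}

#' Parentage LOD score for a candidate father
#'
#' Log-likelihood ratio that the candidate is the father versus a random
#' male drawn from the allele frequencies, summed over loci. With the mother
#' known her genotype enters both hypotheses; with the mother missing the
#' single-parent transition probabilities are used. The error model allows
#' each genotype to be an independent Hardy-Weinberg draw with probability
#' `e`; with `e = 0` a Mendelian incompatibility gives `-Inf` (exclusion).
#'
#' @param gt a [genotype_table()].
#' @param offspring,candidate individual ids.
#' @param mother mother's id, or `NULL` when unknown.
#' @param allele_freqs per-locus frequency list (default pooled from `gt`).
#' @param e per-genotype error rate.
#' @return the LOD (natural log).
#' @export
paternity_lod <- function(gt, offspring, candidate, mother = NULL,
                          allele_freqs = NULL, e = 0.01) {
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  go <- .geno_of(gt, offspring); gf <- .geno_of(gt, candidate)
  gm <- if (!is.null(mother)) .geno_of(gt, mother)
  .paternity_lod_geno(go, gf, gm, allele_freqs, e)
}

.paternity_lod_geno <- function(go, gf, gm, allele_freqs, e) {
  L <- ncol(go)
  lod <- 0
  for (l in seq_len(L)) {
    if (is.na(go[1, l]) || is.na(gf[1, l])) next
    fr <- allele_freqs[[l]]
    ol <- go[, l]; fl <- gf[, l]
    po <- .p_geno(ol, fr)
    tf <- .t_one(ol, fl, fr)
    if (!is.null(gm) && !is.na(gm[1, l])) {
      ml <- gm[, l]
      tmf <- .t_mendel(ol, ml, fl)
      tm <- .t_one(ol, ml, fr)
      num <- e * po + (1 - e) *
        ((1 - e)^2 * tmf + e * (1 - e) * tf + (1 - e) * e * tm + e^2 * po)
      den <- e * po + (1 - e) * ((1 - e) * tm + e * po)
    } else {
      num <- e * po + (1 - e) * ((1 - e) * tf + e * po)
      den <- po
    }
    if (num == 0 && den == 0) next
    if (num == 0) return(-Inf)
    lod <- lod + log(num) - log(den)
  }
  lod
}

.hwe_draw_geno <- function(allele_freqs) {
  L <- length(allele_freqs)
  g <- matrix(0L, 2, L)
  for (l in seq_len(L)) {
    fr <- allele_freqs[[l]]
    g[, l] <- as.integer(sample(names(fr), 2, replace = TRUE, prob = fr))
  }
  g
}

.meiosis_geno <- function(gm, gf) {
  L <- ncol(gm)
  rbind(gm[cbind(sample.int(2, L, replace = TRUE), seq_len(L))],
        gf[cbind(sample.int(2, L, replace = TRUE), seq_len(L))])
}

.apply_error_geno <- function(g, allele_freqs, e) {
  if (e <= 0) return(g)
  L <- ncol(g)
  hit <- which(stats::runif(L) < e)
  for (l in hit) {
    fr <- allele_freqs[[l]]
    g[, l] <- as.integer(sample(names(fr), 2, replace = TRUE, prob = fr))
  }
  g
}

#' Simulate critical LOD-gap thresholds for parentage confidence
#'
#' Monte-Carlo simulation of the parentage design: offspring are generated from
#' random parents, candidate sets are assembled with the true father sampled
#' with probability `prop_sampled` among `n_candidates` males, LOD scores
#' and the gap Delta between the top two candidates are computed, and the
#' critical Delta at a confidence level c is the smallest gap at which the
#' fraction of correct best-candidate assignments reaches c.
#'
#' @param allele_freqs per-locus allele frequency list.
#' @param n_sim simulated offspring (a warning is issued below 1000).
#' @param n_candidates candidate males per offspring.
#' @param prop_sampled probability that the true father is in the set.
#' @param e per-genotype error rate (applied to all simulated genotypes).
#' @param with_mother simulate with the mother's genotype known.
#' @param seed optional integer seed.
#' @return list `delta95`, `delta80`, `sim` (data.frame of delta / correct).
#' @export
paternity_simulate_criticals <- function(allele_freqs, n_sim = 10000,
                                         n_candidates = 10,
                                         prop_sampled = 0.5, e = 0.01,
                                         with_mother = FALSE, seed = NULL) {
  if (n_sim < 1000)
    warning("fewer than 1000 simulated offspring; critical gaps unstable")
  if (!is.null(seed)) set.seed(seed)
  delta <- numeric(n_sim); correct <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    gm <- .hwe_draw_geno(allele_freqs)
    gf_true <- .hwe_draw_geno(allele_freqs)
    go <- .apply_error_geno(.meiosis_geno(gm, gf_true), allele_freqs, e)
    sampled <- stats::runif(1) < prop_sampled
    cands <- vector("list", n_candidates)
    truth_at <- if (sampled) sample.int(n_candidates, 1) else 0L
    for (j in seq_len(n_candidates)) {
      cands[[j]] <- if (j == truth_at)
        .apply_error_geno(gf_true, allele_freqs, e)
      else .hwe_draw_geno(allele_freqs)
    }
    gm_obs <- if (with_mother) .apply_error_geno(gm, allele_freqs, e)
    lods <- vapply(cands, function(gc)
      .paternity_lod_geno(go, gc, gm_obs, allele_freqs, e), numeric(1))
    o <- order(lods, decreasing = TRUE)
    delta[i] <- if (n_candidates > 1) lods[o[1]] - lods[o[2]] else lods[o[1]]
    correct[i] <- o[1] == truth_at
  }
  crit <- function(conf) {
    o <- order(delta, decreasing = TRUE)
    prec <- cumsum(correct[o]) / seq_len(n_sim)
    ok <- which(prec >= conf)
    if (!length(ok)) return(Inf)
    # largest prefix (smallest delta) still meeting the confidence level
    delta[o[max(ok)]]
  }
  list(delta95 = crit(0.95), delta80 = crit(0.80),
       sim = data.frame(delta = delta, correct = correct))
}

#' Assign fathers to offspring with simulated confidence tiers
#'
#' Computes LOD scores of every candidate for every offspring, takes the
#' best candidate and the gap Delta to the second best (the LOD itself when
#' only one candidate exists), and labels each assignment `strict95`,
#' `relaxed80` or `unassigned` against simulated critical gaps.
#'
#' @param gt a [genotype_table()] holding offspring and candidates.
#' @param offspring_ids character vector.
#' @param candidate_ids character vector of candidate father ids.
#' @param mothers optional named vector offspring id -> mother id (NA where
#'   unknown).
#' @param allele_freqs per-locus frequency list (default pooled from `gt`).
#' @param e per-genotype error rate.
#' @param sim list of simulation settings: `n_sim`, `n_candidates`
#'   (default: the real candidate count), `prop_sampled`.
#' @param seed integer seed for the confidence simulation.
#' @return data.frame (class `paternity_calls`): `offspring_id`,
#'   `mother_id`, `best_candidate`, `lod_best`, `delta`, `confidence`,
#'   `n_candidates`; critical gaps in attributes `delta95`/`delta80`.
#' @export
paternity_assign <- function(gt, offspring_ids, candidate_ids,
                             mothers = NULL, allele_freqs = NULL, e = 0.01,
                             sim = list(n_sim = 10000, n_candidates = NULL,
                                        prop_sampled = 0.5),
                             seed = NULL) {
  if (!length(candidate_ids)) stop("candidate set must be non-empty")
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  nc_sim <- if (is.null(sim$n_candidates)) length(candidate_ids)
            else sim$n_candidates
  with_mother <- !is.null(mothers) && any(!is.na(mothers))
  crit <- paternity_simulate_criticals(
    allele_freqs, n_sim = if (is.null(sim$n_sim)) 10000 else sim$n_sim,
    n_candidates = nc_sim,
    prop_sampled = if (is.null(sim$prop_sampled)) 0.5 else sim$prop_sampled,
    e = e, with_mother = with_mother, seed = seed)
  out <- data.frame(offspring_id = offspring_ids,
                    mother_id = NA_character_,
                    best_candidate = NA_character_,
                    lod_best = NA_real_, delta = NA_real_,
                    confidence = "unassigned",
                    n_candidates = length(candidate_ids),
                    stringsAsFactors = FALSE)
  for (i in seq_along(offspring_ids)) {
    mid <- if (!is.null(mothers)) mothers[offspring_ids[i]] else NA
    if (!is.na(mid)) out$mother_id[i] <- mid
    lods <- vapply(candidate_ids, function(cid) {
      paternity_lod(gt, offspring_ids[i], cid,
                    mother = if (is.na(mid)) NULL else mid,
                    allele_freqs = allele_freqs, e = e)
    }, numeric(1))
    o <- order(lods, decreasing = TRUE)
    out$best_candidate[i] <- candidate_ids[o[1]]
    out$lod_best[i] <- lods[o[1]]
    out$delta[i] <- if (length(lods) > 1) lods[o[1]] - lods[o[2]]
                    else lods[o[1]]
    out$confidence[i] <- if (is.finite(out$delta[i]) &&
                             out$delta[i] >= crit$delta95) "strict95"
      else if (is.finite(out$delta[i]) && out$delta[i] >= crit$delta80)
        "relaxed80"
      else "unassigned"
  }
  attr(out, "delta95") <- crit$delta95
  attr(out, "delta80") <- crit$delta80
  class(out) <- c("paternity_calls", "data.frame")
  out
}

# log likelihood ratio paternal half-sib (Rp=0.5, Rm=0) vs unrelated
.half_sib_loglr <- function(gx, gy, allele_freqs) {
  L <- ncol(gx)
  s <- 0
  for (l in seq_len(L)) {
    if (is.na(gx[1, l]) || is.na(gy[1, l])) next
    fr <- allele_freqs[[l]]
    py <- .p_geno(gy[, l], fr)
    t1 <- .t_one(gy[, l], gx[, l], fr)
    s <- s + log(0.5 + 0.5 * t1 / py)
  }
  s
}

#' Simulate the unrelated-pair null distribution of the half-sib LR
#'
#' The null depends only on the allele frequencies (and typed loci), so one
#' simulated set serves every dyad scored against the same frequencies.
#'
#' @param allele_freqs per-locus frequency list.
#' @param n_sim simulated unrelated pairs.
#' @param seed optional integer seed.
#' @return numeric vector of log likelihood ratios.
#' @export
half_sib_null <- function(allele_freqs, n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_sim), function(i) {
    .half_sib_loglr(.hwe_draw_geno(allele_freqs),
                    .hwe_draw_geno(allele_freqs), allele_freqs)
  }, numeric(1))
}

#' Paternal half-sib likelihood-ratio test for one dyad
#'
#' Log-likelihood ratio of the paternal half-sib hypothesis (paternal
#' relatedness 0.5, maternal 0) against unrelatedness, with a P-value from
#' simulated unrelated pairs; the dyad is flagged a half-sib pair when
#' P < 0.05. Monomorphic loci contribute a ratio of one (uninformative).
#'
#' @param gt a [genotype_table()].
#' @param pair character vector of two offspring ids.
#' @param allele_freqs per-locus frequency list (default pooled from `gt`).
#' @param n_sim simulated null pairs.
#' @param seed optional integer seed.
#' @param null optional pre-simulated null LR vector ([half_sib_null()]).
#' @return list `loglr`, `p`, `is_half_sib` (class `half_sib_call`).
#' @export
half_sib_test <- function(gt, pair, allele_freqs = NULL, n_sim = 1000,
                          seed = NULL, null = NULL) {
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  gx <- .geno_of(gt, pair[1]); gy <- .geno_of(gt, pair[2])
  if (!any(!is.na(gx[1, ]) & !is.na(gy[1, ])))
    stop("no locus typed in both offspring")
  obs <- .half_sib_loglr(gx, gy, allele_freqs)
  if (is.null(null)) null <- half_sib_null(allele_freqs, n_sim, seed)
  p <- (sum(null >= obs - 1e-12) + 1) / (length(null) + 1)
  structure(list(pair = pair, loglr = obs, p = p, is_half_sib = p < 0.05),
            class = "half_sib_call")
}

#' Half-sib tests for every within-group offspring dyad
#'
#' @param gt a [genotype_table()].
#' @param study a [study_frame()]; dyads are formed within groups among
#'   individuals with `age == "offspring"`.
#' @param allele_freqs per-locus frequency list (default pooled from `gt`).
#' @param n_sim simulated null pairs (shared across dyads).
#' @param seed optional integer seed.
#' @return data.frame `id1`, `id2`, `group_id`, `loglr`, `p`,
#'   `is_half_sib`.
#' @export
half_sib_matrix <- function(gt, study, allele_freqs = NULL, n_sim = 1000,
                            seed = NULL) {
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  null <- half_sib_null(allele_freqs, n_sim, seed)
  off <- study[study$age == "offspring" &
                 study$individual_id %in% gt$individual_ids, ]
  rows <- list()
  for (g in unique(off$group_id)) {
    ids <- off$individual_id[off$group_id == g]
    if (length(ids) < 2) next
    pr <- utils::combn(ids, 2)
    for (j in seq_len(ncol(pr))) {
      hs <- half_sib_test(gt, pr[, j], allele_freqs, null = null)
      rows[[length(rows) + 1]] <- data.frame(
        id1 = pr[1, j], id2 = pr[2, j], group_id = g, loglr = hs$loglr,
        p = hs$p, is_half_sib = hs$is_half_sib, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(id1 = character(), id2 = character(),
                                       group_id = character(),
                                       loglr = numeric(), p = numeric(),
                                       is_half_sib = logical()))
  do.call(rbind, rows)
}

#' Count sires per group from half-sib calls
#'
#' Partitions each group's offspring into paternal sibships by transitive
#' closure over significant half-sib links; the inferred number of sires is
#' the number of sibships (singletons count as their own sire).
#'
#' @param calls data.frame from [half_sib_matrix()].
#' @param offspring_by_group named list group id -> offspring ids (includes
#'   offspring with no tested partner).
#' @return data.frame `group_id`, `n_offspring`, `n_sires`; attributes
#'   `mean`, `median`, `mode` of the per-group counts.
#' @export
sires_per_group <- function(calls, offspring_by_group) {
  res <- data.frame(group_id = names(offspring_by_group),
                    n_offspring = lengths(offspring_by_group),
                    n_sires = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    ids <- offspring_by_group[[i]]
    parent <- stats::setNames(seq_along(ids), ids)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    cg <- calls[calls$group_id == res$group_id[i] & calls$is_half_sib, ,
                drop = FALSE]
    for (j in seq_len(nrow(cg))) {
      r1 <- find(match(cg$id1[j], ids)); r2 <- find(match(cg$id2[j], ids))
      if (r1 != r2) parent[r2] <- r1
    }
    res$n_sires[i] <- length(unique(vapply(seq_along(ids), find,
                                           numeric(1))))
  }
  counts <- res$n_sires[res$n_offspring > 0]
  attr(res, "mean") <- mean(counts)
  attr(res, "median") <- stats::median(counts)
  tb <- table(counts)
  attr(res, "mode") <- as.integer(names(tb)[which.max(tb)])
  res
}

#' Estimate the per-allele genotyping error rate from repeat genotyping
#'
#' Compares original and repeated calls of the same individuals: the rate is
#' the number of mismatching allele calls over the total compared (missing
#' calls excluded). Each diploid call contributes two allele comparisons,
#' matched as unordered pairs.
#'
#' @param original,repeats [genotype_table()]s over the same individuals
#'   and loci (the repeat table may cover a subset).
#' @return list `rate`, `mismatches`, `compared`.
#' @export
estimate_error_rate <- function(original, repeats) {
  ids <- intersect(original$individual_ids, repeats$individual_ids)
  loci <- intersect(original$locus_ids, repeats$locus_ids)
  if (!length(ids) || !length(loci)) stop("no overlapping calls to compare")
  mism <- 0L; comp <- 0L
  for (id in ids) {
    i1 <- match(id, original$individual_ids)
    i2 <- match(id, repeats$individual_ids)
    for (lc in loci) {
      l1 <- match(lc, original$locus_ids); l2 <- match(lc, repeats$locus_ids)
      g1 <- c(original$a1[i1, l1], original$a2[i1, l1])
      g2 <- c(repeats$a1[i2, l2], repeats$a2[i2, l2])
      if (anyNA(g1) || anyNA(g2)) next
      comp <- comp + 2L
      g1 <- sort(g1); g2 <- sort(g2)
      shared <- 0L
      tmp <- g2
      for (a in g1) {
        hit <- match(a, tmp)
        if (!is.na(hit)) { shared <- shared + 1L; tmp <- tmp[-hit] }
      }
      mism <- mism + (2L - shared)
    }
  }
  if (comp == 0L) return(list(rate = NA_real_, mismatches = 0L,
                              compared = 0L))
  list(rate = mism / comp, mismatches = mism, compared = comp)
}

#' Regression of offspring on adult-female relatedness across groups
#'
#' For each group with at least two adult females and two offspring, the
#' mean pairwise ML relatedness among adult females (x) and among offspring
#' (y) is computed; y is regressed on x by ordinary least squares. A
#' negative slope indicates that groups of closely related females carry
#' less related offspring (multiple sires).
#'
#' @param gt a [genotype_table()].
#' @param study a [study_frame()].
#' @param allele_freqs per-locus frequency list (default pooled from `gt`).
#' @param error_rate per-genotype error rate for the relatedness estimator.
#' @param min_per_class minimum adult females and offspring per group.
#' @return list `slope`, `intercept`, `r2`, `fstat` (`c(F, df1, df2)`),
#'   `p`, `table` (per-group means), `excluded` (group ids dropped).
#' @export
female_offspring_regression <- function(gt, study, allele_freqs = NULL,
                                        error_rate = 0.01,
                                        min_per_class = 2) {
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gt)
  groups <- unique(study$group_id)
  tab <- data.frame(group_id = character(), r_females = numeric(),
                    r_offspring = numeric(), stringsAsFactors = FALSE)
  excluded <- character()
  for (g in groups) {
    fem <- study$individual_id[study$group_id == g & study$sex == "F" &
                                 study$age == "adult"]
    off <- study$individual_id[study$group_id == g &
                                 study$age == "offspring"]
    fem <- intersect(fem, gt$individual_ids)
    off <- intersect(off, gt$individual_ids)
    if (length(fem) < min_per_class || length(off) < min_per_class) {
      excluded <- c(excluded, g); next
    }
    tab <- rbind(tab, data.frame(
      group_id = g,
      r_females = mean_pairwise_relatedness(gt, fem, allele_freqs,
                                            error_rate),
      r_offspring = mean_pairwise_relatedness(gt, off, allele_freqs,
                                              error_rate),
      stringsAsFactors = FALSE))
  }
  if (nrow(tab) < 3) stop("need at least 3 usable groups")
  fit <- stats::lm(r_offspring ~ r_females, data = tab)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared, fstat = unname(fs),
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       table = tab, excluded = excluded)
}
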