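test_that("identical genotypes at polymorphic loci give k2 and r near 1", {
  set.seed(71)
  fr <- flat_freqs(10, 10)
  g <- hwe_genotypes(1, fr, "x")
  gt <- genotype_table(c("x", "y"), g$locus_ids,
                       rbind(g$a1[1, ], g$a1[1, ]),
                       rbind(g$a2[1, ], g$a2[1, ]))
  r <- ml_relatedness(gt, c("x", "y"), fr, error_rate = 0.01)
  expect_gt(r$k2, 0.9)
  expect_gt(r$r, 0.9)
  expect_equal(r$k0 + r$k1 + r$k2, 1, tolerance = 1e-9)
})

test_that("relatedness estimates are invariant to allele relabeling", {
  set.seed(72)
  fr <- flat_freqs(8, 6)
  gt <- hwe_genotypes(2, fr)
  base <- ml_relatedness(gt, gt$individual_ids, fr)$r
  relab <- genotype_table(gt$individual_ids, gt$locus_ids,
                          pmin(7L - gt$a1, 7L - gt$a2),
                          pmax(7L - gt$a1, 7L - gt$a2))
  fr2 <- lapply(fr, function(p) stats::setNames(rev(p), 7 - as.integer(rev(names(p)))))
  expect_equal(ml_relatedness(relab, gt$individual_ids, fr2)$r, base,
               tolerance = 1e-9)
})

test_that("parentage LOD: closed form, exclusion, degenerate candidate", {
  fr <- list(c(`1` = 0.5, `2` = 0.5))
  gt <- genotype_table(c("m", "o", "c"), "L1", matrix(c(1L, 1L, 2L)),
                       matrix(c(1L, 2L, 2L)))
  expect_equal(paternity_lod(gt, "o", "c", "m", fr, e = 0), log(2),
               tolerance = 1e-12)
  fr3 <- list(c(`1` = 0.4, `2` = 0.3, `3` = 0.3))
  gt2 <- genotype_table(c("m", "o", "c"), "L1", matrix(c(1L, 1L, 3L)),
                        matrix(c(2L, 1L, 3L)))
  expect_equal(paternity_lod(gt2, "o", "c", "m", fr3, e = 0), -Inf)
  # with a positive error rate the exclusion softens to a finite penalty
  expect_true(is.finite(paternity_lod(gt2, "o", "c", "m", fr3, e = 0.01)))
})

test_that("true fathers get positive LOD at informative panels", {
  set.seed(73)
  fr <- msat_freqs(10)
  pos <- replicate(100, {
    gm <- harempop:::.hwe_draw_geno(fr)
    gf <- harempop:::.hwe_draw_geno(fr)
    go <- harempop:::.meiosis_geno(gm, gf)
    harempop:::.paternity_lod_geno(go, gf, gm, fr, 0.01) > 0
  })
  expect_gte(mean(pos), 0.95)
})

test_that("paternity assignment semantics: single candidate, tiers", {
  set.seed(74)
  fr <- msat_freqs(10)
  gm <- harempop:::.hwe_draw_geno(fr)
  gf <- harempop:::.hwe_draw_geno(fr)
  go <- harempop:::.meiosis_geno(gm, gf)
  pack <- function(g) c(g[1, ], g[2, ])
  gt <- genotype_table(c("o", "f"), paste0("L", 1:10),
                       rbind(go[1, ], gf[1, ]), rbind(go[2, ], gf[2, ]))
  suppressWarnings(
    pa <- paternity_assign(gt, "o", "f", allele_freqs = fr, e = 0.01,
                           sim = list(n_sim = 800, n_candidates = 1,
                                      prop_sampled = 0.5), seed = 9))
  expect_equal(pa$best_candidate, "f")
  expect_equal(pa$delta, pa$lod_best)   # single candidate: gap is the LOD
})

test_that("unrelated candidate pools yield few strict assignments", {
  set.seed(75)
  fr <- msat_freqs(10)
  n_off <- 60
  offs <- lapply(seq_len(n_off), function(i)
    harempop:::.meiosis_geno(harempop:::.hwe_draw_geno(fr),
                             harempop:::.hwe_draw_geno(fr)))
  cands <- lapply(1:8, function(i) harempop:::.hwe_draw_geno(fr))
  ids <- c(paste0("o", seq_len(n_off)), paste0("c", 1:8))
  a1 <- do.call(rbind, lapply(c(offs, cands), function(g) g[1, ]))
  a2 <- do.call(rbind, lapply(c(offs, cands), function(g) g[2, ]))
  gt <- genotype_table(ids, paste0("L", 1:10), pmin(a1, a2), pmax(a1, a2))
  pa <- paternity_assign(gt, ids[seq_len(n_off)], ids[n_off + 1:8],
                         allele_freqs = fr, e = 0.01,
                         sim = list(n_sim = 2000, prop_sampled = 0.5),
                         seed = 10)
  expect_lte(mean(pa$confidence == "strict95"), 0.05 + 0.08)
})

test_that("half-sib LR: uninformative loci, unshared alleles, rare sharing", {
  fr_mono <- list(c(`1` = 1))
  gt <- genotype_table(c("a", "b"), "L1", matrix(c(1L, 1L)),
                       matrix(c(1L, 1L)))
  hs <- half_sib_test(gt, c("a", "b"), fr_mono, n_sim = 50, seed = 1)
  expect_equal(hs$loglr, 0, tolerance = 1e-12)   # ratio 1 per locus
  # no shared alleles anywhere: LR below 1
  fr <- flat_freqs(6, 8)
  gt2 <- genotype_table(c("a", "b"), paste0("L", 1:6),
                        matrix(rep(c(1L, 3L), each = 6), 2, 6, byrow = TRUE),
                        matrix(rep(c(2L, 4L), each = 6), 2, 6, byrow = TRUE))
  hs2 <- half_sib_test(gt2, c("a", "b"), fr, n_sim = 200, seed = 2)
  expect_lt(hs2$loglr, 0)
  expect_false(hs2$is_half_sib)
  # identical genotypes at rare alleles: significant
  fr_rare <- lapply(1:8, function(l)
    stats::setNames(c(0.9, rep(0.02, 5)), 1:6))
  a <- matrix(5L, 2, 8); b <- matrix(6L, 2, 8)
  gt3 <- genotype_table(c("a", "b"), paste0("L", 1:8), a, b)
  hs3 <- half_sib_test(gt3, c("a", "b"), fr_rare, n_sim = 1000, seed = 3)
  expect_lte(hs3$p, 0.05)
})

test_that("half-sib false-positive rate sits at the nominal level", {
  set.seed(76)
  fr <- msat_freqs(10)
  null <- half_sib_null(fr, 1500, seed = 4)
  rej <- replicate(400, {
    lr <- harempop:::.half_sib_loglr(harempop:::.hwe_draw_geno(fr),
                                     harempop:::.hwe_draw_geno(fr), fr)
    (sum(null >= lr - 1e-12) + 1) / (length(null) + 1) < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("sires_per_group closure handles the extreme call patterns", {
  obg <- list(g1 = paste0("o", 1:4))
  all_sig <- data.frame(id1 = c("o1", "o1", "o1", "o2", "o2", "o3"),
                        id2 = c("o2", "o3", "o4", "o3", "o4", "o4"),
                        group_id = "g1", loglr = 1, p = 0.01,
                        is_half_sib = TRUE)
  expect_equal(sires_per_group(all_sig, obg)$n_sires, 1L)
  none <- all_sig; none$is_half_sib <- FALSE; none$p <- 0.9
  expect_equal(sires_per_group(none, obg)$n_sires, 4L)
  # chain closure: o1-o2 and o2-o3 significant links one sibship of 3
  chain <- all_sig[c(1, 4), ]
  expect_equal(sires_per_group(chain, obg)$n_sires, 2L)
})

test_that("error-rate estimator counts allele mismatches", {
  gt <- random_small_gt(10, 5, 6, seed = 77)
  expect_equal(estimate_error_rate(gt, gt)$rate, 0)
  gt2 <- gt
  gt2$a1[1, 1] <- gt$a1[1, 1] + 50L   # one mismatching allele call
  r <- estimate_error_rate(gt, gt2)
  expect_equal(r$mismatches, 1L)
  expect_equal(r$rate, 1 / r$compared)
  expect_equal(r$compared, 100L)
})

test_that("female-offspring regression: exact line and exclusions", {
  sim <- simulate_colony(sim_config(seed = 12, groups_per_region = 3,
                                    females_per_group = c(4, 8)))
  fo <- female_offspring_regression(sim$gt, sim$study)
  fit <- lm(r_offspring ~ r_females, data = fo$table)
  expect_equal(fo$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(fo$r2, summary(fit)$r.squared, tolerance = 1e-12)
  # groups without enough offspring are excluded and reported
  few <- sim$study
  drop_g <- few$group_id[few$age == "offspring"][1]
  few <- few[!(few$group_id == drop_g & few$age == "offspring"), ]
  fo2 <- female_offspring_regression(sim$gt, study_frame(few))
  expect_true(drop_g %in% fo2$excluded)
})
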