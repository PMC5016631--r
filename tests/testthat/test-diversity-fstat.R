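test_that("expected heterozygosity matches hand computation", {
  # one locus, alleles 1 and 2 each twice over 2 diploids: He = 4/3 * 0.5
  gt <- genotype_table(c("a", "b"), "L1", matrix(c(1L, 2L)),
                       matrix(c(1L, 2L)))
  d <- diversity_summary(gt)
  expect_equal(d$mean_expected_heterozygosity, 2 / 3, tolerance = 1e-12)
  # monomorphic locus: He 0, not polymorphic
  gt2 <- genotype_table(c("a", "b"), c("L1", "L2"),
                        matrix(c(1L, 2L, 5L, 5L), 2),
                        matrix(c(1L, 2L, 5L, 5L), 2))
  d2 <- diversity_summary(gt2)
  expect_equal(unname(d2$he["L2"]), 0)
  expect_equal(d2$proportion_polymorphic_loci, 0.5)
})

test_that("hwe exact test: enumeration cases", {
  # (AA, Aa, aa) = (1, 2, 1): every table is at most as probable -> P = 1
  gt <- genotype_table(paste0("i", 1:4), "L1", matrix(c(1L, 1L, 1L, 2L)),
                       matrix(c(1L, 2L, 2L, 2L)))
  expect_equal(hwe_exact_test(gt, 1)$p, 1, tolerance = 1e-12)
  # 50 heterozygotes, no homozygotes: extreme heterozygote excess
  gt2 <- genotype_table(paste0("i", 1:50), "L1",
                        matrix(rep(1L, 50)), matrix(rep(2L, 50)))
  expect_lt(hwe_exact_test(gt2, 1)$p, 0.01)
  # monomorphic locus undefined
  gt3 <- genotype_table(c("a", "b"), "L1", matrix(c(1L, 1L)),
                        matrix(c(1L, 1L)))
  expect_false(hwe_exact_test(gt3, 1)$defined)
})

test_that("wc theta: fixed difference gives 1, panmixia is centred at 0", {
  gt <- genotype_table(paste0("i", 1:20), "L1",
                       matrix(c(rep(1L, 10), rep(2L, 10))),
                       matrix(c(rep(1L, 10), rep(2L, 10))))
  part <- stats::setNames(rep(c("A", "B"), each = 10), gt$individual_ids)
  expect_equal(wc_fst(gt, part)$theta, 1, tolerance = 1e-12)
  set.seed(31)
  th <- replicate(100, {
    g <- hwe_genotypes(200, flat_freqs(3, 5))
    p <- stats::setNames(rep(c("A", "B"), each = 100), g$individual_ids)
    wc_fst(g, p)$theta
  })
  expect_lt(abs(mean(th)), 0.005)
})

test_that("wc theta and f match the independent variance-components oracle", {
  set.seed(32)
  for (rep in 1:10) {
    gt <- random_small_gt(12, 3, 4)
    ids <- gt$individual_ids
    part <- stats::setNames(rep(c("A", "B"), each = 6), ids)
    got <- wc_fst(gt, part)
    want <- oracle_wc(gt, list(ids[1:6], ids[7:12]))
    expect_equal(got$theta, want$theta, tolerance = 1e-12)
    expect_equal(fis(gt, ids[1:6])$f, oracle_f_single(gt, ids[1:6]),
                 tolerance = 1e-12)
  }
})

test_that("theta is invariant to allele relabeling and individual order", {
  set.seed(33)
  gt <- random_small_gt(10, 2, 4)
  part <- stats::setNames(rep(c("A", "B"), each = 5), gt$individual_ids)
  base <- wc_fst(gt, part)$theta
  relab <- genotype_table(gt$individual_ids, gt$locus_ids,
                          10L - gt$a1, 10L - gt$a2)
  # relabeled codes swap a1/a2 ordering; rebuild as unordered
  relab <- genotype_table(gt$individual_ids, gt$locus_ids,
                          pmin(10L - gt$a1, 10L - gt$a2),
                          pmax(10L - gt$a1, 10L - gt$a2))
  expect_equal(wc_fst(relab, part)$theta, base, tolerance = 1e-12)
  perm <- sample(gt$individual_ids)
  gtp <- subset_genotypes(gt, perm)
  expect_equal(wc_fst(gtp, part[perm])$theta, base, tolerance = 1e-12)
})

test_that("haplotype theta: fixed difference 1, identical spectra <= 0", {
  ht <- haplotype_table(paste0("i", 1:20), rep(c(1L, 2L), each = 10))
  part <- stats::setNames(rep(c("A", "B"), each = 10),
                          paste0("i", 1:20))
  expect_equal(haplotype_fst(ht, part)$theta, 1, tolerance = 1e-12)
  ht2 <- haplotype_table(paste0("i", 1:20), rep(c(1L, 2L), 10))
  expect_lte(haplotype_fst(ht2, part)$theta, 0)
  set.seed(34)
  th <- replicate(100, {
    hap <- sample(1:5, 60, TRUE)
    h <- haplotype_table(paste0("i", 1:60), hap)
    p <- stats::setNames(sample(rep(c("A", "B"), each = 30)),
                         paste0("i", 1:60))
    haplotype_fst(h, p)$theta
  })
  expect_lt(abs(mean(th)), 0.02)
})

test_that("fis: heterozygote-excess limit and monomorphic flagging", {
  gt <- genotype_table(paste0("i", 1:10), "L1",
                       matrix(rep(1L, 10)), matrix(rep(2L, 10)))
  expect_equal(fis(gt)$f, -1, tolerance = 1e-12)
  gt2 <- genotype_table(paste0("i", 1:5), "L1",
                        matrix(rep(1L, 5)), matrix(rep(1L, 5)))
  expect_false(fis(gt2)$defined)
  set.seed(35)
  fbar <- replicate(100, {
    g <- hwe_genotypes(100, flat_freqs(2, 6))
    fis(g)$f
  })
  expect_lt(abs(mean(fbar)), 0.02)
})

test_that("pairwise matrix: determinism, minimal P, clone groups", {
  set.seed(36)
  gt <- hwe_genotypes(24, flat_freqs(3, 6))
  part <- stats::setNames(rep(c("A", "B", "C"), each = 8),
                          gt$individual_ids)
  r1 <- pairwise_fst_matrix(gt, part, n_perm = 99, seed = 7)
  r2 <- pairwise_fst_matrix(gt, part, n_perm = 99, seed = 7)
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$pvals, r2$pvals)
  expect_true(all(r1$pvals[upper.tri(r1$pvals)] >= 1 / 100))
  # fixed difference: smallest achievable P
  gtf <- genotype_table(paste0("i", 1:20), "L1",
                        matrix(c(rep(1L, 10), rep(2L, 10))),
                        matrix(c(rep(1L, 10), rep(2L, 10))))
  pf <- stats::setNames(rep(c("A", "B"), each = 10), gtf$individual_ids)
  rf <- pairwise_fst_matrix(gtf, pf, n_perm = 999, seed = 1)
  expect_equal(rf$pvals[1, 2], 1 / 1000, tolerance = 1e-12)
  # two clones of one group: high P
  gtc <- hwe_genotypes(30, flat_freqs(3, 6))
  pc <- stats::setNames(rep(c("A", "B"), 15), gtc$individual_ids)
  rc <- pairwise_fst_matrix(gtc, pc, n_perm = 199, seed = 2)
  expect_gt(rc$pvals[1, 2], 0.1)
})

test_that("undersized groups are flagged undefined, not errored", {
  set.seed(37)
  gt <- hwe_genotypes(11, flat_freqs(2, 4))
  part <- stats::setNames(c(rep("A", 1), rep("B", 5), rep("C", 5)),
                          gt$individual_ids)
  r <- pairwise_fst_matrix(gt, part, n_perm = 49, seed = 1)
  expect_true(is.na(r$theta["A", "B"]))
  expect_false(is.na(r$theta["B", "C"]))
})

test_that("sequential bonferroni matches the hand-stepped rule", {
  expect_equal(sequential_bonferroni(c(0.001, 0.04, 0.5), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(sequential_bonferroni(rep(1, 5)), rep(FALSE, 5))
  set.seed(38)
  for (rep in 1:20) {
    p <- runif(15)^2
    expect_equal(sequential_bonferroni(p), oracle_holm(p))
  }
  # against stats::p.adjust as an independent cross-check
  p <- c(0.001, 0.01, 0.02, 0.2, 0.9)
  expect_equal(sequential_bonferroni(p),
               unname(p.adjust(p, "holm") <= 0.05))
})

test_that("holm controls family-wise error under the null", {
  set.seed(39)
  fwer <- mean(replicate(2000, any(sequential_bonferroni(runif(66)))))
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("partition_at_level relabels to the sampling hierarchy", {
  sim <- simulate_colony(sim_config(seed = 3, groups_per_region = 2,
                                    females_per_group = c(3, 4)))
  pg <- partition_at_level(sim$study, "group")
  pr <- partition_at_level(sim$study, "region")
  expect_equal(length(unique(pg)), 4)
  expect_equal(length(unique(pr)), 2)
  expect_equal(names(pg), sim$study$individual_id)
})
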