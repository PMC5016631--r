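test_that("the generator is byte-identical under a fixed seed", {
  s1 <- simulate_colony(sim_config(seed = 81, groups_per_region = 2,
                                   females_per_group = c(3, 6)))
  s2 <- simulate_colony(sim_config(seed = 81, groups_per_region = 2,
                                   females_per_group = c(3, 6)))
  expect_identical(s1$gt, s2$gt)
  expect_identical(s1$alignment$sequence, s2$alignment$sequence)
  expect_identical(s1$habitat$values, s2$habitat$values)
  expect_identical(s1$truth$philopatry, s2$truth$philopatry)
})

test_that("full philopatry with one matriline shares one haplotype per group", {
  sim <- simulate_colony(sim_config(seed = 82, philopatry = 1,
                                    matrilines_per_group = 1,
                                    mut_per_transmission = 0,
                                    groups_per_region = 3,
                                    females_per_group = c(4, 8)))
  fem <- sim$study[sim$study$role == "female", ]
  for (g in unique(fem$group_id)) {
    seqs <- sim$alignment$sequence[match(
      fem$individual_id[fem$group_id == g], sim$alignment$id)]
    expect_equal(length(unique(seqs)), 1)
  }
})

test_that("no extra-group paternity makes all pups paternal sibs in truth", {
  sim <- simulate_colony(sim_config(seed = 83, extra_group_paternity = 0,
                                    groups_per_region = 3,
                                    females_per_group = c(4, 8)))
  ped <- sim$truth$pedigree
  off <- ped[!is.na(ped$father_id), ]
  for (g in unique(off$group_id)) {
    expect_equal(length(unique(off$father_id[off$group_id == g])), 1)
  }
})

test_that("realized diversity hits the calibrated targets", {
  stats <- vapply(1:20, function(s) {
    d <- diversity_summary(simulate_colony(sim_config(seed = 8300 + s))$gt)
    c(d$mean_expected_heterozygosity, d$mean_alleles_per_locus)
  }, numeric(2))
  expect_gt(mean(stats[1, ]), 0.56)
  expect_lt(mean(stats[1, ]), 0.66)
  expect_gte(mean(stats[2, ]), 8)
  expect_lte(mean(stats[2, ]), 11)
})

test_that("planted distinct sequences collapse to the planted count", {
  set.seed(84)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, 300, replace = TRUE)
  seqs <- vapply(1:49, function(h) {
    s <- anc
    s[h] <- setdiff(bases, s[h])[1]   # one private substitution each
    paste(s, collapse = "")
  }, character(1))
  copies <- sample(49, 187, replace = TRUE)
  aln <- alignment_table(paste0("ind", 1:187), seqs[copies])
  ht <- collapse_haplotypes(aln)
  expect_equal(length(ht$spectrum), length(unique(copies)))
})

test_that("inconsistent sire knobs raise a config error", {
  expect_error(sim_config(groups_per_region = 2, n_sires = 5,
                          prop_extra_sires_sampled = 1),
               "n_sires exceeds")
  expect_error(sim_config(philopatry = 1.2), "philopatry")
  expect_error(sim_config(females_per_group = c(10, 4)), "range")
})

test_that("philopatry knob raises female relatedness and group F_IS", {
  stat_at <- function(phi) {
    vals <- vapply(1:6, function(s) {
      sim <- simulate_colony(sim_config(seed = 8500 + s + round(phi * 37),
                                        philopatry = phi,
                                        females_per_group = c(6, 12)))
      ft <- fis_table(sim$gt, sim$study)
      fr <- allele_frequencies(sim$gt)
      fem <- sim$study[sim$study$role == "female", ]
      rf <- mean(vapply(unique(fem$group_id)[1:4], function(g) {
        ids <- fem$individual_id[fem$group_id == g]
        mean_pairwise_relatedness(sim$gt, ids, fr)
      }, numeric(1)))
      c(mean(ft$fis, na.rm = TRUE), rf)
    }, numeric(2))
    rowMeans(vals)
  }
  lo <- stat_at(0.05); mid <- stat_at(0.5); hi <- stat_at(0.95)
  expect_lt(lo[1], mid[1]); expect_lt(mid[1], hi[1])   # F_IS
  expect_lt(lo[2], mid[2]); expect_lt(mid[2], hi[2])   # female relatedness
})

test_that("more sires lower offspring relatedness in expectation", {
  r_at <- function(ns) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_colony(sim_config(seed = 8600 + s + ns,
                                        couple_sires_to_philopatry = FALSE,
                                        n_sires = ns, philopatry = 0,
                                        females_per_group = c(8, 12)))
      fr <- allele_frequencies(sim$gt)
      off <- sim$study[sim$study$age == "offspring", ]
      gs <- unique(off$group_id)
      mean(vapply(gs[1:4], function(g) {
        ids <- off$individual_id[off$group_id == g]
        if (length(ids) < 2) return(NA_real_)
        mean_pairwise_relatedness(sim$gt, ids, fr)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1)))
  }
  expect_gt(r_at(1), r_at(5))
})

test_that("truth record scores the generator's own bookkeeping", {
  sim <- simulate_colony(sim_config(seed = 86, groups_per_region = 2,
                                    females_per_group = c(3, 5)))
  ped <- sim$truth$pedigree
  # every offspring has a recorded mother and father
  off <- sim$study$individual_id[sim$study$age == "offspring"]
  po <- ped[match(off, ped$individual_id), ]
  expect_false(anyNA(po$mother_id))
  expect_false(anyNA(po$father_id))
  # recorded sires match the pedigree's father set per group
  for (g in names(sim$truth$sires_by_group)) {
    expect_setequal(sim$truth$sires_by_group[[g]],
                    unique(po$father_id[po$group_id == g]))
  }
})
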