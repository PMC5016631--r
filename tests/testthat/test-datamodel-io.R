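test_that("genotype_table enforces whole-call missingness and positive codes", {
  expect_error(genotype_table(c("a", "b"), "L1",
                              matrix(c(1L, NA)), matrix(c(2L, 3L))),
               "half-missing")
  expect_error(genotype_table("a", "L1", matrix(0L), matrix(1L)),
               "positive")
  gt <- genotype_table(c("a", "b"), c("L1", "L2"),
                       matrix(c(1L, NA, 2L, 2L), 2),
                       matrix(c(2L, NA, 2L, 3L), 2))
  expect_equal(unname(missing_per_individual(gt)), c(0L, 1L))
  f <- filter_missing_individuals(gt, max_missing = 0)
  expect_equal(f$dropped, "b")
  expect_equal(f$gt$individual_ids, "a")
})

test_that("study_frame validates the grouping hierarchy", {
  df <- data.frame(individual_id = c("a", "b"), group_id = c("g1", "g1"),
                   sex = c("F", "M"), age = c("adult", "adult"),
                   locality_id = c("l1", "l2"), region_id = c("r1", "r1"),
                   role = c("female", "harem_male"))
  expect_error(study_frame(df), "several localities")
  df$locality_id <- "l1"
  expect_s3_class(study_frame(df), "study_frame")
  df2 <- df
  df2$age[1] <- "offspring"; df2$role[1] <- "female"
  expect_s3_class(study_frame(df2), "study_frame")
  df2$role[1] <- "offspring"; df2$age[1] <- "adult"
  expect_error(study_frame(df2), "age 'offspring'")
})

test_that("dist_matrix rejects asymmetry and nonzero diagonals", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(dist_matrix(c("a", "b"), m), "symmetric")
  m2 <- matrix(c(1, 2, 2, 0), 2)
  expect_error(dist_matrix(c("a", "b"), m2), "diagonal")
  expect_s3_class(dist_matrix(c("a", "b"), matrix(c(0, 2, 2, 0), 2)),
                  "dist_matrix")
})

test_that("genepop round-trips generated genotypes byte-identically", {
  set.seed(11)
  for (rep in 1:3) {
    gt <- random_small_gt(6, 3, 5)
    gt$a1[2, 1] <- NA; gt$a2[2, 1] <- NA     # one missing call
    pops <- list(gt$individual_ids[1:3], gt$individual_ids[4:6])
    f <- tempfile(fileext = ".gen")
    write_genepop(gt, f, pops)
    rt <- read_genepop(f)
    expect_equal(rt$gt$individual_ids, gt$individual_ids)
    expect_equal(rt$gt$locus_ids, gt$locus_ids)
    expect_equal(rt$gt$a1, gt$a1)
    expect_equal(rt$gt$a2, gt$a2)
    expect_equal(rt$pops, pops)
    # byte-level: writing the parse again reproduces the same file
    f2 <- tempfile(fileext = ".gen")
    write_genepop(rt$gt, f2, rt$pops)
    expect_identical(readLines(f), readLines(f2))
    unlink(c(f, f2))
  }
})

test_that("genepop parser flags ragged records, missing codes and widths", {
  f <- tempfile()
  writeLines(c("title", "L1", "L2", "pop",
               "ind1 , 0102 0304", "ind2 , 0102"), f)
  expect_error(read_genepop(f), "ragged")
  writeLines(c("title", "L1", "pop", "ind1 , 01023"), f)
  expect_error(read_genepop(f), "width")
  writeLines(c("title", "L1", "L2", "pop",
               "ind1 , 0000 0304", "ind2 , 0102 0304"), f)
  gp <- read_genepop(f)
  expect_true(is.na(gp$gt$a1[1, 1]) && is.na(gp$gt$a2[1, 1]))
  expect_equal(gp$gt$a1[1, 2], 3L)
  unlink(f)
})

test_that("fasta alignment reader enforces shape and round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTACGT", ">b", "ACGTACGAACGT",
               ">c", "ACGTACGTACGA"), f)
  aln <- read_fasta_alignment(f)
  expect_equal(nrow(aln), 3)
  expect_equal(attr(aln, "length"), 12L)
  f2 <- tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, f2)
  expect_equal(read_fasta_alignment(f2)$sequence, aln$sequence)
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), f)
  expect_error(read_fasta_alignment(f), "length mismatch")
  writeLines(character(), f)
  expect_error(read_fasta_alignment(f))
  unlink(c(f, f2))
})

test_that("collapse_haplotypes assigns ids by first appearance", {
  aln <- alignment_table(c("a", "b", "c"), c("AAA", "AAT", "AAA"))
  ht <- collapse_haplotypes(aln)
  expect_equal(unname(ht$haplotype_id), c(1L, 2L, 1L))
  expect_equal(unname(ht$spectrum), c(2L, 1L))
  aln4 <- alignment_table(paste0("s", 1:4), rep("ACGT", 4))
  expect_equal(unname(collapse_haplotypes(aln4)$spectrum), 4L)
})

test_that("collapse_haplotypes handles ambiguity per policy", {
  aln <- alignment_table(c("a", "b", "c"), c("ACGT", "ACNT", "ACAT"))
  compat <- collapse_haplotypes(aln, "compatible")
  # b is compatible with a (N at the varying site) and merges with it
  expect_equal(unname(compat$haplotype_id), c(1L, 1L, 2L))
  exact <- collapse_haplotypes(aln, "exact")
  expect_equal(unname(exact$haplotype_id), c(1L, 2L, 3L))
  # all-ambiguous record is missing
  aln2 <- alignment_table(c("a", "b"), c("ACGT", "NNNN"))
  expect_true(is.na(collapse_haplotypes(aln2)$haplotype_id[["b"]]))
})

test_that("collapse is order-invariant up to relabeling; spectrum exactly", {
  set.seed(21)
  seqs <- apply(matrix(sample(c("A", "C", "G", "T"), 5 * 20, TRUE), 5),
                1, paste, collapse = "")
  seqs <- seqs[c(1, 1, 2, 3, 3, 3, 4, 5)]
  aln <- alignment_table(paste0("s", seq_along(seqs)), seqs)
  perm <- sample(seq_along(seqs))
  aln_p <- alignment_table(aln$id[perm], aln$sequence[perm])
  h1 <- collapse_haplotypes(aln)
  h2 <- collapse_haplotypes(aln_p)
  expect_equal(sort(unname(h1$spectrum)), sort(unname(h2$spectrum)))
  # same partition of individuals into haplotype classes
  split1 <- split(aln$id, h1$haplotype_id[aln$id])
  split2 <- split(aln$id, h2$haplotype_id[aln$id])
  expect_setequal(lapply(split1, sort), lapply(split2, sort))
})

test_that("haplotype_table enforces dense ids and spectrum bookkeeping", {
  expect_error(haplotype_table(c("a", "b"), c(1L, 3L)), "dense")
  ht <- haplotype_table(c("a", "b", "c"), c(1L, NA, 2L))
  expect_equal(sum(ht$spectrum), 2L)
})

test_that("habitat_matrix validates set tags and completeness", {
  v <- matrix(1:4, 2, dimnames = list(NULL, c("x", "y")))
  expect_error(habitat_matrix(c("g1", "g2"), v, c("structural", "roost")),
               "scale_set")
  v2 <- v; v2[1, 1] <- NA
  expect_error(habitat_matrix(c("g1", "g2"), v2,
                              c("structural", "microhabitat")), "complete")
  hm <- habitat_matrix(c("g1", "g2"), v,
                       c("structural", "macrohabitat"))
  expect_s3_class(hm, "habitat_matrix")
})
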