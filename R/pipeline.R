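#' Group composition summary
#'
#' Per social group: number of adult males, adult females and offspring,
#' the group inbreeding coefficient when supplied, and the region; a totals
#' row is appended. Groups present in the frame but empty are dropped with
#' a warning.
#'
#' @param study a [study_frame()].
#' @param fis optional [fis_table()] to join.
#' @return data.frame with one row per group plus a `Total` row.
#' @export
tabulate_groups <- function(study, fis = NULL) {
  groups <- unique(study$group_id)
  rows <- lapply(groups, function(g) {
    s <- study[study$group_id == g, ]
    if (!nrow(s)) return(NULL)
    data.frame(group_id = g,
               n_adult_males = sum(s$sex == "M" & s$age == "adult"),
               n_adult_females = sum(s$sex == "F" & s$age == "adult"),
               n_offspring = sum(s$age == "offspring"),
               fis = if (!is.null(fis)) fis$fis[match(g, fis$group_id)]
                     else NA_real_,
               region_id = s$region_id[1], stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning("empty groups dropped")
  out <- do.call(rbind, rows[!empty])
  total <- data.frame(group_id = "Total",
                      n_adult_males = sum(out$n_adult_males),
                      n_adult_females = sum(out$n_adult_females),
                      n_offspring = sum(out$n_offspring),
                      fis = NA_real_, region_id = "",
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

.stage_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %%
  .Machine$integer.max

#' Run the full multi-level analysis pipeline
#'
#' Executes the workflow in dependency order: haplotype collapsing,
#' diversity summary, group composition, per-group inbreeding coefficients
#' (all / adult females / offspring), pairwise F_ST with permutation
#' significance at group, locality and region level for both markers,
#' the pseudo-group randomization null, the isolation-by-distance Mantel
#' test, habitat variance partitioning, and the kinship/paternity stage
#' (parentage tiers, half-sib sires per group, the female-versus-offspring
#' relatedness regression). Every stochastic stage gets its own seed
#' derived from the master seed, so stages are independently reproducible.
#' A failing stage is recorded and its dependents are skipped.
#'
#' @param data list with elements `gt`, `alignment` (or `ht`), `study`,
#'   `habitat`, `coords` — e.g. the output of [simulate_colony()].
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, per-stage TSV/JSON
#'   outputs and the serialized configuration are written there.
#' @param n_perm_fst permutations for pairwise F_ST P-values.
#' @param group_sizes pseudo-group sizes for the randomization null.
#' @param n_iter pseudo-groups per randomization run.
#' @param n_perm_rand permutations per replicate F_ST P-value in the
#'   randomization stage.
#' @param n_perm_mantel Mantel permutations.
#' @param n_perm_partition permutations for partition fraction P-values.
#' @param n_sim_halfsib simulated null pairs for half-sib tests.
#' @param n_sim_paternity simulated offspring for parentage confidence.
#' @param error_rate genotyping error rate used by the likelihood stages.
#' @return list of stage results (class `harempop_run`); failed stages
#'   appear as `list(error = <message>)`, skipped ones as
#'   `list(skipped = <reason>)`.
#' @export
run_pipeline <- function(data, seed = 1L, out_dir = NULL,
                         n_perm_fst = 999, group_sizes = c(11, 15),
                         n_iter = 100, n_perm_rand = 199,
                         n_perm_mantel = 999, n_perm_partition = 199,
                         n_sim_halfsib = 1000, n_sim_paternity = 2000,
                         error_rate = 0.01) {
  res <- list(config = list(seed = seed, n_perm_fst = n_perm_fst,
                            group_sizes = group_sizes, n_iter = n_iter,
                            n_perm_rand = n_perm_rand,
                            n_perm_mantel = n_perm_mantel,
                            n_perm_partition = n_perm_partition,
                            n_sim_halfsib = n_sim_halfsib,
                            n_sim_paternity = n_sim_paternity,
                            error_rate = error_rate))
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
    res[[name]] <<- out
    out
  }
  failed <- function(x) is.list(x) && !is.null(x[["error"]])

  gt <- data$gt; study <- data$study
  ht <- if (!is.null(data$ht)) data$ht else
    stage("haplotypes", collapse_haplotypes(data$alignment))
  if (failed(ht)) ht <- NULL

  stage("diversity", diversity_summary(gt))
  fis_all <- stage("fis_all", fis_table(gt, study, "all"))
  stage("fis_females", fis_table(gt, study, "adult_females"))
  stage("fis_offspring", fis_table(gt, study, "offspring"))
  stage("group_table",
        tabulate_groups(study, if (!failed(fis_all)) fis_all))

  for (lev in c("group", "locality", "region")) {
    part <- partition_at_level(study, lev)
    stage(paste0("fst_msat_", lev),
          pairwise_fst_matrix(gt, part, n_perm = n_perm_fst,
                              seed = .stage_seed(seed, 1L)))
    if (!is.null(ht)) {
      stage(paste0("fst_mtdna_", lev),
            pairwise_fst_matrix(ht, part, n_perm = n_perm_fst,
                                seed = .stage_seed(seed, 2L)))
    } else {
      res[[paste0("fst_mtdna_", lev)]] <- list(skipped = "no haplotypes")
    }
  }
  if (!is.null(res$fst_msat_group) && !failed(res$fst_msat_group)) {
    pv <- res$fst_msat_group$pvals
    res$fst_msat_group_holm <- sequential_bonferroni(pv[upper.tri(pv)])
  }

  part_g <- partition_at_level(study, "group")
  for (gs in group_sizes) {
    stage(paste0("randomization_msat_", gs),
          randomization_test(gt, part_g, gs, n_iter = n_iter,
                             n_perm = n_perm_rand,
                             seed = .stage_seed(seed, 3L + gs)))
    if (!is.null(ht)) {
      stage(paste0("randomization_mtdna_", gs),
            randomization_test(ht, part_g, gs, n_iter = n_iter,
                               n_perm = n_perm_rand,
                               seed = .stage_seed(seed, 4L + gs)))
    }
  }

  if (!is.null(data$coords) && !failed(res$fst_msat_group)) {
    geo <- coord_distances(data$coords)
    th <- res$fst_msat_group$theta[geo$labels, geo$labels]
    th[is.na(th)] <- 0
    gen <- dist_matrix(geo$labels, (th + t(th)) / 2)
    stage("ibd", mantel_test(gen, geo, n_perm = n_perm_mantel,
                             seed = .stage_seed(seed, 7L)))
  } else res$ibd <- list(skipped = "no coordinates or no F_ST matrix")

  if (!is.null(data$habitat) && !failed(fis_all)) {
    ok <- fis_all$defined & is.finite(fis_all$fis)
    if (sum(ok) >= 8) {
      y <- fis_all$fis[match(data$habitat$group_ids, fis_all$group_id)]
      stage("partition",
            variance_partition(y, data$habitat, n_perm = n_perm_partition,
                               seed = .stage_seed(seed, 8L)))
    } else res$partition <- list(skipped = "too few defined group F_IS")
  } else res$partition <- list(skipped = "no habitat data")

  off <- study$individual_id[study$age == "offspring"]
  if (length(off) >= 2) {
    fr <- allele_frequencies(gt)
    males <- study$individual_id[study$role == "harem_male"]
    if (length(males)) {
      stage("paternity",
            paternity_assign(gt, off, males, allele_freqs = fr,
                             e = error_rate,
                             sim = list(n_sim = n_sim_paternity,
                                        prop_sampled = 0.5),
                             seed = .stage_seed(seed, 9L)))
    }
    hs <- stage("half_sibs",
                half_sib_matrix(gt, study, fr, n_sim = n_sim_halfsib,
                                seed = .stage_seed(seed, 10L)))
    if (!failed(hs)) {
      obg <- split(study$individual_id[study$age == "offspring"],
                   study$group_id[study$age == "offspring"])
      obg <- obg[lengths(obg) > 0]
      stage("sires", sires_per_group(hs, obg))
    }
    stage("relatedness_regression",
          female_offspring_regression(gt, study, fr,
                                      error_rate = error_rate))
  } else {
    res$paternity <- res$half_sibs <- res$sires <-
      res$relatedness_regression <- list(skipped = "no offspring in study")
  }

  class(res) <- "harempop_run"
  if (!is.null(out_dir)) .write_bundle(res, out_dir)
  res
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  wr <- function(df, name) utils::write.table(
    df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  if (is.data.frame(res$group_table)) wr(res$group_table, "group_table")
  for (nm in grep("^fst_", names(res), value = TRUE)) {
    x <- res[[nm]]
    if (inherits(x, "fst_result")) {
      wr(as.data.frame(x$theta), paste0(nm, "_theta"))
      wr(as.data.frame(x$pvals), paste0(nm, "_pvals"))
    }
  }
  for (nm in grep("^randomization_", names(res), value = TRUE)) {
    x <- res[[nm]]
    if (inherits(x, "randomization_result")) {
      n <- max(length(x$observed_pvals), length(x$permuted_pvals))
      wr(data.frame(observed = c(x$observed_pvals,
                                 rep(NA, n - length(x$observed_pvals))),
                    permuted = c(x$permuted_pvals,
                                 rep(NA, n - length(x$permuted_pvals)))),
         nm)
    }
  }
  if (inherits(res$paternity, "paternity_calls")) wr(res$paternity,
                                                     "paternity")
  if (is.data.frame(res$half_sibs)) wr(res$half_sibs, "half_sibs")
  if (is.data.frame(res$sires)) wr(res$sires, "sires")
  summ <- list()
  if (!is.null(res$diversity$mean_expected_heterozygosity))
    summ$diversity <- res$diversity[c("mean_alleles_per_locus",
                                      "mean_expected_heterozygosity",
                                      "proportion_polymorphic_loci")]
  if (inherits(res$ibd, "mantel_result"))
    summ$ibd <- res$ibd[c("r", "P")]
  if (inherits(res$partition, "partition_result"))
    summ$partition <- list(fractions = as.list(res$partition$fractions),
                           total_R2 = res$partition$total_R2)
  if (is.list(res$relatedness_regression) &&
        !is.null(res$relatedness_regression$slope))
    summ$relatedness_regression <-
      res$relatedness_regression[c("slope", "r2", "p")]
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.harempop_run <- function(x, ...) {
  nm <- setdiff(names(x), "config")
  status <- vapply(nm, function(n) {
    if (is.list(x[[n]]) && !is.null(x[[n]][["error"]])) "FAILED"
    else if (is.list(x[[n]]) && !is.null(x[[n]][["skipped"]])) "skipped"
    else "ok"
  }, character(1))
  cat("pipeline run:", sum(status == "ok"), "stages ok,",
      sum(status == "FAILED"), "failed,", sum(status == "skipped"),
      "skipped\n")
  if (any(status != "ok"))
    for (n in nm[status != "ok"]) cat(" -", n, ":", status[match(n, nm)],
                                      "\n")
  invisible(x)
}
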