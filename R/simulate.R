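# Forward generator of harem-structured colonies: two weakly diverged
# regions of social groups, each one harem male plus females that are a
# mixture of matriline recruits (philopatry) and immigrants, offspring sired
# by one or several males, maternally transmitted mtDNA, and group-level
# habitat covariates that drive philopatry through the structural set.

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) <= 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Simulation configuration for a harem-structured colony
#'
#' Defaults emulate a two-region study of twelve social groups (one harem
#' male, 4-24 adult females and roughly one pup per female each), ten
#' microsatellite loci with about 9-10 alleles per locus and expected
#' heterozygosity near 0.61, a 1140-bp maternally inherited haplotype
#' locus, and an average of three sires per group.
#'
#' @param n_regions number of regions.
#' @param groups_per_region social groups per region.
#' @param localities_per_region localities per region (groups assigned
#'   round-robin).
#' @param females_per_group integer range (min, max) of adult females.
#' @param males_per_group harem males per group.
#' @param offspring_per_female expected pups per female; the integer part
#'   is deterministic and the fractional part a Bernoulli draw (0.8 gives
#'   one pup for 80 percent of females, 2 gives two pups each).
#' @param n_loci microsatellite loci.
#' @param alleles_per_locus size of the founder allele pool per locus.
#' @param dirichlet_major,dirichlet_alpha shape parameters of the founder
#'   allele-frequency Dirichlet: one major-allele component with shape
#'   `dirichlet_major` and `alleles_per_locus - 1` minor components with
#'   shape `dirichlet_alpha`. The defaults (4 and 0.3 over a pool of 12)
#'   are calibrated once so realized mean expected heterozygosity is near
#'   0.61 with 9-10 observed alleles per locus at the default sample
#'   sizes.
#' @param mtdna_length haplotype sequence length (bp).
#' @param n_founder_haplotypes founder mtDNA haplotypes.
#' @param hap_concentration Dirichlet concentration of the haplotype
#'   spectrum (small values give a few common and many rare haplotypes).
#' @param mut_per_transmission expected new substitutions per maternal
#'   transmission.
#' @param philopatry either `NULL` (philopatry is generated from the
#'   structural habitat covariates) or a fixed per-group value in `[0, 1]`.
#' @param matrilines_per_group number of founding matrilines per group;
#'   recruits are spread across them (1 makes all philopatric females of a
#'   group share a single haplotype).
#' @param philopatry_base baseline philopatry when habitat-driven.
#' @param habitat_effect strength of the structural-covariate effect on
#'   philopatry (0 = no link).
#' @param philopatry_noise_sd group-level noise on philopatry.
#' @param n_sires target number of males siring a group's offspring.
#' @param couple_sires_to_philopatry if `TRUE`, the realized sire number is
#'   1 + Binomial(2*(n_sires-1), philopatry^sire_coupling_power), so more
#'   philopatric groups draw more extra-group sires (mean `n_sires` at
#'   philopatry 0.5 when the coupling power is 1).
#' @param sire_coupling_power exponent on philopatry inside the coupling;
#'   values above 1 delay the rise of the sire number to strongly
#'   philopatric groups.
#' @param extra_group_paternity if non-`NULL`, overrides the sire mechanism:
#'   each pup is sired by the harem male with probability
#'   `1 - extra_group_paternity`, otherwise by a random regional male.
#' @param prop_extra_sires_sampled probability an extra-group sire is
#'   another sampled harem male rather than an unsampled male.
#' @param inbred_recruit_prob probability a matriline recruit stems from a
#'   within-matriline mating (long male tenure), which elevates group F_IS.
#' @param genotyping_error per-genotype error rate applied to the emitted
#'   calls (an erroneous call is a random Hardy-Weinberg draw).
#' @param regional_divergence drift parameter of the founder-frequency
#'   perturbation between regions (F-model).
#' @param seed integer seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_regions = 2, groups_per_region = 6,
                       localities_per_region = c(3, 4),
                       females_per_group = c(4, 24), males_per_group = 1,
                       offspring_per_female = 0.8, n_loci = 10,
                       alleles_per_locus = 12, dirichlet_major = 4,
                       dirichlet_alpha = 0.3,
                       mtdna_length = 1140, n_founder_haplotypes = 40,
                       hap_concentration = 0.35, mut_per_transmission = 0.05,
                       philopatry = NULL, matrilines_per_group = 4,
                       philopatry_base = 0.5,
                       habitat_effect = 1, philopatry_noise_sd = 0.06,
                       n_sires = 3, couple_sires_to_philopatry = TRUE,
                       sire_coupling_power = 1,
                       extra_group_paternity = NULL,
                       prop_extra_sires_sampled = 0.5,
                       inbred_recruit_prob = 0.9,
                       genotyping_error = 0.01,
                       regional_divergence = 0.005, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_regions >= 1, groups_per_region >= 1, n_loci >= 1,
            alleles_per_locus >= 2, mtdna_length >= 10,
            n_founder_haplotypes >= 1, males_per_group >= 1)
  if (any(females_per_group < 1) || females_per_group[1] >
        females_per_group[2])
    stop("females_per_group must be an increasing positive range")
  rates <- c(prop_extra_sires_sampled, inbred_recruit_prob,
             genotyping_error, philopatry_base)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (offspring_per_female < 0) stop("offspring_per_female must be >= 0")
  if (!is.null(philopatry) && any(philopatry < 0 | philopatry > 1))
    stop("philopatry must lie in [0, 1]")
  if (regional_divergence <= 0 || regional_divergence >= 1)
    stop("regional_divergence must lie in (0, 1)")
  if (n_sires < 1) stop("n_sires must be at least 1")
  if (sire_coupling_power <= 0) stop("sire_coupling_power must be positive")
  if (matrilines_per_group < 1) stop("matrilines_per_group must be >= 1")
  avail <- groups_per_region * males_per_group
  if (is.null(extra_group_paternity) && n_sires > avail &&
        prop_extra_sires_sampled >= 1)
    stop("n_sires exceeds available sampled males and no unsampled ",
         "or extra-group route is allowed")
  class(cfg) <- "sim_config"
  cfg
}

.mutate_seq <- function(s, n_mut) {
  if (n_mut <= 0) return(s)
  bases <- c("A", "C", "G", "T")
  v <- strsplit(s, "")[[1]]
  sites <- sample.int(length(v), min(n_mut, length(v)))
  for (i in sites) v[i] <- sample(setdiff(bases, v[i]), 1)
  paste(v, collapse = "")
}

#' Simulate a harem-structured colony
#'
#' Forward simulation over a short pedigree: founder allele frequencies are
#' drawn once, perturbed per region (F-model with drift
#' `regional_divergence`); each group's adult females are matriline recruits
#' with probability `philopatry` (sharing the group matriarch's haplotype,
#' with elevated autosomal kinship and, with probability
#' `inbred_recruit_prob`, pedigree inbreeding from within-matriline mating)
#' or immigrants from the regional pool; pups are sired by the harem male or
#' extra-group males; mtDNA is transmitted maternally with per-transmission
#' mutation; genotyping errors are applied at the configured rate.
#'
#' @param cfg a [sim_config()].
#' @return list with `gt` ([genotype_table()]), `alignment`
#'   (`alignment_table` of mtDNA sequences), `study` ([study_frame()]),
#'   `habitat` ([habitat_matrix()]), `coords` (data.frame `group_id`, `x`,
#'   `y` in km) and `truth` (pedigree, per-group sires, matrilines,
#'   philopatry, founder haplotypes, region frequencies, config).
#' @export
simulate_colony <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  n_groups <- cfg$n_regions * cfg$groups_per_region
  allele_codes <- seq(102, by = 2, length.out = cfg$alleles_per_locus)

  # founder and regional allele frequencies (F-model)
  shape <- c(cfg$dirichlet_major,
             rep(cfg$dirichlet_alpha, cfg$alleles_per_locus - 1))
  global_fr <- lapply(seq_len(cfg$n_loci), function(l) {
    stats::setNames(.rdirichlet(sample(shape)), allele_codes)
  })
  Fm <- cfg$regional_divergence
  region_fr <- lapply(seq_len(cfg$n_regions), function(r) {
    lapply(global_fr, function(p)
      stats::setNames(.rdirichlet(p * (1 - Fm) / Fm), names(p)))
  })

  # founder mtDNA haplotypes and per-region spectra
  anc <- paste(sample(bases, cfg$mtdna_length, replace = TRUE),
               collapse = "")
  founder_haps <- character(cfg$n_founder_haplotypes)
  for (h in seq_len(cfg$n_founder_haplotypes)) {
    repeat {
      s <- .mutate_seq(anc, stats::rpois(1, 4) + 1)
      if (!s %in% founder_haps[seq_len(h - 1)]) break
    }
    founder_haps[h] <- s
  }
  hap_w_global <- .rdirichlet(rep(cfg$hap_concentration,
                                  cfg$n_founder_haplotypes))
  hap_w <- lapply(seq_len(cfg$n_regions), function(r)
    .rdirichlet(hap_w_global * (1 - Fm) / Fm))

  draw_hap <- function(r) {
    s <- founder_haps[sample.int(cfg$n_founder_haplotypes, 1,
                                 prob = hap_w[[r]])]
    .mutate_seq(s, stats::rpois(1, cfg$mut_per_transmission))
  }
  transmit_hap <- function(s) .mutate_seq(s, stats::rpois(
    1, cfg$mut_per_transmission))
  hwe <- function(r) .hwe_draw_geno(region_fr[[r]])

  # geography: regions ~85 km apart, localities spread inside regions
  loc_per_reg <- rep_len(cfg$localities_per_region, cfg$n_regions)
  region_centers <- cbind(x = (seq_len(cfg$n_regions) - 1) * 85, y = 0)
  group_region <- rep(seq_len(cfg$n_regions), each = cfg$groups_per_region)
  group_loc <- unlist(lapply(seq_len(cfg$n_regions), function(r)
    paste0("L", r, "_", rep_len(seq_len(loc_per_reg[r]),
                                cfg$groups_per_region))))
  loc_centers <- list()
  coords <- data.frame(group_id = paste0("G", seq_len(n_groups)),
                       x = NA_real_, y = NA_real_)
  for (i in seq_len(n_groups)) {
    lc <- group_loc[i]
    if (is.null(loc_centers[[lc]]))
      loc_centers[[lc]] <- region_centers[group_region[i], ] +
        stats::runif(2, -7, 7)
    coords$x[i] <- loc_centers[[lc]][1] + stats::rnorm(1, 0, 0.5)
    coords$y[i] <- loc_centers[[lc]][2] + stats::rnorm(1, 0, 0.5)
  }

  # habitat covariates; structural set drives philopatry
  tent_height <- stats::rnorm(n_groups, 8, 2)
  plant_height <- tent_height + stats::rnorm(n_groups, 3, 1.5)
  coconut <- stats::rbinom(n_groups, 1, 0.6)
  n_trees <- stats::rpois(n_groups, 10)
  light <- stats::rnorm(n_groups, 50, 15)
  herb_cover <- stats::rnorm(n_groups, 40, 20)
  human_modified <- stats::rbinom(n_groups, 1, 0.7)
  dist_forest <- round(stats::rexp(n_groups, 2) * human_modified, 3)
  hab <- habitat_matrix(
    coords$group_id,
    cbind(tent_height = tent_height, plant_height = plant_height,
          coconut = coconut, n_trees = n_trees, light = light,
          herb_cover = herb_cover, human_modified = human_modified,
          dist_forest = dist_forest),
    c("structural", "structural", "structural", "microhabitat",
      "microhabitat", "microhabitat", "macrohabitat", "macrohabitat"))

  if (is.null(cfg$philopatry)) {
    zt <- as.numeric(scale(tent_height))
    zc <- coconut - mean(coconut)
    phi <- cfg$philopatry_base +
      cfg$habitat_effect * (0.25 * zt + 0.15 * zc) +
      stats::rnorm(n_groups, 0, cfg$philopatry_noise_sd)
    phi <- pmin(pmax(phi, 0.02), 0.98)
  } else {
    phi <- rep_len(cfg$philopatry, n_groups)
  }

  ids <- character(); a1 <- NULL; a2 <- NULL
  seqs <- character(); meta <- list(); ped <- list()
  sires_by_group <- stats::setNames(vector("list", n_groups),
                                    coords$group_id)
  matriline_hap <- character(n_groups)
  genos <- list()   # id -> 2 x L matrix (pre-error)

  add_ind <- function(id, g, geno, hap, sex, age, role) {
    genos[[id]] <<- geno
    ids <<- c(ids, id)
    seqs <<- c(seqs, hap)
    meta[[length(meta) + 1]] <<- data.frame(
      individual_id = id, group_id = coords$group_id[g], sex = sex,
      age = age, locality_id = group_loc[g],
      region_id = paste0("R", group_region[g]), role = role,
      stringsAsFactors = FALSE)
  }

  harem_males <- stats::setNames(vector("list", n_groups), coords$group_id)
  females_of <- stats::setNames(vector("list", n_groups), coords$group_id)
  mothers_hap <- list(); mothers_geno <- list()

  for (g in seq_len(n_groups)) {
    r <- group_region[g]
    gid <- coords$group_id[g]
    # founding matrilines: each a matriarch (unsampled) and a resident
    # within-matriline male (her son), the sire of inbred recruits
    k_mat <- cfg$matrilines_per_group
    mat_geno <- lapply(seq_len(k_mat), function(j) hwe(r))
    mat_hap <- vapply(seq_len(k_mat), function(j) draw_hap(r), character(1))
    son_geno <- lapply(mat_geno, function(mg) .meiosis_geno(mg, hwe(r)))
    matriline_hap[g] <- mat_hap[1]
    for (m in seq_len(cfg$males_per_group)) {
      id <- paste0(gid, "_M", m)
      add_ind(id, g, hwe(r), draw_hap(r), "M", "adult", "harem_male")
      harem_males[[gid]] <- c(harem_males[[gid]], id)
      ped[[length(ped) + 1]] <- data.frame(
        individual_id = id, mother_id = NA, father_id = NA,
        group_id = gid, philopatric = NA, stringsAsFactors = FALSE)
    }
    n_f <- sample(seq(cfg$females_per_group[1], cfg$females_per_group[2]), 1)
    for (f in seq_len(n_f)) {
      id <- paste0(gid, "_F", f)
      philo <- stats::runif(1) < phi[g]
      if (philo) {
        j <- sample.int(k_mat, 1)
        father <- if (stats::runif(1) < cfg$inbred_recruit_prob)
          son_geno[[j]] else hwe(r)
        geno <- .meiosis_geno(mat_geno[[j]], father)
        hap <- transmit_hap(mat_hap[j])
        mother_id <- paste0(gid, "_MAT", j)
      } else {
        geno <- hwe(r)
        hap <- draw_hap(r)
        mother_id <- NA
      }
      add_ind(id, g, geno, hap, "F", "adult", "female")
      females_of[[gid]] <- c(females_of[[gid]], id)
      mothers_hap[[id]] <- hap
      mothers_geno[[id]] <- geno
      ped[[length(ped) + 1]] <- data.frame(
        individual_id = id, mother_id = mother_id, father_id = NA,
        group_id = gid, philopatric = philo, stringsAsFactors = FALSE)
    }
  }

  # offspring and sires
  unsampled_n <- 0L
  for (g in seq_len(n_groups)) {
    r <- group_region[g]
    gid <- coords$group_id[g]
    moms <- females_of[[gid]]
    opf <- cfg$offspring_per_female
    n_pups <- floor(opf) +
      (stats::runif(length(moms)) < (opf - floor(opf)))
    has_pup <- rep(moms, n_pups)
    if (!length(has_pup)) { sires_by_group[[gid]] <- character(); next }
    if (!is.null(cfg$extra_group_paternity)) {
      sire_of <- vapply(has_pup, function(m) {
        if (stats::runif(1) < cfg$extra_group_paternity) "EXTRA"
        else harem_males[[gid]][1]
      }, character(1))
      extra_idx <- which(sire_of == "EXTRA")
      pool <- NULL
    } else {
      k <- if (cfg$couple_sires_to_philopatry)
        1 + stats::rbinom(1, 2 * (cfg$n_sires - 1),
                          phi[g]^cfg$sire_coupling_power)
      else cfg$n_sires
      k <- min(k, length(has_pup))
      pool <- harem_males[[gid]][1]
      while (length(pool) < k) {
        if (stats::runif(1) < cfg$prop_extra_sires_sampled) {
          others <- setdiff(unlist(harem_males[group_region ==
                                                 r & seq_len(n_groups) != g]),
                            pool)
          if (length(others)) {
            pool <- c(pool, sample(others, 1)); next
          }
        }
        unsampled_n <- unsampled_n + 1L
        uid <- paste0("U", unsampled_n)
        genos[[uid]] <- hwe(r)
        pool <- c(pool, uid)
      }
      sire_of <- stats::setNames(sample(pool, length(has_pup),
                                        replace = TRUE), has_pup)
    }
    for (j in seq_along(has_pup)) {
      mom <- has_pup[j]
      sid <- sire_of[j]
      if (identical(unname(sid), "EXTRA")) {
        unsampled_n <- unsampled_n + 1L
        sid <- paste0("U", unsampled_n)
        genos[[sid]] <- hwe(r)
      }
      oid <- paste0(gid, "_O", j)
      geno <- .meiosis_geno(mothers_geno[[mom]], genos[[sid]])
      hap <- transmit_hap(mothers_hap[[mom]])
      add_ind(oid, g, geno, hap,
              sample(c("F", "M"), 1), "offspring", "offspring")
      ped[[length(ped) + 1]] <- data.frame(
        individual_id = oid, mother_id = mom, father_id = sid,
        group_id = gid, philopatric = NA, stringsAsFactors = FALSE)
      sires_by_group[[gid]] <- union(sires_by_group[[gid]], sid)
    }
  }

  # emit genotype table with genotyping error
  L <- cfg$n_loci
  a1 <- matrix(NA_integer_, length(ids), L)
  a2 <- matrix(NA_integer_, length(ids), L)
  n_error_calls <- 0L
  for (i in seq_along(ids)) {
    gobs <- genos[[ids[i]]]
    if (cfg$genotyping_error > 0) {
      pre <- gobs
      gobs <- .apply_error_geno(gobs, region_fr[[1]], cfg$genotyping_error)
      n_error_calls <- n_error_calls + sum(colSums(pre != gobs) > 0)
    }
    a1[i, ] <- pmin(gobs[1, ], gobs[2, ])
    a2[i, ] <- pmax(gobs[1, ], gobs[2, ])
  }
  gt <- genotype_table(ids, paste0("loc", seq_len(L)), a1, a2)
  study <- study_frame(do.call(rbind, meta))
  aln <- alignment_table(ids, seqs)
  truth <- list(pedigree = do.call(rbind, ped),
                sires_by_group = sires_by_group,
                philopatry = stats::setNames(phi, coords$group_id),
                matriline_hap = matriline_hap,
                founder_haplotypes = founder_haps,
                region_frequencies = region_fr,
                n_error_calls = n_error_calls,
                config = cfg)
  list(gt = gt, alignment = aln, study = study, habitat = hab,
       coords = coords, truth = truth)
}

#' Synthetic clustering log-likelihood table with a planted kink
#'
#' Generates per-K, per-run log-likelihoods whose mean curve rises steeply
#' up to `K_true` and flattens after it, with run-level Gaussian noise: a
#' test fixture for [evanno_delta_k()].
#'
#' @param K_max largest K (from 1).
#' @param K_true planted number of clusters (>= 2).
#' @param n_runs runs per K.
#' @param noise_sd run-level standard deviation (0 gives the degenerate
#'   sd = 0 path).
#' @param seed optional integer seed.
#' @return data.frame `K`, `run`, `lnP`.
#' @export
simulate_lnk_table <- function(K_max = 8, K_true = 2, n_runs = 3,
                               noise_sd = 5, seed = NULL) {
  if (K_true < 2) stop("K_true must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  Ks <- seq_len(K_max)
  mu <- -5000 + 400 * pmin(Ks, K_true) + 15 * pmax(Ks - K_true, 0)
  out <- expand.grid(run = seq_len(n_runs), K = Ks)[, c("K", "run")]
  out$lnP <- mu[out$K] + stats::rnorm(nrow(out), 0, noise_sd)
  out
}
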