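# Canned simulation scenarios used by the validation suites. Each is a
# thin wrapper around sim_config() that fixes the knobs defining one study
# regime; everything not listed stays at the calibrated defaults.

#' Canned simulation scenarios
#'
#' Named parameterizations of [sim_config()] for the regimes the validation
#' suites exercise:
#'
#' * `scenario_panmictic`: no philopatry, single region, one matriline
#'   effect removed — groups are random draws from one pool (null regime
#'   for calibration checks).
#' * `scenario_philopatric`: strong fixed philopatry, so matriline
#'   structure dominates group composition (power regime for the
#'   pseudo-group randomization test).
#' * `scenario_coupled_mating`: philopatry driven hard by the structural
#'   habitat (bimodal across groups), philopatric females outbred but
#'   mating with many extra-group males (sire number coupled to
#'   philopatry squared); 24 larger groups with two pups per female for a
#'   stable relatedness regression.
#' * `scenario_habitat_driven`: 24 groups whose philopatry is a strong,
#'   low-noise function of the structural covariates (variance
#'   partitioning regime).
#' * `scenario_sire_recovery`: fixed number of sires per group
#'   (uncoupled), one pup per female and unrelated mothers, so pups are
#'   related through fathers only (the paternal-sibship regime the
#'   half-sib test assumes), for scoring sibship reconstruction against
#'   truth.
#'
#' @param seed integer seed.
#' @param ... further overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
scenario_panmictic <- function(seed, ...) {
  sim_config(seed = seed, philopatry = 0, n_regions = 1,
             groups_per_region = 12, localities_per_region = 3,
             extra_group_paternity = 1, ...)
}

#' @rdname scenario_panmictic
#' @export
scenario_philopatric <- function(seed, ...) {
  sim_config(seed = seed, philopatry = 0.9, matrilines_per_group = 2, ...)
}

#' @rdname scenario_panmictic
#' @export
scenario_coupled_mating <- function(seed, ...) {
  sim_config(seed = seed, habitat_effect = 3, philopatry_noise_sd = 0.02,
             inbred_recruit_prob = 0, matrilines_per_group = 1,
             offspring_per_female = 2, females_per_group = c(8, 14),
             n_sires = 8, sire_coupling_power = 2, groups_per_region = 12,
             ...)
}

#' @rdname scenario_panmictic
#' @export
scenario_habitat_driven <- function(seed, ...) {
  sim_config(seed = seed, groups_per_region = 12, habitat_effect = 3,
             philopatry_noise_sd = 0.02, ...)
}

#' @rdname scenario_panmictic
#' @export
scenario_sire_recovery <- function(seed, ...) {
  sim_config(seed = seed, couple_sires_to_philopatry = FALSE, n_sires = 3,
             offspring_per_female = 1, females_per_group = c(10, 14),
             philopatry = 0, genotyping_error = 0, ...)
}
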