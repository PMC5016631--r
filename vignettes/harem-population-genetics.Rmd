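---
title: "Multi-scale population genetics of harem-forming social groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale population genetics of harem-forming social groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harempop)
```

## The problem

Many colonial mammals live in harems: one resource-defending male, a set of
adult females, and their dependent young. Whether such groups are kin
structured depends on female natal philopatry (daughters recruiting into
the natal group), on how many males sire a group's offspring, and — the
question this package is built around — on whether those quantities track
habitat features of the roost at several spatial scales. The package
provides the full analysis chain for a two-marker study design
(codominant nuclear microsatellites plus a maternally inherited haplotype
locus such as cytochrome-b) of social groups nested in localities nested
in regions, together with a ground-truthed forward simulator so every
estimator can be validated end to end without any external data.

## Estimators and tests

**F-statistics.** Differentiation uses the Weir–Cockerham (1984)
variance-components estimator: for each allele at each locus, components
$a$ (among populations), $b$ (among individuals within populations) and
$c$ (within individuals) are accumulated, and
$\hat\theta = \sum a / \sum (a+b+c)$. Negative estimates are reported
unmodified. For haploid haplotype data the within-individual level drops
out and haplotypes act as alleles of one locus (`haplotype_fst()`); a
sequence-distance-weighted variant is deliberately not the default
because the group-level comparisons are frequency questions. The
within-group inbreeding coefficient is the single-population reduction
$\hat f = \sum b' / \sum (b'+c)$ (`fis()`), which equals $-1$ for a group
of pure heterozygotes and is flagged undefined for monomorphic groups.

**Permutation significance.** `pairwise_fst_matrix()` attaches to every
pair of groups a P-value from random reassignment of whole individuals
(diploid) or single haplotypes (haploid) between the two groups, with the
add-one estimator $P = (\#\{\theta^\ast \ge \theta\} + 1)/(B+1)$ so no
P-value is ever zero. Internally a permutation set is a 0/1 selection
matrix multiplied against pre-expanded per-allele dosage and
heterozygosity matrices, so a 999-permutation scan of all 66 pairs of a
twelve-group study runs in about a second. Family-wise correction uses
the Holm step-down rule (`sequential_bonferroni()`).

**The pseudo-group randomization null.** To ask whether real social
groups are more differentiated than arbitrary sets of the same size,
`randomization_test()` draws `n_iter` pseudo-groups of a fixed size with
replacement from the pooled marker distribution, computes pairwise
F$_{ST}$ P-values among all pseudo-group pairs, and compares observed and
pseudo P-value distributions with a Mann–Whitney U test
(`mann_whitney_u()`: exact via the tie-free Wilcoxon distribution when
there are no ties and $n_1 n_2 \le 400$, otherwise a tie- and
continuity-corrected normal approximation). Drawing "from the frequency
table" is interpreted as i.i.d. with-replacement sampling, since a
frequency table carries no individual identity; the diploid version
samples whole individuals, with a without-replacement option. Group sizes
(e.g. the mean 15 and mode 11 of a real study) are caller-supplied.

A caution established by the package's own calibration suite: the U test
treats the pairwise P-values as independent, but P-values sharing a group
are clustered (measured design effect around 3.5). Under exchangeable
data the test therefore rejects far more often than its nominal level —
about 40% of null replicates at $\alpha = 0.05$ rather than 5% — and this
pseudo-replication is inherent to the procedure, not to this
implementation (observed and pseudo marginal distributions agree to
within 0.01 under the null). Directional conclusions at extremely small
P-values are unaffected, but borderline Mann–Whitney P-values from this
design should not be taken at face value.

**Isolation by distance and cluster-number arithmetic.**
`mantel_test()` correlates off-diagonal entries after the standard
linearization: genetic distances become $F_{ST}/(1-F_{ST})$ with negative
estimates truncated at zero (a raw log option exists for strictly
positive matrices, but the log of a non-positive F$_{ST}$ estimate is
undefined, which is why the linearization is the default), geographic
distances become $\log_{10}$ with zero distances offset by half the
smallest positive distance. Significance permutes row/column labels of
one matrix jointly; the default alternative is one-sided (differentiation
increasing with distance). `evanno_delta_k()` performs the second-order
rate-of-change arithmetic $\Delta K = |L''(K)|/\mathrm{sd}(L(K))$ on a
user-supplied table of clustering log-likelihood runs; the clustering
program itself is out of scope, and `simulate_lnk_table()` plants a kink
at a known $K$ for testing.

**Habitat variance partitioning.** `variance_partition()` decomposes the
variance of a group-level response (typically group F$_{IS}$) over three
covariate sets — structural (roost attributes), microhabitat (plot around
the roost plant), macrohabitat (landscape) — by inclusion–exclusion on
the $R^2$ of the seven union regressions, yielding three unique
fractions, three pairwise-shared fractions, one three-way fraction and a
residual. With the Ezekiel adjustment (the default, because a dozen
groups against multi-variable sets inflates raw $R^2$) shared fractions
may be negative; with raw $R^2$ the eight fractions sum to one exactly,
which the tests verify at machine precision. Rank-deficient unions mark
the affected fractions undefined rather than silently dropping them. Full
single-set fractions are tested by permuting the response; unique
fractions by permuting residuals of the reduced model containing the
other two sets. `within_set_regression()` mirrors the follow-up
"which variables within the winning set" question with an ordinary
F-tested least-squares fit controlling for group size.

**Kinship and parentage.** All likelihoods share one error model: with
probability $e$ an observed genotype is an independent Hardy–Weinberg
draw (default $e = 0.01$, replaceable by the repeat-genotyping estimate
from `estimate_error_rate()`, which counts mismatching allele calls over
compared calls). `ml_relatedness()` maximizes the product over loci of
$k_0 P_0 + k_1 P_1 + k_2 P_2$ over the IBD simplex by a deterministic
coarse grid (step 0.02) with fine refinement (step 0.002), reporting
$r = k_1/2 + k_2$. `paternity_lod()` is the log-ratio of the candidate
father against a random male, with and without a known mother, with
Mendelian exclusions giving $-\infty$ only at $e = 0$.
`paternity_assign()` calibrates the LOD gap $\Delta$ between the top two
candidates by Monte-Carlo simulation and labels assignments at the
conventional strict (95%) and relaxed (80%) confidence tiers.
`half_sib_test()` evaluates the paternal half-sib hypothesis
($R_p = 0.5, R_m = 0$) against unrelatedness with a simulated
unrelated-pair null — the null depends only on the allele frequencies, so
`half_sib_matrix()` simulates it once and shares it across all dyads —
and `sires_per_group()` counts paternal sibships by transitive closure
over significant dyads. `female_offspring_regression()` regresses
per-group mean offspring relatedness on per-group mean adult-female
relatedness, the package's summary of the philopatry/multiple-paternity
coupling.

## The colony generator

`simulate_colony()` is first-class, tested code, not a fixture. At the
calibrated defaults it emulates a two-region study of twelve harem
groups: one harem male and 4–24 adult females per group (with about 0.8
pups per female), ten microsatellite loci, and a 1140-bp maternally
inherited sequence locus.

* **Allele frequencies.** Per locus, founder frequencies are Dirichlet
  with one major-allele shape 4 and eleven minor shapes 0.3 over a pool
  of twelve alleles. This constant was calibrated once, before any test
  was frozen, so that realized samples show mean expected heterozygosity
  near 0.61 with 8–10 observed alleles per locus — the regime of a
  typical tropical-bat microsatellite panel (a symmetric Dirichlet cannot
  reach that combination: matching the heterozygosity leaves most alleles
  too rare to observe). Regions perturb the founder frequencies through
  an F-model with drift parameter `regional_divergence` (default 0.005).
* **Matrilines and philopatry.** Each group holds several founding
  matrilines (default 4). An adult female is a matriline recruit with
  probability equal to the group's philopatry, sharing her matriarch's
  haplotype; with probability `inbred_recruit_prob` (default 0.9) she is
  the product of a within-matriline mating — the long-male-tenure,
  father–daughter regime — carrying pedigree inbreeding $F \approx 0.25$.
  This is what makes group F$_{IS}$ rise monotonically with philopatry: a
  single big sibship actually shows a heterozygote *excess* against its
  own allele pool, so positive group F$_{IS}$ needs several partly inbred
  matrilines side by side (a within-group Wahlund effect).
* **Sires.** A group's pups are sired by the harem male plus extra-group
  males; when coupled (the default), the number of sires is
  $1 + \mathrm{Binomial}(2(s-1), \phi^{p})$ with $s$ = `n_sires`,
  $\phi$ = philopatry and $p$ = `sire_coupling_power`, so strongly
  philopatric groups draw more extra-group sires. An
  `extra_group_paternity` rate is available as an alternative mechanism.
* **Habitat.** Structural covariates (tent height, plant height, a
  coconut-palm indicator) drive philopatry linearly with configurable
  strength and noise; microhabitat and macrohabitat covariates are
  generated without any planted effect, so the partition analysis has a
  known answer.
* **Truth record.** The pedigree, each group's realized sires, the
  matriline haplotypes and the philopatry vector are returned, which is
  what lets the validation suites score every estimator exactly.

Named scenarios freeze the regimes the validation suites use:
`scenario_panmictic()` (null calibration), `scenario_philopatric()`
(matriline-dominated groups), `scenario_habitat_driven()` (24 groups,
strong low-noise structural link — at twelve groups the adjusted-$R^2$
fractions are too noisy for a stable winner), `scenario_coupled_mating()`
(24 larger groups, two pups per female, philopatric-but-outbred females,
sires coupled to $\phi^2$) and `scenario_sire_recovery()` (fixed three
sires, one pup per female, unrelated mothers). The coupled-mating
scenario's design is worth spelling out: recruits are *outbred* there
because inbred matrilines transmit so much maternal-side relatedness to
offspring that offspring relatedness rebounds at high philopatry and the
negative female-versus-offspring relationship disappears; and sires track
$\phi^2$ because mean female relatedness itself scales with the
probability that *both* members of a pair are recruits. With two pups per
female, maternal half-sibs (same mother, different fathers) are genuinely
related and correctly flagged by the paternal half-sib test, which chains
paternal sibships together — that is a confound of pairwise half-sib
counting in general, which is why the sire-recovery scenario uses one pup
per female.

## Numerical choices and problem sizes

Permutation and simulation sizes used by the shipped validation suites
are design choices of this package: 199 permutations per pairwise
F$_{ST}$ P-value inside the randomization null (the paper-scale 10,000 is
available through the arguments), 100 pseudo-groups, 999–30,000 Mantel
permutations, 1,000 simulated unrelated pairs per half-sib null, 2,000 to
4,000 simulated offspring for parentage confidence, and 15–20 simulation
replicates for the power suites. Ties in permutation statistics are
counted as at least as extreme (conservative); all stochastic entry
points take explicit seeds and are bit-reproducible under them.

## What passing tests do and do not show

The generator produces family structure, matrilineal haplotype sharing,
habitat-linked philopatry and genotyping error, but not null alleles,
allele-size homoplasy, linkage, spatial roost ecology beyond the
covariate links, or deep coalescent history; regional divergence is a
founder-frequency perturbation only. Two honest limitations established
by the suites themselves:

* The realized regional F$_{ST}$ at the defaults (~0.01) sits above the
  very weak values typical of continuous bat populations, because a
  dozen family-structured groups per region put a floor under the
  between-region variance component regardless of the founder drift
  parameter.
* Counting sires by transitive closure over $\alpha = 0.05$ pairwise
  half-sib calls cannot recover a planted three-sire truth within ±1 in
  much more than ~65–70% of groups at a ten-locus, $H_e \approx 0.61$
  panel: the dyad likelihood-ratio test (the Neyman–Pearson optimum for
  that hypothesis pair) has ~0.47 power, and false-positive merges and
  false-negative splits cannot both be driven down. A random-graph
  computation with those two rates reproduces the ceiling. Larger panels,
  not better code, are the remedy.
* Similarly, the Mann–Whitney comparison in the randomization null is
  anti-conservative under exchangeability (see above); its calibration
  suite documents the measured rejection rate rather than hiding it.

## A worked run

```{r, eval = FALSE}
sim <- simulate_colony(sim_config(seed = 42))
ht  <- collapse_haplotypes(sim$alignment)
div <- diversity_summary(sim$gt)

part <- partition_at_level(sim$study, "group")
fst  <- pairwise_fst_matrix(ht, part, n_perm = 999, seed = 1)
rnd  <- randomization_test(ht, part, group_size = 11, n_iter = 100,
                           n_perm = 199, seed = 2)

ft <- fis_table(sim$gt, sim$study)
vp <- variance_partition(ft$fis[match(sim$habitat$group_ids,
                                      ft$group_id)],
                         sim$habitat, n_perm = 499, seed = 3)

fo <- female_offspring_regression(sim$gt, sim$study)
```

`run_pipeline()` chains all stages with per-stage seeds derived from one
master seed and, given an output directory, writes the per-stage TSV and
JSON tables.
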