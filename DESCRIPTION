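Package: harempop
Title: Multi-Scale Population Genetics of Harem-Forming Social Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the population-genetic structure of socially
    structured (harem-forming) populations typed at microsatellite loci and a
    maternally inherited haplotype marker. Implements Weir-Cockerham
    F-statistics with permutation significance, a pseudo-group randomization
    null for social-group differentiation, isolation-by-distance Mantel tests,
    Evanno delta-K model selection arithmetic, three-set variance partitioning
    of group inbreeding coefficients against habitat covariates, and
    likelihood-based pairwise relatedness, parentage assignment and paternal
    half-sib inference. A forward simulator of harem-structured colonies
    (matrilineal philopatry, multiple sires, habitat-linked group structure)
    generates fully ground-truthed datasets so the whole pipeline runs
    self-contained.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
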