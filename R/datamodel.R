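#' Construct a diploid genotype table
#'
#' Holds multi-allelic codominant genotypes (e.g. microsatellites) for a set
#' of individuals. Allele calls are positive integer codes; a call is either
#' wholly present or wholly missing (half-calls are rejected).
#'
#' @param individual_ids character vector of unique individual identifiers.
#' @param locus_ids character vector of unique locus identifiers.
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes of each call; `NA` in both marks a missing call.
#' @return An object of class `genotype_table` with elements
#'   `individual_ids`, `locus_ids`, `a1`, `a2`.
#' @export
genotype_table <- function(individual_ids, locus_ids, a1, a2) {
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(individual_ids), length(locus_ids))) ||
      !all(dim(a2) == dim(a1))) {
    stop("allele matrices must be individuals x loci")
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    stop("half-missing diploid call at individual ",
         individual_ids[which(half, arr.ind = TRUE)[1, 1]])
  }
  bad <- (!is.na(a1) & a1 <= 0L) | (!is.na(a2) & a2 <= 0L)
  if (any(bad)) stop("allele codes must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, locus_ids)
  structure(list(individual_ids = individual_ids, locus_ids = locus_ids,
                 a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individual_ids), "individuals x",
      length(x$locus_ids), "loci;",
      sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

#' Number of missing calls per individual
#' @param gt a `genotype_table`.
#' @return named integer vector of missing-locus counts.
#' @export
missing_per_individual <- function(gt) {
  rowSums(is.na(gt$a1))
}

#' Drop individuals with too many missing genotypes
#'
#' Individuals with more than `max_missing` missing locus calls are removed
#' (the conventional treatment of poorly amplifying samples).
#'
#' @param gt a `genotype_table`.
#' @param max_missing maximum tolerated number of missing loci (default 3
#'   of a 10-locus panel).
#' @return list with the filtered `genotype_table` and the character vector
#'   `dropped` of removed individual ids.
#' @export
filter_missing_individuals <- function(gt, max_missing = 3L) {
  nm <- missing_per_individual(gt)
  keep <- nm <= max_missing
  list(gt = subset_genotypes(gt, gt$individual_ids[keep]),
       dropped = gt$individual_ids[!keep])
}

#' Subset a genotype table by individual ids
#' @param gt a `genotype_table`.
#' @param ids individual ids to retain, in the requested order.
#' @return a `genotype_table`.
#' @export
subset_genotypes <- function(gt, ids) {
  idx <- match(ids, gt$individual_ids)
  if (anyNA(idx)) stop("unknown individual id: ", ids[which(is.na(idx))[1]])
  genotype_table(ids, gt$locus_ids,
                 gt$a1[idx, , drop = FALSE], gt$a2[idx, , drop = FALSE])
}

#' Construct a haplotype table
#'
#' Per-individual mitochondrial haplotype assignments plus the pooled
#' haplotype frequency spectrum. Haplotype ids are dense integers from 1,
#' assigned in order of first appearance.
#'
#' @param individual_ids character vector.
#' @param haplotype_id integer vector (NA = missing), same length.
#' @return object of class `haplotype_table` with `individual_ids`,
#'   `haplotype_id` and `spectrum` (named counts).
#' @export
haplotype_table <- function(individual_ids, haplotype_id) {
  individual_ids <- as.character(individual_ids)
  haplotype_id <- as.integer(haplotype_id)
  if (length(individual_ids) != length(haplotype_id))
    stop("id and haplotype vectors differ in length")
  ok <- !is.na(haplotype_id)
  if (any(haplotype_id[ok] <= 0L)) stop("haplotype ids must be positive")
  u <- sort(unique(haplotype_id[ok]))
  if (length(u) && !identical(u, seq_along(u)))
    stop("haplotype ids must be dense from 1")
  spectrum <- table(factor(haplotype_id[ok], levels = u))
  spectrum <- stats::setNames(as.integer(spectrum), names(spectrum))
  structure(list(individual_ids = individual_ids,
                 haplotype_id = stats::setNames(haplotype_id, individual_ids),
                 spectrum = spectrum),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$individual_ids), "individuals,",
      length(x$spectrum), "haplotypes\n")
  invisible(x)
}

#' Construct and validate a study frame
#'
#' Binds individuals to the social structure: social group, sex, age class,
#' locality and region, plus the social role. Checks the grouping hierarchy
#' (each group in exactly one locality, each locality in exactly one region).
#'
#' @param df data.frame with columns `individual_id`, `group_id`, `sex`
#'   (F/M/U), `age` (adult/offspring), `locality_id`, `region_id`, `role`
#'   (harem_male/female/offspring/other).
#' @return the validated data.frame with class `study_frame` prepended.
#' @export
study_frame <- function(df) {
  need <- c("individual_id", "group_id", "sex", "age", "locality_id",
            "region_id", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("study frame missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids")
  if (!all(df$sex %in% c("F", "M", "U"))) stop("sex must be F, M or U")
  if (!all(df$age %in% c("adult", "offspring")))
    stop("age must be adult or offspring")
  if (!all(df$role %in% c("harem_male", "female", "offspring", "other")))
    stop("unknown role value")
  if (any(df$role == "offspring" & df$age != "offspring"))
    stop("role 'offspring' requires age 'offspring'")
  g2l <- unique(df[, c("group_id", "locality_id")])
  if (anyDuplicated(g2l$group_id)) stop("a group maps to several localities")
  l2r <- unique(df[, c("locality_id", "region_id")])
  if (anyDuplicated(l2r$locality_id)) stop("a locality maps to several regions")
  class(df) <- c("study_frame", "data.frame")
  df
}

#' Construct a habitat covariate matrix
#'
#' Group-level habitat covariates, each tagged with one of the three scale
#' sets: `structural` (roost attributes), `microhabitat` (plot around the
#' roost plant) or `macrohabitat` (landscape / land-use). Categorical
#' variables must be pre-expanded to 0/1 dummy columns.
#'
#' @param group_ids character vector of group identifiers (row order).
#' @param values numeric matrix (groups x variables) with column names.
#' @param scale_set character vector assigning each column to one scale set.
#' @return object of class `habitat_matrix`.
#' @export
habitat_matrix <- function(group_ids, values, scale_set) {
  group_ids <- as.character(group_ids)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("habitat variables must be named")
  if (nrow(values) != length(group_ids)) stop("rows must align with group_ids")
  if (length(scale_set) != ncol(values))
    stop("one scale_set tag per variable required")
  if (!all(scale_set %in% c("structural", "microhabitat", "macrohabitat")))
    stop("scale_set must be structural, microhabitat or macrohabitat")
  if (anyNA(values)) stop("habitat matrix must be complete after preparation")
  if (anyDuplicated(colnames(values))) stop("duplicate variable names")
  rownames(values) <- group_ids
  structure(list(group_ids = group_ids, values = values,
                 scale_set = stats::setNames(scale_set, colnames(values))),
            class = "habitat_matrix")
}

#' Construct a labelled distance matrix
#'
#' @param labels character vector of unit labels.
#' @param values symmetric numeric matrix with zero diagonal.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(labels, values) {
  labels <- as.character(labels)
  values <- as.matrix(values)
  if (nrow(values) != length(labels) || ncol(values) != length(labels))
    stop("matrix dimensions must match labels")
  if (!isTRUE(all.equal(values, t(values), tolerance = 0)))
    stop("distance matrix must be exactly symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be exactly zero")
  offd <- values[row(values) != col(values)]
  if (any(!is.finite(offd))) stop("off-diagonal entries must be finite")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "dist_matrix")
}

#' Pairwise great-ellipse-free Euclidean distances from planar coordinates
#'
#' Coordinates are taken as planar (km); adequate at the within-study extents
#' (tens of km) this package targets.
#'
#' @param coords data.frame with columns `group_id`, `x`, `y` (km).
#' @return a `dist_matrix` of between-group distances.
#' @export
coord_distances <- function(coords) {
  m <- as.matrix(stats::dist(coords[, c("x", "y")]))
  diag(m) <- 0
  m[lower.tri(m)] <- t(m)[lower.tri(m)]  # enforce exact symmetry
  dist_matrix(coords$group_id, m)
}
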