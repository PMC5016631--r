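#' Read a Genepop genotype file
#'
#' Parses the Genepop 4.x dialect: a title line, one locus name per line (or
#' a single comma-separated line), then `pop` blocks of
#' `id , 0102 0304 ...` records with 2- or 3-digit allele encoding.
#' `00`/`000` (or the doubled code) marks a missing call.
#'
#' @param path file path.
#' @return list with `gt` (a [genotype_table()]) and `pops`, an ordered list
#'   of per-population individual-id vectors.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no 'pop' separator")
  locus_lines <- body[seq_len(first_pop - 1)]
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  if (!length(locus_ids)) stop("no locus names before first 'pop'")
  recs <- body[seq(first_pop, length(body))]
  pop_idx <- cumsum(grepl("^\\s*pop\\s*$", recs, ignore.case = TRUE))
  recs_keep <- !grepl("^\\s*pop\\s*$", recs, ignore.case = TRUE)
  pop_of <- pop_idx[recs_keep]
  recs <- recs[recs_keep]
  if (!length(recs)) stop("no individuals after 'pop'")

  ids <- character(length(recs))
  n_loc <- length(locus_ids)
  a1 <- matrix(NA_integer_, length(recs), n_loc)
  a2 <- matrix(NA_integer_, length(recs), n_loc)
  width <- NA_integer_
  for (i in seq_along(recs)) {
    parts <- strsplit(recs[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed record (no comma) at line: ", recs[i])
    ids[i] <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    calls <- calls[nzchar(calls)]
    if (length(calls) != n_loc)
      stop("ragged locus count (", length(calls), " of ", n_loc,
           ") for individual '", ids[i], "'")
    w <- unique(nchar(calls)) / 2
    if (length(w) != 1 || !w %in% c(2, 3))
      stop("unknown allele encoding width for individual '", ids[i],
           "': field widths ", paste(unique(nchar(calls)), collapse = ","))
    if (is.na(width)) width <- as.integer(w)
    if (w != width) stop("mixed allele widths in file")
    x1 <- as.integer(substr(calls, 1, width))
    x2 <- as.integer(substr(calls, width + 1, 2 * width))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids in Genepop file")
  gt <- genotype_table(ids, locus_ids, a1, a2)
  pops <- split(ids, pop_of)
  names(pops) <- paste0("pop", seq_along(pops))
  list(gt = gt, pops = unname(pops))
}

#' Write a Genepop genotype file
#'
#' Uses 3-digit allele encoding; missing calls are written `000000`.
#'
#' @param gt a [genotype_table()].
#' @param pops ordered list of per-population individual-id vectors; default
#'   one population holding everyone.
#' @param path output file path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, pops = list(gt$individual_ids),
                          title = "harempop export") {
  if (any(unlist(lapply(pops, function(p) !p %in% gt$individual_ids))))
    stop("population lists contain unknown ids")
  if (max(c(0L, gt$a1, gt$a2), na.rm = TRUE) > 999L)
    stop("allele codes exceed 3-digit encoding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$locus_ids, con)
  fmt <- function(x) ifelse(is.na(x), "000", formatC(x, width = 3, flag = "0"))
  for (p in pops) {
    writeLines("pop", con)
    idx <- match(p, gt$individual_ids)
    for (i in idx) {
      fields <- paste0(fmt(gt$a1[i, ]), fmt(gt$a2[i, ]))
      writeLines(paste0(gt$individual_ids[i], " , ",
                        paste(fields, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All records must share one length (an alignment); ids must be unique.
#'
#' @param path FASTA file path.
#' @return object of class `alignment_table`: data.frame with columns `id`,
#'   `sequence` (upper-case), and attribute `length`.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (!length(seqs)) stop("empty FASTA file")
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  chr <- vapply(as.character(seqs),
                function(s) paste(toupper(s), collapse = ""), character(1))
  lens <- nchar(chr)
  if (length(unique(lens)) != 1)
    stop("alignment length mismatch: lengths ",
         paste(unique(lens), collapse = ", "))
  alignment_table(ids, unname(chr))
}

#' Construct an alignment table from ids and sequence strings
#' @param ids character vector of unique record ids.
#' @param sequences character vector of equal-length sequence strings.
#' @return an `alignment_table` data.frame.
#' @export
alignment_table <- function(ids, sequences) {
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) stop("sequences differ in length")
  out <- data.frame(id = as.character(ids),
                    sequence = toupper(as.character(sequences)),
                    stringsAsFactors = FALSE)
  attr(out, "length") <- lens
  class(out) <- c("alignment_table", "data.frame")
  out
}

#' Write an alignment table as FASTA
#' @param aln an `alignment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", aln$id, "\n", aln$sequence), con)
  invisible(path)
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences share one haplotype id; ids are assigned in order of
#' first appearance. Under `missing_policy = "compatible"`, a sequence with
#' ambiguous sites (`N`, `-`, `?`) is merged into the first earlier haplotype
#' it matches at every unambiguous site; under `"exact"`, only literal string
#' identity merges records.
#'
#' @param aln an `alignment_table`.
#' @param missing_policy `"compatible"` (default) or `"exact"`.
#' @return a [haplotype_table()]; individuals whose sequence is entirely
#'   ambiguous are MISSING.
#' @export
collapse_haplotypes <- function(aln, missing_policy = c("compatible", "exact")) {
  missing_policy <- match.arg(missing_policy)
  n <- nrow(aln)
  amb <- c("N", "-", "?")
  hap <- integer(n)
  reps <- list()   # representative character vectors per haplotype
  for (i in seq_len(n)) {
    s <- strsplit(aln$sequence[i], "")[[1]]
    known <- !(s %in% amb)
    if (!any(known)) { hap[i] <- NA_integer_; next }
    found <- 0L
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      if (missing_policy == "exact") {
        if (all(r == s)) { found <- h; break }
      } else {
        rk <- !(r %in% amb)
        both <- known & rk
        if (all(r[both] == s[both])) {
          found <- h
          # refine representative with newly resolved sites
          fill <- known & !rk
          if (any(fill)) reps[[h]][fill] <- s[fill]
          break
        }
      }
    }
    if (found == 0L) {
      reps[[length(reps) + 1L]] <- s
      found <- length(reps)
    }
    hap[i] <- found
  }
  haplotype_table(aln$id, hap)
}

#' Read individual metadata into a study frame
#' @param path CSV with the [study_frame()] columns.
#' @return a `study_frame`.
#' @export
read_study_frame <- function(path) {
  study_frame(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
}

#' Read group-level habitat covariates
#'
#' Expects a CSV whose first row of data belongs to column `group_id`, with a
#' companion header tagging line not required: instead the scale membership is
#' supplied via `scale_sets`, a named vector or a second CSV of
#' `variable,scale_set` pairs.
#'
#' @param path CSV with `group_id` plus numeric variable columns.
#' @param scale_sets either a named character vector mapping variable ->
#'   scale set, or a path to a two-column CSV `variable,scale_set`.
#' @return a [habitat_matrix()].
#' @export
read_habitat_matrix <- function(path, scale_sets) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group_id" %in% names(df)) stop("habitat CSV needs a group_id column")
  if (is.character(scale_sets) && length(scale_sets) == 1 &&
      file.exists(scale_sets)) {
    map <- utils::read.csv(scale_sets, stringsAsFactors = FALSE)
    scale_sets <- stats::setNames(map$scale_set, map$variable)
  }
  vars <- setdiff(names(df), "group_id")
  habitat_matrix(df$group_id, as.matrix(df[, vars, drop = FALSE]),
                 unname(scale_sets[vars]))
}

#' Read group coordinates
#' @param path CSV with columns `group_id`, `x`, `y` (km).
#' @return data.frame.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "x", "y")
  if (!all(need %in% names(df))) stop("coordinates CSV needs group_id, x, y")
  df
}
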