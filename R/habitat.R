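# Three-set variance partitioning of a group-level response (typically the
# group inbreeding coefficient) against structural, microhabitat and
# macrohabitat covariate sets, by inclusion-exclusion on the R-squared of
# the seven union regressions.

.r2_fit <- function(y, X) {
  # returns R2, rank-deficiency flag and the lm-style pieces
  Xd <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xd)
  deficient <- qrx$rank < ncol(Xd)
  fit <- stats::lm.fit(Xd, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(r2 = r2, p = qrx$rank - 1, deficient = deficient,
       fitted = fit$fitted.values, resid = fit$residuals)
}

.adj_r2 <- function(r2, n, p) {
  if (n - p - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Three-set variance partitioning of a group-level response
#'
#' Decomposes the variance of `y` explained by the three habitat scale sets
#' into unique fractions (a: structural, b: microhabitat, c: macrohabitat),
#' pairwise shared fractions (d: structural+microhabitat, e:
#' structural+macrohabitat, f: microhabitat+macrohabitat), the three-way
#' shared fraction g, and the residual, by inclusion-exclusion on the
#' R-squared of the seven union regressions. With `adjusted = TRUE`
#' (default) each R-squared is Ezekiel-adjusted before the decomposition,
#' so shared fractions may be negative; with `adjusted = FALSE` the eight
#' fractions sum to one exactly.
#'
#' Significance: the full-set fractions (the R-squared of each single-set
#' model) are tested by permutation of the response; the unique fractions by
#' permutation of the residuals of the reduced model containing the other
#' two sets.
#'
#' @param y numeric response per group (e.g. group F_IS).
#' @param X a [habitat_matrix()] aligned with `y`.
#' @param adjusted use adjusted R-squared for reported fractions.
#' @param n_perm permutations for fraction P-values (0 to skip).
#' @param seed optional integer seed.
#' @return object of class `partition_result`: `fractions` (named a..g +
#'   residual), `total_R2`, `set_R2`, `pvals` (per testable fraction),
#'   `adjusted`, `n_groups`, `undefined` (names of fractions flagged by
#'   rank deficiency).
#' @export
variance_partition <- function(y, X, adjusted = TRUE, n_perm = 999,
                               seed = NULL) {
  stopifnot(inherits(X, "habitat_matrix"))
  if (length(y) != length(X$group_ids)) stop("y must align with group rows")
  if (any(!is.finite(y))) stop("response must be finite for all groups")
  n <- length(y)
  sets <- list(structural = which(X$scale_set == "structural"),
               microhabitat = which(X$scale_set == "microhabitat"),
               macrohabitat = which(X$scale_set == "macrohabitat"))
  if (any(lengths(sets) == 0)) stop("all three scale sets must be non-empty")
  if (n <= max(lengths(sets)) + 1)
    stop("too few groups for the largest single-set model")
  unions <- list(s1 = 1, s2 = 2, s3 = 3, s12 = c(1, 2), s13 = c(1, 3),
                 s23 = c(2, 3), s123 = 1:3)
  fit_union <- function(u, yy) {
    cols <- unlist(sets[u])
    .r2_fit(yy, X$values[, cols, drop = FALSE])
  }
  fits <- lapply(unions, fit_union, yy = y)
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  defic <- vapply(fits, `[[`, logical(1), "deficient")
  r2u <- if (adjusted) {
    mapply(function(f) .adj_r2(f$r2, n, f$p), fits)
  } else r2
  frac <- c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
            e = NA_real_, f = NA_real_, g = NA_real_, residual = NA_real_)
  need <- list(a = c("s123", "s23"), b = c("s123", "s13"),
               c = c("s123", "s12"),
               g = c("s1", "s2", "s3", "s12", "s13", "s23", "s123"),
               d = c("s1", "s2", "s12", "s1", "s2", "s3", "s12", "s13",
                     "s23", "s123"),
               e = c("s1", "s3", "s13", "s1", "s2", "s3", "s12", "s13",
                     "s23", "s123"),
               f = c("s2", "s3", "s23", "s1", "s2", "s3", "s12", "s13",
                     "s23", "s123"),
               residual = "s123")
  ok <- function(us) !any(defic[unique(us)])
  if (ok(need$a)) frac["a"] <- r2u["s123"] - r2u["s23"]
  if (ok(need$b)) frac["b"] <- r2u["s123"] - r2u["s13"]
  if (ok(need$c)) frac["c"] <- r2u["s123"] - r2u["s12"]
  g <- r2u["s1"] + r2u["s2"] + r2u["s3"] - r2u["s12"] - r2u["s13"] -
    r2u["s23"] + r2u["s123"]
  if (ok(need$g)) frac["g"] <- g
  if (ok(need$d)) frac["d"] <- r2u["s1"] + r2u["s2"] - r2u["s12"] - g
  if (ok(need$e)) frac["e"] <- r2u["s1"] + r2u["s3"] - r2u["s13"] - g
  if (ok(need$f)) frac["f"] <- r2u["s2"] + r2u["s3"] - r2u["s23"] - g
  if (ok(need$residual)) frac["residual"] <- 1 - r2u["s123"]
  undefined <- names(frac)[is.na(frac)]

  pvals <- c(set_structural = NA_real_, set_microhabitat = NA_real_,
             set_macrohabitat = NA_real_, unique_structural = NA_real_,
             unique_microhabitat = NA_real_, unique_macrohabitat = NA_real_)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    # full single-set fractions: permute the response
    for (s in 1:3) {
      if (defic[[s]]) next
      obs <- r2[[s]]
      cnt <- 0L
      for (k in seq_len(n_perm)) {
        if (fit_union(s, sample(y))$r2 >= obs - 1e-12) cnt <- cnt + 1L
      }
      pvals[s] <- (cnt + 1) / (n_perm + 1)
    }
    # unique fractions: permute residuals of the reduced (other-two) model
    reduced_of <- c("s23", "s13", "s12")
    for (s in 1:3) {
      red <- reduced_of[s]
      if (defic[[red]] || defic[["s123"]]) next
      obs <- r2[["s123"]] - r2[[red]]
      rf <- fits[[red]]
      cnt <- 0L
      for (k in seq_len(n_perm)) {
        ystar <- rf$fitted + sample(rf$resid)
        stat <- fit_union(1:3, ystar)$r2 -
          fit_union(setdiff(1:3, s), ystar)$r2
        if (stat >= obs - 1e-12) cnt <- cnt + 1L
      }
      pvals[3 + s] <- (cnt + 1) / (n_perm + 1)
    }
  }
  structure(list(fractions = frac, total_R2 = r2u[["s123"]],
                 set_R2 = c(structural = r2u[["s1"]],
                            microhabitat = r2u[["s2"]],
                            macrohabitat = r2u[["s3"]]),
                 pvals = pvals, adjusted = adjusted, n_groups = n,
                 undefined = undefined),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("variance partitioning over %d groups (%s R2)\n", x$n_groups,
              if (x$adjusted) "adjusted" else "raw"))
  print(round(x$fractions, 3))
  cat(sprintf("total explained: %.3f\n", x$total_R2))
  invisible(x)
}

#' Within-set multiple regression controlling for group size
#'
#' Ordinary least squares of the response on group size plus the variables
#' of one habitat set, with the overall F test and per-variable t tests.
#'
#' @param y numeric response per group.
#' @param X_set numeric matrix of the set's variables (groups x variables).
#' @param group_size numeric vector of group sizes.
#' @return list `coefficients` (summary table), `r2`, `fstat`
#'   (`c(F, df1, df2)`), `p`, `collinear` (TRUE when the design was
#'   rank-deficient and a pseudo-inverse style fit was used).
#' @export
within_set_regression <- function(y, X_set, group_size) {
  X_set <- as.matrix(X_set)
  n <- length(y)
  p <- ncol(X_set) + 1
  if (n <= p + 2) stop("too few groups for this set size")
  df <- data.frame(y = y, group_size = group_size, X_set)
  qrx <- qr(cbind(1, group_size, X_set))
  collinear <- qrx$rank < p + 1
  if (collinear)
    warning("collinear design; coefficients from a rank-truncated fit")
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  fs <- sm$fstatistic
  pval <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  list(coefficients = stats::coef(sm), r2 = sm$r.squared,
       fstat = if (is.null(fs)) c(NA, NA, NA) else unname(fs),
       p = unname(pval), collinear = collinear)
}
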