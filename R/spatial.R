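#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and a
#' geographic distance matrix, with significance from joint row/column
#' permutations of one matrix. Default transforms follow the standard
#' isolation-by-distance linearization: genetic distances become
#' F_ST / (1 - F_ST) with negative estimates truncated to 0, geographic
#' distances become log10 (zero distances offset by half the smallest
#' positive distance). A raw-log option is available for strictly positive
#' genetic matrices.
#'
#' @param gen,geo [dist_matrix()] objects with identical labels and order.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param transform_genetic `"fst_linear"` (default), `"log10"` or `"none"`.
#' @param transform_geo `"log10"` (default) or `"none"`.
#' @param alternative `"greater"` (default; the isolation-by-distance
#'   direction), `"less"` or `"two.sided"`.
#' @return object of class `mantel_result`: `r`, `P`, `n_perm`, transforms.
#'   If a matrix is constant after transform, `r` is `NA` and
#'   `defined = FALSE`.
#' @export
mantel_test <- function(gen, geo, n_perm = 999, seed = NULL,
                        transform_genetic = c("fst_linear", "log10", "none"),
                        transform_geo = c("log10", "none"),
                        alternative = c("greater", "less", "two.sided")) {
  transform_genetic <- match.arg(transform_genetic)
  transform_geo <- match.arg(transform_geo)
  alternative <- match.arg(alternative)
  if (!identical(gen$labels, geo$labels))
    stop("matrices must share labels and order")
  n <- length(gen$labels)
  if (n < 4) stop("need at least 4 units")
  G <- gen$values; D <- geo$values
  G <- switch(transform_genetic,
              fst_linear = { g <- pmax(G, 0); g / (1 - g) },
              log10 = {
                if (any(G[row(G) != col(G)] <= 0))
                  stop("log10 transform needs strictly positive entries")
                log10(G + diag(1, n))  # diagonal untouched placeholder
              },
              none = G)
  if (transform_genetic == "log10") diag(G) <- 0
  D <- switch(transform_geo,
              log10 = {
                off <- D[row(D) != col(D)]
                pos <- off[off > 0]
                if (!length(pos)) stop("all geographic distances are zero")
                eps <- min(pos) / 2
                d <- D; d[d == 0] <- eps; d <- log10(d); diag(d) <- 0; d
              },
              none = D)
  lt <- lower.tri(G)
  x <- G[lt]; y <- D[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, P = NA_real_, defined = FALSE,
                          n_perm = n_perm,
                          transform_genetic = transform_genetic,
                          transform_geo = transform_geo),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm[k] <- stats::cor(G[p, p][lt], y)
  }
  P <- switch(alternative,
              greater = (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1),
              less = (sum(r_perm <= r_obs + 1e-12) + 1) / (n_perm + 1),
              two.sided = (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) /
                (n_perm + 1))
  structure(list(r = r_obs, P = P, defined = TRUE, n_perm = n_perm,
                 transform_genetic = transform_genetic,
                 transform_geo = transform_geo),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, P = %.4g (%d permutations)\n",
              x$r, x$P, x$n_perm))
  invisible(x)
}

#' Evanno delta-K table from clustering log-likelihood runs
#'
#' Given repeated runs of a model-based clustering method at consecutive
#' numbers of clusters K, computes the Evanno statistics:
#' L'(K) = mean L(K) - mean L(K-1), |L''(K)| = |L'(K+1) - L'(K)|, and
#' delta K = |L''(K)| / sd(L(K)). delta K is defined only for interior K
#' with positive run-to-run standard deviation.
#'
#' @param runs data.frame with columns `K` (integer) and `lnP`
#'   (log-likelihood of one run).
#' @return data.frame per K: `K`, `n_runs`, `mean_lnP`, `sd_lnP`, `lprime`,
#'   `lsecond`, `delta_k`, `defined`.
#' @export
evanno_delta_k <- function(runs) {
  if (!all(c("K", "lnP") %in% names(runs)))
    stop("runs must have columns K and lnP")
  Ks <- sort(unique(runs$K))
  if (length(Ks) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1)) stop("K values must be consecutive")
  mu <- vapply(Ks, function(k) mean(runs$lnP[runs$K == k]), numeric(1))
  sdv <- vapply(Ks, function(k) stats::sd(runs$lnP[runs$K == k]), numeric(1))
  nr <- vapply(Ks, function(k) sum(runs$K == k), integer(1))
  if (any(nr < 2)) stop("need at least 2 runs per K for sd")
  m <- length(Ks)
  lprime <- c(NA, diff(mu))                       # L'(K), defined from 2nd K
  lsec <- rep(NA_real_, m)
  lsec[2:(m - 1)] <- abs(lprime[3:m] - lprime[2:(m - 1)])
  dk <- rep(NA_real_, m)
  defined <- rep(FALSE, m)
  interior <- 2:(m - 1)
  for (i in interior) {
    if (!is.na(sdv[i]) && sdv[i] > 0) {
      dk[i] <- lsec[i] / sdv[i]
      defined[i] <- TRUE
    }
  }
  data.frame(K = Ks, n_runs = nr, mean_lnP = mu, sd_lnP = sdv,
             lprime = lprime, lsecond = lsec, delta_k = dk,
             defined = defined)
}
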