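#' PCA-Mahalanobis selection-outlier scan
#'
#' Genotypes are mean-imputed, centered and scaled, and the leading K
#' principal components are extracted. Each SNP is regressed on the K score
#' vectors; the resulting z-score vectors are summarised per SNP by their
#' Mahalanobis distance under a robust (minimum covariance determinant)
#' estimate of the z covariance across SNPs. Distances are recalibrated by
#' the genomic inflation factor `gif = median(D2) / median(chi2_K)`, converted
#' to upper-tail chi-squared p-values, and to Storey q-values; outliers are
#' the sites with `q <= alpha`.
#'
#' Zero-variance SNPs receive missing p/q-values. The robust covariance falls
#' back to the sample covariance when fewer than `10 * K` sites are available.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of principal components capturing population structure
#'   (an explicit analyst choice; see [scree_report()] for assistance).
#' @param alpha q-value cutoff for the outlier set (default 0.1).
#' @param robust use the MCD covariance when feasible (default `TRUE`).
#' @param seed RNG seed for the MCD subsampling (restored afterwards), so
#'   scans are reproducible.
#' @return object of class `outlier_scan`: `table` tibble (`site`, `chrom`,
#'   `pos`, `d2`, `p`, `q`, `outlier`), plus `K`, `gif`, `alpha`, `pi0`.
#' @export
outlier_scan <- function(gm, K, alpha = 0.1, robust = TRUE, seed = 1) {
  n <- nrow(gm$dosages)
  if (K >= n) stop("K must be below the number of individuals")
  X <- gm$dosages
  mu <- colMeans(X, na.rm = TRUE)
  na_idx <- which(is.na(X))
  if (length(na_idx)) X[na_idx] <- mu[((na_idx - 1) %/% n) + 1]
  Xc <- sweep(X, 2, colMeans(X))
  sdv <- apply(Xc, 2, sd)
  keep <- sdv > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, sdv[keep], "/")
  sv <- svd(Xs, nu = K, nv = 0)
  S <- sv$u                                  # orthonormal score basis
  # per-SNP multiple regression on the K components (orthonormal design)
  B <- crossprod(S, Xs)                      # K x L_kept coefficients
  rss <- colSums(Xs^2) - colSums(B^2)
  df <- n - K - 1
  sigma <- sqrt(pmax(rss, 0) / df)
  Z <- t(B) / sigma                          # L_kept x K z-scores
  zok <- is.finite(rowSums(Z))
  covz <- if (robust && sum(zok) >= 10 * K) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    rb <- MASS::cov.rob(Z[zok, , drop = FALSE], method = "mcd")
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    list(center = rb$center, cov = rb$cov)
  } else {
    list(center = colMeans(Z[zok, , drop = FALSE]),
         cov = cov(Z[zok, , drop = FALSE]))
  }
  d2 <- rep(NA_real_, nrow(Z))
  d2[zok] <- mahalanobis(Z[zok, , drop = FALSE], covz$center, covz$cov)
  gif <- median(d2, na.rm = TRUE) / qchisq(0.5, df = K)
  p <- pchisq(d2 / gif, df = K, lower.tail = FALSE)
  q <- storey_qvalue(p)

  full <- function(v) {
    out <- rep(NA_real_, ncol(gm$dosages)); out[keep] <- v; out
  }
  tab <- tibble(
    site = gm$sites$site, chrom = gm$sites$chrom, pos = gm$sites$pos,
    d2 = full(d2), p = full(p), q = full(as.numeric(q))
  )
  tab$outlier <- !is.na(tab$q) & tab$q <= alpha
  structure(list(table = tab, K = K, gif = gif, alpha = alpha,
                 pi0 = attr(q, "pi0")),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("<outlier_scan> K = %d, GIF = %.3f, %d / %d outliers at q <= %g\n",
              x$K, x$gif, sum(x$table$outlier), nrow(x$table), x$alpha))
  invisible(x)
}

#' Site ids flagged by an outlier scan
#'
#' @param scan an [outlier_scan()] result.
#' @return character vector of `chrom:pos` site ids.
#' @export
outlier_sites <- function(scan) {
  scan$table$site[scan$table$outlier]
}
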