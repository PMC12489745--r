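#' PCA of a genotype matrix with mean imputation
#'
#' Missing dosages are replaced by the site mean, columns are centered but not
#' variance-scaled, and the decomposition is taken by SVD of the centered
#' matrix. Scores are the principal coordinates (`U %*% D`), loadings the site
#' eigenvectors, and eigenvalues those of the covariance matrix (descending).
#'
#' @param gm a [genotype_matrix()].
#' @param n_axes number of axes to retain (default: full rank).
#' @param scale_sites scale columns to unit variance before decomposition
#'   (default `FALSE`, the convention for dosage PCA here).
#' @return object of class `geno_pca`: `scores` (n x n_axes), `loadings`
#'   (sites x n_axes), `eigenvalues`, `var_explained`, `site_means`,
#'   `individuals`.
#' @export
pca_impute <- function(gm, n_axes = NULL, scale_sites = FALSE) {
  X <- gm$dosages
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu)) stop("site(s) with all genotypes missing; filter first")
  na_idx <- which(is.na(X))
  if (length(na_idx)) X[na_idx] <- mu[((na_idx - 1) %/% nrow(X)) + 1]
  Xc <- sweep(X, 2, mu)
  if (scale_sites) {
    sdv <- apply(Xc, 2, sd)
    sdv[sdv == 0] <- 1
    Xc <- sweep(Xc, 2, sdv, "/")
  }
  r <- min(dim(Xc))
  if (is.null(n_axes)) n_axes <- r
  if (n_axes > r) stop("n_axes exceeds matrix rank bound")
  sv <- svd(Xc, nu = n_axes, nv = n_axes)
  ev <- sv$d^2 / (nrow(Xc) - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- gm$individuals$id
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  loadings <- sv$v
  rownames(loadings) <- gm$sites$site
  colnames(loadings) <- colnames(scores)
  structure(list(
    scores = scores, loadings = loadings,
    eigenvalues = ev[seq_len(n_axes)],
    var_explained = ev[seq_len(n_axes)] / sum(ev),
    site_means = mu, individuals = gm$individuals
  ), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d individuals, %d axes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], NA)))
  invisible(x)
}

#' Scree report with a Cattell-style elbow suggestion
#'
#' Reports eigenvalues and the axis of maximum perpendicular distance above
#' the line joining the first and last scree points — an assistive elbow
#' suggestion only; the number of axes to interpret remains an analyst choice.
#'
#' @param pca a [pca_impute()] fit.
#' @param max_axes number of leading axes to profile.
#' @return tibble with `axis`, `eigenvalue`, `prop_var`, and attribute
#'   `"suggested_k"`.
#' @export
scree_report <- function(pca, max_axes = 20) {
  k <- min(max_axes, length(pca$eigenvalues))
  ev <- pca$eigenvalues[seq_len(k)]
  # distance of each scree point from the chord between endpoints
  x <- seq_len(k); y <- ev
  dx <- k - 1; dy <- y[k] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * 1) / sqrt(dx^2 + dy^2)
  out <- tibble(axis = x, eigenvalue = ev, prop_var = ev / sum(pca$eigenvalues))
  attr(out, "suggested_k") <- which.max(d)
  out
}
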