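#' Partial redundancy analysis of allele frequencies on environment
#'
#' Constrained ordination (via vegan) of the individual-allele-frequency
#' matrix on standardized environmental predictors, with population-structure
#' PCs (and any conditioned-out predictors) removed first. Reports canonical
#' eigenvalues, SNP loadings, per-axis permutation tests, and an adjusted-R2
#' variance partition: full model (environment + conditioning), environment
#' given conditioning, and conditioning given environment — all by the
#' small-sample (Ezekiel) correction `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param Y response matrix (individuals x SNPs), e.g.
#'   [individual_allele_freq()].
#' @param X environmental predictors: tibble with `id` column or numeric
#'   matrix; columns are standardized internally.
#' @param Z conditioning variables (structure PCs, conditioned-out
#'   predictors) in the same formats, or `NULL` for plain RDA.
#' @param n_perm permutations for the per-axis tests (0 skips them).
#' @param seed RNG seed for the permutations.
#' @return object of class `prda_fit`: `eig` tibble, `loadings` (SNP x axis),
#'   `site_scores` (individual x axis), `r2` list (`full`, `env_given_cond`,
#'   `cond_given_env`, `unadjusted`), `axis_tests` tibble, `Y`, `X`, `model`
#'   (the vegan object).
#' @export
prda <- function(Y, X, Z = NULL, n_perm = 199, seed = 1) {
  Xm <- scale(.env_matrix(X))
  Zm <- if (!is.null(Z)) .env_matrix(Z) else NULL
  if (!is.null(Zm) && ncol(Zm) == 0) Zm <- NULL
  n <- nrow(Y)
  p <- ncol(Xm)
  rZ <- if (is.null(Zm)) 0 else qr(Zm)$rank
  if (n <= p + rZ + 1) stop("too few individuals for the requested model")
  mod <- if (is.null(Zm)) vegan::rda(Y, Xm) else vegan::rda(Y, Xm, Zm)
  eig <- mod$CCA$eig
  loadings <- mod$CCA$v
  site_scores <- mod$CCA$u %*% diag(sqrt(eig), length(eig))
  colnames(site_scores) <- names(eig)
  r2_env <- vegan::RsquareAdj(mod)
  r2 <- list(unadjusted = r2_env$r.squared, env_given_cond = r2_env$adj.r.squared)
  if (!is.null(Zm)) {
    r2$full <- vegan::RsquareAdj(vegan::rda(Y, cbind(Xm, Zm)))$adj.r.squared
    r2$cond_given_env <- vegan::RsquareAdj(vegan::rda(Y, Zm, Xm))$adj.r.squared
  } else {
    r2$full <- r2_env$adj.r.squared
    r2$cond_given_env <- NA_real_
  }
  axis_tests <- NULL
  if (n_perm > 0) {
    set.seed(seed)
    at <- anova(mod, by = "axis", permutations = n_perm)
    axis_tests <- tibble(axis = seq_len(nrow(at) - 1),
                         variance = at$Variance[-nrow(at)],
                         F = at$F[-nrow(at)],
                         p = at$`Pr(>F)`[-nrow(at)])
  }
  structure(list(
    eig = tibble(axis = seq_along(eig), eigenvalue = unname(eig),
                 prop = unname(eig) / sum(eig)),
    loadings = loadings, site_scores = site_scores, r2 = r2,
    axis_tests = axis_tests, Y = Y, X = Xm, Z = Zm, model = mod
  ), class = "prda_fit")
}

#' @export
print.prda_fit <- function(x, ...) {
  cat(sprintf("<prda_fit> %d constrained axes; adj R2: full %.3f, env|cond %.3f, cond|env %.3f\n",
              nrow(x$eig), x$r2$full, x$r2$env_given_cond,
              ifelse(is.na(x$r2$cond_given_env), NA, x$r2$cond_given_env)))
  invisible(x)
}
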