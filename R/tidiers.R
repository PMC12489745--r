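#' Tidy a genotype PCA
#'
#' @param x a [pca_impute()] fit.
#' @param n_axes number of leading axes to return (default 2... all
#'   available axes up to 10).
#' @param ... unused.
#' @return tibble: `id`, metadata columns, `PC1..PCk`.
#' @export
tidy.geno_pca <- function(x, n_axes = min(10, ncol(x$scores)), ...) {
  dplyr::bind_cols(x$individuals,
                   as_tibble(x$scores[, seq_len(n_axes), drop = FALSE]))
}

#' @export
glance.geno_pca <- function(x, ...) {
  tibble(n_individuals = nrow(x$scores), n_axes = ncol(x$scores),
         pc1_var = x$var_explained[1],
         pc2_var = ifelse(length(x$var_explained) > 1, x$var_explained[2], NA))
}

#' @export
tidy.cluster_scan <- function(x, ...) x$scan

#' @export
glance.cluster_scan <- function(x, ...) {
  tibble(chosen_k = x$chosen_k, bic_min = min(x$scan$bic))
}

#' @export
tidy.dapc_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(group = x$groups, assigned = x$assignments),
                   as_tibble(x$ind_coord))
}

#' @export
glance.dapc_fit <- function(x, ...) {
  tibble(best_n_pc = x$best_n_pc, a_score = max(x$a_score$a_score),
         n_functions = ncol(x$discriminant_axes),
         reassignment = mean(x$assignments == x$groups))
}

#' @export
tidy.admix_fit <- function(x, ...) {
  Q <- as.data.frame(x$Q)
  names(Q) <- paste0("Q", seq_len(x$K))
  dplyr::bind_cols(tibble(id = x$ids), as_tibble(Q)) |>
    tidyr::pivot_longer(dplyr::starts_with("Q"), names_to = "ancestry",
                        values_to = "proportion")
}

#' @export
glance.admix_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, cv_error = x$cv_error,
         n_iter = length(x$loglik_trace), converged = x$converged)
}

#' @export
tidy.admix_scan <- function(x, ...) x$scan

#' @export
tidy.outlier_scan <- function(x, ...) x$table

#' @export
glance.outlier_scan <- function(x, ...) {
  tibble(K = x$K, gif = x$gif, pi0 = x$pi0, alpha = x$alpha,
         n_outliers = sum(x$table$outlier, na.rm = TRUE))
}

#' @export
tidy.pop_stats <- function(x, ...) x$per_locus

#' @export
glance.pop_stats <- function(x, ...) x$global

#' @export
tidy.wc_stats <- function(x, ...) x$per_locus

#' @export
glance.wc_stats <- function(x, ...) tibble(theta = x$theta, fis = x$fis)

#' @export
tidy.beta_stats <- function(x, ...) x$per_pop

#' @export
glance.beta_stats <- function(x, ...) x$overall

#' @export
tidy.pairwise_fst <- function(x, ...) x$pairs

#' Tidy a kinship matrix into dyads
#'
#' @param x a `kinship_mat`.
#' @param ... unused.
#' @return tibble of unordered pairs: `id1`, `id2`, `kinship`.
#' @export
tidy.kinship_mat <- function(x, ...) {
  ut <- which(upper.tri(x$beta), arr.ind = TRUE)
  tibble(id1 = x$labels[ut[, 1]], id2 = x$labels[ut[, 2]],
         kinship = x$beta[ut])
}

#' @export
glance.kinship_mat <- function(x, ...) {
  off <- x$beta[upper.tri(x$beta)]
  tibble(type = x$type, n = length(x$labels),
         mean_inbreeding = if (x$type == "beta") mean(diag(x$beta)) else NA,
         max_kinship = max(off, na.rm = TRUE))
}

#' @export
tidy.prda_fit <- function(x, ...) x$eig

#' @export
glance.prda_fit <- function(x, ...) {
  tibble(r2_full = x$r2$full, r2_env_given_cond = x$r2$env_given_cond,
         r2_cond_given_env = x$r2$cond_given_env,
         n_axes = nrow(x$eig))
}

#' @export
tidy.lfmm_fit <- function(x, ...) x$table

#' @export
glance.lfmm_fit <- function(x, ...) {
  tibble(K = x$K, lambda = x$lambda, fdr = x$fdr,
         gif_median = median(x$gif),
         n_significant = length(significant_sites(x)))
}
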