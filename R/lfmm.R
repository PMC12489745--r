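#' Latent-factor ridge associations between SNPs and environment
#'
#' Fits the latent factor model `Y = X B' + U V' + E` by alternating a
#' rank-K truncated SVD of `Y - X B'` (for the latent factors U V') with a
#' ridge regression of `Y - U V'` on X (penalty `lambda` on B), for at most
#' `max_iter` iterations. Association z-scores then come from per-SNP least
#' squares of Y on X with the latent factors U as covariates. Per variable,
#' squared z-scores are recalibrated by the genomic inflation factor
#' `lambda_gif = median(z^2) / median(chi2_1)`, converted to upper-tail
#' chi-squared p-values and to Storey q-values; SNPs with `q <= fdr` are
#' significant. Multiple testing is handled per environmental variable, not
#' pooled.
#'
#' @param Y response matrix (individuals x SNPs), columns are centered
#'   internally.
#' @param X environmental predictors (tibble with `id` or matrix), centered
#'   internally.
#' @param K number of latent factors (0 reduces to per-SNP regression;
#'   with `lambda = 0` that is exactly OLS).
#' @param lambda ridge penalty on the effect sizes (default 1e-5).
#' @param fdr q-value significance cutoff (default 0.1).
#' @param max_iter alternation cap (default 100).
#' @param tol relative objective change declaring convergence.
#' @return object of class `lfmm_fit`: `table` tibble (`site`, `variable`,
#'   `beta`, `z`, `p_raw`, `p_adj`, `q`, `significant`), `gif` named vector,
#'   `B`, `U`, `V`, `K`, `lambda`, `fdr`, `objective`.
#' @export
lfmm_scan <- function(Y, X, K = 5, lambda = 1e-5, fdr = 0.1,
                      max_iter = 100, tol = 1e-8) {
  Xm <- .env_matrix(X)
  n <- nrow(Y)
  if (K >= n) stop("K must be below the number of individuals")
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(Xm, scale = FALSE)
  p <- ncol(Xc)
  XtX <- crossprod(Xc) + diag(lambda, p)
  W <- matrix(0, n, ncol(Yc))
  B <- matrix(0, ncol(Yc), p)
  U <- NULL; V <- NULL
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    B <- t(solve(XtX, crossprod(Xc, Yc - W)))
    R <- Yc - Xc %*% t(B)
    if (K > 0) {
      sv <- svd(R, nu = K, nv = K)
      d <- sv$d[seq_len(K)]
      U <- sv$u %*% diag(d, K)
      V <- sv$v
      W <- tcrossprod(U, V)
    }
    o <- sum((Yc - Xc %*% t(B) - W)^2) + lambda * sum(B^2)
    obj <- c(obj, o)
    if (K == 0) break
    if (it > 1 && abs(obj[it - 1] - o) <= tol * max(obj[1], 1)) break
  }
  # per-SNP least squares with the latent factors as covariates
  D <- if (K > 0) cbind(Xc, sv$u[, seq_len(K), drop = FALSE]) else Xc
  H <- solve(crossprod(D))
  Co <- H %*% crossprod(D, Yc)                    # (p + K) x L coefficients
  rss <- colSums(Yc^2) - colSums(Co * crossprod(D, Yc))
  df <- n - ncol(D) - 1
  sigma2 <- pmax(rss, 0) / df
  sites <- colnames(Y)
  if (is.null(sites)) sites <- paste0("snp", seq_len(ncol(Y)))
  tabs <- vector("list", p)
  gif <- setNames(numeric(p), colnames(Xm))
  for (v in seq_len(p)) {
    se <- sqrt(H[v, v] * sigma2)
    z <- Co[v, ] / se
    z[!is.finite(z)] <- NA
    gif[v] <- median(z^2, na.rm = TRUE) / qchisq(0.5, df = 1)
    p_raw <- pchisq(z^2, df = 1, lower.tail = FALSE)
    p_adj <- pchisq(z^2 / gif[v], df = 1, lower.tail = FALSE)
    q <- storey_qvalue(p_adj)
    tabs[[v]] <- tibble(
      site = sites, variable = colnames(Xm)[v],
      beta = B[, v], z = z, p_raw = p_raw, p_adj = p_adj,
      q = as.numeric(q), significant = !is.na(q) & q <= fdr
    )
  }
  structure(list(
    table = dplyr::bind_rows(tabs), gif = gif, B = B, U = U, V = V,
    K = K, lambda = lambda, fdr = fdr, objective = obj
  ), class = "lfmm_fit")
}

#' @export
print.lfmm_fit <- function(x, ...) {
  cat(sprintf("<lfmm_fit> K = %d, lambda = %g; %d significant SNP-variable pairs at q <= %g\n",
              x$K, x$lambda, sum(x$table$significant, na.rm = TRUE), x$fdr))
  invisible(x)
}

#' Sites significant in an LFMM fit (any environmental variable)
#'
#' @param fit an [lfmm_scan()] result.
#' @param fdr optional override of the fit's q-value cutoff.
#' @return character vector of site ids.
#' @export
significant_sites <- function(fit, fdr = NULL) {
  tab <- fit$table
  if (is.null(fdr)) {
    unique(tab$site[tab$significant])
  } else {
    unique(tab$site[!is.na(tab$q) & tab$q <= fdr])
  }
}
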