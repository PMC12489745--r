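#' Admixture model fit by EM
#'
#' Maximises the binomial-mixture log-likelihood
#' `sum_ij [ g_ij log h_ij + (2 - g_ij) log(1 - h_ij) ]` with
#' `h_ij = sum_k q_ik f_kj` over ancestry fractions Q (rows summing to one)
#' and ancestral allele frequencies F, by EM block updates. Missing genotypes
#' are ignored by both the likelihood and the updates. The log-likelihood is
#' non-decreasing at every iteration; F is clamped to `[1e-6, 1 - 1e-6]`.
#'
#' Cross-validation masks a random `1/cv_folds` of the called genotype
#' entries per fold, refits, and scores the masked entries by the squared
#' prediction error `(g - 2*h)^2`.
#'
#' @param gm a [genotype_matrix()] (intended use: MAF-filtered, LD-pruned,
#'   relatedness-pruned data).
#' @param K number of ancestral populations (K = 1 has the closed form
#'   Q = 1, F = observed frequencies).
#' @param seed RNG seed (initialisation and CV fold assignment).
#' @param tol stop when the log-likelihood improves by less than this.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE` with a
#'   warning.
#' @param cv_folds number of CV folds (0 = skip cross-validation).
#' @return object of class `admix_fit`: `K`, `Q`, `F`, `loglik`,
#'   `loglik_trace`, `cv_error`, `converged`.
#' @export
admixture_fit <- function(gm, K, seed = 1, tol = 1e-3, max_iter = 1000,
                          cv_folds = 0) {
  stopifnot(K >= 1)
  G <- gm$dosages
  fit <- .admix_em(G, K, seed = seed, tol = tol, max_iter = max_iter)
  cv_error <- NA_real_
  if (cv_folds >= 2) {
    set.seed(seed + 1L)
    called <- which(!is.na(G))
    fold <- sample(rep_len(seq_len(cv_folds), length(called)))
    errs <- vapply(seq_len(cv_folds), function(f) {
      Gm <- G
      mask <- called[fold == f]
      Gm[mask] <- NA_integer_
      ft <- .admix_em(Gm, K, seed = seed + f, tol = tol, max_iter = max_iter,
                      quiet = TRUE)
      H <- ft$Q %*% ft$F
      mean((G[mask] - 2 * H[mask])^2)
    }, numeric(1))
    cv_error <- mean(errs)
  }
  structure(c(fit, list(cv_error = cv_error, ids = gm$individuals$id)),
            class = "admix_fit")
}

.admix_em <- function(G, K, seed = 1, tol = 1e-3, max_iter = 1000,
                      quiet = FALSE) {
  n <- nrow(G); L <- ncol(G)
  called <- !is.na(G)
  G0 <- G; G0[!called] <- 0L
  A2 <- 2L - G0; A2[!called] <- 0L         # reference-allele counts
  L_i <- rowSums(called)
  p_hat <- colSums(G0) / pmax(1, 2 * colSums(called))
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  if (K == 1) {
    Fm <- matrix(clamp(p_hat), 1, L)
    Q <- matrix(1, n, 1)
    H <- Q %*% Fm
    ll <- sum((G0 * log(H) + A2 * log(1 - H))[called])
    return(list(K = K, Q = Q, F = Fm, loglik = ll, loglik_trace = ll,
                converged = TRUE))
  }
  set.seed(seed)
  Q <- matrix(rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  Fm <- clamp(matrix(rep(p_hat, each = K), K, L) +
                matrix(runif(K * L, -0.1, 0.1), K, L))
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- Q %*% Fm
    H <- pmin(pmax(H, 1e-9), 1 - 1e-9)
    ll <- sum(G0[called] * log(H[called]) + A2[called] * log(1 - H[called]))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    Qn <- matrix(0, n, K)
    Fn <- Fm
    for (k in seq_len(K)) {
      Ak <- (Q[, k] %o% Fm[k, ]) / H        # P(ancestry k | alt allele)
      Bk <- (Q[, k] %o% (1 - Fm[k, ])) / (1 - H)
      Ea <- G0 * Ak                          # expected alt alleles from k
      Er <- A2 * Bk                          # expected ref alleles from k
      Qn[, k] <- rowSums(Ea + Er) / (2 * L_i)
      Fn[k, ] <- colSums(Ea) / pmax(colSums(Ea) + colSums(Er), 1e-12)
    }
    Q <- Qn / rowSums(Qn)
    Fm <- clamp(Fn)
  }
  if (!converged && !quiet) {
    warning("admixture EM did not converge in ", max_iter, " iterations")
  }
  list(K = K, Q = Q, F = Fm, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged)
}

#' Scan admixture models across K with cross-validation
#'
#' @param gm a [genotype_matrix()].
#' @param K_range integer vector of K values.
#' @param cv_folds CV folds (default 5).
#' @param ... passed to [admixture_fit()].
#' @return list of class `admix_scan`: `scan` tibble (`K`, `loglik`,
#'   `cv_error`), `best_K` (minimum CV error), `fits` (list of `admix_fit`).
#' @export
admixture_scan <- function(gm, K_range = 2:6, cv_folds = 5, ...) {
  fits <- lapply(K_range, function(k) admixture_fit(gm, k, cv_folds = cv_folds, ...))
  scan <- tibble(
    K = K_range,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    cv_error = vapply(fits, `[[`, numeric(1), "cv_error")
  )
  structure(list(scan = scan, best_K = K_range[which.min(scan$cv_error)],
                 fits = setNames(fits, paste0("K", K_range))),
            class = "admix_scan")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("<admix_fit> K = %d, %d individuals, loglik %.1f%s\n",
              x$K, nrow(x$Q), x$loglik,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' @export
print.admix_scan <- function(x, ...) {
  cat(sprintf("<admix_scan> K = %s; best K by CV error = %d\n",
              paste(range(x$scan$K), collapse = ".."), x$best_K))
  invisible(x)
}

#' Align the columns of an ancestry matrix with a reference
#'
#' Searches column permutations for the one minimising the mean absolute
#' difference — used to compare an estimated Q with a simulated truth whose
#' cluster labels are arbitrary.
#'
#' @param Q estimated ancestry matrix.
#' @param Q_ref reference matrix of the same shape.
#' @return `Q` with columns permuted to best match `Q_ref`.
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  perms <- .permutations(K)
  errs <- vapply(perms, function(pp) mean(abs(Q[, pp] - Q_ref)), numeric(1))
  Q[, perms[[which.min(errs)]]]
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- list()
  for (s in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(s, k, after = pos - 1L)
    }
  }
  out
}

#' Write ancestry fractions in the whitespace-delimited .Q layout
#'
#' @param fit an [admixture_fit()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(fit, path) {
  write.table(format(fit$Q, digits = 6), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
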