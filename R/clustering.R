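#' k-means scan over K with a BIC criterion
#'
#' For each candidate number of clusters the best of `n_starts` k-means runs
#' is kept and scored by `BIC = n * ln(WSS/n) + k * ln(n)` (WSS floored at a
#' small epsilon for degenerate zero-variance fits). The chosen K is the first
#' local BIC minimum — the last K before the BIC first increases — which can
#' be overridden through `choose_k`.
#'
#' @param scores PC score matrix, or a [pca_impute()] fit.
#' @param k_max largest K scanned (must be below the number of individuals).
#' @param n_starts random starts per K.
#' @param seed RNG seed.
#' @param n_axes optionally restrict to the leading axes of `scores`.
#' @param choose_k optional manual override of the chosen K.
#' @return object of class `cluster_scan`: `scan` tibble (`k`, `bic`, `wss`),
#'   `chosen_k`, `assignments` (factor) at the chosen K.
#' @export
kmeans_bic <- function(scores, k_max = 20, n_starts = 10, seed = 1,
                       n_axes = NULL, choose_k = NULL) {
  if (inherits(scores, "geno_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (!is.null(n_axes)) scores <- scores[, seq_len(n_axes), drop = FALSE]
  n <- nrow(scores)
  if (k_max < 2) stop("k_max must be at least 2")
  if (k_max >= n) stop("k_max must be below the number of individuals")
  eps <- 1e-10
  n_distinct_rows <- nrow(unique(scores))
  set.seed(seed)
  fits <- vector("list", k_max)
  wss <- numeric(k_max)
  wss[1] <- sum(scale(scores, scale = FALSE)^2)
  fits[[1]] <- list(cluster = rep(1L, n))
  for (k in 2:k_max) {
    if (n_distinct_rows < k) {
      # fewer distinct points than centers: a perfect fit with duplicates
      uq <- unique(scores)
      cl <- match(asplit(scores, 1), asplit(uq, 1))
      fits[[k]] <- list(cluster = as.integer(cl))
      wss[k] <- 0
    } else {
      km <- kmeans(scores, centers = k, nstart = n_starts, iter.max = 50)
      fits[[k]] <- km
      wss[k] <- km$tot.withinss
    }
  }
  bic <- n * log(pmax(wss, eps) / n) + seq_len(k_max) * log(n)
  k_hat <- if (!is.null(choose_k)) choose_k else {
    up <- which(diff(bic) > 0)
    if (length(up)) up[1] else which.min(bic)
  }
  structure(list(
    scan = tibble(k = seq_len(k_max), wss = wss, bic = bic),
    chosen_k = k_hat,
    assignments = factor(fits[[k_hat]]$cluster)
  ), class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("<cluster_scan> k = 1..%d, chosen k = %d\n",
              max(x$scan$k), x$chosen_k))
  invisible(x)
}

#' Discriminant analysis of principal components
#'
#' Fits linear discriminant functions on retained PC scores for given groups,
#' choosing the number of retained PCs by the a-score: for each candidate, the
#' mean over groups of (observed correct-reassignment rate minus the mean
#' reassignment rate under `n_perm` random permutations of the group labels).
#' At most `n_groups - 1` discriminant functions exist.
#'
#' @param scores PC score matrix or [pca_impute()] fit.
#' @param groups group labels, one per individual; every group needs at least
#'   two members.
#' @param n_pc_grid candidate numbers of retained PCs (default: 10 evenly
#'   spaced values up to a safe maximum).
#' @param n_perm label permutations per candidate (default 50).
#' @param seed RNG seed.
#' @return object of class `dapc_fit`: `best_n_pc`, `a_score` tibble,
#'   `discriminant_axes` (loadings of the LDA functions on the PCs),
#'   `ind_coord` (individuals on the discriminant functions), `assignments`,
#'   `group_centroids`, `prop_trace`.
#' @export
dapc_fit <- function(scores, groups, n_pc_grid = NULL, n_perm = 50, seed = 1) {
  if (inherits(scores, "geno_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  n <- nrow(scores)
  p_max <- min(ncol(scores), n - nlevels(groups) - 1)
  if (is.null(n_pc_grid)) {
    n_pc_grid <- unique(pmax(1, round(seq(1, p_max, length.out = 10))))
  }
  n_pc_grid <- n_pc_grid[n_pc_grid <= p_max]
  set.seed(seed)
  rate_by_group <- function(fit, S, g) {
    pred <- predict(fit, S)$class   # reassignment of the training individuals
    tapply(pred == g, g, mean)
  }
  a_scores <- vapply(n_pc_grid, function(np) {
    S <- scores[, seq_len(np), drop = FALSE]
    fit <- MASS::lda(S, grouping = groups)
    obs <- rate_by_group(fit, S, groups)
    perm <- replicate(n_perm, {
      gp <- sample(groups)
      fp <- MASS::lda(S, grouping = gp)
      rate_by_group(fp, S, gp)
    })
    mean(obs - rowMeans(perm))
  }, numeric(1))
  best <- n_pc_grid[which.max(a_scores)]
  S <- scores[, seq_len(best), drop = FALSE]
  fit <- MASS::lda(S, grouping = groups)
  pred <- predict(fit, S)
  centro <- apply(pred$x, 2, tapply, groups, mean)
  structure(list(
    best_n_pc = best,
    a_score = tibble(n_pc = n_pc_grid, a_score = a_scores),
    discriminant_axes = fit$scaling,
    ind_coord = pred$x,
    assignments = pred$class,
    groups = groups,
    group_centroids = centro,
    prop_trace = fit$svd^2 / sum(fit$svd^2)
  ), class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf("<dapc_fit> %d groups, %d PCs retained (best a-score), %d discriminant function(s)\n",
              nlevels(x$groups), x$best_n_pc, ncol(x$discriminant_axes)))
  invisible(x)
}
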