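#' Allele-sharing beta-kinship with inbreeding on the diagonal
#'
#' Per locus the matching proportion between individuals i and j with dosages
#' x is `(x_i x_j + (2 - x_i)(2 - x_j)) / 4`, and an individual's
#' self-matching is `1 - x (2 - x) / 2`. Matchings are averaged over
#' pairwise-complete loci, referenced to the mean off-diagonal matching M_B,
#' and scaled: `beta_ij = (M_ij - M_B) / (1 - M_B)`. The diagonal reports the
#' inbreeding coefficient `2 * beta*_ii - 1` computed from the
#' self-matching. By construction the off-diagonal betas average to zero, so
#' kinship is relative to the sampled set. Intended input is a dataset *not*
#' filtered on MAF — removing rare alleles degrades the estimator.
#'
#' @param gm a [genotype_matrix()].
#' @param min_loci individuals with fewer called loci are flagged (their
#'   estimates remain but are unreliable).
#' @return object of class `kinship_mat`: `beta` matrix (off-diagonal
#'   beta-kinship, diagonal inbreeding), `M_B`, `labels`, `flagged`,
#'   `call_rate`, `type = "beta"`.
#' @export
beta_kinship <- function(gm, min_loci = 100) {
  X <- gm$dosages
  called <- !is.na(X)
  A <- X; A[!called] <- 0L
  B <- 2L - X; B[!called] <- 0L
  Np <- tcrossprod(called * 1)              # shared called loci
  M <- (tcrossprod(A) + tcrossprod(B)) / (4 * Np)
  n_called <- rowSums(called)
  self_m <- 1 - rowSums(A * B, na.rm = TRUE) / (2 * n_called)
  off <- M[upper.tri(M)]
  M_B <- mean(off)
  beta <- (M - M_B) / (1 - M_B)
  diag(beta) <- 2 * (self_m - M_B) / (1 - M_B) - 1
  dimnames(beta) <- list(gm$individuals$id, gm$individuals$id)
  structure(list(beta = beta, M_B = M_B, labels = gm$individuals$id,
                 flagged = gm$individuals$id[n_called < min_loci],
                 call_rate = n_called / ncol(X), type = "beta"),
            class = "kinship_mat")
}

#' Robust pairwise kinship (between-family estimator)
#'
#' For each pair, `phi = (N_het_het - 2 * N_opposing_hom) /
#' (N_het_i + N_het_j)` over pairwise-complete loci — the KING-robust
#' estimator, which stays unbiased under population structure within
#' families and can go negative for individuals from diverged populations
#' (no clamping). The diagonal is the self-comparison value 0.5.
#'
#' @param gm a [genotype_matrix()].
#' @return object of class `kinship_mat` with `type = "robust"`; pairs with a
#'   zero denominator get `NA`.
#' @export
robust_kinship <- function(gm) {
  X <- gm$dosages
  called <- (!is.na(X)) * 1
  H <- (X == 1) * 1; H[is.na(X)] <- 0
  h0 <- (X == 0) * 1; h0[is.na(X)] <- 0
  h2 <- (X == 2) * 1; h2[is.na(X)] <- 0
  N_hh <- tcrossprod(H)
  N_opp <- tcrossprod(h0, h2) + tcrossprod(h2, h0)
  denom <- H %*% t(called) + called %*% t(H)
  phi <- (N_hh - 2 * N_opp) / denom
  phi[denom == 0] <- NA
  diag(phi) <- 0.5
  dimnames(phi) <- list(gm$individuals$id, gm$individuals$id)
  structure(list(beta = phi, M_B = NA_real_, labels = gm$individuals$id,
                 flagged = character(0),
                 call_rate = rowSums(called) / ncol(X), type = "robust"),
            class = "kinship_mat")
}

#' @export
print.kinship_mat <- function(x, ...) {
  off <- x$beta[upper.tri(x$beta)]
  cat(sprintf("<kinship_mat> (%s) %d individuals; off-diagonal range [%.3f, %.3f]\n",
              x$type, length(x$labels), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  if (length(x$flagged)) {
    cat("flagged (few called loci):", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Greedy removal of related individuals
#'
#' While any pair has kinship at or above the threshold, removes the
#' individual participating in the most such pairs; ties are broken by lower
#' call rate, then lexicographically smaller id. The survivors have no
#' remaining pair at or above the threshold.
#'
#' @param K a `kinship_mat` or plain symmetric matrix with id dimnames.
#' @param threshold removal threshold (default 0.125).
#' @param call_rate optional per-individual call rate for tie-breaking
#'   (taken from the `kinship_mat` when available).
#' @return character vector of removed ids (possibly empty).
#' @export
prune_relatives <- function(K, threshold = 0.125, call_rate = NULL) {
  if (inherits(K, "kinship_mat")) {
    if (is.null(call_rate)) call_rate <- K$call_rate
    K <- K$beta
  }
  K <- as.matrix(K)
  ids <- rownames(K)
  if (is.null(call_rate)) call_rate <- rep(1, nrow(K))
  adj <- !is.na(K) & K >= threshold
  diag(adj) <- FALSE
  removed <- character(0)
  alive <- rep(TRUE, nrow(K))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    cand <- cand[order(call_rate[cand], ids[cand])]
    drop <- cand[1]
    removed <- c(removed, ids[drop])
    alive[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  removed
}

#' Write a kinship matrix as TSV with id header row and column
#'
#' @param K a `kinship_mat`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = K$labels, K$beta, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
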