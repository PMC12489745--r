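# Small builders and independent oracles shared across test files.

# genotype matrix from a plain dosage matrix, sites evenly spaced on one chrom
make_gm <- function(dos, pos = NULL, chrom = "chr1", qual = NULL,
                    site_depth = NULL, region = NULL) {
  dos <- as.matrix(dos)
  n <- nrow(dos); L <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          ref = "A", alt = "T")
  if (!is.null(qual)) sites$qual <- qual
  if (!is.null(site_depth)) sites$mean_depth <- site_depth
  ind <- tibble::tibble(id = sprintf("i%02d", seq_len(n)))
  if (!is.null(region)) ind$region <- region
  genotype_matrix(dos, sites, ind)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# mean silhouette on euclidean distances (independent of any clustering pkg)
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  labels <- as.character(labels)
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# exhaustive minimum vertex cover size of the kinship graph (<= ~15 nodes)
min_vertex_cover <- function(adj) {
  n <- nrow(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  for (k in 0:n) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      covered <- apply(edges, 1, function(e) any(e %in% sub))
      if (all(covered)) return(k)
    }
  }
  n
}

# brute-force within-window LD violation count for a pruned set: all pairs of
# kept sites that share at least one half-open sliding window and exceed the
# r2 threshold
ld_violations <- function(gm, kept, window_kb, step_kb, r2_threshold) {
  idx <- match(kept, gm$sites$site)
  pos <- gm$sites$pos[idx]
  chrom <- gm$sites$chrom[idx]
  w <- window_kb * 1000; st <- step_kb * 1000
  bad <- 0L
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a || chrom[b] != chrom[a]) next
      pmin_ <- min(pos[a], pos[b]); pmax_ <- max(pos[a], pos[b])
      starts <- seq(0, pmax_, by = st)
      if (!any(starts <= pmin_ & pmax_ < starts + w)) next
      r2 <- suppressWarnings(
        cor(gm$dosages[, idx[a]], gm$dosages[, idx[b]],
            use = "pairwise.complete.obs")^2)
      if (!is.na(r2) && r2 > r2_threshold) bad <- bad + 1L
    }
  }
  bad
}

# independent VIF computation from the correlation matrix inverse
vif_oracle <- function(X) {
  R <- cor(X)
  diag(solve(R))
}
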