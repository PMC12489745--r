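#' @keywords internal
#' Resolve a population grouping: either a metadata column name or a label
#' vector aligned with individuals.
.resolve_pops <- function(gm, pops) {
  if (length(pops) == 1 && is.character(pops) &&
      pops %in% names(gm$individuals)) {
    pops <- gm$individuals[[pops]]
  }
  if (length(pops) != nrow(gm$dosages)) {
    stop("pops must name a metadata column or give one label per individual")
  }
  factor(pops)
}

#' @keywords internal
#' Per-population, per-locus sufficient statistics: called count, alt-allele
#' sum, squared-dosage sum, het count. Each is a pops x loci matrix.
.pop_locus_stats <- function(dos, pops) {
  lv <- levels(pops)
  called <- !is.na(dos)
  d0 <- dos; d0[!called] <- 0L
  agg <- function(M) {
    m <- vapply(lv, function(g) colSums(M[pops == g, , drop = FALSE]),
                numeric(ncol(M)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)   # single-locus input
    t(m)
  }
  list(levels = lv,
       n = agg(called * 1),
       s1 = agg(d0),
       s2 = agg(d0^2),
       het = agg((dos == 1 & called) * 1))
}

#' Nei diversity and differentiation statistics
#'
#' Per-locus observed heterozygosity (Ho, unweighted mean across
#' populations), within-population gene diversity Hs with the Nei-Chesser
#' small-sample correction using the harmonic mean sample size, and total
#' gene diversity Ht from mean allele frequencies with the matching
#' correction. Global values are locus averages (ratio-of-averages), with
#' `Fst = 1 - Hs/Ht` and `Fis = 1 - Ho/Hs`. Loci lacking two called
#' genotypes in every population are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param pops metadata column name (e.g. `"region"`) or per-individual label
#'   vector.
#' @return object of class `pop_stats`: `per_locus` tibble and `global`
#'   one-row tibble (`ho`, `hs`, `ht`, `fst`, `fis`).
#' @export
nei_basic_stats <- function(gm, pops) {
  pops <- .resolve_pops(gm, pops)
  st <- .pop_locus_stats(gm$dosages, pops)
  if (any(rowSums(st$n) == 0)) {
    stop("population with no called data: ",
         paste(st$levels[rowSums(st$n) == 0], collapse = ", "))
  }
  use <- colSums(st$n >= 2) == length(st$levels)
  if (!any(use)) stop("no locus with >= 2 called genotypes in every population")
  n <- st$n[, use, drop = FALSE]
  p <- st$s1[, use, drop = FALSE] / (2 * n)
  ho_pop <- st$het[, use, drop = FALSE] / n
  r <- length(st$levels)
  mho <- colMeans(ho_pop)
  msp2 <- colMeans(p^2 + (1 - p)^2)
  nh <- r / colSums(1 / n)                    # harmonic mean sample size
  hs <- nh / (nh - 1) * (1 - msp2 - mho / (2 * nh))
  pbar <- colMeans(p)
  ht <- 1 - (pbar^2 + (1 - pbar)^2) + hs / (nh * r) - mho / (2 * nh * r)
  per_locus <- tibble(
    site = gm$sites$site[use], ho = mho, hs = hs, ht = ht,
    fst = 1 - hs / ht, fis = 1 - mho / hs
  )
  glob <- tibble(ho = mean(mho), hs = mean(hs), ht = mean(ht))
  glob$fst <- 1 - glob$hs / glob$ht
  glob$fis <- 1 - glob$ho / glob$hs
  structure(list(per_locus = per_locus, global = glob, pops = pops),
            class = "pop_stats")
}

#' @export
print.pop_stats <- function(x, ...) {
  cat("<pop_stats>", nrow(x$per_locus), "loci,", nlevels(x$pops), "populations\n")
  print(x$global)
  invisible(x)
}

#' @keywords internal
#' Weir-Cockerham per-locus variance components a (among populations),
#' b (among individuals within populations), c (within individuals).
.wc_components <- function(st, use = NULL) {
  n_all <- st$n
  if (is.null(use)) use <- rep(TRUE, ncol(n_all))
  idx <- which(use)
  a <- b <- cc <- rep(NA_real_, length(idx))
  for (j in seq_along(idx)) {
    l <- idx[j]
    inpop <- st$n[, l] > 0
    n_i <- st$n[inpop, l]
    r <- sum(inpop)
    if (r < 2) next
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nsum <- sum(n_i)
    nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
    if (nc <= 0) next
    p_i <- st$s1[inpop, l] / (2 * n_i)
    h_i <- st$het[inpop, l] / n_i
    pbar <- sum(n_i * p_i) / nsum
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / nsum
    pq <- pbar * (1 - pbar)
    a[j] <- (nbar / nc) *
      (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[j] <- (nbar / (nbar - 1)) *
      (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[j] <- hbar / 2
  }
  list(a = a, b = b, c = cc, idx = idx)
}

#' Weir-Cockerham theta and f
#'
#' Per-locus variance components a/b/c of the Weir-Cockerham (1984)
#' hierarchical model, aggregated across loci as ratios of sums:
#' `theta = sum(a) / sum(a + b + c)` and `f = 1 - sum(c) / sum(b + c)`.
#'
#' @inheritParams nei_basic_stats
#' @return object of class `wc_stats`: `theta`, `fis`, `per_locus` tibble of
#'   components.
#' @export
wc_stats <- function(gm, pops) {
  pops <- .resolve_pops(gm, pops)
  st <- .pop_locus_stats(gm$dosages, pops)
  comp <- .wc_components(st)
  ok <- !is.na(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || denom <= 0) {
    stop("theta undefined: no polymorphic locus with usable samples")
  }
  theta <- sum(comp$a[ok]) / denom
  fis <- 1 - sum(comp$c[ok]) / sum(comp$b[ok] + comp$c[ok])
  structure(list(
    theta = theta, fis = fis,
    per_locus = tibble(site = gm$sites$site[comp$idx[ok]],
                       a = comp$a[ok], b = comp$b[ok], c = comp$c[ok])
  ), class = "wc_stats")
}

#' @export
print.wc_stats <- function(x, ...) {
  cat(sprintf("<wc_stats> theta = %.4f, f = %.4f (%d loci)\n",
              x$theta, x$fis, nrow(x$per_locus)))
  invisible(x)
}

#' Population-specific beta-FST (allele matching) with bootstrap CIs
#'
#' Within-population matching `M_i` is the average allele-matching proportion
#' between distinct individuals of population i; `M_B` is the mean matching
#' between individuals of different populations, averaged over population
#' pairs. `beta_i = (M_i - M_B) / (1 - M_B)` after averaging the matchings
#' across loci; the overall beta is the mean of the per-population values.
#' Percentile confidence intervals come from bootstrapping loci.
#'
#' @inheritParams nei_basic_stats
#' @param n_boot bootstrap replicates over loci (>= 2).
#' @param seed RNG seed for the bootstrap.
#' @param ci confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @return object of class `beta_stats`: `per_pop` tibble (`pop`, `beta`,
#'   `ci_low`, `ci_high`, `fis`), `overall` tibble, `n_boot`.
#' @export
beta_fst <- function(gm, pops, n_boot = 1000, seed = 1, ci = 0.95) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  pops <- .resolve_pops(gm, pops)
  if (nlevels(pops) < 2) stop("need at least 2 populations")
  st <- .pop_locus_stats(gm$dosages, pops)
  lv <- st$levels
  r <- length(lv)
  L <- ncol(st$n)
  # per-locus within-population matching between distinct individuals
  Mw <- matrix(NA_real_, L, r, dimnames = list(NULL, lv))
  for (i in seq_len(r)) {
    n <- st$n[i, ]; s1 <- st$s1[i, ]; s2 <- st$s2[i, ]
    t1 <- 2 * n - s1
    t2 <- 4 * n - 4 * s1 + s2
    m <- ((s1^2 - s2) + (t1^2 - t2)) / (4 * n * (n - 1))
    m[n < 2] <- NA
    Mw[, i] <- m
  }
  # per-locus between-population matching, mean over population pairs
  pair_idx <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  Mb <- matrix(NA_real_, L, nrow(pair_idx))
  for (k in seq_len(nrow(pair_idx))) {
    i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
    ni <- st$n[i, ]; nj <- st$n[j, ]
    m <- (st$s1[i, ] * st$s1[j, ] +
            (2 * ni - st$s1[i, ]) * (2 * nj - st$s1[j, ])) / (4 * ni * nj)
    m[ni < 1 | nj < 1] <- NA
    Mb[, k] <- m
  }
  beta_from <- function(rows) {
    mw <- colMeans(Mw[rows, , drop = FALSE], na.rm = TRUE)
    mb <- mean(colMeans(Mb[rows, , drop = FALSE], na.rm = TRUE))
    (mw - mb) / (1 - mb)
  }
  est <- beta_from(seq_len(L))
  set.seed(seed)
  boot <- t(replicate(n_boot, beta_from(sample.int(L, L, replace = TRUE))))
  qs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  ci_mat <- apply(boot, 2, quantile, probs = qs, na.rm = TRUE)
  ov_boot <- rowMeans(boot)
  # per-population Fis (small-sample-corrected within-population diversity)
  fis_i <- vapply(seq_len(r), function(i) {
    n <- st$n[i, ]; ok <- n >= 2
    p <- st$s1[i, ok] / (2 * n[ok])
    ho <- st$het[i, ok] / n[ok]
    hs <- n[ok] / (n[ok] - 1) * (2 * p * (1 - p) - ho / (2 * n[ok]))
    1 - mean(ho) / mean(hs)
  }, numeric(1))
  structure(list(
    per_pop = tibble(pop = lv, beta = unname(est),
                     ci_low = unname(ci_mat[1, ]),
                     ci_high = unname(ci_mat[2, ]), fis = fis_i),
    overall = tibble(beta = mean(est),
                     ci_low = quantile(ov_boot, qs[1], names = FALSE),
                     ci_high = quantile(ov_boot, qs[2], names = FALSE)),
    n_boot = n_boot, seed = seed
  ), class = "beta_stats")
}

#' @export
print.beta_stats <- function(x, ...) {
  cat("<beta_stats> population-specific beta-FST (", x$n_boot, "bootstraps )\n")
  print(x$per_pop)
  invisible(x)
}

#' Pairwise Weir-Cockerham FST with bootstrap CIs
#'
#' Applies the two-population Weir-Cockerham estimator to every population
#' pair, with percentile bootstrap over loci.
#'
#' @inheritParams beta_fst
#' @return object of class `pairwise_fst`: `fst`, `ci_low`, `ci_high`
#'   (symmetric matrices, zero diagonal) and `pairs` tibble.
#' @export
pairwise_fst <- function(gm, pops, n_boot = 100, seed = 1, ci = 0.95) {
  pops <- .resolve_pops(gm, pops)
  lv <- levels(pops)
  r <- length(lv)
  if (r < 2) stop("need at least 2 populations")
  st <- .pop_locus_stats(gm$dosages, pops)
  qs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  fst <- lo <- hi <- matrix(0, r, r, dimnames = list(lv, lv))
  pairs <- list()
  set.seed(seed)
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      sub <- list(levels = lv[c(i, j)],
                  n = st$n[c(i, j), , drop = FALSE],
                  s1 = st$s1[c(i, j), , drop = FALSE],
                  s2 = st$s2[c(i, j), , drop = FALSE],
                  het = st$het[c(i, j), , drop = FALSE])
      comp <- .wc_components(sub)
      ok <- which(!is.na(comp$a))
      a <- comp$a[ok]; b <- comp$b[ok]; cc <- comp$c[ok]
      th <- sum(a) / sum(a + b + cc)
      bt <- replicate(n_boot, {
        s <- sample.int(length(a), length(a), replace = TRUE)
        sum(a[s]) / sum(a[s] + b[s] + cc[s])
      })
      cl <- quantile(bt, qs[1], na.rm = TRUE, names = FALSE)
      ch <- quantile(bt, qs[2], na.rm = TRUE, names = FALSE)
      fst[i, j] <- fst[j, i] <- th
      lo[i, j] <- lo[j, i] <- cl
      hi[i, j] <- hi[j, i] <- ch
      pairs[[length(pairs) + 1]] <-
        tibble(pop_a = lv[i], pop_b = lv[j], fst = th,
               ci_low = cl, ci_high = ch)
    }
  }
  structure(list(fst = fst, ci_low = lo, ci_high = hi,
                 pairs = dplyr::bind_rows(pairs), n_boot = n_boot),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("<pairwise_fst> Weir-Cockerham, bootstrap CIs over loci\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Nei's genetic distance between groups
#'
#' Standard (1972) distance `D = -ln( J_xy / sqrt(J_x * J_y) )` with identity
#' sums accumulated over loci before the ratio; the 1978 variant applies the
#' small-sample correction to the within-group identities. Individual-level
#' distances (each individual a "population" of one, frequencies 0/0.5/1 from
#' its two alleles) are obtained by passing `groups = "id"`.
#'
#' @param gm a [genotype_matrix()].
#' @param groups metadata column name or label vector.
#' @param variant `"1972"` (default) or `"1978"` (unbiased).
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_D <- function(gm, groups, variant = c("1972", "1978")) {
  variant <- match.arg(variant)
  groups <- .resolve_pops(gm, groups)
  st <- .pop_locus_stats(gm$dosages, groups)
  if (any(rowSums(st$n) == 0)) {
    stop("group with no called data: ",
         paste(st$levels[rowSums(st$n) == 0], collapse = ", "))
  }
  lv <- st$levels
  r <- length(lv)
  P <- st$s1 / (2 * st$n)                   # r x L alt frequency (NaN if n=0)
  D <- matrix(0, r, r, dimnames = list(lv, lv))
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      ok <- st$n[i, ] > 0 & st$n[j, ] > 0
      pi_ <- P[i, ok]; pj <- P[j, ok]
      jxy <- sum(pi_ * pj + (1 - pi_) * (1 - pj))
      if (variant == "1972") {
        jx <- sum(pi_^2 + (1 - pi_)^2)
        jy <- sum(pj^2 + (1 - pj)^2)
      } else {
        ni2 <- 2 * st$n[i, ok]; nj2 <- 2 * st$n[j, ok]
        jx <- sum((ni2 * (pi_^2 + (1 - pi_)^2) - 1) / (ni2 - 1))
        jy <- sum((nj2 * (pj^2 + (1 - pj)^2) - 1) / (nj2 - 1))
      }
      D[i, j] <- D[j, i] <- -log(jxy / sqrt(jx * jy))
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch lengths are clamped to
#' zero with the magnitude transferred to the sister edge so leaf-to-leaf path
#' lengths through the parent are preserved.
#'
#' @param D symmetric distance matrix with labels.
#' @param clamp_negative apply the negative-branch adjustment (default TRUE).
#' @return newick string (with the `phylo` tree attached as attribute
#'   `"tree"`).
#' @export
nj_tree <- function(D, clamp_negative = TRUE) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 labels")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(D))
  if (clamp_negative && any(tr$edge.length < 0)) {
    for (e in which(tr$edge.length < 0)) {
      parent <- tr$edge[e, 1]
      sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
      neg <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      if (length(sib)) {
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + abs(neg)
      }
    }
  }
  nwk <- ape::write.tree(tr)
  attr(nwk, "tree") <- tr
  nwk
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D symmetric labelled distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(D, path) {
  D <- as.matrix(D)
  lines <- c(format(nrow(D)),
             paste(formatC(rownames(D), width = 10, flag = "-"),
                   apply(format(D, digits = 6), 1, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
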