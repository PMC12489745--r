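#' Pairwise linkage disequilibrium (r-squared)
#'
#' r² between two sites is the squared Pearson correlation of their dosage
#' vectors over individuals called at both sites. Pairs are restricted to the
#' same chromosome, at most `window_snps` apart in SNP order and at most
#' `max_dist_kb` apart physically. Pairs where either site has no dosage
#' variance among the shared calls are kept in the output with `r2 = NA`.
#'
#' @param gm a [genotype_matrix()] with sites sorted by position.
#' @param window_snps maximum number of intervening SNPs (default 100).
#' @param max_dist_kb maximum physical distance in kb (default 1000).
#' @return tibble: `chrom`, `site_a`, `site_b`, `distance_bp`, `r2`.
#' @export
ld_pairs <- function(gm, window_snps = 100, max_dist_kb = 1000) {
  out <- vector("list", 0L)
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    pos <- gm$sites$pos[idx]
    dos <- gm$dosages[, idx, drop = FALSE]
    n <- length(idx)
    if (n < 2) next
    res <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      jmax <- min(n, i + window_snps)
      j <- (i + 1L):jmax
      j <- j[pos[j] - pos[i] <= max_dist_kb * 1000]
      if (length(j) == 0) next
      r <- suppressWarnings(
        cor(dos[, i], dos[, j, drop = FALSE], use = "pairwise.complete.obs")
      )
      res[[i]] <- tibble(
        chrom = chr,
        site_a = gm$sites$site[idx[i]], site_b = gm$sites$site[idx[j]],
        distance_bp = pos[j] - pos[i], r2 = as.vector(r)^2
      )
    }
    out <- c(out, res)
  }
  dplyr::bind_rows(out)
}

#' Bin r-squared by physical distance (LD decay profile)
#'
#' @param pairs output of [ld_pairs()].
#' @param bin_width_kb bin width in kb; bins are half-open and cover
#'   \[0, max distance\]; empty bins are emitted with `n_pairs = 0`.
#' @return tibble: `bin_start_kb`, `bin_end_kb`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(pairs, bin_width_kb) {
  if (bin_width_kb <= 0) stop("bin_width_kb must be positive")
  if (nrow(pairs) == 0) stop("empty pair list")
  w <- bin_width_kb * 1000
  bin <- floor(pairs$distance_bp / w)
  all_bins <- 0:max(bin)
  ok <- !is.na(pairs$r2)
  agg <- tibble(bin = bin[ok], r2 = pairs$r2[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n())
  tibble(bin = all_bins) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::mutate(
      bin_start_kb = .data$bin * bin_width_kb,
      bin_end_kb = (.data$bin + 1) * bin_width_kb,
      n_pairs = dplyr::coalesce(.data$n_pairs, 0L)
    ) |>
    dplyr::select("bin_start_kb", "bin_end_kb", "mean_r2", "n_pairs")
}

#' Windowed LD pruning
#'
#' Sites are ranked by a keep-priority (lower missingness first, then smaller
#' position; chromosome order breaks remaining ties) and a site is removed
#' exactly when some higher-priority site sharing a sliding window has
#' r² strictly above the threshold with it. After pruning, no two surviving
#' sites that share a window exceed the threshold, and the removed set grows
#' monotonically as the threshold decreases.
#'
#' @param gm a [genotype_matrix()].
#' @param window_kb sliding window width in kb (default 50); windows are
#'   half-open `[start, start + window)` and advance by `step_kb`.
#' @param step_kb window step in kb (default 10).
#' @param r2_threshold removal threshold in (0, 1]; comparison is strict.
#' @return list of class `ld_prune`: `kept` and `removed` site-id character
#'   vectors and `params`.
#' @export
ld_prune <- function(gm, window_kb = 50, step_kb = 10, r2_threshold = 0.2) {
  if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must be in (0, 1]")
  f_miss <- colMeans(is.na(gm$dosages))
  removed <- logical(ncol(gm$dosages))
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    pos <- gm$sites$pos[idx]
    w <- window_kb * 1000
    starts <- seq(0, max(pos), by = step_kb * 1000)
    starts <- starts[starts + w > min(pos)]
    # priority: smaller is better (kept); a pair's worse member gets removed
    prio <- order(order(f_miss[idx], pos))
    for (s0 in starts) {
      inw <- which(pos >= s0 & pos < s0 + w)
      if (length(inw) < 2) next
      r2 <- suppressWarnings(
        cor(gm$dosages[, idx[inw], drop = FALSE], use = "pairwise.complete.obs")^2
      )
      hit <- which(r2 > r2_threshold & upper.tri(r2), arr.ind = TRUE)
      if (nrow(hit) == 0) next
      a <- inw[hit[, 1]]; b <- inw[hit[, 2]]
      worse <- ifelse(prio[a] > prio[b], a, b)
      removed[idx[worse]] <- TRUE
    }
  }
  structure(list(
    kept = gm$sites$site[!removed],
    removed = gm$sites$site[removed],
    params = list(window_kb = window_kb, step_kb = step_kb,
                  r2_threshold = r2_threshold)
  ), class = "ld_prune")
}

#' @export
print.ld_prune <- function(x, ...) {
  cat(sprintf("<ld_prune> kept %d / removed %d sites (window %g kb, step %g kb, r2 > %g)\n",
              length(x$kept), length(x$removed), x$params$window_kb,
              x$params$step_kb, x$params$r2_threshold))
  invisible(x)
}

#' Write a site-id list (one `chrom:pos` per line)
#'
#' @param sites character vector of site ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_list <- function(sites, path) {
  writeLines(sites, path)
  invisible(path)
}
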