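#' Site filter configuration
#'
#' Holds the per-site quality-control thresholds. Defaults are the working
#' values for low-coverage whole-genome data: mean depth in \[5, 12\] (about
#' twice the mean coverage as the upper bound), QUAL at least 50, at most 10%
#' missing genotypes, biallelic SNPs only, and no MAF floor (set `maf_min` to
#' e.g. 0.05 for analyses that need common variants).
#'
#' @param min_mean_depth,max_mean_depth bounds on per-site mean depth (x).
#' @param min_qual minimum variant QUAL.
#' @param max_missing_frac maximum fraction of missing genotypes per site.
#' @param maf_min minimum minor allele frequency (sites with MAF strictly
#'   below are removed); must be < 0.5.
#' @param biallelic_only keep only single-base REF/ALT SNPs.
#' @return a `site_filter_config` list.
#' @export
site_filter_config <- function(min_mean_depth = 5, max_mean_depth = 12,
                               min_qual = 50, max_missing_frac = 0.10,
                               maf_min = 0, biallelic_only = TRUE) {
  if (min_mean_depth > max_mean_depth) stop("min_mean_depth > max_mean_depth")
  if (maf_min >= 0.5 || maf_min < 0) stop("maf_min must be in [0, 0.5)")
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must be in [0, 1]")
  }
  structure(list(min_mean_depth = min_mean_depth,
                 max_mean_depth = max_mean_depth,
                 min_qual = min_qual,
                 max_missing_frac = max_missing_frac,
                 maf_min = maf_min,
                 biallelic_only = biallelic_only),
            class = "site_filter_config")
}

#' Apply individual and site quality filters
#'
#' Individuals are filtered first — mean depth below `ind_min_depth` (in x
#' coverage) or missing-genotype fraction above `ind_max_missing` — then sites
#' are filtered on mean depth, QUAL, missingness, biallelic status and MAF,
#' with site missingness and MAF recomputed on the surviving individuals.
#' Per-individual depth and missingness are frozen into the metadata on first
#' use so that re-applying the same configuration is a no-op (idempotent
#' filtering).
#'
#' Depth and QUAL rules are skipped for records whose metadata lacks the
#' corresponding value (`NA` passes); a rule can therefore only remove records
#' it can actually evaluate.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [site_filter_config()].
#' @param ind_min_depth minimum per-individual mean depth (x).
#' @param ind_max_missing maximum per-individual missing fraction.
#' @return list with `genotypes` (filtered `geno_mat`) and `report` (tibble of
#'   per-rule removal counts plus in/out totals; a record can fail several
#'   rules). Write the report with [write_filter_report()].
#' @export
filter_genotypes <- function(gm, cfg = site_filter_config(),
                             ind_min_depth = 3, ind_max_missing = 0.20) {
  stopifnot(inherits(gm, "geno_mat"), inherits(cfg, "site_filter_config"))
  if (nrow(gm$dosages) == 0 || ncol(gm$dosages) == 0) stop("empty genotype matrix")
  ind <- gm$individuals
  if (!"mean_depth" %in% names(ind)) ind$mean_depth <- NA_real_
  if (!"f_missing" %in% names(ind)) ind$f_missing <- rowMeans(is.na(gm$dosages))
  fail_depth <- !is.na(ind$mean_depth) & ind$mean_depth < ind_min_depth
  fail_miss <- ind$f_missing > ind_max_missing
  keep_ind <- !(fail_depth | fail_miss)
  if (!any(keep_ind)) stop("all individuals removed by filters")
  gm$individuals <- ind
  g2 <- gm[keep_ind, ]

  s <- g2$sites
  dos <- g2$dosages
  site_md <- if ("mean_depth" %in% names(s)) s$mean_depth else rep(NA_real_, nrow(s))
  site_q <- if ("qual" %in% names(s)) s$qual else rep(NA_real_, nrow(s))
  f_site_miss <- colMeans(is.na(dos))
  p <- .alt_freq(dos)
  site_maf <- pmin(p, 1 - p)
  is_snp <- if (all(c("ref", "alt") %in% names(s))) {
    s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T")
  } else rep(TRUE, nrow(s))

  fail <- list(
    site_depth_low  = !is.na(site_md) & site_md < cfg$min_mean_depth,
    site_depth_high = !is.na(site_md) & site_md > cfg$max_mean_depth,
    site_qual       = !is.na(site_q) & site_q < cfg$min_qual,
    site_missing    = f_site_miss > cfg$max_missing_frac,
    site_biallelic  = if (cfg$biallelic_only) !is_snp else rep(FALSE, nrow(s)),
    site_maf        = !is.na(site_maf) & site_maf < cfg$maf_min
  )
  keep_site <- !Reduce(`|`, fail)
  out <- g2[, keep_site]

  report <- tibble(
    rule = c("ind_depth", "ind_missing", names(fail)),
    n_removed = c(sum(fail_depth), sum(fail_miss), vapply(fail, sum, integer(1)))
  )
  attr(report, "totals") <- list(
    n_individuals_in = nrow(gm$dosages), n_individuals_out = nrow(out$dosages),
    n_sites_in = ncol(gm$dosages), n_sites_out = ncol(out$dosages)
  )
  list(genotypes = out, report = report)
}

#' Write a filter report as JSON
#'
#' @param report the `report` element returned by [filter_genotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  totals <- attr(report, "totals")
  obj <- c(totals, list(per_rule = as.list(setNames(report$n_removed, report$rule))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
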