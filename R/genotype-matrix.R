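#' Genotype matrix container
#'
#' Bundles an individuals-by-sites biallelic dosage matrix (counts of the
#' alternate allele: 0, 1, 2, or `NA` for missing) with per-site and
#' per-individual metadata. Every stage of the pipeline consumes and returns
#' this container; results themselves come back as tibbles.
#'
#' @param dosages integer matrix, individuals in rows and sites in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param sites data frame with one row per site: `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, and optionally `qual` and `mean_depth`. Positions must be
#'   strictly increasing within a chromosome.
#' @param individuals data frame with one row per individual: `id` (unique),
#'   and optionally `region`, `subregion`, `lat`, `lon`.
#'
#' @return An object of class `geno_mat`: a list with elements `dosages`,
#'   `sites` (tibble, with a `site` id column `chrom:pos`) and `individuals`
#'   (tibble).
#' @export
genotype_matrix <- function(dosages, sites, individuals) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  sites <- as_tibble(sites)
  individuals <- as_tibble(individuals)
  if (nrow(sites) != ncol(dosages)) stop("sites rows must match dosage columns")
  if (nrow(individuals) != nrow(dosages)) {
    stop("individuals rows must match dosage rows")
  }
  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  if (!all(c("chrom", "pos") %in% names(sites))) stop("sites needs chrom and pos")
  for (chr in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == chr]
    if (any(diff(p) <= 0)) stop("site positions must strictly increase within ", chr)
  }
  if (!"site" %in% names(sites)) {
    sites$site <- paste0(sites$chrom, ":", sites$pos)
  }
  sites <- dplyr::relocate(sites, "site")
  rownames(dosages) <- individuals$id
  colnames(dosages) <- sites$site
  structure(list(dosages = dosages, sites = sites, individuals = individuals),
            class = "geno_mat")
}

#' @export
print.geno_mat <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("<geno_mat> %d individuals x %d sites (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_mat <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i individual index (logical, integer or id character vector).
#' @param j site index (logical, integer or site id character vector).
#' @param ... unused.
#' @return a `geno_mat` restricted to the selected rows/columns.
#' @export
`[.geno_mat` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$individuals$id)
  if (is.character(j)) j <- match(j, x$sites$site)
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  x$sites[j, , drop = FALSE],
                  x$individuals[i, , drop = FALSE])
}

#' Per-site minor allele frequency
#'
#' The alternate-allele frequency at a site is the dosage sum over twice the
#' number of called genotypes; the MAF is the lesser of that frequency and its
#' complement, so relabelling the alleles leaves it unchanged. Sites with no
#' called genotype get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @return tibble with columns `site`, `chrom`, `pos`, `alt_freq`, `maf`.
#' @export
maf <- function(gm) {
  p <- .alt_freq(gm$dosages)
  tibble(site = gm$sites$site, chrom = gm$sites$chrom, pos = gm$sites$pos,
         alt_freq = p, maf = pmin(p, 1 - p))
}

.alt_freq <- function(dos) {
  n_called <- colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  unname(p)
}
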