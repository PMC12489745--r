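#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) with vcfR and encodes each diploid GT call as the count
#' of alternate alleles. Half-calls (`./1`), non-diploid records and calls to
#' alleles other than 0/1 become missing. When per-genotype `DP` is present,
#' per-site mean depth and per-individual mean depth / missing fraction are
#' recorded in the metadata; alternatively the site depth can be taken from
#' `INFO/DP` divided by the number of samples.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param metadata optional individual metadata: a data frame or path to a
#'   tab-delimited file with header `id region subregion lat lon`. Every
#'   metadata id must be present in the VCF.
#' @param depth_from `"format"` (default, mean of `FORMAT/DP` across samples)
#'   or `"info"` (`INFO/DP` divided by sample count).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, metadata = NULL, depth_from = c("format", "info")) {
  depth_from <- match.arg(depth_from)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_chr <- vcfR::extract.gt(v, element = "GT")            # sites x individuals
  ids <- colnames(gt_chr)
  dos <- .gt_to_dosage(gt_chr)                              # sites x individuals
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(dp) && all(is.na(dp))) dp <- NULL
  mean_depth <- rep(NA_real_, nrow(fix))
  if (depth_from == "format" && !is.null(dp)) {
    mean_depth <- unname(rowMeans(dp, na.rm = TRUE))
  } else if (depth_from == "info") {
    m <- regmatches(fix$INFO, regexpr("(?<=^DP=|;DP=)[0-9.]+", fix$INFO, perl = TRUE))
    has <- grepl("(^|;)DP=", fix$INFO)
    mean_depth[has] <- as.numeric(m) / length(ids)
  }

  sites <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, qual = qual, mean_depth = mean_depth
  )
  individuals <- tibble(id = ids)
  if (!is.null(dp)) {
    individuals$mean_depth <- unname(colMeans(dp, na.rm = TRUE))
  }
  individuals$f_missing <- colMeans(is.na(dos))

  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read_metadata(metadata) else as_tibble(metadata)
    absent <- setdiff(md$id, ids)
    if (length(absent) > 0) {
      stop("metadata id not present in VCF: ", paste(absent, collapse = ", "))
    }
    individuals <- dplyr::left_join(individuals, md, by = "id")
  }
  genotype_matrix(t(dos), sites, individuals)
}

.gt_to_dosage <- function(gt_chr) {
  u <- unique(as.vector(gt_chr))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".") || !all(al %in% c("0", "1"))) {
      return(NA_integer_)
    }
    sum(al == "1")
  }, integer(1))
  out <- lut[match(as.vector(gt_chr), u)]
  dim(out) <- dim(gt_chr)
  dimnames(out) <- dimnames(gt_chr)
  out
}

#' Read an individual metadata table
#'
#' Tab-delimited with header `id region subregion lat lon`.
#' @param path file path.
#' @return tibble.
#' @export
read_metadata <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, colClasses = list(id = "character")))
}

#' Write a genotype matrix as VCF v4.2
#'
#' Dosages are serialized as unphased diploid GT (`0/0`, `0/1`, `1/1`, `./.`).
#' An optional per-genotype depth matrix is written as `FORMAT/DP`; site QUAL
#' comes from the site metadata when present.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @param depth optional integer matrix of per-genotype depths, same shape as
#'   `gm$dosages`.
#' @param source_note free-text string recorded in the header (e.g. the
#'   generating seed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, depth = NULL, source_note = NULL) {
  dos <- gm$dosages
  n_ind <- nrow(dos)
  gt <- c("0/0", "0/1", "1/1")[dos + 1L]
  gt[is.na(dos)] <- "./."
  dim(gt) <- dim(dos)
  fmt <- "GT"
  if (!is.null(depth)) {
    stopifnot(all(dim(depth) == dim(dos)))
    gt <- matrix(paste0(gt, ":", as.integer(depth)), nrow = n_ind)
    fmt <- "GT:DP"
  }
  s <- gm$sites
  qual <- if ("qual" %in% names(s)) ifelse(is.na(s$qual), ".", format(s$qual)) else "."
  ref <- if ("ref" %in% names(s)) s$ref else "A"
  alt <- if ("alt" %in% names(s)) s$alt else "T"
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=popgea", if (!is.null(source_note)) paste0(" ", source_note)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(depth))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals$id), collapse = "\t")
  )
  body <- paste(s$chrom, s$pos, s$site, ref, alt, qual, ".", ".", fmt, sep = "\t")
  gt_cols <- apply(gt, 2, paste, collapse = "\t")   # one string per site
  writeLines(c(hdr, paste(body, gt_cols, sep = "\t")), path)
  invisible(path)
}
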