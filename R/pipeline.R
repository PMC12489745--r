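#' Pipeline configuration with study defaults
#'
#' Collects every stage's parameters with defaults matching the package's
#' standard workflow: site filters (depth 5-12x, QUAL 50, 10% missingness),
#' LD pruning at r2 0.2 in 50/10 kb windows, outlier scan with K = 5 at
#' q <= 0.1, k-means BIC scan, admixture over a K range with 5-fold CV,
#' 1000-bootstrap summary statistics, kinship pruning at 0.125, and the
#' triple-evidence GEA (3 retained axes, SD cutoff 3, FDR 0.05, K = 5).
#'
#' @param ... named overrides; nested lists are merged (e.g.
#'   `ld = list(r2_threshold = 0.1)`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    stages = c("filter", "ld", "scan", "structure", "stats", "kinship",
               "relatives", "admixture", "gea"),
    filter = list(min_mean_depth = 5, max_mean_depth = 12, min_qual = 50,
                  max_missing_frac = 0.10, maf_min = 0.05,
                  ind_min_depth = 3, ind_max_missing = 0.20),
    kinship_maf_min = 0,
    ld = list(window_kb = 50, step_kb = 10, r2_threshold = 0.2),
    scan = list(K = 5, alpha = 0.1),
    structure = list(k_max = 10, n_starts = 10),
    stats = list(pops = "region", n_boot = 1000),
    kinship = list(threshold = 0.125),
    admixture = list(K_range = 2:6, cv_folds = 5),
    gea = list(r_max = 0.7, vif_max = 3, retained_axes = 3, sd_mult = 3,
               fdr = 0.05, K = 5, n_structure_pcs = 3, n_perm = 99)
  )
  user <- list(...)
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      modifyList(cfg[[nm]], user[[nm]])
    } else user[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates filter -> LD prune -> outlier scan -> structure (PCA,
#' k-means, DAPC) -> summary statistics -> kinship -> relative pruning ->
#' admixture -> GEA, as toggled in `cfg$stages`, writing each stage's
#' tables (TSV/JSON) and a line-oriented log into `out_dir`. Kinship runs on
#' the LD-pruned data *without* a MAF floor; structure, admixture and GEA
#' run on the MAF-filtered, LD-pruned (and, where required,
#' relatedness-pruned) data. Re-running with the same inputs, config and
#' seed reproduces the artifacts.
#'
#' @param genotypes a [genotype_matrix()] or path to a VCF.
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param metadata optional metadata table/path (when `genotypes` is a VCF
#'   path).
#' @param env optional environmental table (tibble with `id`, or TSV path);
#'   required for the `gea` stage.
#' @return named list of stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(genotypes, cfg = pipeline_config(), out_dir,
                         metadata = NULL, env = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  logline <- function(...) {
    cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n"),
        file = log_path, append = TRUE)
  }
  logline("popgea %s | seed %d | stages: %s",
          as.character(utils::packageVersion("popgea")), cfg$seed,
          paste(cfg$stages, collapse = ","))
  st <- function(s) s %in% cfg$stages
  need <- function(s, dep) {
    if (!st(dep)) stop("stage '", s, "' requires stage '", dep, "'")
  }
  gm <- if (is.character(genotypes)) read_vcf(genotypes, metadata) else genotypes
  if (is.character(env)) {
    env <- as_tibble(read.table(env, header = TRUE, sep = "\t",
                                colClasses = list(id = "character")))
  }
  res <- list()

  if (st("filter")) {
    f <- cfg$filter
    sf <- site_filter_config(f$min_mean_depth, f$max_mean_depth, f$min_qual,
                             f$max_missing_frac, maf_min = f$maf_min)
    fr <- filter_genotypes(gm, sf, f$ind_min_depth, f$ind_max_missing)
    # a parallel dataset without the MAF floor, for kinship
    sf0 <- site_filter_config(f$min_mean_depth, f$max_mean_depth, f$min_qual,
                              f$max_missing_frac, maf_min = cfg$kinship_maf_min)
    fr0 <- filter_genotypes(gm, sf0, f$ind_min_depth, f$ind_max_missing)
    gm <- fr$genotypes
    gm_maf0 <- fr0$genotypes
    write_filter_report(fr$report, file.path(out_dir, "filter_report.json"))
    res$filter <- fr
    logline("filter: %d individuals, %d sites retained (MAF >= %g); %d sites at MAF >= %g",
            nrow(gm$dosages), ncol(gm$dosages), f$maf_min,
            ncol(gm_maf0$dosages), cfg$kinship_maf_min)
  } else {
    gm_maf0 <- gm
  }

  if (st("ld")) {
    pr <- ld_prune(gm, cfg$ld$window_kb, cfg$ld$step_kb, cfg$ld$r2_threshold)
    write_site_list(pr$removed, file.path(out_dir, "ld_removed_sites.txt"))
    gm <- gm[, pr$kept]
    pr0 <- ld_prune(gm_maf0, cfg$ld$window_kb, cfg$ld$step_kb,
                    cfg$ld$r2_threshold)
    gm_maf0 <- gm_maf0[, pr0$kept]
    res$ld <- pr
    logline("ld: removed %d sites at r2 > %g", length(pr$removed),
            cfg$ld$r2_threshold)
  }

  if (st("scan")) {
    sc <- outlier_scan(gm, cfg$scan$K, cfg$scan$alpha)
    write.table(sc$table, file.path(out_dir, "outlier_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_site_list(outlier_sites(sc), file.path(out_dir, "outlier_sites.txt"))
    res$scan <- sc
    logline("scan: K = %d, GIF = %.3f, %d outliers at q <= %g", sc$K, sc$gif,
            sum(sc$table$outlier), sc$alpha)
  }

  if (st("structure")) {
    pca <- pca_impute(gm, n_axes = min(20, nrow(gm$dosages) - 1))
    km <- kmeans_bic(pca$scores, k_max = min(cfg$structure$k_max,
                                             nrow(gm$dosages) - 1),
                     n_starts = cfg$structure$n_starts, seed = cfg$seed)
    dap <- dapc_fit(pca$scores, km$assignments, seed = cfg$seed)
    write.table(tidy(pca), file.path(out_dir, "pca_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(km$scan, file.path(out_dir, "kmeans_bic.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$structure <- list(pca = pca, kmeans = km, dapc = dap)
    logline("structure: chosen k = %d, DAPC retained %d PCs", km$chosen_k,
            dap$best_n_pc)
  }

  if (st("stats")) {
    pops <- cfg$stats$pops
    nei <- nei_basic_stats(gm, pops)
    wc <- wc_stats(gm, pops)
    bs <- beta_fst(gm, pops, n_boot = cfg$stats$n_boot, seed = cfg$seed)
    pw <- pairwise_fst(gm, pops, n_boot = min(cfg$stats$n_boot, 200),
                       seed = cfg$seed)
    D <- nei_D(gm, pops)
    write.table(nei$global, file.path(out_dir, "nei_global.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(bs$per_pop, file.path(out_dir, "beta_fst.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pw$pairs, file.path(out_dir, "pairwise_fst.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_phylip(D, file.path(out_dir, "nei_D.phylip"))
    if (nrow(D) >= 3) writeLines(nj_tree(D), file.path(out_dir, "nj_tree.nwk"))
    res$stats <- list(nei = nei, wc = wc, beta = bs, pairwise = pw, nei_D = D)
    logline("stats: Nei Fst %.4f, WC theta %.4f", nei$global$fst, wc$theta)
  }

  if (st("kinship")) {
    kin <- beta_kinship(gm_maf0)
    write_kinship(kin, file.path(out_dir, "kinship.tsv"))
    res$kinship <- kin
    logline("kinship: mean inbreeding %.4f", mean(diag(kin$beta)))
  }

  keep_ids <- gm$individuals$id
  if (st("relatives")) {
    # structure-robust estimator: beta-kinship is referenced to the cohort
    # mean and flags whole drifted populations, so pruning uses the
    # between-family estimator instead
    rk <- robust_kinship(gm)
    removed <- prune_relatives(rk, cfg$kinship$threshold)
    writeLines(removed, file.path(out_dir, "removed_relatives.txt"))
    keep_ids <- setdiff(gm$individuals$id, removed)
    res$relatives <- removed
    logline("relatives: removed %d of %d at kinship >= %g", length(removed),
            nrow(gm$dosages), cfg$kinship$threshold)
  }
  gm_unrel <- gm[keep_ids, ]

  if (st("admixture")) {
    need("admixture", "relatives")
    ad <- admixture_scan(gm_unrel, cfg$admixture$K_range,
                         cv_folds = cfg$admixture$cv_folds, seed = cfg$seed)
    write.table(ad$scan, file.path(out_dir, "admixture_cv.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_q_matrix(ad$fits[[paste0("K", ad$best_K)]],
                   file.path(out_dir, sprintf("admixture_K%d.Q", ad$best_K)))
    res$admixture <- ad
    logline("admixture: best K = %d by CV error", ad$best_K)
  }

  if (st("gea")) {
    need("gea", "relatives")
    need("gea", "scan")
    if (is.null(env)) stop("stage 'gea' requires an environmental table")
    g <- cfg$gea
    env_u <- env[match(keep_ids, env$id), ]
    ep <- prep_env(env_u, g$r_max, g$vif_max)
    Y <- individual_allele_freq(gm_unrel)
    # structure PCs from the outlier-filtered dataset
    gm_neutral <- gm_unrel[, setdiff(gm_unrel$sites$site,
                                     outlier_sites(res$scan))]
    pcs <- pca_impute(gm_neutral, n_axes = g$n_structure_pcs)$scores
    Z <- cbind(pcs, .env_matrix(ep$conditioned))
    fit <- prda(Y, ep$kept, Z, n_perm = g$n_perm, seed = cfg$seed)
    rc <- rda_candidates(fit, g$retained_axes, g$sd_mult)
    lf <- lfmm_scan(Y, ep$kept, K = g$K, fdr = g$fdr)
    final <- intersect_candidates(rc, lf, res$scan,
                                  universe = gm_unrel$sites$site)
    write.table(as.data.frame(final), file.path(out_dir, "gea_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_candidate_summary(final, file.path(out_dir, "gea_summary.json"))
    res$gea <- list(env = ep, prda = fit, rda_candidates = rc, lfmm = lf,
                    final = final)
    logline("gea: %d RDA, %d LFMM, %d scan -> %d final candidates",
            nrow(rc), length(significant_sites(lf)),
            sum(res$scan$table$outlier), nrow(final))
  }
  logline("done")
  invisible(res)
}
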