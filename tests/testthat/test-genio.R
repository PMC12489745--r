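test_that("VCF genotypes are encoded as alt-allele dosages, odd calls missing", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "T", "99", ".", ".", "GT",
            "0/0", "0/1", "1/1", "./."), collapse = "\t"),
    paste(c("chr1", "200", ".", "G", "C", "99", ".", ".", "GT",
            "0|1", "./1", "1/1/1", "1|1"), collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- read_vcf(path)
  expect_equal(unname(gm$dosages[, 1]), c(0L, 1L, 2L, NA))
  # half-call and triploid record -> missing; phased calls fine
  expect_equal(unname(gm$dosages[, 2]), c(1L, NA, NA, 2L))
  expect_equal(gm$sites$pos, c(100L, 200L))
})

test_that("write -> read round trip preserves dosages and coordinates", {
  sim <- simulate_popgen(sim_config(seed = 2, n_pops = 2, n_per_pop = 5,
                                    n_loci = 100, missing_rate = 0.05))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path, depth = sim$depth)
  gm2 <- read_vcf(path)
  expect_equal(unname(gm2$dosages), unname(sim$genotypes$dosages))
  expect_equal(gm2$sites$pos, sim$genotypes$sites$pos)
  expect_equal(gm2$sites$chrom, sim$genotypes$sites$chrom)
  expect_equal(gm2$individuals$id, sim$genotypes$individuals$id)
  # depth metadata survives via FORMAT/DP
  expect_equal(gm2$sites$mean_depth, colMeans(sim$depth), tolerance = 1e-6)
})

test_that("metadata joins on id and unknown metadata ids are an error", {
  sim <- simulate_popgen(sim_config(seed = 2, n_pops = 1, n_per_pop = 4,
                                    n_loci = 20))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  md <- sim$genotypes$individuals[c("id", "region", "subregion", "lat", "lon")]
  gm <- read_vcf(path, metadata = md)
  expect_equal(gm$individuals$region, md$region)
  md_bad <- md
  md_bad$id[1] <- "ghost001"
  expect_error(read_vcf(path, metadata = md_bad), "ghost001")
})

test_that("duplicate individual ids are rejected", {
  dos <- matrix(c(0L, 1L), 2, 3)
  sites <- tibble::tibble(chrom = "chr1", pos = c(1L, 5L, 9L),
                          ref = "A", alt = "T")
  ind <- tibble::tibble(id = c("a", "a"))
  expect_error(genotype_matrix(dos, sites, ind), "duplicate")
})

test_that("MAF follows the alt-frequency arithmetic and ignores missing", {
  gm <- make_gm(rbind(c(0, 0, 2), c(0, 0, 2), c(1, 0, 1), c(2, NA, NA)))
  m <- maf(gm)
  expect_equal(m$maf[1], 3 / 8)           # dosages 0,0,1,2
  expect_equal(m$maf[2], 0)               # monomorphic
  expect_equal(m$maf[3], 1 / 6)           # 2,2,1,missing -> alt 5/6
  # invariance under allele relabeling
  gm_flip <- make_gm(2L - gm$dosages)
  expect_equal(maf(gm_flip)$maf, m$maf)
})

test_that("site filters enforce the missingness, depth, qual and MAF rules", {
  # site 2 has 11% missing at max_missing 0.10 -> removed
  set.seed(1)
  dos <- matrix(1L, 100, 3)
  dos[1:11, 2] <- NA
  gm <- make_gm(dos, qual = c(99, 99, 99), site_depth = c(8, 8, 8))
  fr <- filter_genotypes(gm, site_filter_config(max_missing_frac = 0.10),
                         ind_max_missing = 0.5)
  expect_equal(fr$genotypes$sites$site, gm$sites$site[c(1, 3)])

  # extreme thresholds pass everything through
  fr2 <- filter_genotypes(gm, site_filter_config(0, Inf, 0, 1, 0,
                                                 biallelic_only = FALSE),
                          ind_min_depth = 0, ind_max_missing = 1)
  expect_equal(dim(fr2$genotypes$dosages), dim(gm$dosages))
  expect_true(all(fr2$report$n_removed == 0))
})

test_that("a hand-enumerated 5x6 matrix is filtered rule by rule", {
  dos <- rbind(c(0, 1, 2, 0, 1, 2),
               c(1, 1, NA, 0, 1, 0),
               c(2, 0, NA, 0, 1, 1),
               c(0, 1, NA, 0, 2, 1),
               c(1, 2, 1, 0, NA, 0))
  qual <- c(60, 40, 60, 60, 60, 60)
  depth <- c(6, 6, 6, 4, 13, 7)
  gm <- make_gm(dos, qual = qual, site_depth = depth)
  cfg <- site_filter_config(min_mean_depth = 5, max_mean_depth = 12,
                            min_qual = 50, max_missing_frac = 0.5,
                            maf_min = 0.05)
  fr <- filter_genotypes(gm, cfg, ind_min_depth = 0, ind_max_missing = 1)
  # by hand: site2 fails qual(40); site3 fails missing 3/5 > 0.5;
  # site4 fails depth low and is monomorphic (MAF 0); site5 fails depth high;
  # sites 1 and 6 survive
  expect_equal(fr$genotypes$sites$site, gm$sites$site[c(1, 6)])
  rep <- setNames(fr$report$n_removed, fr$report$rule)
  expect_equal(unname(rep["site_qual"]), 1L)
  expect_equal(unname(rep["site_depth_low"]), 1L)
  expect_equal(unname(rep["site_depth_high"]), 1L)
  expect_equal(unname(rep["site_missing"]), 1L)
  expect_equal(unname(rep["site_maf"]), 1L)
})

test_that("filtering is idempotent and totals are consistent", {
  sim <- simulate_popgen(sim_config(seed = 4, n_pops = 2, n_per_pop = 15,
                                    n_loci = 300, missing_rate = 0.05))
  cfg <- site_filter_config(maf_min = 0.05)
  f1 <- filter_genotypes(sim$genotypes, cfg)
  f2 <- filter_genotypes(f1$genotypes, cfg)
  expect_equal(f2$genotypes$dosages, f1$genotypes$dosages)
  expect_equal(f2$genotypes$sites, f1$genotypes$sites)
  t1 <- attr(f1$report, "totals")
  expect_lte(t1$n_sites_out, t1$n_sites_in)
  expect_lte(t1$n_individuals_out, t1$n_individuals_in)
  expect_gte(sum(f1$report$n_removed[-(1:2)]),
             t1$n_sites_in - t1$n_sites_out)
})

test_that("removing every individual is an error", {
  gm <- make_gm(matrix(c(0L, 1L, NA, NA), 2, 2))
  expect_error(filter_genotypes(gm, site_filter_config(),
                                ind_max_missing = 0.1),
               "all individuals")
})
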