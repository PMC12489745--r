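#' Simulation configuration
#'
#' Defines a genotype-environment simulation with known truth: K discrete
#' populations drifted from a shared ancestral pool (Balding-Nichols Beta
#' frequencies), optional selfing-driven inbreeding, Dirichlet-admixed
#' individuals, pedigree relatives built by gene dropping, environmental
#' variables laid out as a north-south gradient plus correlated noise, and
#' adaptive loci whose allele frequencies track an environmental variable on
#' the logit scale. All randomness derives from the single seed.
#'
#' @param seed integer seed.
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (recycled to `n_pops`).
#' @param fst_per_pop drift F per population in \[0, 1) (recycled); 0 means
#'   no drift from the ancestral pool.
#' @param n_loci number of biallelic loci.
#' @param n_chrom number of chromosomes the loci are spread over.
#' @param ancestral_maf_range ancestral allele frequencies are uniform on
#'   this range.
#' @param selfing_rate partial-selfing rate s; equilibrium inbreeding is
#'   `F = s / (2 - s)`.
#' @param n_admixed number of admixed individuals appended (region `ADM`).
#' @param dirichlet_alpha Dirichlet concentration for admixture proportions.
#' @param pedigree named counts of relative pairs to append, e.g.
#'   `c(full_sib = 5, half_sib = 3, parent_offspring = 2)`; built by gene
#'   dropping from unrelated founders of population 1.
#' @param n_env_vars number of environmental variables.
#' @param env_correlation pairwise correlation among the noise components of
#'   the environmental variables.
#' @param env_gradient_weight weight of the shared north-south gradient in
#'   each environmental variable.
#' @param n_adaptive number of environmentally driven loci.
#' @param effect_size logit-scale shift per SD of environment at adaptive
#'   loci.
#' @param missing_rate genotype missingness rate.
#' @param depth_mean mean sequencing depth (per-genotype depths are Poisson
#'   around a per-individual mean).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_pops = 5, n_per_pop = 54,
                       fst_per_pop = 0.15, n_loci = 5000, n_chrom = 5,
                       ancestral_maf_range = c(0.05, 0.5),
                       selfing_rate = 0, n_admixed = 0, dirichlet_alpha = 1,
                       pedigree = c(), n_env_vars = 4, env_correlation = 0.3,
                       env_gradient_weight = 0.6, n_adaptive = 0,
                       effect_size = 1, missing_rate = 0.008,
                       depth_mean = 6) {
  if (n_adaptive > n_loci) stop("n_adaptive must not exceed n_loci")
  if (any(fst_per_pop < 0 | fst_per_pop >= 1)) {
    stop("fst_per_pop must be in [0, 1)")
  }
  if (selfing_rate < 0 || selfing_rate >= 1) stop("selfing_rate must be in [0, 1)")
  cfg <- list(seed = seed, n_pops = n_pops,
              n_per_pop = rep_len(n_per_pop, n_pops),
              fst_per_pop = rep_len(fst_per_pop, n_pops),
              n_loci = n_loci, n_chrom = n_chrom,
              ancestral_maf_range = ancestral_maf_range,
              selfing_rate = selfing_rate, n_admixed = n_admixed,
              dirichlet_alpha = dirichlet_alpha, pedigree = pedigree,
              n_env_vars = n_env_vars, env_correlation = env_correlation,
              env_gradient_weight = env_gradient_weight,
              n_adaptive = n_adaptive, effect_size = effect_size,
              missing_rate = missing_rate, depth_mean = depth_mean)
  structure(cfg, class = "sim_config")
}

#' The default study-shaped simulation preset
#'
#' Five populations of ~54 individuals (269 total), drift F = 0.15, one
#' Dirichlet-admixed group and planted pedigree pairs — a shape for
#' integration tests, not a claim of equivalence to any real dataset.
#'
#' @param seed integer seed.
#' @param n_loci number of loci.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
paperlike_config <- function(seed = 1, n_loci = 5000, ...) {
  sim_config(seed = seed, n_pops = 5, n_per_pop = c(54, 54, 54, 54, 53),
             fst_per_pop = 0.15, n_loci = n_loci, n_admixed = 10,
             pedigree = c(full_sib = 6, half_sib = 4, parent_offspring = 4),
             n_adaptive = round(0.01 * n_loci), effect_size = 1.5, ...)
}

#' Simulate a genotype-environment dataset with known truth
#'
#' @param cfg a [sim_config()].
#' @return object of class `popgen_sim`: `genotypes` ([genotype_matrix()]),
#'   `env` (tibble `id` + `env_*`), `depth` (per-genotype depth matrix) and
#'   `truth` (list: per-pop `F`, admixture `Q`, `pedigree` dyad tibble,
#'   `adaptive` tibble, `pop_freq`, `p_anc`, selfing equilibrium
#'   `f_inbreeding`).
#' @export
simulate_popgen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  K <- cfg$n_pops
  p_anc <- runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  pop_freq <- matrix(NA_real_, L, K)
  for (k in seq_len(K)) {
    Fk <- cfg$fst_per_pop[k]
    pop_freq[, k] <- if (Fk == 0) p_anc else {
      rbeta(L, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
    }
  }
  pop_freq <- pmin(pmax(pop_freq, 1e-4), 1 - 1e-4)

  # individuals: populations, then admixed, then pedigree members
  pop_ids <- rep(seq_len(K), cfg$n_per_pop)
  n_pop_ind <- length(pop_ids)
  Q <- matrix(0, n_pop_ind, K)
  Q[cbind(seq_len(n_pop_ind), pop_ids)] <- 1
  region <- paste0("P", pop_ids)
  if (cfg$n_admixed > 0) {
    Qa <- matrix(rgamma(cfg$n_admixed * K, cfg$dirichlet_alpha),
                 cfg$n_admixed, K)
    Qa <- Qa / rowSums(Qa)
    Q <- rbind(Q, Qa)
    region <- c(region, rep("ADM", cfg$n_admixed))
  }
  n_free <- nrow(Q)

  # geography: populations strung north to south; env = gradient + noise
  pop_lat <- seq(-35, -42, length.out = K)
  lat <- pop_lat[max.col(Q)] + rnorm(n_free, 0, 0.4)
  lon <- 174 + rnorm(n_free, 0, 0.8)

  # per-individual allele frequencies, with adaptive shifts
  P <- Q %*% t(pop_freq)                     # n_free x L
  adaptive <- tibble(locus = integer(), variable = character(),
                     effect = numeric())
  lat_std <- as.numeric(scale(lat))
  w <- cfg$env_gradient_weight
  rho <- cfg$env_correlation
  shared <- rnorm(n_free)
  E <- vapply(seq_len(cfg$n_env_vars), function(v) {
    noise <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n_free)
    as.numeric(scale(w * lat_std + sqrt(1 - w^2) * noise))
  }, numeric(n_free))
  colnames(E) <- paste0("env_", seq_len(cfg$n_env_vars))
  if (cfg$n_adaptive > 0) {
    loci_sel <- sample.int(L, cfg$n_adaptive)
    var_sel <- rep_len(seq_len(cfg$n_env_vars), cfg$n_adaptive)
    adaptive <- tibble(locus = loci_sel,
                       variable = colnames(E)[var_sel],
                       effect = cfg$effect_size)
    shift <- E[, var_sel, drop = FALSE] * cfg$effect_size   # n_free x n_adaptive
    lo <- log(P[, loci_sel, drop = FALSE] / (1 - P[, loci_sel, drop = FALSE]))
    P[, loci_sel] <- 1 / (1 + exp(-(lo + shift)))
  }

  # genotypes with heterozygote deficit from partial selfing
  f_is <- cfg$selfing_rate / (2 - cfg$selfing_rate)
  G <- .draw_genotypes(P, f_is)

  ids <- sprintf("ind%03d", seq_len(n_free))
  ped <- .gene_drop(cfg, pop_freq[, 1], n_free)
  if (!is.null(ped)) {
    G <- rbind(G, ped$G)
    Q <- rbind(Q, matrix(rep(Q[1, , drop = FALSE] * 0, nrow(ped$G)),
                         nrow(ped$G), K))
    Q[(n_free + 1):nrow(Q), 1] <- 1
    region <- c(region, rep("PED", nrow(ped$G)))
    lat <- c(lat, rep(pop_lat[1], nrow(ped$G)) + rnorm(nrow(ped$G), 0, 0.4))
    lon <- c(lon, 174 + rnorm(nrow(ped$G), 0, 0.8))
    E <- rbind(E, matrix(rnorm(nrow(ped$G) * ncol(E)), nrow(ped$G), ncol(E)))
    ids <- c(ids, sprintf("ped%03d", seq_len(nrow(ped$G))))
  }
  n <- nrow(G)

  # positions: loci spread over chromosomes, sorted unique positions
  chrom_of <- sort(rep_len(seq_len(cfg$n_chrom), L))
  pos <- unlist(lapply(split(seq_len(L), chrom_of), function(ix) {
    sort(sample.int(2e7, length(ix)))
  }), use.names = FALSE)

  # depth and missingness
  ind_depth <- rgamma(n, shape = 20, rate = 20 / cfg$depth_mean)
  depth <- matrix(rpois(n * L, rep(ind_depth, L)), n, L)
  miss <- matrix(runif(n * L) < cfg$missing_rate, n, L)
  G[miss] <- NA_integer_
  qual <- round(rgamma(L, shape = 4, scale = 60), 1)

  individuals <- tibble(
    id = ids, region = region,
    subregion = paste0(region, rep_len(c("a", "b"), n)),
    lat = lat, lon = lon,
    mean_depth = rowMeans(depth), f_missing = rowMeans(is.na(G))
  )
  sites <- tibble(
    chrom = paste0("chr", chrom_of), pos = pos,
    ref = "A", alt = "T", qual = qual, mean_depth = colMeans(depth)
  )
  gm <- genotype_matrix(G, sites, individuals)
  env <- tibble(id = ids, as_tibble(E))
  adaptive$site <- gm$sites$site[adaptive$locus]
  truth <- list(
    F = cfg$fst_per_pop, Q = Q,
    pedigree = if (is.null(ped)) tibble(id1 = character(), id2 = character(),
                                        kinship = numeric()) else {
      tibble(id1 = ids[n_free + ped$dyads$i1],
             id2 = ids[n_free + ped$dyads$i2],
             kinship = ped$dyads$kinship)
    },
    adaptive = adaptive, pop_freq = pop_freq, p_anc = p_anc,
    f_inbreeding = f_is, env = env
  )
  structure(list(genotypes = gm, env = env, depth = depth, truth = truth,
                 config = cfg),
            class = "popgen_sim")
}

#' @keywords internal
#' Genotypes from individual frequencies with heterozygote deficit f_is.
.draw_genotypes <- function(P, f_is) {
  n <- nrow(P); L <- ncol(P)
  p <- as.numeric(P)
  q <- 1 - p
  p2 <- p^2 + p * q * f_is
  phet <- 2 * p * q * (1 - f_is)
  u <- runif(n * L)
  g <- ifelse(u < p2, 2L, ifelse(u < p2 + phet, 1L, 0L))
  matrix(as.integer(g), n, L)
}

#' @keywords internal
#' Pedigree blocks by gene dropping from founders with the given allele
#' frequency vector. Returns genotypes of all created individuals and the
#' expected-kinship dyad table (indices into the returned block).
.gene_drop <- function(cfg, freq, n_free) {
  ped <- cfg$pedigree
  if (length(ped) == 0 || sum(unlist(ped)) == 0) return(NULL)
  L <- length(freq)
  draw_founder <- function() {
    list(a = as.integer(runif(L) < freq), b = as.integer(runif(L) < freq))
  }
  child_of <- function(f1, f2) {
    list(a = ifelse(runif(L) < 0.5, f1$a, f1$b),
         b = ifelse(runif(L) < 0.5, f2$a, f2$b))
  }
  members <- list()
  dyads <- list()
  add <- function(g) {
    members[[length(members) + 1]] <<- g$a + g$b
    length(members)
  }
  rel <- function(i1, i2, k) {
    dyads[[length(dyads) + 1]] <<- tibble(i1 = i1, i2 = i2, kinship = k)
  }
  for (nm in names(ped)) {
    for (b in seq_len(ped[[nm]])) {
      if (nm == "full_sib") {
        f1 <- draw_founder(); f2 <- draw_founder()
        c1 <- add(child_of(f1, f2)); c2 <- add(child_of(f1, f2))
        rel(c1, c2, 0.25)
      } else if (nm == "half_sib") {
        f1 <- draw_founder(); f2 <- draw_founder(); f3 <- draw_founder()
        c1 <- add(child_of(f1, f2)); c2 <- add(child_of(f1, f3))
        rel(c1, c2, 0.125)
      } else if (nm == "parent_offspring") {
        f1 <- draw_founder(); f2 <- draw_founder()
        p1 <- add(list(a = f1$a, b = f1$b))
        c1 <- add(child_of(f1, f2))
        rel(p1, c1, 0.25)
      } else {
        stop("unknown pedigree relationship: ", nm)
      }
    }
  }
  G <- do.call(rbind, members)
  storage.mode(G) <- "integer"
  list(G = G, dyads = dplyr::bind_rows(dyads))
}

#' @export
print.popgen_sim <- function(x, ...) {
  cat("<popgen_sim> seed", x$config$seed, "\n")
  print(x$genotypes)
  cat(sprintf("env: %d variable(s); adaptive loci: %d; pedigree dyads: %d\n",
              ncol(x$env) - 1, nrow(x$truth$adaptive), nrow(x$truth$pedigree)))
  invisible(x)
}

#' Write a simulated dataset to disk (VCF + env TSV + truth JSON)
#'
#' @param sim a [simulate_popgen()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"), depth = sim$depth,
            source_note = paste0("seed=", sim$config$seed))
  write.table(sim$env, file.path(dir, "env.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$genotypes$individuals[c("id", "region", "subregion", "lat", "lon")],
              file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$Q <- unname(as.data.frame(truth$Q))
  truth$pop_freq <- NULL
  truth$p_anc <- NULL
  truth$env <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
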