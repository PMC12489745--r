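env_fixture <- function(n = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("i%02d", 1:n),
    temp = rnorm(n),
    temp_copy = NA_real_,   # filled below: nearly collinear with temp
    rain = rnorm(n),
    seas = rnorm(n)
  ) |> (\(d) { d$temp_copy <- d$temp + rnorm(n, 0, 0.05); d })()
}

test_that("correlation stage drops the later of a collinear pair", {
  env <- env_fixture()
  ep <- prep_env(env, r_max = 0.7, vif_max = 3)
  expect_true("temp" %in% names(ep$kept))
  expect_false("temp_copy" %in% names(ep$kept))
  expect_false("temp_copy" %in% names(ep$conditioned))  # dropped, not conditioned
  expect_true(any(ep$log$stage == "correlation" &
                    ep$log$variable == "temp_copy"))
})

test_that("orthogonal designs have unit VIFs and survive untouched", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  env <- tibble::tibble(id = sprintf("i%02d", 1:40),
                        a = Q[, 1], b = Q[, 2], c = Q[, 3])
  ep <- prep_env(env)
  expect_equal(sort(names(ep$kept)), c("a", "b", "c", "id"))
  expect_equal(nrow(ep$log), 0)
  expect_equal(unname(vif_oracle(Q)), rep(1, 3), tolerance = 1e-3)
})

test_that("sequential VIF removal matches an independent recomputation", {
  set.seed(3)
  n <- 80
  base <- matrix(rnorm(n * 4), n, 4)
  env <- tibble::tibble(id = sprintf("i%02d", 1:n))
  for (j in 1:4) env[[paste0("v", j)]] <- base[, j]
  # collinear block: v5..v7 are sums of the basis plus small noise
  env$v5 <- base[, 1] + base[, 2] + rnorm(n, 0, 0.3)
  env$v6 <- base[, 2] + base[, 3] + rnorm(n, 0, 0.3)
  env$v7 <- base[, 1] - base[, 3] + rnorm(n, 0, 0.3)
  ep <- prep_env(env, r_max = 0.95, vif_max = 3)
  # replay the documented procedure with the independent VIF oracle
  kept <- paste0("v", 1:7)
  cond <- character(0)
  repeat {
    vifs <- vif_oracle(as.matrix(env[kept]))
    if (max(vifs) <= 3) break
    worst <- kept[which.max(vifs)]
    cond <- c(cond, worst)
    kept <- setdiff(kept, worst)
  }
  expect_setequal(setdiff(names(ep$kept), "id"), kept)
  expect_setequal(setdiff(names(ep$conditioned), "id"), cond)
})

test_that("individual allele frequencies follow the dosage/2 rule", {
  dos <- rbind(c(0L, 2L, NA), c(2L, 1L, 1L), c(2L, 2L, 2L), c(NA, 1L, 1L))
  Y <- individual_allele_freq(make_gm(dos))
  expect_equal(Y[1, 2], 1.0)
  expect_equal(Y[2, 2], 0.5)
  # missing at site 1: mean of called frequencies (0, 1, 1) -> 2/3
  expect_equal(Y[4, 1], 2 / 3)
  expect_true(all(Y >= 0 & Y <= 1))
})

test_that("unconditioned RDA on one variable reduces to regression R2", {
  set.seed(4)
  n <- 50
  Y <- matrix(rnorm(n * 30), n, 30)
  x <- rnorm(n)
  Y[, 1:5] <- Y[, 1:5] + outer(x, rep(0.8, 5))
  fit <- prda(Y, cbind(x = x), Z = NULL, n_perm = 0)
  # RDA R2 = ratio of fitted to total sum of squares from direct regressions
  Yc <- scale(Y, scale = FALSE)
  fitted <- vapply(seq_len(ncol(Yc)), function(j) {
    sum(lm(Yc[, j] ~ x)$fitted.values^2)
  }, numeric(1))
  r2_direct <- sum(fitted) / sum(Yc^2)
  expect_equal(fit$r2$unadjusted, r2_direct, tolerance = 1e-8)
  # Ezekiel small-sample correction
  p <- 1
  expect_equal(fit$r2$env_given_cond,
               1 - (1 - r2_direct) * (n - 1) / (n - p - 1), tolerance = 1e-8)
  # eigenvalue sum bounded by the response variance
  expect_lte(sum(fit$eig$eigenvalue), sum(Yc^2) / (n - 1) + 1e-8)
})

test_that("planted dependence loads axis 1 and is detected by permutation", {
  set.seed(5)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  Y <- matrix(rnorm(n * 200, sd = 1), n, 200)
  dep <- 1:20
  Y[, dep] <- Y[, dep] + outer(x1, rep(1, 20))
  fit <- prda(Y, cbind(x1 = x1, x2 = x2), Z = NULL, n_perm = 199, seed = 1)
  expect_lt(fit$axis_tests$p[1], 0.05)
  l1 <- abs(fit$loadings[, 1])
  expect_gt(mean(rank(l1)[dep]), 150)   # dependent SNPs enriched at the top
})

test_that("conditioning on the predictor itself removes the signal", {
  set.seed(6)
  n <- 60
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 100), n, 100) + outer(x, rep(0.7, 100))
  plain <- prda(Y, cbind(x = x), n_perm = 0)
  part <- prda(Y, cbind(noise = rnorm(n)), Z = cbind(x = x), n_perm = 0)
  expect_gt(plain$r2$unadjusted, 10 * part$r2$unadjusted)
  expect_false(is.na(part$r2$cond_given_env))
})

test_that("SD-loading candidates have the right tail mass and nest", {
  set.seed(7)
  n <- 80; L <- 2000
  Y <- matrix(rnorm(n * L), n, L)
  colnames(Y) <- paste0("s", 1:L)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  fit <- prda(Y, X, n_perm = 0)
  c25 <- rda_candidates(fit, retained_axes = 2, sd_mult = 2.5)
  c30 <- rda_candidates(fit, retained_axes = 2, sd_mult = 3)
  expect_true(all(c30$site %in% c25$site))
  # per-axis expected flag fraction ~ 2 * pnorm(-sd_mult) under a normal null
  expected <- 2 * 2 * pnorm(-2.5) * L       # union bound over 2 axes
  expect_lt(nrow(c25), 2.5 * expected)
  expect_gt(nrow(c25), 0)
  expect_error(rda_candidates(fit, 2, sd_mult = 0), "positive")
})

test_that("planted environmental drivers get assigned to the right variable", {
  set.seed(8)
  n <- 80; L <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  Y <- matrix(rnorm(n * L, sd = 0.5), n, L)
  colnames(Y) <- paste0("s", 1:L)
  dep <- 1:25
  Y[, dep] <- Y[, dep] + outer(x1, rep(0.8, 25))
  fit <- prda(Y, cbind(x1 = x1, x2 = x2), n_perm = 0)
  cand <- rda_candidates(fit, retained_axes = 1, sd_mult = 2.5)
  hits <- cand[cand$site %in% paste0("s", dep), ]
  expect_gte(mean(hits$variable == "x1"), 0.8)
})

test_that("LFMM with no factors and no penalty is exactly per-SNP OLS", {
  set.seed(9)
  n <- 40; L <- 30
  X <- cbind(a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * L), n, L)
  fit <- lfmm_scan(Y, X, K = 0, lambda = 0)
  B_ols <- t(coef(lm(Y ~ X))[-1, ])
  expect_equal(unname(fit$B), unname(B_ols), tolerance = 1e-8)
})

test_that("latent factors absorb structure-confounded nulls", {
  sim <- simulate_popgen(sim_config(seed = 90, n_pops = 3, n_per_pop = 40,
                                    fst_per_pop = 0.1, n_loci = 1500))
  gm <- sim$genotypes
  Y <- individual_allele_freq(gm)
  # environment tracking the population means only: no per-SNP effect
  pop <- as.integer(factor(gm$individuals$region))
  x <- c(-1, 0, 1)[pop] + rnorm(nrow(Y), 0, 0.3)
  fit <- lfmm_scan(Y, cbind(x = x), K = 3, fdr = 0.1)
  expect_gt(ks.test(fit$table$p_adj, "punif")$p.value, 0.01)
})

test_that("planted environmental effects are recovered with bounded FDR", {
  rec <- fdp <- numeric(3)
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 100; L <- 1000
    x <- rnorm(n)
    Y <- matrix(rnorm(n * L, sd = 1), n, L)
    colnames(Y) <- paste0("s", 1:L)
    dep <- sample(L, 50)
    Y[, dep] <- Y[, dep] + outer(x, rep(0.33, 50))  # r ~ 0.3
    fit <- lfmm_scan(Y, cbind(x = x), K = 0, fdr = 0.1)
    hits <- significant_sites(fit)
    rec[s] <- mean(paste0("s", dep) %in% hits)
    fdp[s] <- ifelse(length(hits) > 0,
                     mean(!(hits %in% paste0("s", dep))), 0)
  }
  expect_gte(mean(rec), 0.6)
  expect_lte(mean(fdp), 0.2)
})

test_that("intersection obeys set laws and filters to triple evidence", {
  cand <- tibble::tibble(site = c("chr1:1", "chr1:2", "chr1:3"),
                         axis = 1L, variable = "x1", cor = 0.5)
  class(cand) <- c("candidate_set", class(cand))
  out <- intersect_candidates(cand, c("chr1:2", "chr1:3", "chr1:4"),
                              c("chr1:3", "chr1:5"))
  expect_equal(out$site, "chr1:3")
  expect_true(all(out$rda & out$lfmm & out$scan))
  expect_lte(nrow(out), min(3, 3, 2))
  # any empty input empties the result
  empty <- intersect_candidates(cand, character(0), c("chr1:1"))
  expect_equal(nrow(empty), 0)
  # disjoint universes are an error
  expect_error(
    intersect_candidates(cand, c("chrX:9"), c("chr1:1"),
                         universe = paste0("chr1:", 1:5)),
    "universe")
})
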