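# Shared small-n fixtures for estimator oracles
two_pop_gm <- function(dos1, dos2) {
  dos <- rbind(dos1, dos2)
  make_gm(dos, region = rep(c("A", "B"), c(nrow(dos1), nrow(dos2))))
}

test_that("Nei statistics match a step-by-step hand computation", {
  # 2 pops x 2 loci, genotypes chosen so every quantity is hand-checkable
  d1 <- rbind(c(0, 1), c(1, 1), c(2, 0))     # pop A: n = 3
  d2 <- rbind(c(2, 0), c(1, 0), c(2, 2))     # pop B: n = 3
  ns <- nei_basic_stats(two_pop_gm(d1, d2), "region")

  # independent spreadsheet-style oracle, locus by locus
  oracle <- function(gA, gB) {
    n <- 3
    pA <- sum(gA) / (2 * n); pB <- sum(gB) / (2 * n)
    hoA <- mean(gA == 1); hoB <- mean(gB == 1)
    mho <- (hoA + hoB) / 2
    msp2 <- ((pA^2 + (1 - pA)^2) + (pB^2 + (1 - pB)^2)) / 2
    nh <- 2 / (1 / n + 1 / n)
    hs <- nh / (nh - 1) * (1 - msp2 - mho / (2 * nh))
    pb <- (pA + pB) / 2
    ht <- 1 - (pb^2 + (1 - pb)^2) + hs / (2 * nh) - mho / (4 * nh)
    c(ho = mho, hs = hs, ht = ht)
  }
  o1 <- oracle(d1[, 1], d2[, 1])
  o2 <- oracle(d1[, 2], d2[, 2])
  expect_equal(ns$per_locus$ho, c(o1["ho"], o2["ho"]), ignore_attr = TRUE)
  expect_equal(ns$per_locus$hs, c(o1["hs"], o2["hs"]), ignore_attr = TRUE)
  expect_equal(ns$per_locus$ht, c(o1["ht"], o2["ht"]), ignore_attr = TRUE)
  # ratio-of-averages identities
  expect_equal(ns$global$fst, 1 - ns$global$hs / ns$global$ht,
               tolerance = 1e-10)
  expect_equal(ns$global$fis, 1 - ns$global$ho / ns$global$hs,
               tolerance = 1e-10)
})

test_that("Nei Fst vanishes under a shared HWE pool and hits 1 at fixation", {
  set.seed(21)
  d1 <- matrix(rbinom(200 * 40, 2, 0.5), 200, 40)
  d2 <- matrix(rbinom(200 * 40, 2, 0.5), 200, 40)
  ns <- nei_basic_stats(two_pop_gm(d1, d2), "region")
  expect_lt(abs(ns$global$fst), 0.02)

  fixed <- two_pop_gm(matrix(2L, 50, 5), matrix(0L, 50, 5))
  nf <- nei_basic_stats(fixed, "region")
  expect_equal(nf$global$ho, 0)
  expect_equal(nf$global$fst, 1, tolerance = 1e-10)
  expect_equal(nf$global$ht, 0.5, tolerance = 0.01)
})

test_that("Weir-Cockerham components match a hand-enumerated two-by-two case", {
  # single locus, two pops of 2: genotypes A = {0,1}, B = {2,2}
  gm <- two_pop_gm(rbind(0L, 1L), rbind(2L, 2L))
  wc <- wc_stats(gm, "region")
  # independent scalar arithmetic, following the published estimator
  n_i <- c(2, 2); r <- 2; nbar <- 2; nsum <- 4
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  p_i <- c(1 / 4, 1); h_i <- c(1 / 2, 0)
  pbar <- sum(n_i * p_i) / nsum
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / nsum
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - 3 / 8 * hbar)
  cc <- hbar / 2
  expect_equal(wc$per_locus$a, a, tolerance = 1e-12)
  expect_equal(wc$per_locus$b, b, tolerance = 1e-12)
  expect_equal(wc$per_locus$c, cc, tolerance = 1e-12)
  expect_equal(wc$theta, a / (a + b + cc), tolerance = 1e-12)
})

test_that("theta is null under exchangeability and errors when undefined", {
  set.seed(22)
  d1 <- matrix(rbinom(100 * 50, 2, 0.4), 100, 50)
  d2 <- matrix(rbinom(100 * 50, 2, 0.4), 100, 50)
  wc <- wc_stats(two_pop_gm(d1, d2), "region")
  expect_lt(abs(wc$theta), 0.02)
  mono <- two_pop_gm(matrix(0L, 5, 4), matrix(0L, 5, 4))
  expect_error(wc_stats(mono, "region"), "undefined")
})

test_that("Nei Fst and WC theta agree on balanced many-population sims", {
  # Hs/Ht-based Fst carries an (r-1)/r factor relative to theta, so the two
  # estimators coincide in the many-population, low-drift regime
  sim <- simulate_popgen(sim_config(seed = 23, n_pops = 8, n_per_pop = 60,
                                    fst_per_pop = 0.05, n_loci = 2000))
  f1 <- nei_basic_stats(sim$genotypes, "region")$global$fst
  f2 <- wc_stats(sim$genotypes, "region")$theta
  expect_lt(abs(f1 - f2), 0.02)
})

test_that("beta-FST is null for a panmictic pool and ranks drifted pops", {
  set.seed(24)
  dos <- matrix(rbinom(120 * 3000, 2, runif(3000, 0.1, 0.9)[
    rep(1:3000, each = 120)]), 120, 3000)
  gm <- make_gm(dos, region = rep(c("A", "B", "C"), each = 40))
  bs <- beta_fst(gm, "region", n_boot = 100, seed = 1)
  expect_true(all(abs(bs$per_pop$beta) < 0.02))

  sim <- simulate_popgen(sim_config(seed = 25, n_pops = 5, n_per_pop = 25,
                                    fst_per_pop = c(0.1, 0.1, 0.5, 0.1, 0.1),
                                    n_loci = 2000))
  bs2 <- beta_fst(sim$genotypes, "region", n_boot = 100, seed = 1)
  expect_equal(unname(which.max(bs2$per_pop$beta)), 3)
  # CIs contain the point estimates
  expect_true(all(bs2$per_pop$ci_low <= bs2$per_pop$beta + 1e-9))
  expect_true(all(bs2$per_pop$ci_high >= bs2$per_pop$beta - 1e-9))
})

test_that("seed-fixed bootstraps are reproducible and need n_boot >= 2", {
  sim <- simulate_popgen(sim_config(seed = 26, n_pops = 2, n_per_pop = 15,
                                    n_loci = 300))
  b1 <- beta_fst(sim$genotypes, "region", n_boot = 50, seed = 9)
  b2 <- beta_fst(sim$genotypes, "region", n_boot = 50, seed = 9)
  expect_identical(b1$per_pop, b2$per_pop)
  expect_error(beta_fst(sim$genotypes, "region", n_boot = 1), "n_boot")
})

test_that("pairwise FST is structurally sound and rank-concordant", {
  set.seed(27)
  # a population split at random into two labels: FST ~ 0
  dos <- matrix(rbinom(80 * 1000, 2, 0.4), 80, 1000)
  gm <- make_gm(dos, region = sample(rep(c("A", "B"), 40)))
  pw0 <- pairwise_fst(gm, "region", n_boot = 50, seed = 1)
  expect_lt(abs(pw0$fst["A", "B"]), 0.01)

  sim <- simulate_popgen(sim_config(seed = 28, n_pops = 3, n_per_pop = 40,
                                    fst_per_pop = c(0.02, 0.02, 0.15),
                                    n_loci = 2000))
  pw <- pairwise_fst(sim$genotypes, "region", n_boot = 50, seed = 1)
  expect_true(max(abs(pw$fst - t(pw$fst))) < 1e-12)
  expect_true(all(diag(pw$fst) == 0))
  # P1-P2 (both weakly drifted) must be the closest pair
  expect_lt(pw$fst["P1", "P2"], min(pw$fst["P1", "P3"], pw$fst["P2", "P3"]))
  expect_true(all(pw$pairs$ci_low <= pw$pairs$fst + 1e-9 &
                    pw$pairs$fst <= pw$pairs$ci_high + 1e-9))
})

test_that("Nei's D has its closed forms and stays non-negative", {
  # identical profiles -> 0
  gm_same <- two_pop_gm(rbind(c(0, 2), c(2, 0)), rbind(c(0, 2), c(2, 0)))
  D0 <- nei_D(gm_same, "region")
  expect_equal(D0["A", "B"], 0, tolerance = 1e-12)

  # p_x = 1, p_y = 0.5 at one locus: D = ln sqrt(2)
  gm1 <- two_pop_gm(rbind(2L, 2L), rbind(2L, 0L))
  expect_equal(nei_D(gm1, "region")["A", "B"], log(sqrt(2)),
               tolerance = 1e-12)

  sim <- simulate_popgen(sim_config(seed = 29, n_pops = 4, n_per_pop = 15,
                                    n_loci = 400))
  D <- nei_D(sim$genotypes, "region")
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  # 1978 unbiased variant shrinks the within-group identity upward
  D78 <- nei_D(sim$genotypes, "region", variant = "1978")
  expect_true(all(is.finite(D78[upper.tri(D78)])))
})

test_that("neighbour joining recovers an additive four-leaf metric exactly", {
  # tree ((A:1,B:2):1.5,(C:3,D:4)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["C", "D"] <- D["D", "C"] <- 7
  D["A", "C"] <- D["C", "A"] <- 1 + 1.5 + 3
  D["A", "D"] <- D["D", "A"] <- 1 + 1.5 + 4
  D["B", "C"] <- D["C", "B"] <- 2 + 1.5 + 3
  D["B", "D"] <- D["D", "B"] <- 2 + 1.5 + 4
  nwk <- nj_tree(D)
  tr <- attr(nwk, "tree")
  expect_setequal(tr$tip.label, LETTERS[1:4])
  # recovered tree reproduces the input metric exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]],
               D, tolerance = 1e-10)

  # 3 leaves: unique star resolution via the three-point formulas
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- attr(nj_tree(D3), "tree")
  len <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(len["x"]), (2 + 3 - 4) / 2)
  expect_equal(unname(len["y"]), (2 + 4 - 3) / 2)
  expect_equal(unname(len["z"]), (3 + 4 - 2) / 2)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "3 labels")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("removing scan outliers lowers global differentiation", {
  set.seed(30)
  sim <- simulate_popgen(sim_config(seed = 30, n_pops = 2, n_per_pop = 60,
                                    fst_per_pop = 0.03, n_loci = 2000))
  gm <- sim$genotypes
  sel <- sample(ncol(gm$dosages), 60)
  pop <- gm$individuals$region
  for (l in sel) {
    p1 <- 0.3
    gm$dosages[pop == "P1", l] <- rbinom(sum(pop == "P1"), 2, p1)
    gm$dosages[pop == "P2", l] <- rbinom(sum(pop == "P2"), 2, p1 + 0.5)
  }
  sc <- outlier_scan(gm, K = 1, alpha = 0.1)
  full_fst <- wc_stats(gm, "region")$theta
  kept <- setdiff(gm$sites$site, outlier_sites(sc))
  red_fst <- wc_stats(gm[, kept], "region")$theta
  expect_lt(red_fst, full_fst)
})
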