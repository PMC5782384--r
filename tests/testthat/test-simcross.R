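# The advanced-intercross simulator: meiosis model, population propagation,
# trait and expression architectures.

test_that("meiosis follows the Haldane model", {
  pos <- c(0, 10)
  set.seed(2)
  n <- 20000
  rec <- logical(n)
  for (i in seq_len(n)) {
    g <- simulate_meiosis(c(0L, 0L), c(1L, 1L), pos)
    rec[i] <- g[1] != g[2]
  }
  # closed form: r = (1 - exp(-2d/100)) / 2 = 0.09063 at 10 cM
  expect_equal(mean(rec), (1 - exp(-0.2)) / 2, tolerance = 0.005 / 0.09)

  # markers 0 cM apart are always co-inherited
  g0 <- replicate(500, simulate_meiosis(c(0L, 0L), c(1L, 1L), c(5, 5)))
  expect_true(all(g0[1, ] == g0[2, ]))

  expect_error(simulate_meiosis(integer(0), integer(0), numeric(0)), "empty")
})

test_that("two generations give exact F2 segregation; chromosomes assort independently", {
  cfg <- sim_config(map = small_map(), generations = 2, pop_size = 50,
                    n_final = 2000, frac_partial = 0, geno_missing = 0,
                    qtl = no_qtl(), epistasis = no_epistasis(), hotspot = NULL)
  set.seed(3)
  ail <- simulate_ail(cfg)
  freq <- colMeans(ail$geno_true == 2L)      # heterozygote share, expect 1/2
  expect_true(all(abs(freq - 0.5) < 0.04))
  p_aa <- colMeans(ail$geno_true == 1L)      # expect 1/4
  expect_true(all(abs(p_aa - 0.25) < 0.04))
  # independent assortment across chromosomes: xa scores uncorrelated
  xa <- ail$geno_true - 2
  r_between <- cor(xa[, 1], xa[, 9])         # chr 1 vs chr 2 marker
  expect_lt(abs(r_between), 0.06)
})

test_that("F8 accumulates recombination (map expansion) and drifts around 0.5", {
  cfg2 <- sim_config(map = small_map(), generations = 2, pop_size = 60,
                     n_final = 800, frac_partial = 0, geno_missing = 0,
                     qtl = no_qtl(), epistasis = no_epistasis(), hotspot = NULL)
  cfg8 <- sim_config(map = small_map(), generations = 8, pop_size = 60,
                     n_final = 800, frac_partial = 0, geno_missing = 0,
                     qtl = no_qtl(), epistasis = no_epistasis(), hotspot = NULL)
  set.seed(4)
  x2 <- simulate_ail(cfg2)$geno_true - 2
  x8 <- simulate_ail(cfg8)$geno_true - 2
  # association between adjacent markers decays with accumulated meioses
  adj <- cbind(1:7, 2:8)                     # adjacent pairs on chromosome 1
  r2 <- mean(vapply(1:7, function(i) cor(x2[, i], x2[, i + 1]), 0))
  r8 <- mean(vapply(1:7, function(i) cor(x8[, i], x8[, i + 1]), 0))
  expect_gt(r2, r8 + 0.05)

  # allele-frequency drift: mean near 0.5, variance of the right order
  # (Wright-Fisher: p q (1 - (1 - 1/2N)^t) over the post-F1 generations)
  set.seed(5)
  reps <- 120
  pf <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(map = sim_map(1, 2, 100, 50), generations = 8,
                      pop_size = 30, n_final = 30, frac_partial = 0,
                      geno_missing = 0, qtl = no_qtl(),
                      epistasis = no_epistasis(), hotspot = NULL)
    mean(simulate_ail(cfg)$geno_true[, 1] - 1) / 2
  }, 0)
  expect_lt(abs(mean(pf) - 0.5), 0.03)
  expected_var <- 0.25 * (1 - (1 - 1 / 60)^7)
  expect_gt(var(pf), 0.4 * expected_var)
  expect_lt(var(pf), 2.0 * expected_var)
})

test_that("partial informativeness and missingness are applied as observation masks", {
  cfg <- sim_config(map = small_map(), generations = 3, pop_size = 40,
                    n_final = 200, frac_partial = 0.25, geno_missing = 0.05,
                    qtl = no_qtl(), epistasis = no_epistasis(), hotspot = NULL)
  set.seed(6)
  ail <- simulate_ail(cfg)
  expect_length(ail$partial_markers, round(0.25 * 16))
  j <- match(ail$partial_markers[1], ail$map$marker)
  obs <- ail$geno_obs[, j]
  expect_true(all(obs[!is.na(obs)] %in% c(1L, 3L, 4L, 5L)))  # never plain AB
  expect_equal(mean(is.na(ail$geno_obs)), 0.05, tolerance = 0.2)
  # full markers keep their true codes where not missing
  full <- setdiff(seq_len(16), match(ail$partial_markers, ail$map$marker))
  ok <- !is.na(ail$geno_obs[, full])
  expect_equal(ail$geno_obs[, full][ok], ail$geno_true[, full][ok])
})

test_that("a variance-scaled planted QTL realizes its fraction of trait variance", {
  set.seed(7)
  r2 <- vapply(1:15, function(i) {
    cfg <- sim_config(map = small_map(), n_final = 400, frac_partial = 0,
                      geno_missing = 0,
                      qtl = data.frame(trait = "w112", chr = "1", pos_cm = 60,
                                       var_explained = 0.09, d_frac = 0,
                                       a_sex_frac = 0),
                      epistasis = no_epistasis(), hotspot = NULL)
    ail <- simulate_ail(cfg)
    tr <- simulate_traits(ail$geno_true, ail$map, cfg)
    j <- match(tr$truth$marker[1], ail$map$marker)
    xa <- ail$geno_true[, j] - 2
    xd <- as.numeric(ail$geno_true[, j] == 2)
    summary(lm(tr$pheno$w112 ~ xa + xd))$r.squared
  }, 0)
  expect_equal(mean(r2), 0.09, tolerance = 0.02 / 0.09)
})

test_that("simulation is reproducible under a fixed seed and records truth", {
  cfg <- sim_config(map = small_map(), n_final = 60, n_expr = 30,
                    n_probesets = 40, probes_per_probeset = 1,
                    n_local_eqtl = 4, n_trans_eqtl = 2,
                    qtl = data.frame(trait = "w112", chr = "2", pos_cm = 50,
                                     var_explained = 0.1, d_frac = 0.3,
                                     a_sex_frac = 0),
                    epistasis = no_epistasis(), hotspot = NULL, seed = 123)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$cross$geno, b$cross$geno)
  expect_identical(a$cross$pheno, b$cross$pheno)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  # truth tables reference simulated entities only
  expect_true(all(a$truth$qtl$marker %in% a$cross$map$marker))
  expect_true(all(a$truth$eqtl$probeset %in% a$annotation$probeset))
  expect_equal(ncol(a$expr), 30)
})

test_that("a mediated hotspot wires targets through the mediator", {
  st <- shared_study()
  med <- st$truth$mediation
  expect_equal(nrow(med), 6)
  expect_equal(length(unique(med$mediator)), 1)
  m <- st$expr[med$mediator[1], ]
  for (tg in med$target) {
    # conditioning on the mediator removes most of the target's variance
    # attributable to it by construction
    r <- cor(st$expr[tg, ], m)
    expect_gt(abs(r), 0.4)
  }
})
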