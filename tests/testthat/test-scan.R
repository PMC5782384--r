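# Haley-Knott scans, permutation thresholds, support intervals, 2D scans,
# multiple-QTL models and analytic power.

small_scan_study <- function() {
  cache_fixture("small_scan_study", function() {
    st <- simulate_study(sim_config(
      map = small_map(), n_final = 150, n_expr = 5, n_probesets = 30,
      probes_per_probeset = 1, n_local_eqtl = 0, n_trans_eqtl = 0,
      qtl = data.frame(trait = "w112", chr = "1", pos_cm = 60,
                       var_explained = 0.15, d_frac = 0.3, a_sex_frac = -0.3),
      epistasis = no_epistasis(), hotspot = NULL, seed = 31))
    list(st = st, gp = calc_genoprob(st$cross, step = 2))
  })
}

test_that("scan LOD equals an explicit least-squares oracle", {
  st <- simulate_study(sim_config(
    map = small_map(), n_final = 22, n_expr = 5, n_probesets = 30,
    probes_per_probeset = 1, n_local_eqtl = 0, n_trans_eqtl = 0,
    geno_missing = 0.05, qtl = no_qtl(), epistasis = no_epistasis(),
    hotspot = NULL, seed = 17))
  cross <- st$cross
  gp <- calc_genoprob(cross, step = 4)
  for (interact in c(FALSE, TRUE)) {
    s1 <- scan_one(cross, gp, "w112", sex_interaction = interact, min_n = 10)
    sc <- genotype_scores(gp)
    y <- cross$pheno$w112
    sexn <- ifelse(cross$covar$sex == "male", 1, -1)
    batch <- factor(cross$covar$batch)
    oracle <- vapply(seq_len(nrow(sc$grid)), function(k) {
      d <- data.frame(y = y, sexn = sexn, batch = batch,
                      xa = sc$xa[, k], xd = sc$xd[, k])
      f0 <- lm(y ~ sexn + batch, data = d)
      f1 <- if (interact)
        lm(y ~ sexn + batch + xa + xd + xa:sexn + xd:sexn, data = d)
      else lm(y ~ sexn + batch + xa + xd, data = d)
      nrow(d) / 2 * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
    }, 0)
    expect_lt(max(abs(s1$lod - oracle)), 1e-8)
  }
})

test_that("peak effect estimates match lm coefficients and standard errors", {
  fx <- small_scan_study()
  s1 <- scan_one(fx$st$cross, fx$gp, "w112", sex_interaction = TRUE)
  pk <- attr(s1, "peaks")
  pk1 <- pk[pk$chr == "1", ]
  sc <- genotype_scores(fx$gp)
  k <- which(sc$grid$chr == "1" & abs(sc$grid$pos_cm - pk1$pos_cm) < 1e-9)
  d <- data.frame(y = fx$st$cross$pheno$w112,
                  sexn = ifelse(fx$st$cross$covar$sex == "male", 1, -1),
                  batch = factor(fx$st$cross$covar$batch),
                  xa = sc$xa[, k], xd = sc$xd[, k])
  fit <- lm(y ~ sexn + batch + xa + xd + xa:sexn + xd:sexn, data = d)
  co <- summary(fit)$coefficients
  expect_equal(pk1$a, co["xa", 1], tolerance = 1e-8)
  expect_equal(pk1$se_a, co["xa", 2], tolerance = 1e-8)
  expect_equal(pk1$d, co["xd", 1], tolerance = 1e-8)
  expect_equal(pk1$a_by_sex, co["sexn:xa", 1], tolerance = 1e-8)
  expect_equal(pk1$se_d_by_sex, co["sexn:xd", 2], tolerance = 1e-8)
})

test_that("permutation thresholds are empirical quantiles of null maxima", {
  fx <- small_scan_study()
  thr <- permutation_thresholds(fx$st$cross, fx$gp, "w42", n_perm = 120,
                                alphas = c(0.05, 0.20, 1.0), seed = 5)
  expect_equal(length(thr$max_lods), 120)
  # alpha = 1 edge: the minimum of the null maxima
  expect_equal(unname(thr$thresholds[3]), min(thr$max_lods))
  expect_equal(unname(thr$thresholds[1]),
               unname(quantile(thr$max_lods, 0.95)))
  expect_true(thr$thresholds[1] >= thr$thresholds[2])
  # reproducible under the seed
  thr2 <- permutation_thresholds(fx$st$cross, fx$gp, "w42", n_perm = 120,
                                 alphas = c(0.05, 0.20, 1.0), seed = 5)
  expect_identical(thr$max_lods, thr2$max_lods)
  expect_error(permutation_thresholds(fx$st$cross, fx$gp, "w42",
                                      n_perm = 10, alphas = 0.05),
               "n_perm")
})

test_that("family PCs retain structure-associated components only", {
  fx <- small_scan_study()
  cross <- fx$st$cross
  # trait built from PC3 is recovered
  num <- matrix(c(-1, 0, 1, -0.5, 0.5)[cross$geno], nrow(cross$geno))
  num[is.na(num)] <- 0
  pc <- prcomp(num)
  set.seed(8)
  y <- pc$x[, 3] + rnorm(n_ind(cross), 0, 0.1 * sd(pc$x[, 3]))
  pcs <- family_pcs(cross, y)
  expect_true("PC3" %in% colnames(pcs))
  expect_error(family_pcs(subset_cross(cross, 1:5), "w112", k = 10),
               "k \\+ 1")
  # independent noise trait keeps few PCs (5% per-PC false-positive rate)
  set.seed(9)
  kept <- vapply(1:30, function(i)
    ncol(family_pcs(cross, rnorm(n_ind(cross)))), 0)
  expect_lt(mean(kept), 1.5)   # expectation 0.5 under the null
})

test_that("LOD-drop intervals behave on closed-form curves and nest", {
  # triangular curve solvable by hand: peak 6 at 50 cM, slope 0.1/cM,
  # 1.8-drop crosses at 32 and 68, expanded one 2-cM grid step outward
  pos <- seq(0, 100, by = 2)
  tri <- data.frame(chr = "1", pos_cm = pos, pos_mb = pos / 10,
                    lod = 6 - 0.1 * abs(pos - 50))
  ci <- lod_interval(tri, "1", drop = 1.8)
  expect_equal(ci$peak_cm, 50)
  expect_equal(ci$lo_cm, 30)
  expect_equal(ci$hi_cm, 70)
  expect_false(ci$whole_chr)
  # flat curve: whole chromosome, flagged
  flat <- data.frame(chr = "1", pos_cm = pos, pos_mb = pos / 10, lod = 3)
  expect_true(lod_interval(flat, "1")$whole_chr)
  # nesting: a 3.0-drop interval contains the 1.8-drop interval
  fx <- small_scan_study()
  s1 <- scan_one(fx$st$cross, fx$gp, "w112")
  ci18 <- lod_interval(s1, "1", drop = 1.8)
  ci30 <- lod_interval(s1, "1", drop = 3.0)
  expect_lte(ci30$lo_cm, ci18$lo_cm)
  expect_gte(ci30$hi_cm, ci18$hi_cm)
})

test_that("overlapping support intervals merge into regions", {
  iv <- data.frame(chr = c("1", "1", "1", "2"),
                   lo_mb = c(10, 18, 40, 5), hi_mb = c(20, 30, 50, 6))
  rg <- merge_qtl_regions(iv)
  expect_equal(nrow(rg), 3)
  expect_equal(rg$n_intervals[rg$chr == "1" & rg$lo_mb == 10], 2)
  # half-open: touching intervals do not merge
  iv2 <- data.frame(chr = "1", lo_mb = c(0, 10), hi_mb = c(10, 20))
  expect_equal(nrow(merge_qtl_regions(iv2)), 2)
})

test_that("two-locus statistics equal a direct regression oracle", {
  st <- simulate_study(sim_config(
    map = sim_map(2, 3, c(40, 40), c(30, 30)), n_final = 60, n_expr = 5,
    n_probesets = 30, probes_per_probeset = 1, n_local_eqtl = 0,
    n_trans_eqtl = 0, geno_missing = 0, qtl = no_qtl(),
    epistasis = no_epistasis(), hotspot = NULL, seed = 21))
  cross <- st$cross
  gp <- calc_genoprob(cross, step = 1e6)   # markers only
  s2 <- scan_two(cross, gp, "w112", step = 1e-6)
  sc <- genotype_scores(gp)
  y <- cross$pheno$w112
  sexn <- ifelse(cross$covar$sex == "male", 1, -1)
  batch <- factor(cross$covar$batch)
  n <- length(y)
  lodf <- function(f0, f1) n / 2 * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
  f0 <- lm(y ~ sexn + batch)
  for (r in sample(nrow(s2$pairs), 5)) {
    i <- which(sc$grid$chr == s2$pairs$chr1[r] &
                 abs(sc$grid$pos_cm - s2$pairs$pos1_cm[r]) < 1e-9)
    j <- which(sc$grid$chr == s2$pairs$chr2[r] &
                 abs(sc$grid$pos_cm - s2$pairs$pos2_cm[r]) < 1e-9)
    a1 <- sc$xa[, i]; d1 <- sc$xd[, i]; a2 <- sc$xa[, j]; d2 <- sc$xd[, j]
    fadd <- lm(y ~ sexn + batch + a1 + d1 + a2 + d2)
    ffull <- lm(y ~ sexn + batch + a1 + d1 + a2 + d2 +
                  a1:a2 + a1:d2 + d1:a2 + d1:d2)
    f1a <- lm(y ~ sexn + batch + a1 + d1)
    f1b <- lm(y ~ sexn + batch + a2 + d2)
    best1 <- max(lodf(f0, f1a), lodf(f0, f1b))
    expect_equal(s2$pairs$lod_full[r], lodf(f0, ffull), tolerance = 1e-8)
    expect_equal(s2$pairs$lod_add[r], lodf(f0, fadd), tolerance = 1e-8)
    expect_equal(s2$pairs$lod_int[r], lodf(f0, ffull) - lodf(f0, fadd),
                 tolerance = 1e-8)
    expect_equal(s2$pairs$lod_fv1[r], lodf(f0, ffull) - best1, tolerance = 1e-8)
    expect_equal(s2$pairs$lod_av1[r], lodf(f0, fadd) - best1, tolerance = 1e-8)
  }
})

test_that("an interaction-only pair lights up lod_int but not the 1D scan", {
  # XOR-like architecture: effect on the product of additive scores only
  set.seed(22)
  st <- simulate_study(sim_config(
    map = small_map(), n_final = 300, n_expr = 5, n_probesets = 30,
    probes_per_probeset = 1, n_local_eqtl = 0, n_trans_eqtl = 0,
    frac_partial = 0, geno_missing = 0, qtl = no_qtl(),
    epistasis = data.frame(trait = "w42", chr1 = "1", pos_cm1 = 60,
                           chr2 = "2", pos_cm2 = 50, aa = 90),
    hotspot = NULL, seed = 23))
  gp <- calc_genoprob(st$cross, step = 10)
  s2 <- scan_two(st$cross, gp, "w42", step = 15)
  hit <- s2$pairs[s2$pairs$chr1 == "1" & s2$pairs$chr2 == "2", ]
  best <- hit[which.max(hit$lod_int), ]
  expect_gt(best$lod_int, 4)
  # marginal scans stay flat: no 1D LOD near the planted loci approaches it
  expect_lt(max(s2$grid$lod1), best$lod_int)
  # additive-only planted pair: lod_int small, lod_av1 large
  st2 <- simulate_study(sim_config(
    map = small_map(), n_final = 300, n_expr = 5, n_probesets = 30,
    probes_per_probeset = 1, n_local_eqtl = 0, n_trans_eqtl = 0,
    frac_partial = 0, geno_missing = 0,
    qtl = data.frame(trait = "w42", chr = c("1", "2"), pos_cm = c(60, 50),
                     var_explained = c(0.12, 0.12), d_frac = 0, a_sex_frac = 0),
    epistasis = no_epistasis(), hotspot = NULL, seed = 24))
  gp2 <- calc_genoprob(st2$cross, step = 10)
  s2b <- scan_two(st2$cross, gp2, "w42", step = 15)
  hit2 <- s2b$pairs[s2b$pairs$chr1 == "1" & s2b$pairs$chr2 == "2", ]
  best2 <- hit2[which.max(hit2$lod_add), ]
  expect_gt(best2$lod_av1, 4)
  expect_lt(best2$lod_int, 2)
  # the joint declaration rule picks up the additive pair
  dec <- declare_epistatic_pairs(s2b, thresholds = c(full = 8, fv1 = 6,
                                                     int = 5, add = 5, av1 = 3))
  expect_true(any(dec$chr1 == "1" & dec$chr2 == "2"))
})

test_that("multiple-QTL models recover planted loci and variance", {
  fx <- small_scan_study()
  s1 <- scan_one(fx$st$cross, fx$gp, "w112", sex_interaction = TRUE)
  pk <- attr(s1, "peaks")
  fit <- fit_multiqtl(fx$st$cross, fx$gp, "w112",
                      pk[, c("chr", "pos_cm")], threshold = 3)
  expect_s3_class(fit, "ail_qtlfit")
  expect_true("1" %in% fit$loci$chr)
  on1 <- fit$loci[fit$loci$chr == "1", ]
  expect_equal(on1$varexp, 15, tolerance = 6 / 15)
  expect_true(all(fit$loci$drop_lod > 3))
  expect_true(fit$model_varexp >= max(fit$loci$varexp) - 1e-8)
  expect_error(fit_multiqtl(fx$st$cross, fx$gp, "w112",
                            data.frame(chr = character(), pos_cm = numeric())),
               "empty")
})

test_that("analytic power is calibrated and monotone", {
  # limits: vanishing effect gives the alpha-level tail of the central
  # chi-square at the threshold
  thr <- 4
  p0 <- power_detect(400, 1e-9, thr)
  expect_equal(p0, pchisq(2 * log(10) * thr, 2, lower.tail = FALSE),
               tolerance = 1e-4)
  # monotone in n and in effect size
  expect_true(all(diff(power_detect(c(100, 200, 400, 800), 0.05, thr)) > 0))
  expect_true(all(diff(power_detect(300, c(0.02, 0.05, 0.1, 0.2), thr)) > 0))
  expect_error(power_detect(100, 1.2, 4), "effect_fraction")
  # Monte-Carlo cross-check at the true locus: n = 130, f = 0.16, thr = 4
  set.seed(25)
  n <- 130; f <- 0.16
  hits <- vapply(1:400, function(i) {
    g <- sample(0:2, n, replace = TRUE, prob = c(1, 2, 1))
    xa <- g - 1; xd <- as.numeric(g == 1)
    a <- sqrt(f / (1 - f) / var(xa))
    y <- a * xa + rnorm(n)
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(resid(lm(y ~ xa + xd))^2)
    n / 2 * log10(rss0 / rss1) >= 4
  }, TRUE)
  expect_equal(mean(hits), power_detect(130, 0.16, 4), tolerance = 0.06 / 0.8)
})
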