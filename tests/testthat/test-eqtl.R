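# Expression preprocessing and local/distal eQTL mapping.

test_that("quantile normalization equalizes column distributions", {
  # hand-computed 3x3 example: sorted-row means are (2, 4, 6)
  m <- matrix(c(1, 3, 5,
                2, 4, 6,
                3, 5, 7), nrow = 3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), matrix(c(2, 4, 6, 2, 4, 6, 2, 4, 6), 3))
  # already identically distributed columns are unchanged
  m2 <- cbind(c(5, 1, 3), c(1, 3, 5), c(3, 5, 1))
  expect_equal(unname(quantile_normalize(m2)), unname(m2))
  # sorted values identical across columns, by definition
  set.seed(1)
  m3 <- matrix(rnorm(60), 12, 5)
  qn3 <- quantile_normalize(m3)
  s <- apply(qn3, 2, sort)
  expect_lt(max(abs(s - s[, 1])), 1e-12)
  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), "2 columns")
})

# independent iterative median-polish oracle
polish_oracle <- function(x, iter = 10) {
  overall <- 0; re <- rep(0, nrow(x)); ce <- rep(0, ncol(x))
  for (i in seq_len(iter)) {
    rm_ <- apply(x, 1, median); x <- sweep(x, 1, rm_); re <- re + rm_
    dc <- median(ce); ce <- ce - dc; overall <- overall + dc
    cm_ <- apply(x, 2, median); x <- sweep(x, 2, cm_); ce <- ce + cm_
    dr <- median(re); re <- re - dr; overall <- overall + dr
  }
  overall + ce
}

test_that("median polish summarization matches an independent oracle", {
  set.seed(2)
  x <- matrix(rnorm(12, 8), 3, 4)
  got <- median_polish_summarize(x, rep("ps1", 3))
  expect_equal(unname(got["ps1", ]), unname(polish_oracle(x)), tolerance = 1e-6)
  # single-probe probeset passes through
  y <- matrix(1:4, 1, 4)
  expect_equal(unname(median_polish_summarize(y, "ps2")["ps2", ]),
               as.numeric(1:4))
  # sample-shift equivariance: adding a constant to one column shifts only
  # that sample's summary by the constant
  # (the iteration cap leaves a small residual on non-converged layouts)
  x2 <- x; x2[, 2] <- x2[, 2] + 5
  got2 <- median_polish_summarize(x2, rep("ps1", 3))
  expect_equal(unname(got2["ps1", ] - got["ps1", ]), c(0, 5, 0, 0),
               tolerance = 0.01)
  expect_error(median_polish_summarize(x, rep("a", 2)), "label")
})

test_that("ComBat-style batch adjustment removes planted offsets and shrinks", {
  set.seed(3)
  G <- 60; n <- 24
  m <- matrix(rnorm(G * n, 8), G, n)
  rownames(m) <- paste0("g", 1:G)
  # two identical batches (duplicated data): adjustment is near a no-op
  # (empirical-Bayes variance shrinkage leaves a small per-gene wobble)
  dup <- cbind(m, m)
  out <- adjust_batch(dup, rep(c("a", "b"), each = n))
  expect_lt(max(abs(out - dup)), 0.2)
  expect_gt(cor(as.vector(out), as.vector(dup)), 0.999)
  # planted constant offset on batch b is removed
  batch <- rep(c("a", "b"), each = n / 2)
  m2 <- m
  m2[, batch == "b"] <- m2[, batch == "b"] + 2
  out2 <- adjust_batch(m2, batch)
  gap <- rowMeans(out2[, batch == "b"]) - rowMeans(out2[, batch == "a"])
  raw_gap <- rowMeans(m2[, batch == "b"]) - rowMeans(m2[, batch == "a"])
  expect_lt(max(abs(gap)), 0.8)
  expect_lt(mean(abs(gap)), 0.2)
  expect_lt(mean(abs(gap)), 0.2 * mean(abs(raw_gap)))
  expect_lt(mean(apply(out2, 1, var)), mean(apply(m2, 1, var)))
  # overall gene means preserved
  expect_equal(rowMeans(out2), rowMeans(m2), tolerance = 0.05)
  expect_error(adjust_batch(m2, rep("a", n)), "batch")
  expect_error(adjust_batch(m2, c("a", rep("b", n - 1))), "single-sample")
})

eqtl_study <- function() {
  cache_fixture("eqtl_study", function() {
    st <- shared_study()
    cre <- subset_cross(st$cross, st$expr_ids)
    cre$covar <- st$expr_covar
    gpe <- calc_genoprob(cre, step = 2)
    expr <- adjust_batch(quantile_normalize(st$expr),
                         st$expr_covar$batch_expr)
    list(st = st, cre = cre, gpe = gpe, expr = expr)
  })
}

# window rule used below (mirrors the scan's definition)
local_window_positions <- function(grid, chr, pos, window)
  which(grid$chr == chr & abs(grid$pos_cm - pos) <= window / 2)

test_that("planted local eQTL are found inside their windows; windows clip", {
  fx <- eqtl_study()
  loc <- scan_local(fx$expr, fx$st$annotation, fx$cre, fx$gpe, threshold = 4)
  planted <- fx$st$truth$eqtl
  planted_local <- planted$probeset[planted$type == "local"]
  found <- intersect(loc$probeset, planted_local)
  expect_gt(length(found) / length(planted_local), 0.6)
  # every local record's peak lies within 50 cM of its gene
  ann <- fx$st$annotation
  gene_cm <- ann$pos_cm[match(loc$probeset, ann$probeset)]
  gene_chr <- ann$chr[match(loc$probeset, ann$probeset)]
  expect_true(all(loc$chr == gene_chr))
  expect_true(all(abs(loc$peak_cm - gene_cm) <= 50 + 1e-9))
  # a gene at a chromosome start has its window clipped at 0
  sc <- genotype_scores(fx$gpe)
  win <- sc$grid[local_window_positions(sc$grid, "1", 0, 100), ]
  expect_true(all(win$pos_cm <= 50 + 1e-9))
  expect_true(all(win$chr == "1"))
})

test_that("distal scans exclude the local window and apply the class filter", {
  fx <- eqtl_study()
  dis <- scan_distal(fx$expr, fx$st$annotation, fx$cre, fx$gpe,
                     threshold = 6, class_filter = 10)
  expect_true(!is.null(dis) && nrow(dis) > 0)
  ann <- fx$st$annotation
  for (r in seq_len(nrow(dis))) {
    ai <- match(dis$probeset[r], ann$probeset)
    same <- dis$chr[r] == ann$chr[ai]
    if (same)   # a "distal" peak on the gene's own chromosome is > 50 cM away
      expect_gt(abs(dis$peak_cm[r] - ann$pos_cm[ai]), 50 - 1e-9)
  }
  expect_true(all(dis$min_class_n > 10))
})

test_that("a strong trans signal carried by a rare genotype class is filtered", {
  # explicit construction: a marker with exactly 8 AA individuals
  map <- sim_map(2, 6, c(100, 100), c(80, 80))
  n <- 130
  set.seed(4)
  g_skew <- c(rep(1L, 8), sample(c(2L, 3L), n - 8, TRUE))
  geno <- vapply(seq_len(nrow(map)), function(j)
    sample(1:3, n, TRUE, prob = c(1, 2, 1)), integer(n))
  geno[, 3] <- g_skew                      # C1M03 is the skewed marker
  colnames(geno) <- map$marker
  rownames(geno) <- paste0("i", seq_len(n))
  y <- 3 * (as.numeric(g_skew) - 2) + rnorm(n, 0, 0.5)
  cr <- make_cross(geno, map, pheno = data.frame(dummy = y),
                   covar = data.frame(sex = rep(c("male", "female"),
                                                length.out = n)))
  gp <- calc_genoprob(cr, step = 5)
  e1 <- matrix(y, 1, dimnames = list("PSX", rownames(geno)))
  annX <- data.frame(probeset = "PSX", gene = "GX", chr = "2",
                     pos_cm = 50, pos_mb = 40)
  # with the default filter (> 10 per class required) the hit is dropped
  out10 <- scan_distal(e1, annX, cr, gp, covar = "sex", threshold = 6,
                       class_filter = 10)
  expect_false("1" %in% (if (is.null(out10)) character() else out10$chr))
  # with a permissive filter the same signal is reported
  out5 <- scan_distal(e1, annX, cr, gp, covar = "sex", threshold = 6,
                      class_filter = 5)
  expect_true("1" %in% out5$chr)
})

test_that("subsampled-probeset thresholds: trans exceeds local, seed-stable", {
  fx <- eqtl_study()
  thr <- subsampled_thresholds(fx$expr, fx$st$annotation, fx$cre, fx$gpe,
                               n_probesets = 100, n_reps = 60, seed = 5)
  expect_gt(thr$trans, thr$local)
  thr2 <- subsampled_thresholds(fx$expr, fx$st$annotation, fx$cre, fx$gpe,
                                n_probesets = 100, n_reps = 60, seed = 5)
  expect_identical(thr$null_trans, thr2$null_trans)
  expect_error(subsampled_thresholds(fx$expr[1:20, ], fx$st$annotation,
                                     fx$cre, fx$gpe, n_probesets = 100,
                                     n_reps = 10),
               "probesets")
})

test_that("effect-direction summaries reflect the planted architecture", {
  fx <- eqtl_study()
  loc <- scan_local(fx$expr, fx$st$annotation, fx$cre, fx$gpe, threshold = 4)
  sm <- effect_direction_summary(loc)
  expect_true(all(c("class", "sex", "effect", "prop_pos") %in% names(sm)))
  expect_true(all(sm$n_pos + sm$n_neg <= nrow(loc)))
  # empty input gives an empty summary
  expect_equal(nrow(effect_direction_summary(loc[0, ])), 0)
  # symmetric additive effects: pooled-sex additive sign near 50/50 when
  # enough records (generator draws effect signs symmetrically)
  a_rows <- sm[sm$effect == "a", ]
  if (sum(a_rows$n_pos + a_rows$n_neg) >= 20)
    expect_gt(min(a_rows$prop_pos), 0.1)
})
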