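# Simulation of an F8 advanced intercross (AIL) with planted trait QTL and
# expression-QTL architectures. The generator emulates the design of a wild x
# domestic chicken intercross: two inbred-like founder lines, an F1, then
# random non-self mating at ~100 individuals per generation up to F8, a
# genotyped/phenotyped final generation, and a subset of individuals with
# two-colour microarray expression data (batch = slide, dye = fluorophore).

#' Build a marker map for simulation
#'
#' Markers are evenly spaced along each chromosome; cM and Mb coordinates are
#' proportional within a chromosome. Chromosome lengths default to an
#' F8-expanded map (the accumulated recombinations of an AIL inflate the
#' realised map), with physical lengths summing to ~1 Gb.
#'
#' @param n_chr Number of autosomes.
#' @param markers_per_chr Markers per chromosome (recycled).
#' @param length_cm Chromosome lengths in cM (recycled).
#' @param length_mb Chromosome lengths in Mb (recycled).
#' @return Map data frame (`marker`, `chr`, `pos_cm`, `pos_mb`).
#' @export
sim_map <- function(n_chr = 6, markers_per_chr = 20,
                    length_cm = c(400, 350, 320, 280, 250, 200),
                    length_mb = c(200, 180, 170, 160, 150, 140)) {
  markers_per_chr <- rep_len(markers_per_chr, n_chr)
  length_cm <- rep_len(length_cm, n_chr)
  length_mb <- rep_len(length_mb, n_chr)
  maps <- lapply(seq_len(n_chr), function(i) {
    k <- markers_per_chr[i]
    pos <- seq(0, length_cm[i], length.out = k)
    data.frame(marker = sprintf("C%dM%02d", i, seq_len(k)),
               chr = as.character(i), pos_cm = pos,
               pos_mb = pos / length_cm[i] * length_mb[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulation configuration for an F8 advanced intercross study
#'
#' Collects every dial of the generator: the pedigree scale, the marker map,
#' the trait QTL architecture and the expression architecture. The defaults
#' describe the study the package is modelled on: eight generations at ~100
#' individuals each, a genotyped final generation, six rearing batches,
#' strong sexual size dimorphism, one major growth locus (~9% of variance)
#' plus minor and epistatic loci, and an expression study on a 130-individual
#' subset with local eQTL, trans eQTL, pervasive sex interactions and one
#' mediated trans-hotspot.
#'
#' @param map Marker map from [sim_map()].
#' @param generations Number of intercross generations (8 = F8).
#' @param pop_size Individuals per intermediate generation.
#' @param n_final Individuals in the final (studied) generation.
#' @param n_expr Size of the expression subset (<= `n_final`).
#' @param frac_partial Fraction of markers that are only partially
#'   informative (heterozygote indistinguishable from one homozygote).
#' @param geno_missing Per-genotype missing rate.
#' @param n_batches Number of rearing batches for traits.
#' @param qtl Data frame of planted trait QTL with columns `trait`, `chr`,
#'   `pos_cm`, and effect columns `a`, `d`, `a_by_sex`, `d_by_sex` (trait
#'   units); alternatively a column `var_explained` (fraction of trait
#'   variance, converted to an additive effect from the realised genotype
#'   variance at simulation time).
#' @param epistasis Data frame of planted pairs: `trait`, `chr1`, `pos_cm1`,
#'   `chr2`, `pos_cm2`, `aa` (coefficient on the product of additive scores)
#'   and optionally `dd`.
#' @param trait_sd Named numeric: residual SD per mass trait (grams).
#' @param sex_effect Named numeric: male minus female offset per trait.
#' @param batch_sd Between-batch SD (grams).
#' @param n_probesets Number of probesets on the simulated array.
#' @param probes_per_probeset Probes per probeset (2-3 on the emulated
#'   platform); set to 1 to emit probeset-level data directly.
#' @param n_local_eqtl,n_trans_eqtl Numbers of planted local / trans eQTL.
#' @param eqtl_var Fraction of residual (covariate-adjusted) expression
#'   variance a planted eQTL explains through its additive term.
#' @param eqtl_d_range Dominance of planted eQTL, drawn uniformly from this
#'   range as a fraction of the additive effect (the mild negative skew
#'   mirrors heterozygotes sitting below the mid-homozygote value).
#' @param sex_int_frac Fraction of planted eQTL given a sex-specific effect.
#' @param hotspot List describing the mediated trans-hotspot: `chr`,
#'   `pos_cm`, `n_targets`, `beta` (mediator-to-target slope), `var`
#'   (variance fraction of the mediator's own local eQTL).
#' @param expr_sd Residual SD of log2 expression.
#' @param expr_batch_sd,expr_dye_sd SDs of slide (batch) and fluorophore
#'   (dye) offsets on the log2 scale.
#' @param seed Integer seed recorded in the output metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(map = sim_map(),
                       generations = 8, pop_size = 100, n_final = 300,
                       n_expr = 130, frac_partial = 0.155,
                       geno_missing = 0.01, n_batches = 6,
                       qtl = NULL, epistasis = NULL,
                       trait_sd = c(w8 = 8, w42 = 60, w112 = 180, w212 = 220),
                       sex_effect = c(w8 = 2, w42 = 40, w112 = 250, w212 = 400),
                       batch_sd = 30,
                       n_probesets = 1500, probes_per_probeset = 2,
                       n_local_eqtl = 120, n_trans_eqtl = 25,
                       eqtl_var = 0.2, eqtl_d_range = c(-0.6, 0.2),
                       sex_int_frac = 0.6,
                       hotspot = list(chr = "5", pos_cm = 125, n_targets = 8,
                                      beta = 1, var = 0.5),
                       expr_sd = 0.5, expr_batch_sd = 0.3, expr_dye_sd = 0.2,
                       seed = 1L) {
  if (pop_size < 2 || n_final < 2) stop("population sizes must be >= 2")
  if (is.null(qtl)) {
    qtl <- data.frame(
      trait = c("w112", "w112", "w212", "g42.112", "g42.112"),
      chr = c("1", "2", "1", "3", "5"),
      pos_cm = c(210, 160, 210, 100, 220),
      var_explained = c(0.09, 0.02, 0.084, 0.025, 0.02),
      d_frac = c(0.6, 0.3, 0.1, 0.5, 0.3),
      a_sex_frac = c(-0.4, 0, -0.45, 0.3, 0),
      stringsAsFactors = FALSE)
  }
  if (is.null(epistasis)) {
    epistasis <- data.frame(trait = "w212", chr1 = "4", pos_cm1 = 140,
                            chr2 = "6", pos_cm2 = 60, aa = 45,
                            stringsAsFactors = FALSE)
  }
  structure(list(map = map, generations = generations, pop_size = pop_size,
                 n_final = n_final, n_expr = n_expr,
                 frac_partial = frac_partial, geno_missing = geno_missing,
                 n_batches = n_batches, qtl = qtl, epistasis = epistasis,
                 trait_sd = trait_sd, sex_effect = sex_effect,
                 batch_sd = batch_sd, n_probesets = n_probesets,
                 probes_per_probeset = probes_per_probeset,
                 n_local_eqtl = n_local_eqtl, n_trans_eqtl = n_trans_eqtl,
                 eqtl_var = eqtl_var, eqtl_d_range = eqtl_d_range,
                 sex_int_frac = sex_int_frac,
                 hotspot = hotspot, expr_sd = expr_sd,
                 expr_batch_sd = expr_batch_sd, expr_dye_sd = expr_dye_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one meiosis on one chromosome
#'
#' Haldane (no-interference) model: the number of crossovers is
#' Poisson(length_cM / 100), crossover positions are uniform, and the gamete
#' is a mosaic of the two parental haplotypes starting from a random one.
#'
#' @param hap1,hap2 Allele vectors (one entry per marker) of the two
#'   parental haplotypes.
#' @param pos_cm Marker positions in cM on this chromosome.
#' @return Gamete allele vector.
#' @export
simulate_meiosis <- function(hap1, hap2, pos_cm) {
  m <- length(pos_cm)
  if (m == 0) stop("empty chromosome")
  L <- pos_cm[m] - pos_cm[1]
  n_xo <- if (L > 0) stats::rpois(1, L / 100) else 0L
  phase0 <- sample.int(2L, 1L) - 1L          # 0 -> start on hap1
  if (n_xo == 0) {
    phase <- rep(phase0, m)
  } else {
    xo <- stats::runif(n_xo, pos_cm[1], pos_cm[m])
    phase <- (phase0 + findInterval(pos_cm, sort(xo))) %% 2L
  }
  ifelse(phase == 0L, hap1, hap2)
}

# One generation of random non-self mating: returns list(hapA, hapB),
# n_off x m matrices of founder-line alleles (0 = wild A, 1 = domestic B).
mate_generation <- function(hapA, hapB, map_split, n_off) {
  n <- nrow(hapA)
  m <- ncol(hapA)
  dam <- sample.int(n, n_off, replace = TRUE)
  sire <- sample.int(n - 1L, n_off, replace = TRUE)
  sire <- ifelse(sire >= dam, sire + 1L, sire)   # exclude selfing
  offA <- matrix(0L, n_off, m)
  offB <- matrix(0L, n_off, m)
  for (i in seq_len(n_off)) {
    for (sp in map_split) {
      offA[i, sp$idx] <- simulate_meiosis(hapA[dam[i], sp$idx],
                                          hapB[dam[i], sp$idx], sp$pos)
      offB[i, sp$idx] <- simulate_meiosis(hapA[sire[i], sp$idx],
                                          hapB[sire[i], sp$idx], sp$pos)
    }
  }
  list(hapA = offA, hapB = offB)
}

#' Simulate founder-origin genotypes for the final AIL generation
#'
#' Founders are fully inbred and fixed for alternative alleles, so the F1 is
#' uniformly heterozygous; generations 2..`generations` are produced by
#' random non-self mating (sib mating allowed, as in a closed flock) at
#' `pop_size` individuals, and the final generation at `n_final`. Marker
#' informativeness is then emulated by masking: partially informative markers
#' report one homozygote class merged with the heterozygote (not-AA or
#' not-BB, direction random per marker), and genotypes go missing at rate
#' `geno_missing`.
#'
#' @param config A [sim_config()].
#' @return List with `geno_true` (codes 1/2/3), `geno_obs` (codes 1..5 with
#'   `NA`s), `map`, and `partial_markers`.
#' @export
simulate_ail <- function(config) {
  map <- config$map
  m <- nrow(map)
  chrs <- unique(map$chr)
  map_split <- lapply(chrs, function(ch) {
    idx <- which(map$chr == ch)
    list(idx = idx, pos = map$pos_cm[idx])
  })
  # F1: every individual A|B at every marker
  hapA <- matrix(0L, config$pop_size, m)
  hapB <- matrix(1L, config$pop_size, m)
  gens <- config$generations
  if (gens < 2) stop("generations must be >= 2")
  for (g in seq(2, gens)) {
    n_off <- if (g == gens) config$n_final else config$pop_size
    off <- mate_generation(hapA, hapB, map_split, n_off)
    hapA <- off$hapA; hapB <- off$hapB
  }
  geno_true <- hapA + hapB + 1L            # 1 = AA, 2 = AB, 3 = BB
  colnames(geno_true) <- map$marker
  # observation model: partial informativeness + missingness
  n_part <- round(config$frac_partial * m)
  partial <- sort(sample.int(m, n_part))
  dir_notAA <- sample(c(TRUE, FALSE), n_part, replace = TRUE)
  geno_obs <- geno_true
  for (k in seq_along(partial)) {
    j <- partial[k]
    if (dir_notAA[k]) {      # AB and BB indistinguishable -> not-AA
      geno_obs[geno_obs[, j] %in% c(2L, 3L), j] <- 5L
    } else {                 # AA and AB indistinguishable -> not-BB
      geno_obs[geno_obs[, j] %in% c(1L, 2L), j] <- 4L
    }
  }
  if (config$geno_missing > 0) {
    drop <- which(stats::runif(length(geno_obs)) < config$geno_missing)
    geno_obs[drop] <- NA_integer_
  }
  list(geno_true = geno_true, geno_obs = geno_obs, map = map,
       partial_markers = map$marker[partial])
}

# Additive/dominance scores from true genotype codes at one marker.
true_scores <- function(g) {
  list(xa = as.numeric(g) - 2, xd = as.numeric(g == 2L))
}

nearest_marker <- function(map, chr, pos_cm) {
  idx <- which(map$chr == as.character(chr))
  if (!length(idx)) stop("QTL chromosome off-map: ", chr)
  idx[which.min(abs(map$pos_cm[idx] - pos_cm))]
}

#' Simulate body-mass and growth traits on simulated genotypes
#'
#' The trait model is
#' `y = mu + batch + sex_offset * sex/2 + sum_q [a x_a + d x_d +
#' (a_by_sex x_a + d_by_sex x_d) * sex] + epistasis + N(0, sigma^2)`
#' with additive score `x_a` in -1/0/1, dominance score `x_d` in 0/1 and sex
#' coded -1 (female) / +1 (male). QTL specified via `var_explained` have
#' their additive effect solved from the realised additive-score variance so
#' the planted locus explains the requested fraction of trait variance;
#' `d_frac` and `a_sex_frac` then scale d and a-by-sex relative to a.
#'
#' @param geno_true True genotype matrix (codes 1/2/3) from [simulate_ail()].
#' @param map Marker map.
#' @param config A [sim_config()].
#' @return List with `pheno` (w8/w42/w112/w212 plus derived growth traits)
#'   and `covar` (sex, batch), plus `truth`, the realised QTL effect table.
#' @export
simulate_traits <- function(geno_true, map, config) {
  n <- nrow(geno_true)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  sexn <- ifelse(sex == "male", 1, -1)
  batch <- factor(sample(paste0("b", seq_len(config$n_batches)), n, replace = TRUE))
  batch_eff <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  traits <- c("w8", "w42", "w112", "w212")
  base_mean <- c(w8 = 65, w42 = 450, w112 = 1100, w212 = 1500)
  pheno <- data.frame(row.names = seq_len(n))
  truth <- NULL
  qtl <- config$qtl
  for (tr in traits) {
    sd_tr <- config$trait_sd[[tr]]
    y <- base_mean[[tr]] + batch_eff[as.integer(batch)] +
      config$sex_effect[[tr]] * sexn / 2
    rows <- if (!is.null(qtl) && nrow(qtl)) which(qtl$trait == tr) else integer(0)
    scaled <- logical(length(rows))
    # fixed-effect QTL enter the base; variance-scaled QTL are added after
    # the base (incl. noise) is complete, so `var_explained` is a fraction
    # of total trait variance -- the quantity a drop-one fit estimates
    for (ri in seq_along(rows)) {
      r <- rows[ri]
      if (!is.null(qtl$var_explained) && !is.na(qtl$var_explained[r])) {
        scaled[ri] <- TRUE
        next
      }
      j <- nearest_marker(map, qtl$chr[r], qtl$pos_cm[r])
      sc <- true_scores(geno_true[, j])
      a <- qtl$a[r]
      d <- if (!is.null(qtl$d)) qtl$d[r] else 0
      a_sex <- if (!is.null(qtl$a_by_sex)) qtl$a_by_sex[r] else 0
      d_sex <- if (!is.null(qtl$d_by_sex)) qtl$d_by_sex[r] else 0
      y <- y + a * sc$xa + d * sc$xd + (a_sex * sc$xa + d_sex * sc$xd) * sexn
      truth <- rbind(truth, data.frame(
        trait = tr, marker = map$marker[j], chr = map$chr[j],
        pos_cm = map$pos_cm[j], a = a, d = d, a_by_sex = a_sex,
        d_by_sex = d_sex, var_explained = NA_real_, stringsAsFactors = FALSE))
    }
    epi <- config$epistasis
    erows <- if (!is.null(epi) && nrow(epi)) which(epi$trait == tr) else integer(0)
    for (r in erows) {
      j1 <- nearest_marker(map, epi$chr1[r], epi$pos_cm1[r])
      j2 <- nearest_marker(map, epi$chr2[r], epi$pos_cm2[r])
      s1 <- true_scores(geno_true[, j1]); s2 <- true_scores(geno_true[, j2])
      y <- y + epi$aa[r] * s1$xa * s2$xa
      if (!is.null(epi$dd) && !is.na(epi$dd[r]))
        y <- y + epi$dd[r] * s1$xd * s2$xd
    }
    y <- y + stats::rnorm(n, 0, sd_tr)
    v_base <- stats::var(y)
    f_all <- sum(qtl$var_explained[rows[scaled]])
    for (r in rows[scaled]) {
      j <- nearest_marker(map, qtl$chr[r], qtl$pos_cm[r])
      sc <- true_scores(geno_true[, j])
      f <- qtl$var_explained[r]
      d_frac <- if (!is.null(qtl$d_frac) && !is.na(qtl$d_frac[r])) qtl$d_frac[r] else 0
      s_frac <- if (!is.null(qtl$a_sex_frac) && !is.na(qtl$a_sex_frac[r])) qtl$a_sex_frac[r] else 0
      term <- sc$xa + d_frac * sc$xd + s_frac * sc$xa * sexn
      # scale by the covariate-orthogonal variance: under drift a skewed
      # marker makes parts of the term collinear with sex, which the scan
      # model absorbs and which therefore must not count toward f
      vt <- stats::var(stats::lm.fit(cbind(1, sexn), term)$residuals)
      if (vt <= 1e-8) stop("variance-scaled QTL has no genotype variance at its marker")
      a <- sqrt(f / (1 - f_all) * v_base / vt)
      y <- y + a * term
      truth <- rbind(truth, data.frame(
        trait = tr, marker = map$marker[j], chr = map$chr[j],
        pos_cm = map$pos_cm[j], a = a, d = a * d_frac, a_by_sex = a * s_frac,
        d_by_sex = 0, var_explained = f, stringsAsFactors = FALSE))
    }
    pheno[[tr]] <- y
  }
  covar <- data.frame(sex = sex, batch = batch, stringsAsFactors = FALSE)
  list(pheno = pheno, covar = covar, truth = truth)
}

#' Simulate a liver expression study on a subset of the cross
#'
#' Probesets are placed uniformly over the physical genome. Planted local
#' eQTL shift a probeset's mean by the genotype at the marker nearest its own
#' annotated position; trans eQTL by the genotype at a distant marker. The
#' mediated hotspot follows the causal chain genotype -> mediator ->
#' targets: the mediator gene has a local eQTL at the hotspot locus and each
#' target equals `beta * mediator + noise`, so conditioning on the mediator
#' removes the targets' genotype signal. Slide (batch), fluorophore (dye)
#' and sex offsets are added; probe-level data (probeset signal + probe
#' affinity + noise) are emitted when `probes_per_probeset > 1`.
#'
#' @param geno_true True genotype matrix of the expression subset.
#' @param map Marker map.
#' @param covar Covariate table (needs `sex`) for the subset.
#' @param config A [sim_config()].
#' @return List with `expr` (probeset x individual log2 matrix),
#'   `probe_expr` (probe-level matrix or NULL), `probe_annot`,
#'   `annotation` (probeset genomic positions), `covar` (with slide batch
#'   and dye added) and `truth` (planted eQTL and mediation links).
#' @export
simulate_expression <- function(geno_true, map, covar, config) {
  n <- nrow(geno_true)
  P <- config$n_probesets
  sexn <- ifelse(covar$sex == "male", 1, -1)
  chrs <- unique(map$chr)
  chr_mb <- vapply(chrs, function(ch) max(map$pos_mb[map$chr == ch]), 0)
  # uniform placement over the physical genome
  probs <- chr_mb / sum(chr_mb)
  ann_chr <- sample(chrs, P, replace = TRUE, prob = probs)
  ann_mb <- stats::runif(P) * chr_mb[ann_chr]
  annotation <- data.frame(
    probeset = sprintf("PS%04d", seq_len(P)),
    gene = sprintf("GENE%04d", seq_len(P)),
    chr = ann_chr, pos_mb = ann_mb,
    pos_cm = vapply(seq_len(P),
                    function(i) mb_to_cm(map, ann_chr[i], ann_mb[i]), 0),
    stringsAsFactors = FALSE)
  # slide batches of ~16 (two-colour: 8 arrays x 2 samples) and dye labels
  slide <- factor(paste0("s", ceiling(seq_len(n) / 16)))
  dye <- factor(rep_len(c("Cy3", "Cy5"), n))
  slide_eff <- stats::rnorm(nlevels(slide), 0, config$expr_batch_sd)
  dye_eff <- c(0, stats::rnorm(1, 0, config$expr_dye_sd))
  base <- stats::rnorm(P, 8, 1.2)
  expr <- matrix(stats::rnorm(P * n, 0, config$expr_sd), P, n)
  expr <- expr + base
  sex_dim <- stats::rnorm(P, 0, 0.15)       # mild sexual dimorphism throughout
  expr <- expr + outer(sex_dim, sexn)

  eqtl_effect <- function(var_frac, xa) {
    va <- stats::var(xa)
    if (va <= 0) return(0)
    config$expr_sd * sqrt(var_frac / ((1 - var_frac) * va))
  }
  truth <- NULL
  add_eqtl <- function(expr, ps, j, type, var_frac, sex_spec) {
    sc <- true_scores(geno_true[, j])
    a <- eqtl_effect(var_frac, sc$xa)
    d <- a * stats::runif(1, config$eqtl_d_range[1], config$eqtl_d_range[2])
    w <- if (sex_spec) (1 + sexn) / 2 * sample(c(1, -1) * 1.6, 1) + 0.2 else 1
    expr[ps, ] <- expr[ps, ] + (a * sc$xa + d * sc$xd) * w
    truth <<- rbind(truth, data.frame(
      probeset = annotation$probeset[ps], type = type,
      marker = map$marker[j], chr = map$chr[j], pos_cm = map$pos_cm[j],
      a = a, d = d, sex_specific = sex_spec, stringsAsFactors = FALSE))
    expr
  }
  hs <- config$hotspot
  n_special <- if (is.null(hs)) 0 else 1 + hs$n_targets
  free <- sample(P - n_special) + n_special  # probesets 1..n_special reserved
  n_loc <- min(config$n_local_eqtl, length(free))
  loc_ps <- free[seq_len(n_loc)]
  for (ps in loc_ps) {
    j <- nearest_marker(map, annotation$chr[ps], annotation$pos_cm[ps])
    expr <- add_eqtl(expr, ps, j, "local", config$eqtl_var,
                     stats::runif(1) < config$sex_int_frac)
  }
  n_tr <- min(config$n_trans_eqtl, length(free) - n_loc)
  tr_ps <- free[n_loc + seq_len(n_tr)]
  for (ps in tr_ps) {
    repeat {                                 # a marker far from the gene
      j <- sample.int(nrow(map), 1)
      far <- map$chr[j] != annotation$chr[ps] ||
        abs(map$pos_cm[j] - annotation$pos_cm[ps]) > 60
      if (far) break
    }
    expr <- add_eqtl(expr, ps, j, "trans", config$eqtl_var,
                     stats::runif(1) < config$sex_int_frac)
  }
  mediation <- NULL
  if (!is.null(hs)) {
    j <- nearest_marker(map, hs$chr, hs$pos_cm)
    med <- 1L
    # mediator annotated at the hotspot locus
    annotation$chr[med] <- map$chr[j]
    annotation$pos_cm[med] <- map$pos_cm[j]
    annotation$pos_mb[med] <- cm_to_mb(map, map$chr[j], map$pos_cm[j])
    sc <- true_scores(geno_true[, j])
    a <- eqtl_effect(hs$var, sc$xa)
    expr[med, ] <- expr[med, ] + a * sc$xa
    truth <- rbind(truth, data.frame(
      probeset = annotation$probeset[med], type = "local",
      marker = map$marker[j], chr = map$chr[j], pos_cm = map$pos_cm[j],
      a = a, d = 0, sex_specific = FALSE, stringsAsFactors = FALSE))
    targets <- 1L + seq_len(hs$n_targets)
    for (ps in targets) {
      # annotate targets away from the hotspot chromosome
      och <- sample(setdiff(chrs, map$chr[j]), 1)
      annotation$chr[ps] <- och
      annotation$pos_mb[ps] <- stats::runif(1) * chr_mb[och]
      annotation$pos_cm[ps] <- mb_to_cm(map, och, annotation$pos_mb[ps])
      expr[ps, ] <- expr[ps, ] + hs$beta * (expr[med, ] - mean(expr[med, ]))
      mediation <- rbind(mediation, data.frame(
        mediator = annotation$probeset[med], target = annotation$probeset[ps],
        marker = map$marker[j], chr = map$chr[j], pos_cm = map$pos_cm[j],
        beta = hs$beta, stringsAsFactors = FALSE))
    }
  }
  expr <- expr + rep(slide_eff[as.integer(slide)], each = P) +
    rep(dye_eff[as.integer(dye)], each = P)
  rownames(expr) <- annotation$probeset
  colnames(expr) <- rownames(geno_true)
  probe_expr <- NULL; probe_annot <- NULL
  k <- config$probes_per_probeset
  if (k > 1) {
    nprobe <- sample(2:max(2, k), P, replace = TRUE)
    probe_ps <- rep(seq_len(P), nprobe)
    affinity <- stats::rnorm(length(probe_ps), 0, 0.4)
    probe_expr <- expr[probe_ps, , drop = FALSE] + affinity +
      matrix(stats::rnorm(length(probe_ps) * n, 0, 0.2), length(probe_ps), n)
    probe_annot <- data.frame(
      probe = sprintf("%s_p%d", annotation$probeset[probe_ps],
                      unlist(lapply(nprobe, seq_len))),
      probeset = annotation$probeset[probe_ps], stringsAsFactors = FALSE)
    rownames(probe_expr) <- probe_annot$probe
  }
  covar$batch_expr <- slide
  covar$dye <- dye
  list(expr = expr, probe_expr = probe_expr, probe_annot = probe_annot,
       annotation = annotation, covar = covar,
       truth = list(eqtl = truth, mediation = mediation))
}

#' Simulate a complete genetical-genomics study
#'
#' Runs [simulate_ail()], [simulate_traits()] and [simulate_expression()]
#' under one seed and assembles an `ail_cross`, the expression study for the
#' expression subset, and truth tables for parameter-recovery checks.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study` with elements `cross`, `geno_true`,
#'   `expr`, `probe_expr`, `probe_annot`, `annotation`, `expr_ids` (row
#'   indices of the expression subset), `truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  ail <- simulate_ail(config)
  tr <- simulate_traits(ail$geno_true, ail$map, config)
  rownames(ail$geno_true) <- rownames(ail$geno_obs) <-
    sprintf("ind%03d", seq_len(nrow(ail$geno_true)))
  cross <- make_cross(ail$geno_obs, ail$map, tr$pheno, tr$covar)
  cross <- derive_growth_traits(cross)
  expr_ids <- sort(sample.int(config$n_final, min(config$n_expr, config$n_final)))
  ex <- simulate_expression(ail$geno_true[expr_ids, , drop = FALSE], ail$map,
                            tr$covar[expr_ids, , drop = FALSE], config)
  structure(list(cross = cross, geno_true = ail$geno_true,
                 partial_markers = ail$partial_markers,
                 expr = ex$expr, probe_expr = ex$probe_expr,
                 probe_annot = ex$probe_annot, annotation = ex$annotation,
                 expr_covar = ex$covar, expr_ids = expr_ids,
                 truth = list(qtl = tr$truth, eqtl = ex$truth$eqtl,
                              mediation = ex$truth$mediation),
                 config = config),
            class = "sim_study")
}
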