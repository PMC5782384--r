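# Haley-Knott regression genome scans: single-locus scans with covariates
# and genotype-by-sex interactions, permutation thresholds, LOD-drop support
# intervals, two-dimensional epistasis scans, multiple-QTL models and
# analytic power. LOD = (n/2) log10(RSS0 / RSS1) against the covariates-only
# null, with the genotype entering through its expected additive and
# dominance scores.

# Design matrix from a covariate data frame: intercept, sex coded -1/+1
# (female/male), factors expanded to dummies, numeric columns as-is.
# Returns list(Z, sexn).
build_design <- function(covar, use = names(covar), pcs = NULL) {
  n <- nrow(covar)
  Z <- matrix(1, n, 1)
  colnames(Z) <- "(Intercept)"
  sexn <- NULL
  for (nm in use) {
    v <- covar[[nm]]
    if (is.null(v)) next
    if (nm == "sex") {
      sexn <- ifelse(as.character(v) == "male", 1, -1)
      Z <- cbind(Z, sex = sexn)
    } else if (is.factor(v) || is.character(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        D <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(D) <- paste0(nm, levels(f)[-1])
        Z <- cbind(Z, D)
      }
    } else {
      Z <- cbind(Z, as.numeric(v))
      colnames(Z)[ncol(Z)] <- nm
    }
  }
  if (!is.null(pcs)) Z <- cbind(Z, as.matrix(pcs))
  list(Z = Z, sexn = sexn)
}

# Core engine: LOD for many traits at many positions in one pass.
# Y (n x P) traits, Z (n x q) covariates incl. intercept, xa/xd
# (n x npos) genotype scores; sexn enables the 4-column interactive model.
hk_scan_matrix <- function(Y, Z, xa, xd, sexn = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  qrZ <- qr(Z)
  Q <- qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE]
  Yr <- Y - Q %*% crossprod(Q, Y)
  rss0 <- colSums(Yr^2)
  npos <- ncol(xa)
  lod <- matrix(0, npos, ncol(Y))
  for (j in seq_len(npos)) {
    X <- cbind(xa[, j], xd[, j])
    if (!is.null(sexn)) X <- cbind(X, sexn * xa[, j], sexn * xd[, j])
    Xr <- X - Q %*% crossprod(Q, X)
    qrX <- qr(Xr)
    if (qrX$rank == 0) next
    Q2 <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    expl <- colSums(crossprod(Q2, Yr)^2)
    rss1 <- pmax(rss0 - expl, rss0 * 1e-12)
    lod[j, ] <- n / 2 * log10(rss0 / rss1)
  }
  lod
}

# Complete-case index over a trait vector and covariate columns.
scan_cases <- function(y, covar, use) {
  ok <- !is.na(y)
  for (nm in intersect(use, names(covar))) ok <- ok & !is.na(covar[[nm]])
  which(ok)
}

#' Single-locus Haley-Knott genome scan
#'
#' At each grid position the trait is regressed on the covariates plus the
#' additive and dominance genotype scores (plus their products with sex when
#' `sex_interaction = TRUE`); the LOD compares this fit to the
#' covariates-only null. Individuals missing the trait or a covariate are
#' dropped listwise.
#'
#' @param cross An `ail_cross`.
#' @param gp Genotype probabilities from [calc_genoprob()].
#' @param trait Trait name in `cross$pheno`, or a numeric vector.
#' @param covar Character vector of covariate columns to include
#'   (additively) from `cross$covar`.
#' @param pcs Optional matrix of additional covariates (e.g. from
#'   [family_pcs()]), one row per individual of the full cross.
#' @param sex_interaction Include genotype-by-sex interaction terms?
#' @param min_n Minimum number of complete cases.
#' @return Data frame of class `ail_scan` with columns `chr`, `pos_cm`,
#'   `pos_mb`, `marker`, `lod`; attributes `trait`, `n`, `sex_interaction`
#'   and `peaks` (per-chromosome maxima with effect estimates and standard
#'   errors fitted at the peak).
#' @export
scan_one <- function(cross, gp, trait, covar = c("sex", "batch"), pcs = NULL,
                     sex_interaction = FALSE, min_n = 30) {
  y <- if (is.character(trait)) cross$pheno[[trait]] else trait
  trait_name <- if (is.character(trait)) trait else "trait"
  if (is.null(y)) stop("unknown trait: ", trait_name)
  cases <- scan_cases(y, cross$covar, covar)
  if (length(cases) < min_n)
    stop("only ", length(cases), " complete cases for ", trait_name)
  des <- build_design(cross$covar[cases, , drop = FALSE], covar,
                      pcs = if (is.null(pcs)) NULL else pcs[cases, , drop = FALSE])
  if (sex_interaction && is.null(des$sexn))
    stop("sex_interaction requires a sex covariate")
  sc <- genotype_scores(gp)
  xa <- sc$xa[cases, , drop = FALSE]
  xd <- sc$xd[cases, , drop = FALSE]
  lod <- hk_scan_matrix(matrix(y[cases]), des$Z, xa, xd,
                        sexn = if (sex_interaction) des$sexn else NULL)[, 1]
  out <- cbind(sc$grid, lod = lod)
  peaks <- NULL
  for (ch in unique(out$chr)) {
    idx <- which(out$chr == ch)
    k <- idx[which.max(out$lod[idx])]
    eff <- fit_effects_at(y[cases], des, xa[, k], xd[, k], sex_interaction)
    peaks <- rbind(peaks, data.frame(
      chr = ch, pos_cm = out$pos_cm[k], pos_mb = out$pos_mb[k],
      lod = out$lod[k], eff, stringsAsFactors = FALSE))
  }
  structure(out, class = c("ail_scan", "data.frame"), trait = trait_name,
            n = length(cases), sex_interaction = sex_interaction,
            peaks = peaks)
}

# Effect estimates (a, d, a_by_sex, d_by_sex) with standard errors at one
# position, by least squares given the covariate design.
fit_effects_at <- function(y, des, xa, xd, sex_interaction) {
  X <- cbind(des$Z, a = xa, d = xd)
  if (sex_interaction && !is.null(des$sexn))
    X <- cbind(X, a_by_sex = des$sexn * xa, d_by_sex = des$sexn * xd)
  fit <- stats::lm.fit(X, y)
  ok <- !is.na(fit$coefficients)
  rss <- sum(fit$residuals^2)
  df <- length(y) - sum(ok)
  sigma2 <- rss / max(df, 1)
  XtXi <- tryCatch(chol2inv(chol(crossprod(X[, ok, drop = FALSE]))),
                   error = function(e) NULL)
  se <- rep(NA_real_, ncol(X))
  if (!is.null(XtXi)) se[ok] <- sqrt(diag(XtXi) * sigma2)
  names(se) <- colnames(X)
  co <- fit$coefficients
  out <- data.frame(a = unname(co["a"]), se_a = unname(se["a"]),
                    d = unname(co["d"]), se_d = unname(se["d"]))
  if (sex_interaction && !is.null(des$sexn)) {
    out$a_by_sex <- unname(co["a_by_sex"]); out$se_a_by_sex <- unname(se["a_by_sex"])
    out$d_by_sex <- unname(co["d_by_sex"]); out$se_d_by_sex <- unname(se["d_by_sex"])
  }
  out
}

#' Genome-wide permutation significance thresholds
#'
#' Trait values are permuted within the scanned individual set (covariates
#' stay attached to the genotypes), the genome-wide maximum LOD is recorded
#' for each permutation, and thresholds are the empirical `1 - alpha`
#' quantiles of those maxima. The conventional choices are 5% genome-wide
#' (significant) and 20% (suggestive).
#'
#' @inheritParams scan_one
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param alphas Genome-wide error rates for which thresholds are returned.
#' @param seed Integer seed for the permutation RNG (recorded in output).
#' @return List of class `ail_thresholds`: `thresholds` (named by alpha),
#'   `max_lods`, `n_perm`, `alphas`, `seed`.
#' @export
permutation_thresholds <- function(cross, gp, trait, covar = c("sex", "batch"),
                                   pcs = NULL, sex_interaction = FALSE,
                                   n_perm = 1000, alphas = c(0.05, 0.20),
                                   seed = NULL) {
  if (n_perm * min(alphas) < 1)
    stop("n_perm too small for requested quantile")
  if (!is.null(seed)) set.seed(seed)
  y <- if (is.character(trait)) cross$pheno[[trait]] else trait
  cases <- scan_cases(y, cross$covar, covar)
  des <- build_design(cross$covar[cases, , drop = FALSE], covar,
                      pcs = if (is.null(pcs)) NULL else pcs[cases, , drop = FALSE])
  sc <- genotype_scores(gp)
  xa <- sc$xa[cases, , drop = FALSE]
  xd <- sc$xd[cases, , drop = FALSE]
  yy <- y[cases]
  Y <- vapply(seq_len(n_perm), function(i) sample(yy), numeric(length(yy)))
  lod <- hk_scan_matrix(Y, des$Z, xa, xd,
                        sexn = if (sex_interaction) des$sexn else NULL)
  mx <- apply(lod, 2, max)
  thr <- stats::quantile(mx, 1 - alphas, names = FALSE)
  structure(list(thresholds = stats::setNames(thr, paste0(alphas * 100, "%")),
                 max_lods = mx, n_perm = n_perm, alphas = alphas, seed = seed),
            class = "ail_thresholds")
}

#' @export
print.ail_thresholds <- function(x, ...) {
  cat("Permutation thresholds (", x$n_perm, " permutations):\n", sep = "")
  print(round(x$thresholds, 2))
  invisible(x)
}

#' Family-structure principal-component covariates
#'
#' PCA of the numerically coded genotype matrix (additive scores,
#' mean-imputed) captures family structure in the intercross; each of the
#' first `k` PCs is regressed on the trait and the significant ones
#' (p < `p_threshold`) are returned for use as covariates.
#'
#' @param cross An `ail_cross`.
#' @param trait Trait name or numeric vector.
#' @param k Number of leading PCs to screen (default 10).
#' @param p_threshold Per-PC significance level for retention.
#' @return Matrix (individuals x retained PCs), possibly with 0 columns;
#'   attribute `pvalues` holds all `k` screening p-values.
#' @export
family_pcs <- function(cross, trait, k = 10, p_threshold = 0.05) {
  n <- nrow(cross$geno)
  if (n < k + 1) stop("need at least k + 1 individuals")
  num <- matrix(c(-1, 0, 1, -0.5, 0.5)[cross$geno], n, ncol(cross$geno))
  mu <- colMeans(num, na.rm = TRUE)
  for (j in seq_len(ncol(num))) num[is.na(num[, j]), j] <- mu[j]
  keep <- apply(num, 2, stats::sd) > 0
  if (!any(keep)) stop("degenerate genotype matrix (no variable markers)")
  pc <- stats::prcomp(num[, keep, drop = FALSE], center = TRUE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  y <- if (is.character(trait)) cross$pheno[[trait]] else trait
  pv <- vapply(seq_len(k), function(j) {
    ok <- !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor.test(y[ok], scores[ok, j])$p.value
  }, 0)
  sel <- which(!is.na(pv) & pv < p_threshold)
  out <- scores[, sel, drop = FALSE]
  if (length(sel)) colnames(out) <- paste0("PC", sel)
  attr(out, "pvalues") <- pv
  out
}

#' LOD-drop support interval around a peak
#'
#' The widest contiguous region around the peak where the LOD stays within
#' `drop` units of the peak, expanded outward by one grid position past the
#' drop on each side. If the whole chromosome stays within the drop the
#' interval is the chromosome, flagged.
#'
#' @param scan An `ail_scan` from [scan_one()].
#' @param chr Chromosome of the peak.
#' @param drop LOD units (1.8 is the convention for an F8 AIL).
#' @return One-row data frame: `chr`, `peak_cm`, `peak_mb`, `peak_lod`,
#'   `lo_cm`, `hi_cm`, `lo_mb`, `hi_mb`, `whole_chr` flag.
#' @export
lod_interval <- function(scan, chr, drop = 1.8) {
  idx <- which(scan$chr == as.character(chr))
  if (!length(idx)) stop("unknown chromosome: ", chr)
  lod <- scan$lod[idx]
  pk <- which.max(lod)
  above <- lod >= lod[pk] - drop
  lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < length(idx) && above[hi + 1]) hi <- hi + 1
  whole <- lo == 1 && hi == length(idx)
  lo <- max(lo - 1, 1); hi <- min(hi + 1, length(idx))  # one step past the drop
  data.frame(chr = as.character(chr),
             peak_cm = scan$pos_cm[idx[pk]], peak_mb = scan$pos_mb[idx[pk]],
             peak_lod = lod[pk],
             lo_cm = scan$pos_cm[idx[lo]], hi_cm = scan$pos_cm[idx[hi]],
             lo_mb = scan$pos_mb[idx[lo]], hi_mb = scan$pos_mb[idx[hi]],
             whole_chr = whole, stringsAsFactors = FALSE)
}

#' Merge overlapping QTL support intervals into genomic regions
#'
#' Intervals (half-open, Mb) from different traits that overlap on the same
#' chromosome collapse into a single region, the convention used when
#' counting distinct genomic regions associated with a trait family.
#'
#' @param intervals Data frame with columns `chr`, `lo_mb`, `hi_mb`.
#' @return Data frame of merged regions (`chr`, `lo_mb`, `hi_mb`,
#'   `n_intervals`).
#' @export
merge_qtl_regions <- function(intervals) {
  out <- NULL
  for (ch in unique(intervals$chr)) {
    sub <- intervals[intervals$chr == ch, , drop = FALSE]
    sub <- sub[order(sub$lo_mb), , drop = FALSE]
    lo <- sub$lo_mb[1]; hi <- sub$hi_mb[1]; cnt <- 1L
    flush <- function(lo, hi, cnt)
      data.frame(chr = ch, lo_mb = lo, hi_mb = hi, n_intervals = cnt,
                 stringsAsFactors = FALSE)
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      if (sub$lo_mb[i] < hi) {          # half-open overlap
        hi <- max(hi, sub$hi_mb[i]); cnt <- cnt + 1L
      } else {
        out <- rbind(out, flush(lo, hi, cnt))
        lo <- sub$lo_mb[i]; hi <- sub$hi_mb[i]; cnt <- 1L
      }
    }
    out <- rbind(out, flush(lo, hi, cnt))
  }
  out
}

#' Two-dimensional scan for epistatic locus pairs
#'
#' For every pair of grid positions (coarsened to `step` cM) five statistics
#' are computed against the covariates-only null: the full two-locus model
#' with interactions (`lod_full`), the additive two-locus model
#' (`lod_add`), `lod_fv1 = lod_full - best single-locus LOD` of the pair,
#' `lod_int = lod_full - lod_add`, and `lod_av1 = lod_add - best single`.
#'
#' @inheritParams scan_one
#' @param step Minimum spacing of the coarse 2D grid in cM.
#' @return List of class `ail_scan2`: `pairs` data frame with positions and
#'   the five statistics, `grid` (the coarse grid with 1D LODs), `trait`.
#' @export
scan_two <- function(cross, gp, trait, covar = c("sex", "batch"), pcs = NULL,
                     step = 5, min_n = 30) {
  y <- if (is.character(trait)) cross$pheno[[trait]] else trait
  cases <- scan_cases(y, cross$covar, covar)
  if (length(cases) < min_n) stop("too few complete cases")
  des <- build_design(cross$covar[cases, , drop = FALSE], covar,
                      pcs = if (is.null(pcs)) NULL else pcs[cases, , drop = FALSE])
  sc <- genotype_scores(gp)
  keep <- coarse_grid(sc$grid, step)
  if (min(table(sc$grid$chr[keep])) < 2)
    stop("2D grid too coarse: fewer than 2 positions on a chromosome")
  grid <- sc$grid[keep, , drop = FALSE]
  xa <- sc$xa[cases, keep, drop = FALSE]
  xd <- sc$xd[cases, keep, drop = FALSE]
  yy <- y[cases]
  lod1 <- hk_scan_matrix(matrix(yy), des$Z, xa, xd)[, 1]
  qrZ <- qr(des$Z)
  Q <- qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE]
  yr <- yy - Q %*% crossprod(Q, yy)
  rss0 <- sum(yr^2)
  n <- length(yy)
  K <- length(keep)
  pairs <- vector("list", K * (K - 1) / 2)
  pi <- 0L
  expl <- function(X) {
    Xr <- X - Q %*% crossprod(Q, X)
    qrX <- qr(Xr)
    if (qrX$rank == 0) return(0)
    Q2 <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    sum(crossprod(Q2, yr)^2)
  }
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    Xadd <- cbind(xa[, i], xd[, i], xa[, j], xd[, j])
    Xfull <- cbind(Xadd, xa[, i] * xa[, j], xa[, i] * xd[, j],
                   xd[, i] * xa[, j], xd[, i] * xd[, j])
    rss_add <- rss0 - expl(Xadd)
    rss_full <- rss0 - expl(Xfull)
    lod_add <- n / 2 * log10(rss0 / max(rss_add, rss0 * 1e-12))
    lod_full <- n / 2 * log10(rss0 / max(rss_full, rss0 * 1e-12))
    best1 <- max(lod1[i], lod1[j])
    pi <- pi + 1L
    pairs[[pi]] <- c(i = i, j = j, lod_full = lod_full,
                     lod_fv1 = lod_full - best1,
                     lod_int = lod_full - lod_add,
                     lod_add = lod_add, lod_av1 = lod_add - best1)
  }
  pairs <- as.data.frame(do.call(rbind, pairs[seq_len(pi)]))
  pairs <- cbind(data.frame(chr1 = grid$chr[pairs$i], pos1_cm = grid$pos_cm[pairs$i],
                            chr2 = grid$chr[pairs$j], pos2_cm = grid$pos_cm[pairs$j],
                            stringsAsFactors = FALSE),
                 pairs[, c("lod_full", "lod_fv1", "lod_int", "lod_add", "lod_av1")])
  structure(list(pairs = pairs, grid = cbind(grid, lod1 = lod1),
                 trait = if (is.character(trait)) trait else "trait",
                 n = n),
            class = "ail_scan2")
}

coarse_grid <- function(grid, step) {
  keep <- logical(nrow(grid))
  for (ch in unique(grid$chr)) {
    idx <- which(grid$chr == ch)
    last <- -Inf
    for (i in idx) {
      if (grid$pos_cm[i] >= last + step || i == idx[length(idx)]) {
        keep[i] <- TRUE
        last <- grid$pos_cm[i]
      }
    }
  }
  which(keep)
}

#' Declare epistatic pairs from a 2D scan
#'
#' Applies the joint two-locus rule: a pair is declared if its full-model
#' LOD clears the full threshold and either the full-vs-one or the
#' interaction statistic clears its threshold, or if the additive model
#' clears both the additive and additive-vs-one thresholds. Defaults are the
#' approximate genome-wide 5% values for an intercross of this marker
#' density (full ~11, full-vs-one ~9, interactive ~7, additive ~7,
#' additive-vs-one ~4).
#'
#' @param scan2 An `ail_scan2` from [scan_two()].
#' @param thresholds Named numeric: `full`, `fv1`, `int`, `add`, `av1`.
#' @return The declared rows of `scan2$pairs`, best pair per chromosome
#'   pair, with a `via` column saying which clause declared it.
#' @export
declare_epistatic_pairs <- function(scan2,
                                    thresholds = c(full = 11, fv1 = 9, int = 7,
                                                   add = 7, av1 = 4)) {
  p <- scan2$pairs
  clause_full <- p$lod_full >= thresholds["full"] &
    (p$lod_fv1 >= thresholds["fv1"] | p$lod_int >= thresholds["int"])
  clause_add <- p$lod_add >= thresholds["add"] & p$lod_av1 >= thresholds["av1"]
  hit <- clause_full | clause_add
  if (!any(hit)) return(p[0, ])
  p <- p[hit, , drop = FALSE]
  p$via <- ifelse(clause_full[hit], "full", "additive")
  key <- paste(p$chr1, p$chr2)
  best <- unlist(lapply(split(seq_len(nrow(p)), key), function(ii)
    ii[which.max(p$lod_full[ii])]))
  p[sort(best), , drop = FALSE]
}

#' Multiple-QTL model by forward inclusion
#'
#' Candidate loci are added in order of decreasing single-locus LOD; a locus
#' is kept if its drop-one LOD in the growing model exceeds `threshold`.
#' After inclusion, a genotype-by-sex interaction for the locus is retained
#' when it improves the model LOD by more than `sex_delta_lod`. Candidate
#' epistatic pairs whose loci are in the model contribute interaction terms
#' kept by the same drop-one rule against `int_threshold`. Per-locus percent
#' variance explained is `100 (RSS_without - RSS_with) / TSS`.
#'
#' @inheritParams scan_one
#' @param loci Data frame of candidate loci (`chr`, `pos_cm`).
#' @param pairs Optional data frame of candidate epistatic pairs
#'   (`chr1`, `pos1_cm`, `chr2`, `pos2_cm`).
#' @param threshold Drop-one LOD threshold for keeping a locus (typically
#'   the genome-wide significant threshold).
#' @param int_threshold Drop-one LOD threshold for an interaction term.
#' @param sex_delta_lod LOD improvement required to keep a sex interaction.
#' @return List of class `ail_qtlfit`: `loci` (with drop-one LOD, percent
#'   variance, effects a/d and their sex interactions with SEs), `pairs`,
#'   `model_varexp`, `n`.
#' @export
fit_multiqtl <- function(cross, gp, trait, loci, pairs = NULL,
                         covar = c("sex", "batch"), pcs = NULL,
                         threshold = 4.3, int_threshold = 7,
                         sex_delta_lod = 1, min_n = 30) {
  if (is.null(loci) || nrow(loci) == 0) stop("empty candidate list")
  y <- if (is.character(trait)) cross$pheno[[trait]] else trait
  cases <- scan_cases(y, cross$covar, covar)
  if (length(cases) < min_n) stop("too few complete cases")
  des <- build_design(cross$covar[cases, , drop = FALSE], covar,
                      pcs = if (is.null(pcs)) NULL else pcs[cases, , drop = FALSE])
  sc <- genotype_scores(gp)
  yy <- y[cases]
  n <- length(yy)
  tss <- sum((yy - mean(yy))^2)
  locus_cols <- function(chr, pos) {
    idx <- which(sc$grid$chr == as.character(chr))
    k <- idx[which.min(abs(sc$grid$pos_cm[idx] - pos))]
    cbind(xa = sc$xa[cases, k], xd = sc$xd[cases, k])
  }
  rss_of <- function(blocks) {
    X <- do.call(cbind, c(list(des$Z), blocks))
    sum(qr.resid(qr(X), yy)^2)
  }
  lod_gain <- function(rss_without, rss_with)
    n / 2 * log10(rss_without / max(rss_with, rss_without * 1e-12))
  L <- lapply(seq_len(nrow(loci)), function(i) locus_cols(loci$chr[i], loci$pos_cm[i]))
  # order candidates by marginal LOD
  rss_null <- rss_of(list())
  marg <- vapply(L, function(B) lod_gain(rss_null, rss_of(list(B))), 0)
  ord <- order(marg, decreasing = TRUE)
  blocks <- list()        # main-effect blocks, named by locus index
  sexint <- list()        # sex-interaction blocks
  kept <- integer(0)
  for (i in ord) {
    cur <- c(blocks, sexint)
    gain <- lod_gain(rss_of(cur), rss_of(c(cur, list(L[[i]]))))
    if (gain > threshold) {
      kept <- c(kept, i)
      blocks[[as.character(i)]] <- L[[i]]
      if (!is.null(des$sexn)) {
        Si <- L[[i]] * des$sexn
        colnames(Si) <- c("a_by_sex", "d_by_sex")
        cur <- c(blocks, sexint)
        dl <- lod_gain(rss_of(cur), rss_of(c(cur, list(Si))))
        if (dl > sex_delta_lod) sexint[[paste0("s", i)]] <- Si
      }
    }
  }
  if (!length(kept)) stop("no locus cleared the drop-one threshold")
  kept_pairs <- NULL
  epi <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    find_kept <- function(chr, pos) {
      hit <- which(loci$chr[kept] == as.character(chr) &
                     abs(loci$pos_cm[kept] - pos) < 1e-6)
      if (length(hit)) kept[hit[1]] else NA_integer_
    }
    for (r in seq_len(nrow(pairs))) {
      i1 <- find_kept(pairs$chr1[r], pairs$pos1_cm[r])
      i2 <- find_kept(pairs$chr2[r], pairs$pos2_cm[r])
      B1 <- if (is.na(i1)) locus_cols(pairs$chr1[r], pairs$pos1_cm[r]) else L[[i1]]
      B2 <- if (is.na(i2)) locus_cols(pairs$chr2[r], pairs$pos2_cm[r]) else L[[i2]]
      E <- cbind(B1[, 1] * B2[, 1], B1[, 1] * B2[, 2],
                 B1[, 2] * B2[, 1], B1[, 2] * B2[, 2])
      extra <- list()
      if (is.na(i1)) extra <- c(extra, list(B1))
      if (is.na(i2)) extra <- c(extra, list(B2))
      cur <- c(blocks, sexint, epi, extra)
      gain <- lod_gain(rss_of(cur), rss_of(c(cur, list(E))))
      if (gain > int_threshold) {
        epi[[paste0("e", length(epi) + 1)]] <- E
        if (length(extra)) {
          names(extra) <- paste0("x", length(blocks) + seq_along(extra))
          blocks <- c(blocks, extra)
        }
        kept_pairs <- rbind(kept_pairs, cbind(pairs[r, , drop = FALSE],
                                              drop_lod = gain))
      }
    }
  }
  all_blocks <- c(blocks, sexint, epi)
  rss_full <- rss_of(all_blocks)
  model_varexp <- 100 * (rss_null - rss_full) / tss
  out <- NULL
  for (i in kept) {
    nm <- as.character(i)
    # the locus's sex-interaction block (if any) is dropped together with it
    drop_names <- c(nm, paste0("s", i))
    without <- all_blocks[setdiff(names(all_blocks), drop_names)]
    rss_without <- rss_of(without)
    droplod <- lod_gain(rss_without, rss_full)
    varexp <- 100 * (rss_without - rss_full) / tss
    has_sex <- paste0("s", i) %in% names(sexint)
    eff <- fit_effects_at(yy, list(Z = cbind(des$Z,
             if (length(without)) do.call(cbind, without)), sexn = des$sexn),
             L[[i]][, 1], L[[i]][, 2], sex_interaction = has_sex)
    # fixed column set so loci with and without sex terms bind together
    for (cn in c("a_by_sex", "se_a_by_sex", "d_by_sex", "se_d_by_sex"))
      if (is.null(eff[[cn]])) eff[[cn]] <- NA_real_
    idx <- which(sc$grid$chr == as.character(loci$chr[i]))
    k <- idx[which.min(abs(sc$grid$pos_cm[idx] - loci$pos_cm[i]))]
    out <- rbind(out, data.frame(
      chr = as.character(loci$chr[i]), pos_cm = sc$grid$pos_cm[k],
      pos_mb = sc$grid$pos_mb[k], drop_lod = droplod, varexp = varexp,
      sex_int = has_sex, eff, stringsAsFactors = FALSE))
  }
  structure(list(loci = out, pairs = kept_pairs, model_varexp = model_varexp,
                 n = n, trait = if (is.character(trait)) trait else "trait"),
            class = "ail_qtlfit")
}

#' @export
print.ail_qtlfit <- function(x, ...) {
  cat("Multiple-QTL model for", x$trait, "(n =", x$n, "):\n")
  print(x$loci, digits = 3)
  cat("full model variance explained:", round(x$model_varexp, 1), "%\n")
  invisible(x)
}

#' Analytic power to detect a QTL
#'
#' Power of a LOD-threshold test for a locus explaining a given fraction of
#' phenotypic variance: the likelihood-ratio statistic `2 ln(10) LOD` is
#' noncentral chi-square with `df` degrees of freedom and noncentrality
#' `n f / (1 - f)`, so power is its upper tail at `2 ln(10) threshold_lod`.
#' `df = 2` for the additive-plus-dominance intercross model.
#'
#' @param n Sample size.
#' @param effect_fraction Fraction of variance explained by the locus, in
#'   (0, 1).
#' @param threshold_lod LOD significance threshold.
#' @param df Degrees of freedom of the locus term.
#' @return Power (probability of detection).
#' @export
power_detect <- function(n, effect_fraction, threshold_lod, df = 2) {
  if (any(effect_fraction <= 0) || any(effect_fraction >= 1))
    stop("effect_fraction must be in (0, 1)")
  ncp <- n * effect_fraction / (1 - effect_fraction)
  stats::pchisq(2 * log(10) * threshold_lod, df = df, ncp = ncp,
                lower.tail = FALSE)
}

#' Extract individuals from a cross
#'
#' @param cross An `ail_cross`.
#' @param idx Integer or logical index of individuals to keep.
#' @return The subsetted `ail_cross`.
#' @export
subset_cross <- function(cross, idx) {
  make_cross(cross$geno[idx, , drop = FALSE], cross$map,
             cross$pheno[idx, , drop = FALSE],
             cross$covar[idx, , drop = FALSE])
}
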