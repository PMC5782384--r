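# Expression preprocessing and eQTL mapping. Probe-level two-colour array
# data are quantile-normalized, summarized to probesets by median polish and
# batch-adjusted (ComBat); probesets are then scanned with Haley-Knott
# regression, locally in a 100 cM window around the gene and genome-wide for
# distal (trans) signals, with subsampled-probeset permutation thresholds
# and a genotype-class filter on trans candidates.

#' Quantile normalization of an expression matrix
#'
#' Forces every column (sample) to share one empirical distribution, the
#' row-wise mean of the sorted columns; ties share the mean of the
#' implicated quantiles.
#'
#' @param m Numeric matrix (probes/probesets x samples), >= 2 columns.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns")
  if (any(colSums(!is.na(m)) == 0)) stop("all-missing column")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Summarize probe-level data to probesets by median polish
#'
#' For each probeset the probes x samples submatrix is decomposed as
#' overall + probe effect + sample effect + residual by iterative median
#' sweeping; the probeset value for a sample is overall + sample effect.
#' Single-probe probesets pass through unchanged.
#'
#' @param probe_matrix Numeric matrix (probes x samples).
#' @param probesets Character vector assigning each probe row to a probeset.
#' @param eps,maxiter Convergence tolerance and iteration cap of the polish.
#' @return Matrix (probesets x samples), rows in first-appearance order.
#' @export
median_polish_summarize <- function(probe_matrix, probesets,
                                    eps = 1e-6, maxiter = 10) {
  probe_matrix <- as.matrix(probe_matrix)
  if (nrow(probe_matrix) != length(probesets))
    stop("probesets must label every probe row")
  sets <- unique(probesets)
  out <- matrix(NA_real_, length(sets), ncol(probe_matrix),
                dimnames = list(sets, colnames(probe_matrix)))
  for (s in sets) {
    rows <- which(probesets == s)
    if (!length(rows)) stop("empty probeset: ", s)
    sub <- probe_matrix[rows, , drop = FALSE]
    if (nrow(sub) == 1) {
      out[s, ] <- sub[1, ]
    } else {
      # the iteration cap is deliberate; non-convergence there is expected
      mp <- suppressWarnings(
        stats::medpolish(sub, eps = eps, maxiter = maxiter, trace.iter = FALSE))
      out[s, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Location/scale batch adjustment per gene with parametric empirical-Bayes
#' shrinkage of the batch means and variances toward an across-gene prior,
#' preserving overall gene means.
#'
#' @param m Numeric matrix (genes x samples).
#' @param batch Batch label per sample; >= 2 batches of >= 2 samples.
#' @return The adjusted matrix.
#' @export
adjust_batch <- function(m, batch) {
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  if (any(table(batch) < 2)) stop("single-sample batch")
  m <- as.matrix(m)
  keep <- apply(m, 1, stats::sd) > 0
  out <- m
  invisible(utils::capture.output(
    out[keep, ] <- suppressMessages(
      sva::ComBat(dat = m[keep, , drop = FALSE], batch = batch,
                  par.prior = TRUE, prior.plots = FALSE))))
  out
}

# LOD matrices (positions x probesets) for an expression matrix under the
# additive covariate model and, optionally, the genotype-by-sex model.
eqtl_lod_matrix <- function(expr, covar, sc, use = c("sex", "batch_expr", "dye"),
                            sex_interaction = FALSE) {
  des <- build_design(covar, use)
  hk_scan_matrix(t(expr), des$Z, sc$xa, sc$xd,
                 sexn = if (sex_interaction) des$sexn else NULL)
}

# Window mask: grid positions within window/2 cM of (chr, pos_cm).
local_window <- function(grid, chr, pos_cm, window = 100) {
  grid$chr == as.character(chr) & abs(grid$pos_cm - pos_cm) <= window / 2
}

# Most-probable genotype class counts at the grid position nearest a peak.
class_counts_at <- function(gp, chr, pos_cm) {
  idx <- which(gp$grid$chr == as.character(chr))
  k <- which.min(abs(gp$grid$pos_cm[idx] - pos_cm))
  p <- gp$prob[[as.character(chr)]][, k, , drop = FALSE]
  cls <- max.col(matrix(p, dim(p)[1], 3))
  tabulate(cls, 3)
}

# Effects a, d per sex at a peak (from the sex-interaction model).
sex_effects_at <- function(y, covar, xa, xd, use) {
  des <- build_design(covar, use)
  eff <- fit_effects_at(y, des, xa, xd, sex_interaction = !is.null(des$sexn))
  if (is.null(des$sexn) || is.null(eff$a_by_sex))
    return(data.frame(a_f = eff$a, d_f = eff$d, a_m = eff$a, d_m = eff$d))
  data.frame(a_f = eff$a - eff$a_by_sex, d_f = eff$d - eff$d_by_sex,
             a_m = eff$a + eff$a_by_sex, d_m = eff$d + eff$d_by_sex)
}

#' Map local eQTL within a window around each gene
#'
#' Each annotated probeset is scanned only in the `window` cM region
#' centred on its own map position (clipped at chromosome ends). A record
#' is returned when the peak LOD clears `threshold`; the genotype-by-sex
#' interaction is retained when it raises the peak LOD by more than
#' `delta_lod`.
#'
#' @param expr Expression matrix (probesets x individuals), preprocessed.
#' @param annotation Data frame (`probeset`, `gene`, `chr`, `pos_cm`,
#'   `pos_mb`); probesets absent from it are skipped (they can only be
#'   scanned distally).
#' @param cross `ail_cross` restricted to the expression individuals.
#' @param gp Genotype probabilities for `cross`.
#' @param covar Covariate columns used in the model (additively).
#' @param threshold Local significance threshold (LOD).
#' @param window Window size in cM (total; half on each side).
#' @param delta_lod Sex-interaction retention rule.
#' @param drop LOD drop for the support interval.
#' @return Data frame of eQTL records (`probeset`, `gene`, `class`, `chr`,
#'   `peak_cm`, `peak_mb`, `lod`, `lo_mb`, `hi_mb`, per-sex effects,
#'   `sex_int`, `min_class_n`).
#' @export
scan_local <- function(expr, annotation, cross, gp,
                       covar = c("sex", "batch_expr", "dye"),
                       threshold = 4.0, window = 100, delta_lod = 1,
                       drop = 1.8) {
  sc <- genotype_scores(gp)
  ann <- annotation[annotation$probeset %in% rownames(expr) &
                      !is.na(annotation$chr), , drop = FALSE]
  E <- expr[ann$probeset, , drop = FALSE]
  lod_add <- eqtl_lod_matrix(E, cross$covar, sc, covar, sex_interaction = FALSE)
  lod_int <- eqtl_lod_matrix(E, cross$covar, sc, covar, sex_interaction = TRUE)
  out <- NULL
  for (i in seq_len(nrow(ann))) {
    win <- which(local_window(sc$grid, ann$chr[i], ann$pos_cm[i], window))
    if (!length(win)) stop("window contains no grid positions for ",
                           ann$probeset[i])
    k <- win[which.max(lod_add[win, i])]
    use_int <- (lod_int[k, i] - lod_add[k, i]) > delta_lod
    curve <- if (use_int) lod_int[, i] else lod_add[, i]
    k <- win[which.max(curve[win])]
    peak_lod <- curve[k]
    if (peak_lod < threshold) next
    rec <- eqtl_record(ann[i, ], "local", sc, curve, k, win, drop,
                       E[i, ], cross, gp, covar, use_int)
    out <- rbind(out, rec)
  }
  out
}

# Assemble one eQTL record row.
eqtl_record <- function(ann_row, class, sc, curve, k, search, drop,
                        y, cross, gp, covar, use_int) {
  grid <- sc$grid
  ch <- grid$chr[k]
  # support interval on this chromosome restricted to the searched region
  idx <- intersect(which(grid$chr == ch), search)
  lodv <- curve[idx]
  pk <- which(idx == k)
  above <- lodv >= curve[k] - drop
  lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < length(idx) && above[hi + 1]) hi <- hi + 1
  lo <- max(lo - 1, 1); hi <- min(hi + 1, length(idx))
  cls <- class_counts_at(gp, ch, grid$pos_cm[k])
  eff <- sex_effects_at(y, cross$covar,
                        sc$xa[, k], sc$xd[, k],
                        covar)
  cbind(data.frame(probeset = ann_row$probeset,
                   gene = if (!is.null(ann_row$gene)) ann_row$gene else NA,
                   class = class, chr = ch,
                   peak_cm = grid$pos_cm[k], peak_mb = grid$pos_mb[k],
                   lod = curve[k],
                   lo_mb = grid$pos_mb[idx[lo]], hi_mb = grid$pos_mb[idx[hi]],
                   lo_cm = grid$pos_cm[idx[lo]], hi_cm = grid$pos_cm[idx[hi]],
                   stringsAsFactors = FALSE),
        eff,
        data.frame(sex_int = use_int, min_class_n = min(cls)))
}

#' Map distal (trans) eQTL genome-wide
#'
#' Genome-wide scan excluding each annotated probeset's local window (so a
#' probeset cannot contribute a "distal" peak at its own locus); per
#' chromosome, the maximum above `threshold` yields a candidate record.
#' Candidates are dropped when any genotype class at the peak has
#' `class_filter` or fewer individuals, a guard against spurious trans
#' signals driven by extreme individuals in rare classes. Unannotated
#' probesets are scanned over the whole genome and all hits labelled distal.
#'
#' @inheritParams scan_local
#' @param threshold Trans significance threshold (LOD).
#' @param class_filter Minimum genotype-class count; candidates with any
#'   class `<= class_filter` are dropped.
#' @return Data frame of distal eQTL records (see [scan_local()]).
#' @export
scan_distal <- function(expr, annotation, cross, gp,
                        covar = c("sex", "batch_expr", "dye"),
                        threshold = 8.0, window = 100, class_filter = 10,
                        delta_lod = 1, drop = 1.8) {
  sc <- genotype_scores(gp)
  ps <- rownames(expr)
  ann <- annotation[match(ps, annotation$probeset), , drop = FALSE]
  lod_add <- eqtl_lod_matrix(expr, cross$covar, sc, covar, sex_interaction = FALSE)
  lod_int <- eqtl_lod_matrix(expr, cross$covar, sc, covar, sex_interaction = TRUE)
  out <- NULL
  for (i in seq_along(ps)) {
    excl <- if (!is.na(ann$chr[i]))
      local_window(sc$grid, ann$chr[i], ann$pos_cm[i], window)
    else rep(FALSE, nrow(sc$grid))
    for (ch in unique(sc$grid$chr)) {
      search <- which(sc$grid$chr == ch & !excl)
      if (!length(search)) next
      k <- search[which.max(lod_add[search, i])]
      use_int <- (lod_int[k, i] - lod_add[k, i]) > delta_lod
      curve <- if (use_int) lod_int[, i] else lod_add[, i]
      k <- search[which.max(curve[search])]
      if (curve[k] < threshold) next
      rec <- eqtl_record(
        data.frame(probeset = ps[i],
                   gene = if (!is.null(ann$gene)) ann$gene[i] else NA),
        "distal", sc, curve, k, search, drop, expr[i, ], cross, gp, covar,
        use_int)
      if (rec$min_class_n > class_filter) out <- rbind(out, rec)
    }
  }
  out
}

#' Permutation thresholds from subsampled probesets
#'
#' Rather than permuting single phenotypes, each permutation replicate
#' sub-samples `n_probesets` probesets, permutes the individual labels once,
#' and records (a) the maximum LOD over the probesets' local windows (the
#' local null) and (b) the maximum genome-wide LOD over the probesets (the
#' trans null). Thresholds are the 95% quantiles of the two null maxima,
#' which accounts for the full array of probeset phenotypes without one
#' permutation scan per probeset.
#'
#' @inheritParams scan_local
#' @param n_probesets Probesets sub-sampled per replicate (100 by
#'   convention).
#' @param n_reps Number of permutation replicates.
#' @param quantile_level Quantile of the null maxima (default 0.95, i.e. a
#'   5% genome-wide error rate).
#' @param seed RNG seed.
#' @return List of class `eqtl_thresholds`: `local`, `trans`, plus the two
#'   null vectors and the settings.
#' @export
subsampled_thresholds <- function(expr, annotation, cross, gp,
                                  covar = c("sex", "batch_expr", "dye"),
                                  n_probesets = 100, n_reps = 200,
                                  window = 100, quantile_level = 0.95,
                                  seed = NULL) {
  if (nrow(expr) < n_probesets)
    stop("fewer than ", n_probesets, " probesets")
  if (!is.null(seed)) set.seed(seed)
  sc <- genotype_scores(gp)
  ann_idx <- match(rownames(expr), annotation$probeset)
  n <- ncol(expr)
  null_local <- null_trans <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sel <- sample.int(nrow(expr), n_probesets)
    perm <- sample.int(n)
    E <- expr[sel, perm, drop = FALSE]
    lod <- eqtl_lod_matrix(E, cross$covar, sc, covar)
    null_trans[r] <- max(lod)
    loc <- -Inf
    for (ii in seq_along(sel)) {
      ai <- ann_idx[sel[ii]]
      if (is.na(ai) || is.na(annotation$chr[ai])) next
      win <- local_window(sc$grid, annotation$chr[ai],
                          annotation$pos_cm[ai], window)
      if (any(win)) loc <- max(loc, max(lod[win, ii]))
    }
    null_local[r] <- loc
  }
  structure(list(local = stats::quantile(null_local[is.finite(null_local)],
                                         quantile_level, names = FALSE),
                 trans = stats::quantile(null_trans, quantile_level,
                                         names = FALSE),
                 null_local = null_local, null_trans = null_trans,
                 n_probesets = n_probesets, n_reps = n_reps, seed = seed),
            class = "eqtl_thresholds")
}

#' @export
print.eqtl_thresholds <- function(x, ...) {
  cat("Subsampled-probeset permutation thresholds (", x$n_reps,
      " replicates of ", x$n_probesets, " probesets):\n", sep = "")
  cat("  local:", round(x$local, 2), "  trans:", round(x$trans, 2), "\n")
  invisible(x)
}

#' Direction-of-effect summary for eQTL records
#'
#' Counts and proportions of positive and negative additive and dominance
#' effects per sex and eQTL class. The sign of the additive effect is
#' relative to the domestic-founder allele; a negative dominance effect
#' means the heterozygote lies below the mid-homozygote expectation.
#'
#' @param records eQTL record data frame from [scan_local()] /
#'   [scan_distal()].
#' @return Data frame with `class`, `sex`, `effect`, `n_pos`, `n_neg`,
#'   `prop_pos`.
#' @export
effect_direction_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(data.frame(class = character(), sex = character(),
                      effect = character(), n_pos = integer(),
                      n_neg = integer(), prop_pos = numeric()))
  cols <- list(c("female", "a", "a_f"), c("female", "d", "d_f"),
               c("male", "a", "a_m"), c("male", "d", "d_m"))
  out <- NULL
  for (cl in unique(records$class)) {
    sub <- records[records$class == cl, , drop = FALSE]
    for (cc in cols) {
      v <- sub[[cc[3]]]
      v <- v[!is.na(v)]
      out <- rbind(out, data.frame(
        class = cl, sex = cc[1], effect = cc[2],
        n_pos = sum(v > 0), n_neg = sum(v < 0),
        prop_pos = if (length(v)) mean(v > 0) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}
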