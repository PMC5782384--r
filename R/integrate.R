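# Integration of trait QTL with expression: candidate quantitative trait
# genes (QTL x local-eQTL overlap plus trait-expression association),
# transcriptome-wide trait association with a max-statistic permutation
# null, and selective-sweep overlap testing.

# Half-open interval overlap on shared Mb coordinates.
overlaps_halfopen <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Candidate quantitative trait genes from QTL x local-eQTL overlap
#'
#' A gene is a candidate for a trait locus when (1) its local eQTL
#' confidence interval overlaps the QTL confidence interval and (2) its
#' expression level is associated with the trait. The association model is
#' `trait ~ expression + dye + batch`, with a sex interaction
#' (`+ sex + sex:expression`) added when the eQTL record carries the
#' sex-interaction flag; the reported p-value is the F-test of the
#' expression terms. Both the plain and sex-interaction p-values are
#' returned.
#'
#' @param qtl_intervals Data frame of trait QTL support intervals: `trait`,
#'   `chr`, `lo_mb`, `hi_mb`.
#' @param eqtl_records Local eQTL records from [scan_local()].
#' @param expr Expression matrix (probesets x expression individuals).
#' @param cross `ail_cross` of the full mapped population.
#' @param expr_ids Indices of the expression individuals within `cross`.
#' @param alpha Association significance level.
#' @return Data frame of candidates: `gene`, `probeset`, `trait`, QTL
#'   interval, eQTL `lod` and interval, `p_value` (model chosen per the
#'   sex flag), `p_plain`, `p_sexint`, `candidate`.
#' @export
candidate_screen <- function(qtl_intervals, eqtl_records, expr, cross,
                             expr_ids, alpha = 0.05) {
  if (!length(intersect(seq_len(n_ind(cross))[expr_ids],
                        which(rowSums(!is.na(as.matrix(cross$pheno))) > 0))))
    stop("expression individuals disjoint from phenotyped individuals")
  loc <- eqtl_records[eqtl_records$class == "local", , drop = FALSE]
  covar <- cross$covar[expr_ids, , drop = FALSE]
  out <- NULL
  for (q in seq_len(nrow(qtl_intervals))) {
    qi <- qtl_intervals[q, ]
    hits <- which(loc$chr == as.character(qi$chr) &
                    overlaps_halfopen(loc$lo_mb, loc$hi_mb, qi$lo_mb, qi$hi_mb))
    for (h in hits) {
      ps <- loc$probeset[h]
      y <- cross$pheno[[qi$trait]][expr_ids]
      x <- expr[ps, ]
      ok <- !is.na(y)
      p2 <- assoc_pvalues(y[ok], x[ok], covar[ok, , drop = FALSE])
      p <- if (isTRUE(loc$sex_int[h])) p2["sexint"] else p2["plain"]
      out <- rbind(out, data.frame(
        gene = loc$gene[h], probeset = ps, trait = qi$trait,
        chr = as.character(qi$chr), qtl_lo_mb = qi$lo_mb, qtl_hi_mb = qi$hi_mb,
        eqtl_lod = loc$lod[h], eqtl_lo_mb = loc$lo_mb[h],
        eqtl_hi_mb = loc$hi_mb[h], sex_int = isTRUE(loc$sex_int[h]),
        p_value = unname(p), p_plain = unname(p2["plain"]),
        p_sexint = unname(p2["sexint"]),
        candidate = unname(p) < alpha, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(out)) out <- out[order(out$trait, out$chr, out$probeset), ]
  rownames(out) <- NULL
  out
}

# F-test p-values for the expression terms, without and with the sex
# interaction, in trait ~ expression + dye + batch (+ sex + sex:expression).
assoc_pvalues <- function(y, x, covar) {
  base <- build_design(covar, c("dye", "batch_expr", "batch"))$Z
  p_of <- function(Z0, Z1) {
    r0 <- sum(qr.resid(qr(Z0), y)^2)
    q0 <- qr(Z0)$rank
    q1 <- qr(Z1)$rank
    r1 <- sum(qr.resid(qr(Z1), y)^2)
    df1 <- q1 - q0
    df2 <- length(y) - q1
    if (df1 <= 0 || df2 <= 0) return(NA_real_)
    f <- (r0 - r1) / df1 / (r1 / df2)
    stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  plain <- p_of(base, cbind(base, x))
  sexn <- build_design(covar, "sex")$sexn
  sexint <- if (!is.null(sexn))
    p_of(cbind(base, sexn), cbind(base, sexn, x, x * sexn))
  else NA_real_
  c(plain = plain, sexint = sexint)
}

#' Transcriptome-wide trait association with a permutation FWER threshold
#'
#' Applies the candidate-gene association model across the whole array:
#' per probeset, the partial correlation of expression with the trait after
#' residualizing both on dye and batch, converted to an F statistic. The
#' family-wise null is the distribution of the maximum statistic across the
#' array under permutation of trait values; probesets whose statistic
#' exceeds the `1 - alpha` null quantile are returned.
#'
#' @param expr Expression matrix (probesets x individuals).
#' @param trait Numeric trait vector for the same individuals.
#' @param covar Covariate data frame (`dye`, `batch_expr`/`batch`).
#' @param n_perm Number of permutations (>= 20).
#' @param alpha Family-wise error rate.
#' @param seed RNG seed.
#' @return Data frame of significant probesets (`probeset`, `stat`,
#'   `p_fwer`), with attributes `threshold` and `n_perm`.
#' @export
transcriptome_wide_association <- function(expr, trait, covar, n_perm = 1000,
                                           alpha = 0.05, seed = NULL) {
  if (n_perm < 20) stop("n_perm too small")
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(trait)
  y <- trait[ok]
  E <- expr[, ok, drop = FALSE]
  Z <- build_design(covar[ok, , drop = FALSE], c("dye", "batch_expr", "batch"))$Z
  qrZ <- qr(Z)
  Q <- qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE]
  n <- length(y)
  q <- qrZ$rank
  Er <- t(E) - Q %*% crossprod(Q, t(E))       # n x P residual expression
  nrm <- sqrt(colSums(Er^2))
  nrm[nrm == 0] <- Inf                        # constant probesets score 0
  Er <- sweep(Er, 2, nrm, "/")
  stat_of <- function(yv) {
    yr <- yv - Q %*% crossprod(Q, yv)
    r <- crossprod(Er, yr) / sqrt(sum(yr^2))  # partial correlations
    (n - q - 1) * r^2 / (1 - r^2)
  }
  if (sum(abs(y - mean(y))) == 0) {
    obs <- rep(0, nrow(expr))
  } else obs <- stat_of(y)[, 1]
  null_max <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(y)
    if (sum(abs(yp - mean(yp))) == 0) 0 else max(stat_of(yp))
  }, 0)
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  sel <- which(obs > thr)
  out <- data.frame(probeset = rownames(expr)[sel], stat = obs[sel],
                    p_fwer = vapply(obs[sel],
                                    function(s) mean(null_max >= s), 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_perm") <- n_perm
  out
}

#' Selective-sweep overlap test
#'
#' Counts overlapping (QTL, sweep) pairs and compares the count with an
#' empirical null in which each sweep is placed uniformly at random within
#' its own chromosome (lengths preserved). The empirical p-value is the
#' fraction of null counts at least as large as the observed count.
#'
#' @param qtl_intervals Data frame `chr`, `lo_mb`, `hi_mb`.
#' @param sweeps Data frame `chr`, `start_mb`, `end_mb`.
#' @param chr_lengths Named vector of chromosome lengths (Mb).
#' @param n_sim Number of null placements.
#' @param seed RNG seed.
#' @return List of class `sweep_overlap`: `observed`, `null_counts`,
#'   `p_value`, `n_sim`.
#' @export
sweep_overlap_test <- function(qtl_intervals, sweeps, chr_lengths,
                               n_sim = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sweeps$end_mb - sweeps$start_mb
  chrl <- chr_lengths[as.character(sweeps$chr)]
  if (any(lens > chrl)) stop("sweep longer than its chromosome")
  count_overlaps <- function(sw_start, sw_end) {
    total <- 0L
    for (q in seq_len(nrow(qtl_intervals))) {
      same <- sweeps$chr == as.character(qtl_intervals$chr[q])
      total <- total + sum(same &
        overlaps_halfopen(sw_start, sw_end,
                          qtl_intervals$lo_mb[q], qtl_intervals$hi_mb[q]))
    }
    total
  }
  observed <- count_overlaps(sweeps$start_mb, sweeps$end_mb)
  null_counts <- vapply(seq_len(n_sim), function(s) {
    st <- stats::runif(nrow(sweeps), 0, chrl - lens)
    count_overlaps(st, st + lens)
  }, 0L)
  structure(list(observed = observed, null_counts = null_counts,
                 p_value = mean(null_counts >= observed), n_sim = n_sim,
                 seed = seed),
            class = "sweep_overlap")
}

#' @export
print.sweep_overlap <- function(x, ...) {
  cat("Sweep-QTL overlap:", x$observed, "observed; null mean",
      round(mean(x$null_counts), 2), "; empirical p =",
      signif(x$p_value, 3), "\n")
  invisible(x)
}
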