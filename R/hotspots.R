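# Trans-eQTL hotspot detection: coverage of distal-eQTL confidence
# intervals along the genome, a random-placement null on a 1 Gb line, and
# conditional mediation analysis of candidate local regulators.

#' Interval coverage track
#'
#' Partitions each chromosome into half-open bins of `bin_mb` and counts how
#' many intervals overlap each bin (half-open \[start, end) semantics).
#'
#' @param intervals Data frame with columns `chr`, `start_mb`, `end_mb`.
#' @param bin_mb Bin width in Mb.
#' @param chr_lengths Optional named vector of chromosome lengths in Mb
#'   (defaults to each chromosome's maximum interval end).
#' @return Data frame of class `coverage_track` (`chr`, `start_mb`,
#'   `end_mb`, `count`), all bins.
#' @export
interval_coverage <- function(intervals, bin_mb = 0.1, chr_lengths = NULL) {
  if (any(intervals$end_mb < intervals$start_mb)) stop("negative-length interval")
  out <- NULL
  for (ch in unique(intervals$chr)) {
    sub <- intervals[intervals$chr == ch, , drop = FALSE]
    len <- if (!is.null(chr_lengths)) chr_lengths[[as.character(ch)]]
           else max(sub$end_mb)
    nbins <- ceiling(len / bin_mb - 1e-9)
    # interval [s, e) covers bins floor(s/w) .. ceiling(e/w) - 1 (0-based)
    b1 <- pmax(floor(sub$start_mb / bin_mb + 1e-9), 0) + 1
    b2 <- pmin(ceiling(sub$end_mb / bin_mb - 1e-9), nbins)
    ok <- b2 >= b1
    cov <- IRanges::coverage(IRanges::IRanges(start = b1[ok], end = b2[ok]),
                             width = nbins)
    out <- rbind(out, data.frame(
      chr = ch,
      start_mb = (seq_len(nbins) - 1) * bin_mb,
      end_mb = pmin(seq_len(nbins) * bin_mb, len),
      count = as.integer(cov), stringsAsFactors = FALSE))
  }
  structure(out, class = c("coverage_track", "data.frame"), bin_mb = bin_mb)
}

# Exact maximum overlap count of a set of 1D intervals (endpoint sweep,
# half-open semantics: an end and a coincident start do not overlap).
max_overlap <- function(start, end) {
  pts <- c(start, end)
  typ <- rep(c(1L, -1L), each = length(start))
  ord <- order(pts, typ)       # ends (-1) before starts (+1) at ties
  max(cumsum(typ[ord]))
}

#' Random-placement null for hotspot coverage
#'
#' Keeps the observed interval lengths, places each interval uniformly at
#' random on an unstructured line of `genome_mb` (1 Gb by default, the
#' sequenced autosomal genome size), and records the maximum coverage in
#' each simulation. The hotspot threshold is the 95% quantile of the null
#' maxima.
#'
#' @param intervals Data frame with `start_mb`, `end_mb` (chromosome
#'   structure is ignored by the null), or a numeric vector of lengths.
#' @param genome_mb Length of the null genome in Mb.
#' @param n_sim Number of simulations (>= 100).
#' @param quantile_level Quantile defining the threshold.
#' @param seed RNG seed.
#' @return List of class `hotspot_null`: `threshold`, `max_coverage`
#'   (length `n_sim`), `genome_mb`, `seed`.
#' @export
random_placement_null <- function(intervals, genome_mb = 1000, n_sim = 1000,
                                  quantile_level = 0.95, seed = NULL) {
  lens <- if (is.numeric(intervals)) intervals
          else intervals$end_mb - intervals$start_mb
  if (any(lens > genome_mb)) stop("interval longer than genome")
  if (n_sim < 100) stop("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  k <- length(lens)
  mx <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    st <- stats::runif(k, 0, genome_mb - lens)
    mx[s] <- max_overlap(st, st + lens)
  }
  structure(list(threshold = stats::quantile(mx, quantile_level, names = FALSE),
                 max_coverage = mx, genome_mb = genome_mb, n_sim = n_sim,
                 seed = seed),
            class = "hotspot_null")
}

#' Call trans-regulatory hotspots
#'
#' Computes the coverage of the distal-eQTL confidence intervals on the real
#' chromosome structure and reports each maximal run of bins whose coverage
#' exceeds the random-placement null threshold, together with its peak
#' coverage and member intervals.
#'
#' @param intervals Data frame with `chr`, `start_mb`, `end_mb` and an id
#'   column `probeset` (or `id`).
#' @param threshold Null coverage threshold (e.g.
#'   `random_placement_null(...)$threshold`); bins strictly above it are
#'   hotspot bins.
#' @param bin_mb Bin width in Mb.
#' @param chr_lengths Optional chromosome lengths (Mb).
#' @return Data frame of hotspot calls: `chr`, `start_mb`, `end_mb`,
#'   `peak_coverage`, `n_members`, `members` (comma-separated ids).
#' @export
call_hotspots <- function(intervals, threshold, bin_mb = 0.1,
                          chr_lengths = NULL) {
  ids <- intervals$probeset
  if (is.null(ids)) ids <- intervals$id
  if (is.null(ids)) ids <- as.character(seq_len(nrow(intervals)))
  track <- interval_coverage(intervals, bin_mb, chr_lengths)
  out <- NULL
  for (ch in unique(track$chr)) {
    sub <- track[track$chr == ch, , drop = FALSE]
    above <- sub$count > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values)) {
      i1 <- starts[seg]; i2 <- ends[seg]
      lo <- sub$start_mb[i1]; hi <- sub$end_mb[i2]
      member <- intervals$chr == ch & intervals$start_mb < hi &
        intervals$end_mb > lo
      out <- rbind(out, data.frame(
        chr = ch, start_mb = lo, end_mb = hi,
        peak_coverage = max(sub$count[i1:i2]),
        n_members = sum(member),
        members = paste(ids[member], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Conditional mediation test of a local regulator
#'
#' Tests whether a local-eQTL gene statistically accounts for a trans
#' association at a hotspot: (1) both expressions are residualized on sex,
#' batch and dye and their Pearson correlation tested; (2) the trans scan at
#' the hotspot locus is refit with the mediator's expression as an
#' additional additive covariate. The local gene is flagged a putative
#' mediator when the correlation is significant (p < `alpha`) and the
#' conditional LOD falls below half the unconditional LOD.
#'
#' @param expr Expression matrix (probesets x individuals).
#' @param mediator,target Probeset ids of the local candidate and the trans
#'   target (must differ).
#' @param chr,pos_cm Hotspot locus at which the trans LOD is evaluated.
#' @param cross `ail_cross` for the expression individuals.
#' @param gp Genotype probabilities for `cross`.
#' @param covar Covariate columns for residualization and the scans.
#' @param alpha Two-sided significance level for the correlation.
#' @return One-row data frame: `mediator`, `target`, `cor`, `cor_p`,
#'   `lod_uncond`, `lod_cond`, `mediated`.
#' @export
mediation_test <- function(expr, mediator, target, chr, pos_cm, cross, gp,
                           covar = c("sex", "batch_expr", "dye"),
                           alpha = 0.05) {
  if (identical(mediator, target)) stop("mediator and target are the same probeset")
  m <- expr[mediator, ]
  t_ <- expr[target, ]
  des <- build_design(cross$covar, covar)
  rm_ <- stats::lm.fit(des$Z, m)$residuals
  rt <- stats::lm.fit(des$Z, t_)$residuals
  ct <- stats::cor.test(rm_, rt)
  sc <- genotype_scores(gp)
  idx <- which(sc$grid$chr == as.character(chr))
  k <- idx[which.min(abs(sc$grid$pos_cm[idx] - pos_cm))]
  lod_u <- hk_scan_matrix(matrix(t_), des$Z,
                          sc$xa[, k, drop = FALSE], sc$xd[, k, drop = FALSE])[1, 1]
  Zc <- cbind(des$Z, mediator = m)
  lod_c <- hk_scan_matrix(matrix(t_), Zc,
                          sc$xa[, k, drop = FALSE], sc$xd[, k, drop = FALSE])[1, 1]
  data.frame(mediator = mediator, target = target,
             cor = unname(ct$estimate), cor_p = ct$p.value,
             lod_uncond = lod_u, lod_cond = lod_c,
             mediated = ct$p.value < alpha & lod_c < 0.5 * lod_u,
             stringsAsFactors = FALSE)
}

#' Export the hotspot regulatory network
#'
#' Nodes are hotspot markers and probesets; edges run from each flagged
#' mediator to its trans targets (putative regulatory relationships), plus
#' an anchoring edge from the hotspot marker to the mediator.
#'
#' @param mediations Data frame of [mediation_test()] rows, with optional
#'   `marker` column naming the hotspot marker; only `mediated == TRUE`
#'   rows become edges.
#' @param path Optional base path; writes `<path>_nodes.csv`,
#'   `<path>_edges.csv` and `<path>.graphml`.
#' @return List with `nodes` (`id`, `type`) and `edges` (`from`, `to`,
#'   `type`) data frames.
#' @export
export_network <- function(mediations, path = NULL) {
  med <- if (!is.null(mediations) && nrow(mediations))
    mediations[mediations$mediated, , drop = FALSE]
  else mediations
  edges <- data.frame(from = character(), to = character(),
                      type = character(), stringsAsFactors = FALSE)
  nodes <- data.frame(id = character(), type = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(med) && nrow(med)) {
    edges <- data.frame(from = med$mediator, to = med$target,
                        type = "mediation", stringsAsFactors = FALSE)
    if (!is.null(med$marker)) {
      anchor <- unique(data.frame(from = med$marker, to = med$mediator,
                                  type = "local_eqtl", stringsAsFactors = FALSE))
      edges <- rbind(anchor, edges)
      nodes <- rbind(nodes, data.frame(id = unique(med$marker),
                                       type = "marker", stringsAsFactors = FALSE))
    }
    nodes <- rbind(nodes, data.frame(
      id = unique(c(med$mediator, med$target)), type = "probeset",
      stringsAsFactors = FALSE))
  }
  if (!is.null(path)) {
    utils::write.csv(nodes, paste0(path, "_nodes.csv"), row.names = FALSE)
    utils::write.csv(edges, paste0(path, "_edges.csv"), row.names = FALSE)
    write_graphml(nodes, edges, paste0(path, ".graphml"))
  }
  list(nodes = nodes, edges = edges)
}

# Minimal GraphML serialization of a node/edge table.
write_graphml <- function(nodes, edges, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <graph edgedefault="directed">',
    sprintf('    <node id="%s"><data key="type">%s</data></node>',
            esc(nodes$id), esc(nodes$type)),
    sprintf('    <edge source="%s" target="%s"/>',
            esc(edges$from), esc(edges$to)),
    "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
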