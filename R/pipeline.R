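# End-to-end orchestration: simulate (or load) a study, compute genotype
# probabilities, run trait scans with permutation thresholds, eQTL scans,
# hotspot detection with mediation, and candidate-gene integration, writing
# all result tables as headered CSV beside a resolved-config copy.

#' Pipeline configuration
#'
#' Collects the constants of the analysis. Defaults are the conventions the
#' package is built around: 1 cM probability grid, genotyping error 0.001,
#' 5%/20% genome-wide thresholds from 1000 permutations, a 100 cM local
#' eQTL window, a more-than-ten-individuals genotype-class filter for trans
#' candidates, a LOD-difference rule of 1 for sex interactions, 1.8-LOD
#' support intervals, 0.1 Mb coverage bins and a 1 Gb random-placement null.
#'
#' @param sim A [sim_config()] describing the synthetic study (used when no
#'   input files are given).
#' @param cross_csv,expr_csv,annotation_csv,sweeps_bed Optional input paths
#'   replacing the simulated study (R/qtl-style cross CSV; probeset x
#'   individual expression CSV; annotation CSV; 3-column BED-like sweep
#'   table in Mb).
#' @param step,error_prob Genotype-probability grid step (cM) and error
#'   rate.
#' @param n_perm,alphas Trait-scan permutation settings.
#' @param traits Traits to scan (default: the mass and growth traits
#'   present).
#' @param window,class_filter,delta_lod eQTL settings: local window (cM),
#'   genotype-class filter, sex-interaction LOD rule.
#' @param eqtl_n_reps Subsampled-probeset permutation replicates.
#' @param lod_drop Support-interval LOD drop.
#' @param bin_mb,genome_mb,n_sim Hotspot settings: coverage bin width,
#'   null genome length, null simulations.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cross_csv = NULL, expr_csv = NULL,
                            annotation_csv = NULL, sweeps_bed = NULL,
                            step = 1, error_prob = 0.001,
                            n_perm = 1000, alphas = c(0.05, 0.20),
                            traits = NULL,
                            window = 100, class_filter = 10, delta_lod = 1,
                            eqtl_n_reps = 200, lod_drop = 1.8,
                            bin_mb = 0.1, genome_mb = 1000, n_sim = 1000,
                            seed = 1L) {
  structure(list(sim = sim, cross_csv = cross_csv, expr_csv = expr_csv,
                 annotation_csv = annotation_csv, sweeps_bed = sweeps_bed,
                 step = step, error_prob = error_prob,
                 n_perm = n_perm, alphas = alphas, traits = traits,
                 window = window, class_filter = class_filter,
                 delta_lod = delta_lod, eqtl_n_reps = eqtl_n_reps,
                 lod_drop = lod_drop, bin_mb = bin_mb, genome_mb = genome_mb,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full genetical-genomics pipeline
#'
#' Executes simulate (or load) -> genotype probabilities -> trait scans with
#' permutation thresholds, support intervals and multiple-QTL models ->
#' eQTL scans (local and distal) -> hotspot detection and mediation ->
#' candidate-gene screen and sweep overlap, writing each stage's result
#' table as CSV into `out_dir`. With a fixed seed the run is deterministic.
#' When no expression input is available the eQTL stages are skipped with a
#' notice.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main result objects; the tables are
#'   in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ailqtl_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  wr <- function(x, name) utils::write.csv(x, file.path(out_dir, name),
                                           row.names = FALSE)
  # --- inputs -------------------------------------------------------------
  if (is.null(config$cross_csv)) {
    study <- simulate_study(config$sim)
    cross <- study$cross
    expr0 <- study$probe_expr
    probe_annot <- study$probe_annot
    annotation <- study$annotation
    expr_ids <- study$expr_ids
    expr_covar <- study$expr_covar
    write_cross_csv(cross, file.path(out_dir, "cross.csv"))
    utils::write.csv(study$truth$qtl, file.path(out_dir, "truth_qtl.csv"),
                     row.names = FALSE)
  } else {
    study <- NULL
    cross <- read_cross_csv(config$cross_csv)
    annotation <- if (!is.null(config$annotation_csv))
      utils::read.csv(config$annotation_csv, stringsAsFactors = FALSE)
    else NULL
    expr0 <- if (!is.null(config$expr_csv)) {
      e <- utils::read.csv(config$expr_csv, row.names = 1, check.names = FALSE)
      as.matrix(e)
    } else NULL
    probe_annot <- NULL
    expr_ids <- if (!is.null(expr0)) match(colnames(expr0), rownames(cross$geno))
    expr_covar <- cross$covar[expr_ids, , drop = FALSE]
  }
  # --- genotype probabilities and trait scans ------------------------------
  gp <- calc_genoprob(cross, step = config$step, error_prob = config$error_prob)
  traits <- config$traits
  if (is.null(traits))
    traits <- intersect(c("w42", "w112", "w212", "g8.42", "g42.112", "g112.212"),
                        names(cross$pheno))
  scan_tbl <- NULL; thr_tbl <- NULL; qtl_tbl <- NULL; interval_tbl <- NULL
  for (tr in traits) {
    pcs <- tryCatch(family_pcs(cross, tr), error = function(e) NULL)
    thr <- permutation_thresholds(cross, gp, tr, pcs = pcs,
                                  n_perm = config$n_perm,
                                  alphas = config$alphas,
                                  seed = config$seed + match(tr, traits))
    sc1 <- scan_one(cross, gp, tr, pcs = pcs)
    scan_tbl <- rbind(scan_tbl, cbind(trait = tr, as.data.frame(sc1)))
    thr_tbl <- rbind(thr_tbl, data.frame(
      trait = tr, significant = thr$thresholds[1],
      suggestive = thr$thresholds[2], n_perm = thr$n_perm))
    peaks <- attr(sc1, "peaks")
    cand <- peaks[peaks$lod >= thr$thresholds[1], , drop = FALSE]
    if (nrow(cand)) {
      fit <- tryCatch(
        fit_multiqtl(cross, gp, tr, cand[, c("chr", "pos_cm")],
                     threshold = thr$thresholds[1], pcs = pcs),
        error = function(e) NULL)
      if (!is.null(fit)) {
        qtl_tbl <- rbind(qtl_tbl, cbind(trait = tr, fit$loci,
                                        model_varexp = fit$model_varexp))
        for (r in seq_len(nrow(fit$loci))) {
          ci <- lod_interval(sc1, fit$loci$chr[r], drop = config$lod_drop)
          interval_tbl <- rbind(interval_tbl, cbind(trait = tr, ci))
        }
      }
    }
  }
  wr(scan_tbl, "scans.csv"); wr(thr_tbl, "thresholds.csv")
  if (!is.null(qtl_tbl)) wr(qtl_tbl, "qtl_models.csv")
  regions <- NULL
  if (!is.null(interval_tbl)) {
    wr(interval_tbl, "qtl_intervals.csv")
    if (!anyNA(interval_tbl$lo_mb)) {     # physical map may be absent
      regions <- merge_qtl_regions(interval_tbl)
      wr(regions, "qtl_regions.csv")
    }
  }
  res <- list(cross = cross, gp = gp, scans = scan_tbl, thresholds = thr_tbl,
              qtl = qtl_tbl, intervals = interval_tbl, regions = regions,
              study = study)
  # --- expression stages ----------------------------------------------------
  if (is.null(expr0)) {
    message("no expression input: eQTL stages skipped")
    save_config(config, out_dir)
    return(invisible(res))
  }
  cross_e <- subset_cross(cross, expr_ids)
  cross_e$covar <- expr_covar
  gp_e <- calc_genoprob(cross_e, step = config$step,
                        error_prob = config$error_prob)
  expr <- quantile_normalize(expr0)
  if (!is.null(probe_annot))
    expr <- median_polish_summarize(expr, probe_annot$probeset)
  if (!is.null(expr_covar$batch_expr) && nlevels(factor(expr_covar$batch_expr)) > 1)
    expr <- adjust_batch(expr, expr_covar$batch_expr)
  ethr <- subsampled_thresholds(expr, annotation, cross_e, gp_e,
                                n_reps = config$eqtl_n_reps,
                                window = config$window,
                                seed = config$seed + 100)
  loc <- scan_local(expr, annotation, cross_e, gp_e, threshold = ethr$local,
                    window = config$window, delta_lod = config$delta_lod,
                    drop = config$lod_drop)
  dis <- scan_distal(expr, annotation, cross_e, gp_e, threshold = ethr$trans,
                     window = config$window, class_filter = config$class_filter,
                     delta_lod = config$delta_lod, drop = config$lod_drop)
  eqtl <- rbind(loc, dis)
  if (!is.null(eqtl)) wr(eqtl, "eqtl.csv")
  wr(data.frame(local = ethr$local, trans = ethr$trans,
                n_reps = ethr$n_reps), "eqtl_thresholds.csv")
  wr(effect_direction_summary(eqtl), "effect_directions.csv")
  res$eqtl <- eqtl; res$eqtl_thresholds <- ethr
  # --- hotspots -------------------------------------------------------------
  chr_mb <- tapply(cross$map$pos_mb, cross$map$chr, max)
  hot <- NULL; medi <- NULL
  if (!is.null(dis) && nrow(dis)) {
    civ <- data.frame(chr = dis$chr, start_mb = dis$lo_mb, end_mb = dis$hi_mb,
                      probeset = dis$probeset)
    null <- random_placement_null(civ, genome_mb = config$genome_mb,
                                  n_sim = config$n_sim,
                                  seed = config$seed + 200)
    hot <- call_hotspots(civ, null$threshold, bin_mb = config$bin_mb,
                         chr_lengths = chr_mb)
    if (!is.null(hot)) {
      wr(hot, "hotspots.csv")
      for (h in seq_len(nrow(hot))) {
        over <- which(loc$chr == hot$chr[h] &
                        overlaps_halfopen(loc$lo_mb, loc$hi_mb,
                                          hot$start_mb[h], hot$end_mb[h]))
        members <- strsplit(hot$members[h], ",")[[1]]
        for (m in over) for (tg in members) {
          if (loc$probeset[m] == tg) next
          drow <- dis[dis$probeset == tg, , drop = FALSE][1, ]
          mt <- mediation_test(expr, loc$probeset[m], tg,
                               hot$chr[h], mean(c(drow$lo_cm, drow$hi_cm)),
                               cross_e, gp_e)
          mt$hotspot <- h
          mt$marker <- nearest_marker_name(cross$map, hot$chr[h],
                                           (hot$start_mb[h] + hot$end_mb[h]) / 2)
          medi <- rbind(medi, mt)
        }
      }
      if (!is.null(medi)) {
        wr(medi, "mediation.csv")
        export_network(medi, file.path(out_dir, "network"))
      }
    }
  }
  res$hotspots <- hot; res$mediation <- medi
  # --- integration ----------------------------------------------------------
  if (!is.null(interval_tbl) && !is.null(loc)) {
    qi <- interval_tbl[, c("trait", "chr", "lo_mb", "hi_mb")]
    cand <- candidate_screen(qi, loc, expr, cross, expr_ids)
    if (!is.null(cand)) wr(cand, "candidates.csv")
    res$candidates <- cand
  }
  if (!is.null(config$sweeps_bed)) {
    sweeps <- utils::read.table(config$sweeps_bed, header = FALSE,
                                col.names = c("chr", "start_mb", "end_mb"))
    sweeps$chr <- as.character(sweeps$chr)
    if (!is.null(interval_tbl)) {
      so <- sweep_overlap_test(interval_tbl, sweeps, chr_mb,
                               n_sim = config$n_sim, seed = config$seed + 300)
      wr(data.frame(observed = so$observed, p_value = so$p_value,
                    null_mean = mean(so$null_counts)), "sweep_overlap.csv")
      res$sweep_overlap <- so
    }
  }
  save_config(config, out_dir)
  invisible(res)
}

nearest_marker_name <- function(map, chr, pos_mb) {
  idx <- which(map$chr == as.character(chr))
  map$marker[idx[which.min(abs(map$pos_mb[idx] - pos_mb))]]
}

save_config <- function(config, out_dir) {
  cfg <- lapply(unclass(config), function(x)
    if (inherits(x, "sim_config")) lapply(unclass(x), simplify_yaml) else simplify_yaml(x))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
}

simplify_yaml <- function(x) {
  if (is.data.frame(x)) as.list(x) else x
}
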