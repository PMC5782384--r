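# Shared fixtures, built in code. Heavier simulated studies are cached in
# an environment so several test files can reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Deterministic 5-individual, 6-marker cross on 2 chromosomes.
toy_cross <- function() {
  map <- data.frame(
    marker = c("m1", "m2", "m3", "m4", "m5", "m6"),
    chr = c("1", "1", "1", "2", "2", "2"),
    pos_cm = c(0, 10, 25, 0, 20, 40),
    pos_mb = c(0, 1, 3, 0, 5, 9))
  geno <- matrix(c(1L, 2L, 3L, 1L, 2L, 3L,
                   2L, 2L, 2L, 4L, 5L, NA,
                   3L, 3L, 3L, 2L, 1L, 1L,
                   1L, NA, 2L, 3L, 3L, 2L,
                   2L, 1L, 1L, 2L, 2L, 2L),
                 nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("ind", 1:5), map$marker))
  pheno <- data.frame(w8 = c(60, 62, NA, 58, 61),
                      w42 = c(460, 480, 455, NA, 470),
                      w112 = c(1100, 1180, 1060, 1120, NA),
                      w212 = c(1500, 1620, 1450, 1540, 1505))
  covar <- data.frame(sex = c("male", "female", "male", "female", "male"),
                      batch = c("b1", "b1", "b2", "b2", "b1"))
  make_cross(geno, map, pheno, covar)
}

# Two-chromosome map for small simulations.
small_map <- function() sim_map(2, 8, c(120, 100), c(80, 60))

# Empty trait architecture (no QTL, no epistasis).
no_qtl <- function()
  data.frame(trait = character(), chr = character(), pos_cm = numeric(),
             var_explained = numeric(), d_frac = numeric(),
             a_sex_frac = numeric())

no_epistasis <- function()
  data.frame(trait = character(), chr1 = character(), pos_cm1 = numeric(),
             chr2 = character(), pos_cm2 = numeric(), aa = numeric())

# A moderate simulated study shared across test files.
shared_study <- function() {
  cache_fixture("shared_study", function() {
    simulate_study(sim_config(
      n_final = 200, n_expr = 100, n_probesets = 150,
      probes_per_probeset = 1, n_local_eqtl = 15, n_trans_eqtl = 3,
      hotspot = list(chr = "5", pos_cm = 125, n_targets = 6, beta = 1,
                     var = 0.5),
      seed = 20260101))
  })
}

shared_genoprob <- function() {
  cache_fixture("shared_genoprob", function()
    calc_genoprob(shared_study()$cross, step = 2))
}
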