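# ailqtl

Genetical genomics for advanced intercross lines: QTL mapping of growth
traits, liver eQTL mapping, trans-hotspot detection with mediation analysis,
and candidate-gene integration, modelled on an F8 intercross between wild
and domestic chicken founder lines.

## The problem

Crossing two divergent founder lines (here: wild Red Junglefowl-type × White
Leghorn-type) and intermating the offspring for several generations produces
an *advanced intercross line* (AIL). Each generation of random mating
accumulates recombinations, so an F8 maps quantitative trait loci (QTL) with
several-fold better resolution than an F2, at the price of drifted allele
frequencies and an expanded genetic map. Measuring an intermediary molecular
phenotype — liver gene expression on two-colour microarrays — in a subset of
the same birds lets one map expression QTL (eQTL), classify them as *local*
(within ±50 cM of the gene) or *distal/trans*, and use the overlap of trait
QTL with local eQTL plus trait–expression association to nominate candidate
quantitative trait genes.

`ailqtl` implements that whole analysis as a tested R package:

* **Cross I/O** — R/qtl-style single-file CSV reader/writer with
  auto-detected genotype codes, cM↔Mb interpolation, growth traits as mass
  differences (`read_cross_csv`, `cm_to_mb`, `derive_growth_traits`).
* **Genotype probabilities** — forward–backward HMM over the AA/AB/BB states
  on a marker + pseudomarker grid, Haldane map function, F2 transition
  model, genotyping-error and partially informative observation classes
  (`calc_genoprob`, `genotype_scores`).
* **Haley–Knott scans** — LOD = (n/2)·log₁₀(RSS₀/RSS₁) of the trait on the
  expected additive score x_a = P(BB) − P(AA) and dominance score
  x_d = P(AB), with batch, sex, and genotype-PC covariates and optional
  genotype-by-sex interactions; genome-wide permutation thresholds (5%
  significant / 20% suggestive); 1.8-LOD support intervals;
  two-dimensional epistasis scans with the five standard two-locus
  statistics; forward-selection multiple-QTL models with drop-one LOD and
  percent variance explained; analytic power via the noncentral chi-square
  (`scan_one`, `permutation_thresholds`, `lod_interval`, `scan_two`,
  `fit_multiqtl`, `power_detect`).
* **eQTL mapping** — quantile normalization, median-polish probeset
  summarization, ComBat batch adjustment; local scans restricted to a
  100 cM window around each gene; distal scans excluding that window with a
  more-than-ten-per-genotype-class filter; subsampled-probeset permutation
  thresholds; effect-direction summaries (`scan_local`, `scan_distal`,
  `subsampled_thresholds`).
* **Hotspots & mediation** — coverage of distal-eQTL confidence intervals
  in 0.1 Mb bins, a random-placement null on a 1 Gb line, and conditional
  mediation: a local gene is a putative regulator when its expression
  correlates with the target's (p < 0.05) and including it as a covariate
  more than halves the trans LOD (`call_hotspots`, `mediation_test`,
  `export_network`).
* **Integration** — candidate screen (QTL ∩ local eQTL + trait–expression
  association), transcriptome-wide association with a max-statistic
  permutation FWER, and selective-sweep overlap against a per-chromosome
  random-placement null (`candidate_screen`,
  `transcriptome_wide_association`, `sweep_overlap_test`).
* **Synthetic study generator** — a full F8 AIL simulator (founders fixed
  for alternative alleles, Poisson/Haldane meioses, ~100 individuals per
  generation, observation masking for partially informative markers) with
  planted trait QTL, epistasis, local/trans eQTL, sex interactions,
  batch/dye effects and a mediated trans-hotspot, all recorded in truth
  tables (`simulate_study`, `sim_config`).

## Worked example

```r
library(ailqtl)

study <- simulate_study(sim_config(n_final = 471, n_expr = 130, seed = 1))
cross <- study$cross                       # 471 birds, 120 markers, 6 autosomes

gp  <- calc_genoprob(cross, step = 2)      # 3-state HMM on a 2 cM grid
pcs <- family_pcs(cross, "w112")           # genotype PCs associated with the trait
scan <- scan_one(cross, gp, "w112", pcs = pcs)
thr  <- permutation_thresholds(cross, gp, "w112", pcs = pcs,
                               n_perm = 1000, seed = 2)
thr
#> Permutation thresholds (1000 permutations):
#>   5%  20%
#> 3.74 3.09

peaks <- attr(scan, "peaks")
subset(peaks, lod > thr$thresholds[1])[, 1:4]
#>   chr pos_cm    pos_mb      lod
#> 1   1    206 103.00000 5.727319
#> 2   2    172  88.45714 3.842476

lod_interval(scan, "1", drop = 1.8)[, c("peak_cm", "lo_mb", "hi_mb")]
#>   peak_cm lo_mb hi_mb
#> 1     206    99   108
```

The day-112 body-mass scan finds the planted major locus on chromosome 1
(LOD 5.7 against a genome-wide 5% threshold of 3.74) and the smaller
second locus on chromosome 2; the chromosome-1 support interval
[99, 108) Mb brackets the true planted position (210.5 cM ≈ 105 Mb). `fit_multiqtl()`
then estimates its effects and percent variance explained, and
`run_pipeline()` chains every stage — scans, eQTL mapping, hotspot calling,
mediation and candidate integration — into one deterministic, seeded run
that writes each result table as CSV.

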