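---
title: "Mapping growth and gene expression in an advanced intercross: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping growth and gene expression in an advanced intercross: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailqtl)
```

`ailqtl` maps quantitative traits and liver gene expression in an F8
advanced intercross line (AIL) between two divergent, inbred-like founder
populations — the design of a wild × domestic chicken cross. This vignette
is the package's own account of the models it fits, the constants it fixes,
what the bundled simulator does and does not emulate, and the places where
the design was genuinely open.

## The mapping model

### Genotype probabilities

Genotypes at SNP markers are observed on the alphabet
{AA, AB, BB, not-AA, not-BB, missing}, where A is the wild-founder allele
and the two "not" codes describe *partially informative* markers at which
the heterozygote cannot be distinguished from one homozygote. Multipoint
probabilities for the latent AA/AB/BB state are computed by
forward–backward over a three-state chain per chromosome
(`calc_genoprob()`), on a grid of markers plus pseudomarkers every `step`
cM (default 1 cM).

Two modelling approximations are deliberate:

* **F2 transitions on the observed map.** The AIL is analysed with F2
  two-locus transition probabilities and Haldane (no-interference)
  recombination fractions, `r = (1 − e^{−2d/100})/2`. This is the same
  approximation made when an AIL is coded as an F2 intercross; the map the
  chain runs on is the *realised* (expanded) F8 map, so the accumulated
  recombinations are already in the distances. A generation-indexed AIL
  transition model is out of scope.
* **Emission model.** With genotyping-error rate ε (default 0.001), a fully
  informative observation is correct with probability 1 − ε and errs
  uniformly over the other two full codes; a partial code sums the
  emissions of its two compatible full codes (e.g. P(not-BB | AA) =
  1 − ε/2, P(not-BB | BB) = ε). Missing observations are uninformative.

Haley–Knott regression then consumes the expected scores
`x_a = P(BB) − P(AA) ∈ [−1, 1]` and `x_d = P(AB) ∈ [0, 1]`.

### Scans, covariates and sex interactions

`scan_one()` regresses the trait on covariates plus (x_a, x_d) at each grid
position; `LOD = (n/2)·log₁₀(RSS₀/RSS₁)` against the covariates-only null.
Standard covariates are rearing batch and sex; family structure is handled
by genotype principal components (`family_pcs()`): the first ten PCs of the
mean-imputed additive-score matrix are screened against the trait and those
with p < 0.05 retained. Sex is coded −1 (female) / +1 (male), so `a` and
`d` are cross-sex means and the interaction coefficients `a_by_sex`,
`d_by_sex` are deviations — directly comparable across models. A
genotype-by-sex interaction is retained when it improves the model LOD by
more than 1, the same rule at trait and expression level.

One caveat found while validating: on very small marker panels (a few tens
of markers) the PC screen is pathological — single markers dominate
individual PCs, so a trait-associated PC can *be* the QTL and absorb its
signal. At the package's default scale (120 markers across six autosomes)
the loadings are spread and the screen behaves as intended; the scale of
the marker panel is therefore part of the study conditions, not a free
knob.

### Thresholds, intervals, epistasis, multiple-QTL models

Genome-wide significance uses the classical permutation approach: trait
values are permuted within the scanned individuals (covariates stay
attached to the genotypes), the genome-wide maximum LOD recorded, and the
5% (significant) and 20% (suggestive) quantiles used as thresholds.
Support intervals are 1.8-LOD drops, expanded one grid position past the
crossing, with Mb limits by piecewise-linear cM→Mb interpolation; all
derived intervals are half-open [start, end) in Mb.

`scan_two()` computes the five standard two-locus statistics (full,
full-vs-one, interactive, additive, additive-vs-one) on a coarsened grid
(≥5 cM by default; nothing is lost at ~15 cM marker spacing), and
`declare_epistatic_pairs()` applies the joint rule — full model significant
*and* (full-vs-one *or* interaction), or additive *and* additive-vs-one —
with defaults (11, 9, 7, 7, 4) appropriate to this marker density.
`fit_multiqtl()` builds the final model by forward inclusion in LOD order,
keeping terms whose drop-one LOD clears the threshold, and reports percent
variance explained per term as `100·(RSS_without − RSS_with)/TSS`, i.e.
relative to total phenotypic variance.

`power_detect()` gives analytic power: `2·ln(10)·LOD` is noncentral
chi-square with `df = 2` (a + d) and noncentrality `n·f/(1 − f)` for a
locus explaining fraction `f` of covariate-adjusted variance.

## Expression mapping

Probe-level two-colour array data are quantile-normalized
(`limma::normalizeQuantiles` behind `quantile_normalize()`), summarized to
probesets by median polish (`stats::medpolish`, 10-iteration cap, probeset
value = overall + sample effect) and batch-adjusted with ComBat
(`sva::ComBat` behind `adjust_batch()`, slides as batches). Dye
(fluorophore) enters every expression model as an additive two-level
covariate alongside sex and batch.

Local eQTL are scanned only in the 100 cM window centred on the gene's
interpolated map position (distances on the F8 map, clipped at chromosome
ends); distal scans cover the rest of the genome, *excluding* the window so
a probeset cannot contribute a "distal" peak at its own locus — the
exclusion is a design choice, switchable via the window argument. Distal
candidates are dropped when any genotype class at the peak has ten or fewer
individuals (classes from the most-probable HMM genotype at the nearest
grid position), a guard against trans artefacts driven by extreme
individuals in rare classes.

Significance thresholds come from subsampled-probeset permutations
(`subsampled_thresholds()`): each replicate samples 100 probesets, permutes
the individual labels once, and records the maximum LOD over the probesets'
local windows (local null) and genome-wide (trans null); thresholds are the
95% quantiles of those maxima. Taking the maximum over the 100 probesets —
rather than pooling them — is the stricter reading of "permuting 100
probesets simultaneously" and is the recorded choice.

## Hotspots and mediation

Distal-eQTL confidence intervals are piled into 0.1 Mb half-open bins
(`interval_coverage()`, via IRanges). The null keeps the interval lengths
and drops them uniformly on a featureless 1 Gb line — the sequenced
autosomal genome size — recording the maximum coverage per simulation;
the hotspot threshold is the 95% quantile of those maxima (the null-summary
choice, since maximum-vs-quantile was unspecified). Observed coverage is
computed on the real chromosome structure, and each maximal run of bins
above the threshold is a hotspot call.

Mediation (`mediation_test()`): both expressions are residualized on sex,
batch and dye; the local gene is a putative regulator of a trans target
when the residual Pearson correlation is significant at p < 0.05
(two-sided — "significant" was otherwise unquantified) *and* adding the
local gene's expression as a covariate reduces the trans LOD by more than
half. Flagged links are exported as a marker → mediator → targets network
(CSV and GraphML).

## Integration

`candidate_screen()` nominates a gene when its local-eQTL interval overlaps
a trait QTL interval (any shared half-open span) and
`trait ~ expression + dye + batch` (plus `sex + sex:expression` where the
eQTL record carries the sex flag) shows association at p < 0.05,
unadjusted — both model variants are reported since the choice per gene is
not determinable. `transcriptome_wide_association()` applies the same model
array-wide with a max-statistic permutation null for family-wise control.
`sweep_overlap_test()` counts QTL × sweep overlapping pairs against a null
that re-places each sweep uniformly *within its own chromosome* — unlike
the hotspot null's single line, because sweeps are compared against
intervals that live on chromosomes.

## The simulator: what it emulates, and what it does not

`simulate_study()` generates the full study: founders fully inbred and
fixed for alternative alleles (the real founders' residual heterozygosity
is instead emulated by masking ~15.5% of markers to partial observation
codes); an all-heterozygous F1; generations 2–8 by random non-self mating
(sib mating allowed — closest to a closed flock of ~100; the true mating
design was not recorded) at 100 individuals per generation; Poisson/Haldane
meioses. Traits follow
`y = μ + batch + sex + Σ(a·x_a + d·x_d + (a_s·x_a + d_s·x_d)·sex) + epistasis + N(0, σ²)`.
A QTL specified by `var_explained` has its additive effect solved from the
*covariate-orthogonal* variance of its realised locus term, so the planted
fraction is a fraction of total trait variance net of what the sex
covariate would absorb — under drift a skewed marker can make the
sex-interaction component collinear with sex itself, and that part must
not count. Expression architecture plants local and trans eQTL (variance
fractions relative to residual expression noise, i.e. the quantity that
enters detection power), sex-specific effect weights, slide and dye
offsets, optional probe-level data (2–3 probes per probeset with affinity
offsets), and one mediated hotspot built as an explicit causal chain
genotype → mediator → targets with slope β, so conditioning on the
mediator removes the targets' genotype signal by construction.

Default scale: six autosomes totalling 1800 cM (F8-expanded) and ~1 Gb,
120 markers (~15 cM spacing), 300 final individuals (471 for
study-scale runs), 130 expression individuals, 1500 probesets. The default
hotspot plants a mediator whose local eQTL explains 50% of its residual
variance and targets with β = 1 — strong enough that the planted hotspot is
detectable at the trans threshold of its own study design, as the
architecture's truth tables promise.

Not emulated: sequence-level variation, linkage disequilibrium beyond the
marker map, selection during propagation, maternal effects on early mass
(early masses are carried but only mass *differences* are scanned),
sex-chromosome inheritance (scans are autosomal), and array-level artefacts
beyond additive batch/dye offsets. Passing tests on this generator
therefore demonstrate the statistical machinery under a faithful but
idealized observation model; they do not certify behaviour under probe
cross-hybridization, spatial array artefacts, or real founder haplotype
structure.

## Numerical choices and degenerate inputs

* Rank-deficient scan designs are handled by QR projection (collinear
  columns contribute nothing rather than erroring); RSS is floored at a
  relative 1e-12 before the log-ratio.
* Probability triples renormalize at every forward–backward step; they sum
  to 1 within 1e-9 by construction.
* A flat LOD curve yields a whole-chromosome support interval, flagged.
* Ties in quantile normalization share the mean of the implicated
  quantiles; single-probe probesets pass through median polish unchanged;
  zero-variance genes are skipped by the batch adjustment.
* Every permutation or simulation routine takes and records a seed; the
  pipeline writes a resolved-config YAML beside its outputs and is
  byte-deterministic under a fixed seed.

## Problem sizes used in validation

The test-suite calibrations use the scales the methods are designed for:
permutation-threshold calibration on ten null crosses of 300 individuals ×
120 markers with 1000-permutation thresholds and 200 null scans in total;
locus recovery at n = 471 over 25 simulation seeds (a purely additive
locus explaining 9% of variance — mean recovered variance sits slightly
below the planted value because observation masking attenuates the HMM
scores, an effect the real study shares); detection power at n = 130 for a
16%-variance expression locus over 200 replicates against the LOD 4 local
threshold; and mediated-hotspot recovery over 15 seeds at n = 130, with
seeds redrawn when drift leaves the planted hotspot marker with a genotype
class of ten or fewer individuals — a locus the trans filter would remove
is not a valid plant, it is a precondition of the construction.

## Known limitations

* The synthetic genome (1800 cM) is shorter than a real F8 chicken map
  (~9000 cM), so genome-wide thresholds land lower (~3.7 vs ~4.3) and the
  local/trans eQTL threshold gap is narrower; the constants are
  configurable where a user maps a real cross.
* Variance-explained estimates inherit the attenuation of Haley–Knott
  scores at partially informative or missing markers; expect recovered
  fractions a little below planted ones.
* The class-count filter uses most-probable genotypes, which at partially
  informative markers can differ from (unavailable) true classes.
* Only F2-coded intercrosses are supported — no backcross or RIL coding,
  no pedigree formats, no mixed-model (kinship) association beyond the PC
  covariates.
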