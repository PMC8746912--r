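---
title: "Methods: retinal microvascular phenotyping at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal microvascular phenotyping at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Retinal fundus photography gives a non-invasive view of the human
microvasculature. Two geometric summaries of a binary vessel segmentation
carry most of the epidemiological signal: the **box-counting fractal
dimension (FD)**, which quantifies branching complexity (≈1 for a single
vessel, approaching 2 for a space-filling network), and **vascular
density**, the number of segmented vessel pixels under a consistent
circular field of view (FOV), reported here as the FOV fraction.

`retivasc` implements the full analysis chain around these two traits:

1. a synthetic fundus simulator with ground-truth vessel masks,
2. a convolutional quality-control (QC) classifier that removes
   poor-quality images before analysis,
3. an ensemble of U-Net segmenters producing per-pixel vessel
   probabilities,
4. FD/density quantification, right/left-eye aggregation and cohort
   z-scoring,
5. the downstream association machinery: phenome-wide scans (logistic for
   prevalent disease, Cox for incident disease, linear for quantitative
   traits) with Benjamini–Hochberg FDR, dichotomized-exposure and
   stratified heterogeneity analyses, a desk-scale GWAS, polygenic scores,
   and one-sample Mendelian randomization (MR) by two-stage least squares.

Everything runs on simulated data with known generative truth, so each
stage is validated against an analytic or generative oracle rather than
against restricted cohort data.

## The synthetic vascular world

`generate_tree()` grows a recursive binary tree: every segment of
generation *g* bifurcates into two children whose calibers follow a
Murray-type split, `w_child = w_parent · 2^(−1/γ)` with `γ = 3` (Murray's
law) by default. Branch angles (mean half-angle 32°) and child lengths
(`length_ratio = 0.78`) carry Gaussian jitter; tortuosity is a smooth
sinusoidal perturbation of each path that leaves endpoints fixed, so the
parent–child adjacency is exact. Four trunks emanate from a nasal
optic-disc point, matching the gross layout of a fundus photograph.

These defaults were chosen once, as plausible desk-scale stand-ins for
fundus geometry: they produce masks whose FD spans roughly 1.25–1.7 as
depth runs over 1–8 generations and whose density sits in the 0.1–0.3
range at a 128-pixel frame, with FD strictly increasing in branching depth
— the one property the downstream analyses rely on. The generator is a
geometric fixture, not a hemodynamic model: it has no arteriole/venule
distinction, no macula, and no perfusion constraints.

`rasterize_tree()` draws hard binary strokes (anti-aliasing off, because
FD and density are defined on binary segmentations), clipped to a circular
FOV of radius `0.48 · min(H, W)`. Coordinates are pixel-centred,
origin top-left, row-major. `render_fundus()` adds the photographic
nuisance structure: a warm background with a radial gradient, a bright
optic-disc blob, per-pixel Gaussian noise, and vessels darkened most
strongly in the green channel (where real vessel contrast is highest).
`degrade_image()` produces the three dominant quality failures — defocus
blur, occlusion, over-exposure — with a severity dial in [0, 1] that is
the identity at 0 and monotone by construction.

What the simulator deliberately does **not** emulate: illumination fields
of real cameras, pathology (hemorrhages, exudates), media opacity
gradations, or inter-grader labelling noise. Consequently, passing the
segmentation and QC benchmarks here demonstrates that the training and
inference machinery is correct and well-calibrated — not that the shipped
defaults would reach the same accuracy on real fundus data, which are
harder on both counts.

## Quality control

The QC model is a compact conv-net (three 3×3 conv blocks of 8/16/32
channels with 2×2 max pooling, global average pooling, and a linear head)
on the standardized green channel resized to 64×64. It is trained with
Adam (lr 2·10⁻³, 10 epochs) on binary good/poor labels; the longer
schedule is what reliably separates the mildest over-exposure cases
(severity just above the 0.4 label boundary) from clean images. In the synthetic
world the "poor" label is any degradation with severity ≥ 0.4 — a
documented stand-in for human quality grades. The decision threshold
defaults to 0.5 and is reported with every metrics object; sensitivity
and specificity come from the 2×2 confusion table, with undefined metrics
reported as missing rather than zero.

Because no neural-network framework is available to R here, the package
carries its own small convolution/backprop engine: 3×3 convolutions are
im2col matrix products against BLAS, with exact analytic gradients
(verified against finite differences) and an Adam optimizer. The same
engine backs the U-Nets.

## Segmentation

Each ensemble member is a U-Net: an encoder of 3×3 conv + ReLU + 2×2
max-pool blocks, a bottleneck, and a decoder of nearest-neighbour
upsampling with skip concatenations, ending in a 1×1 convolution and
sigmoid. Defaults: depth 3, base 8 channels, K = 3 members differing only
by seed and shuffle order, random 64×64 crops, flip/rot90 augmentation,
weighted binary cross-entropy (vessel weight 2, because vessels are the
minority class), Adam lr 10⁻³, 3 epochs. Depth 3 with base 8 keeps a
K = 3 ensemble trainable in minutes on one CPU while exceeding the
package's Dice target on the synthetic task with a wide margin; base
channel count, depth, patch, epochs and member seeds are all exposed in
`seg_config()`.

The ensemble prediction is the arithmetic pixel-wise mean of member
probability maps; `segment_disagreement()` reports the member standard
deviation (identically zero at K = 1). Binarization uses an inclusive
threshold (`prob ≥ t`) inside the FOV only, default t = 0.5. Metrics are
computed over FOV pixels: Dice `2|P∩T|/(|P|+|T|)`, pixel accuracy, and a
rank-based (Mann–Whitney) ROC AUC. Degenerate cases are explicit: empty
truth with empty prediction scores Dice 1 with a flag; empty truth with a
non-empty prediction scores 0.

## Quantification

`box_counting_fd()` implements monofractal Minkowski–Bouligand box
counting: dyadic box sizes {2, 4, …, s_max} with s_max the largest power
of two ≤ min(H, W)/4, at least 4 sizes required, N(s) the number of
origin-aligned s×s cells containing a vessel pixel, and FD the OLS slope
of log N(s) on log(1/s). With origin-aligned dyadic grids the boxes nest,
so N(s) is provably non-increasing — the estimator asserts this on every
call and returns the counts table for audit. Two documented variants are
configurable because the "right" convention is genuinely open:
best-of-4-offsets grid placement, and skeletonization before counting
(default off — FD is computed on the full-width mask).

Density is `|mask ∧ fov| / |fov|`; the raw count is also reported, and
the two are proportional under the fixed FOV.

Per-participant metrics average the available eyes (1 or 2; single-eye
participants keep their single value — exclusion is not assumed),
z-scores use the sample SD (n−1), and "low" flags use the inclusive rule
`x ≤ mean − k·SD` with k = 2 by default, the convention used for
dichotomized mortality-style analyses. `laterality_stats()` gives the
paired right-minus-left mean difference (paired t) and the Spearman
correlation of paired eyes.

## Cohort simulator and association machinery

Genotypes are Binomial(2, MAF) dosages in Hardy–Weinberg and linkage
equilibrium — no LD, so PRS and MR truths stay analytic and independence
pruning is a recorded no-op. Quantitative traits are centred-dosage
weighted sums plus optional covariate terms, an optional latent
confounder, and Gaussian noise, standardized to SD 1 with the truth
record kept. Prevalent outcomes use a logistic link; incident outcomes
use exponential event times (constant hazard, so proportional hazards
holds exactly) with independent Uniform(0, c_max) censoring, c_max solved
numerically so the null censored fraction equals the requested rate.
Confounding is opt-in via the shared latent, and the generative direction
is strictly exposure → outcome.

`fit_association()` adjusts for the covariate table (age, age², sex,
smoking, 10 ancestry components, array indicator in the simulator's
default set); continuous exposures are analysed per 1 SD, 0/1 exposures
per flag, and both effect directions are reported so "per 1-SD decrease"
results need no re-fit. Cox models use Efron tie handling. The scan
applies BH-FDR within each exposure×class scan; outcomes with fewer than
20 cases (configurable) are skipped with a logged reason, and incident
analyses exclude participants whose first diagnosis predates acquisition.
Heterogeneity across strata offers two conventions, both implemented:
Cochran's Q on inverse-variance-weighted stratum effects (strata−1
degrees of freedom) and a joint likelihood-ratio test of the
exposure-by-stratum interaction terms in the pooled model. Q is the
default because it needs only the per-stratum summaries; the two agree
asymptotically under these models.

## GWAS, PRS and Mendelian randomization

The GWAS is per-variant OLS of the standardized trait on dosage plus
covariates, computed by Frisch–Waugh–Lovell residualization (one QR of
the covariate matrix, then vectorized simple regressions with the
covariate degrees of freedom removed) — algebraically identical to the
per-variant joint fit, and verified against `lm()` in the tests. Variants
at MAF ≤ 0.001 (configurable) and constant dosages are dropped and
counted. Selection at p < 5·10⁻⁸ yields a PRS model whose weights are the
effect-allele betas; scores are weighted dosage sums with per-variant
mean imputation of missing dosages.

MR is two-stage least squares with the PRS as instrument: stage 1
regresses exposure on PRS + covariates, stage 2 regresses outcome on the
fitted exposure + covariates, and the variance uses the structural
residuals evaluated at the observed exposure (the standard 2SLS
correction — using stage-2 OLS residuals would understate the SE). A
direct PRS-association mode is available through `prs_phewas()`. Effects
rescale linearly to the requested exposure unit (e.g. per 10 mm Hg; per
2-fold genetic risk via `log(2)` on a log-odds exposure). The first-stage
partial F is reported and estimates under F < 10 are flagged
weak-instrument. The package's MR benchmark runs GWAS and variant
selection on one half of the cohort and instruments the disjoint other
half, avoiding winner's-curse bias in the instrument weights.

## Validation design and problem sizes

The validation suite regenerates every input from seeds and checks
properties with independent oracles: brute-force box counting, pairwise
AUC, step-up BH, closed-form 2×2 odds ratios, rank-definition Spearman,
finite-difference gradients, and generative-truth recovery. The study
conditions are: FD fixtures at 256² (and the depth-5 carpet at 243²); a
branching sweep of generations 1–8 with 10 seeds each; segmentation
trained on 200 clean 128² renders with Dice measured on 20 held-out
renders and FD/density correlations measured across a depth-3–8 sweep; QC
trained on 200 clean + 200 degraded with 100 held-out; PheWAS calibration
over 5×100 null outcomes at n = 2000; GWAS calibration over 10⁴ null
variants at n = 1000; Cox coverage over 500 replicates at n = 5000 with
true HR 1.5; MR recovery at n = 10⁴ evaluation participants with true
slope 0.3 per SD and planted confounding (expected naive bias +0.12), and
null-effect CI coverage over 500 replicates at n = 1500. The demo
pipeline determinism audit runs a reduced config twice and compares
output hashes. These sizes are the package's chosen benchmark conditions;
they keep the whole suite runnable on a single CPU in well under half an
hour.

## Numerical choices and edge cases

* All simulators and trainers are pure functions of their arguments
  including the seed; `.Random.seed` is saved and restored around every
  stochastic call, and pipeline stages derive child seeds from the global
  seed by a string-hash.
* FD is undefined on an empty mask (error, not NaN); fewer than 4 usable
  box sizes is an error.
* z-scoring errors on zero variance; QC metrics with an absent class are
  missing, not zero.
* Logistic/Cox fits flag non-convergence and probable separation instead
  of returning silent NaNs; stratified results are flagged `partial` if a
  stratum fails.
* Binarization, low-value flags and QC calls all use inclusive (≥ or ≤)
  boundary conventions, stated in their docs and pinned by tests.
* Ensembles pad inputs to a multiple of 2^depth and crop back, so any
  image ≥ the FOV minimum works at inference.

## Known limitations

The simulator's cleanliness is the main one: real fundus segmentation is
substantially harder, and the shipped architectures are sized for CPU
demonstration, not leaderboard accuracy. The cohort simulator omits LD,
population structure and relatedness, so the GWAS/PRS machinery is
validated for its algebra and calibration, not for robustness to
stratification. MR assumes no pleiotropy — true in the simulator by
construction — and the heterogeneity test is asymptotic. The phenotype
panel is simulated per outcome; mapping real ICD codes to phecode-style
tables is out of scope and the scan consumes pre-mapped binary tables.
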