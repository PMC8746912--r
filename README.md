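# retivasc

Retinal microvascular phenotyping at desk scale: from fundus-style images
to vessel segmentations, geometric vascular traits, and their phenome-wide
and genetic associations — with every stage exercised on bundled
simulators that carry known ground truth.

## Who this is for

Researchers building or auditing retinal-microvasculature analysis
pipelines: automated image quality control, deep-learning vessel
segmentation, fractal-dimension/density quantification, and the
epidemiological and genetic association layers that consume those traits.
The package needs no restricted cohort data and no downloads; its
simulators regenerate every input from a seed.

## The science in brief

Two traits summarize a binary vessel segmentation under a circular field
of view (FOV):

* **Fractal dimension (FD)** — the Minkowski–Bouligand box-counting
  estimate: with N(s) the number of origin-aligned s×s grid cells
  containing a vessel pixel over dyadic sizes s ∈ {2, 4, …, s_max},

  FD = slope of log N(s) on log(1/s),

  ≈1 for a single vessel, →2 for a space-filling network.
* **Vascular density** — |mask ∧ fov| / |fov|, the FOV fraction of vessel
  pixels (raw count also reported).

Per-participant values average the available eyes and are z-scored over
the cohort (sample SD); "low" flags use x ≤ mean − 2·SD. Downstream,
prevalent disease is modelled by logistic regression (log OR per 1-SD),
incident disease by Cox proportional hazards (log HR per 1-SD, Efron
ties, prevalent cases excluded from the risk set), quantitative traits by
OLS — all covariate-adjusted, with Benjamini–Hochberg FDR across each
scan and Cochran-Q heterogeneity across strata. The genetics layer runs a
per-variant linear-regression GWAS (Frisch–Waugh–Lovell residualization),
builds polygenic scores from genome-wide-significant variants
(p < 5×10⁻⁸), and estimates causal effects by one-sample Mendelian
randomization: two-stage least squares with the PRS as instrument and
proper 2SLS standard errors, rescaled to the requested exposure unit.

Because no neural-network framework is available to R in this
environment, the QC classifier and the U-Net ensemble run on the
package's own compact convolution/backprop engine (im2col + BLAS,
finite-difference-verified gradients, Adam).

## Worked example

```r
library(retivasc)

# 1. simulate a labelled image set (2 eyes per participant)
set <- simulate_image_set(n_participants = 25, canvas = c(128, 128),
                          degraded_fraction = 0.3, seed = 7)

# 2. QC: train on the severity labels, drop poor images
labels <- ifelse(sapply(set, function(r) r$severity >= 0.4), "poor", "good")
qc <- train_qc(lapply(set, `[[`, "image"), labels, seed = 7)
probs <- sapply(set, function(r) predict_qc(qc, r$image))
keep <- which(probs < 0.5)
length(keep)
#> [1] 41

# 3. segment with a U-Net ensemble trained on clean pairs
cfg <- seg_config(ensemble_size = 3, epochs = 3)
ens <- train_segmentation_ensemble(lapply(set[keep][1:16], `[[`, "image"),
                                   lapply(set[keep][1:16], `[[`, "mask"), cfg)
r <- set[[keep[17]]]
pr <- segment(ens, r$image)
segmentation_metrics(pr, binarize(pr, 0.5, r$fov), r$mask, r$fov)
#> <seg_metrics> dice 0.9066, accuracy 0.9684, auc 0.9938

# 4. quantify
fd <- box_counting_fd(binarize(pr, 0.5, r$fov), r$fov)
fd
#> <fd_result> fd = 1.3747 (log-log R^2 = 0.9993, 5 box sizes)
vascular_density(binarize(pr, 0.5, r$fov), r$fov)$fraction
#> [1] 0.1617945

# 5. associations on a simulated cohort with known truth
geno <- simulate_genotypes(2000, 200, seed = 7)
covs <- simulate_covariates(2000, seed = 8)
vg   <- sum(2 * geno$maf[1:5] * (1 - geno$maf[1:5]))
arch <- trait_architecture(geno$variant_ids[1:5], rep(sqrt(0.2 / vg), 5),
                           residual_sd = sqrt(0.8))
trait <- simulate_trait(geno, covs, arch, seed = 9)
gw  <- gwas_scan(geno, trait$trait, covs)
pm  <- select_significant(gw, 5e-8)
pm
#> <prs_model> 5 variants (p < 5e-08; pruning: no-op (linkage equilibrium))
prs <- build_prs(geno, pm)
head(gw[order(gw$p), c("variant", "beta", "se", "p")], 3)
#>    variant      beta         se            p
#> 1 rs000001 0.3876878 0.03034348 5.580021e-36
#> 2 rs000002 0.4165330 0.03601327 5.485701e-30
#> 5 rs000005 0.4090677 0.04202911 6.688114e-22
```

The QC stage removes 9 of the 50 images (the simulator degraded 30% of
them; the mildest corruptions pass); the ensemble reaches Dice 0.91 on an
image it never saw; and the GWAS recovers exactly the five planted causal
variants — and nothing else — at genome-wide significance
(`sqrt(0.2 / vg)` ≈ 0.4 SD per allele at these frequencies). The full demonstration pipeline — simulate → qc → segment →
quantify → phewas/gwas/prs/mr with a hash manifest — runs from one
config:

```r
man <- run_pipeline(default_run_config())
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/retivasc.R show-config
Rscript inst/cli/retivasc.R run --config my.yaml --out runs/demo --seed 1
```

(after installation the script lives at
`system.file("cli", "retivasc.R", package = "retivasc")`).

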