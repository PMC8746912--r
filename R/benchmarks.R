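# Self-contained evaluation recipes: each function regenerates its inputs
# from the bundled simulators, runs the relevant pipeline stage(s) from
# scratch and returns the headline quantities. They back the package's
# validation suite and the reproduction script.

#' Fractal-dimension analytic fixtures
#'
#' Three masks with known dimension: a 1-pixel straight line (FD 1), a
#' filled field-of-view disc (FD -> 2), and a depth-5 Sierpinski carpet
#' (FD = log 8 / log 3 = 1.8928).
#'
#' @return list with `line`, `disc`, `carpet` FD estimates and
#'   `carpet_truth`.
#' @export
fd_fixture_benchmark <- function() {
  line <- matrix(FALSE, 256, 256)
  line[128, ] <- TRUE
  disc <- disc_mask(256, 256, 128.5, 128.5, 0.48 * 256)
  carpet <- matrix(TRUE, 1, 1)
  for (i in 1:5) {
    n <- nrow(carpet)
    out <- matrix(FALSE, 3 * n, 3 * n)
    for (bi in 0:2) {
      for (bj in 0:2) {
        if (bi == 1 && bj == 1) next
        out[bi * n + 1:n, bj * n + 1:n] <- carpet
      }
    }
    carpet <- out
  }
  list(line = box_counting_fd(line)$fd,
       disc = box_counting_fd(disc)$fd,
       carpet = box_counting_fd(carpet)$fd,
       carpet_truth = log(8) / log(3))
}

#' Ground-truth FD across a branching-depth sweep
#'
#' Rasterizes trees at each generation depth (several seeds per depth) and
#' measures the box-counting FD of the ground-truth masks; branching depth
#' is the generative driver of branching complexity, so FD must rise
#' monotonically with it.
#'
#' @param generations vector of depths (default 1:8).
#' @param n_seeds seeds per depth (default 10).
#' @param seed master seed.
#' @return list with `table` (generation, seed, fd) and `spearman_rho`
#'   (pooled, FD versus generation).
#' @export
fd_generation_sweep <- function(generations = 1:8, n_seeds = 10L, seed = 1L) {
  rows <- list()
  for (g in generations) {
    for (s in seq_len(n_seeds)) {
      tp <- tree_params(generations = g,
                        seed = derive_seed(seed, sprintf("sweep-%d-%d", g, s)))
      ras <- rasterize_tree(generate_tree(tp))
      rows[[length(rows) + 1L]] <-
        data.frame(generation = g, seed = s,
                   fd = box_counting_fd(ras$mask, ras$fov)$fd)
    }
  }
  tab <- do.call(rbind, rows)
  rho <- stats::cor(tab$generation, tab$fd, method = "spearman")
  list(table = tab, spearman_rho = rho)
}

#' Simulate the shared image pool for the imaging benchmarks
#'
#' Half the images carry a random degradation (severity 0.4-1), half are
#' clean, at fundus-frame scale 128 x 128 — the common substrate for the
#' QC and segmentation benchmarks.
#'
#' @param n_participants participants (2 eyes each; default 250 -> 500
#'   images).
#' @param seed master seed.
#' @return list of image records (see [simulate_image_set()]).
#' @export
benchmark_image_pool <- function(n_participants = 250L, seed = 1L) {
  simulate_image_set(n_participants, canvas = c(128L, 128L),
                     degraded_fraction = 0.5, seed = derive_seed(seed, "pool"))
}

#' Quality-control benchmark: train on clean/degraded, score held-out images
#'
#' @param pool image pool from [benchmark_image_pool()].
#' @param n_train_per_class training images per class (default 200).
#' @param n_test held-out images (default 100, balanced).
#' @param seed training seed.
#' @return list with `sensitivity`, `specificity`, `n_train`, `n_test`.
#' @export
qc_benchmark <- function(pool, n_train_per_class = 200L, n_test = 100L,
                         seed = 1L) {
  degraded <- vapply(pool, `[[`, TRUE, "degraded")
  poor <- which(degraded)
  good <- which(!degraded)
  if (length(poor) < n_train_per_class + n_test / 2 ||
      length(good) < n_train_per_class + n_test / 2) {
    stopf("image pool too small for the requested split")
  }
  tr <- c(poor[seq_len(n_train_per_class)], good[seq_len(n_train_per_class)])
  te <- c(poor[n_train_per_class + seq_len(n_test / 2)],
          good[n_train_per_class + seq_len(n_test / 2)])
  labels <- ifelse(degraded, "poor", "good")
  model <- train_qc(lapply(pool[tr], `[[`, "image"), labels[tr],
                    seed = derive_seed(seed, "qc-train"))
  probs <- vapply(pool[te], function(r) predict_qc(model, r$image), 0.0)
  m <- evaluate_qc(probs, labels[te])
  list(sensitivity = m$sensitivity, specificity = m$specificity,
       n_train = length(tr), n_test = length(te))
}

#' Segmentation benchmark: ensemble recovery of masks, FD and density
#'
#' Trains the default ensemble on clean images from the pool, measures mean
#' Dice on held-out clean images, and correlates predicted-mask FD and
#' density against ground truth across a branching-depth sweep (the sweep
#' provides genuine biological-style variation for the correlation).
#'
#' @param pool image pool from [benchmark_image_pool()].
#' @param n_train training images (default 200).
#' @param n_test held-out images for Dice (default 20).
#' @param config a [seg_config()] (default: package defaults, K = 3).
#' @param sweep_generations depths for the correlation sweep (default 3:8).
#' @param sweep_seeds seeds per depth (default 4).
#' @param seed master seed.
#' @return list with `mean_dice`, `fd_spearman`, `density_spearman`,
#'   `dice_per_image`, and the sweep table.
#' @export
segmentation_benchmark <- function(pool, n_train = 200L, n_test = 20L,
                                   config = seg_config(),
                                   sweep_generations = 3:8, sweep_seeds = 4L,
                                   seed = 1L) {
  clean <- Filter(function(r) !r$degraded, pool)
  if (length(clean) < n_train + n_test) stopf("not enough clean images")
  tr <- clean[seq_len(n_train)]
  te <- clean[n_train + seq_len(n_test)]
  ens <- train_segmentation_ensemble(lapply(tr, `[[`, "image"),
                                     lapply(tr, `[[`, "mask"), config)
  dice <- vapply(te, function(r) {
    pr <- segment(ens, r$image)
    segmentation_metrics(pr, binarize(pr, 0.5, r$fov), r$mask, r$fov)$dice
  }, 0.0)

  rows <- list()
  for (g in sweep_generations) {
    for (s in seq_len(sweep_seeds)) {
      tp <- tree_params(generations = g, canvas = c(128L, 128L),
                        root_length_px = 23, width_root_px = 2,
                        seed = derive_seed(seed, sprintf("segsweep-%d-%d", g, s)))
      ras <- rasterize_tree(generate_tree(tp), canvas = c(128L, 128L))
      img <- render_fundus(ras$mask, ras$fov,
                           seed = derive_seed(seed, sprintf("segrender-%d-%d", g, s)))
      pr <- segment(ens, img)
      pred <- binarize(pr, 0.5, ras$fov)
      rows[[length(rows) + 1L]] <- data.frame(
        generation = g, seed = s,
        fd_truth = box_counting_fd(ras$mask, ras$fov)$fd,
        fd_pred = if (any(pred)) box_counting_fd(pred, ras$fov)$fd else NA_real_,
        density_truth = vascular_density(ras$mask, ras$fov)$fraction,
        density_pred = vascular_density(pred, ras$fov)$fraction)
    }
  }
  sweep <- do.call(rbind, rows)
  ok <- stats::complete.cases(sweep)
  list(mean_dice = mean(dice), dice_per_image = dice,
       fd_spearman = stats::cor(sweep$fd_truth[ok], sweep$fd_pred[ok],
                                method = "spearman"),
       density_spearman = stats::cor(sweep$density_truth[ok],
                                     sweep$density_pred[ok],
                                     method = "spearman"),
       sweep = sweep)
}

#' Type-I calibration of the PheWAS scan on null outcomes
#'
#' @param n_replicates replicate scans (default 5).
#' @param n_outcomes null binary outcomes per scan (default 100).
#' @param n cohort size (default 2000).
#' @param seed master seed.
#' @return list with `fraction_p05` (pooled over replicates) and
#'   `n_tests`.
#' @export
phewas_null_calibration <- function(n_replicates = 5L, n_outcomes = 100L,
                                    n = 2000L, seed = 1L) {
  ps <- numeric(0)
  for (r in seq_len(n_replicates)) {
    g <- simulate_genotypes(n, 2, seed = derive_seed(seed, paste0("pg", r)))
    tr <- simulate_trait(g, NULL, trait_architecture(),
                         seed = derive_seed(seed, paste0("pt", r)))
    panel <- simulate_phenotype_panel(tr$trait, n_outcomes,
                                      "prevalent-binary", baseline = 0.1,
                                      seed = derive_seed(seed, paste0("pp", r)))
    res <- phewas_scan(tr$trait, panel, NULL)
    ps <- c(ps, res$p)
  }
  list(fraction_p05 = mean(ps < 0.05), n_tests = length(ps))
}

#' Type-I calibration of the GWAS scan on null variants
#'
#' @param m variants (default 1e4).
#' @param n participants (default 1000).
#' @param seed master seed.
#' @return list with `fraction_p05` and `n_variants`.
#' @export
gwas_null_calibration <- function(m = 10000L, n = 1000L, seed = 1L) {
  g <- simulate_genotypes(n, m, seed = derive_seed(seed, "gnull"))
  tr <- simulate_trait(g, NULL, trait_architecture(),
                       seed = derive_seed(seed, "gnull-trait"))
  rows <- gwas_scan(g, tr$trait, NULL, maf_min = 0.001)
  list(fraction_p05 = mean(rows$p < 0.05), n_variants = nrow(rows))
}

#' Cox confidence-interval coverage of a known hazard ratio
#'
#' @param n_replicates replicates (default 500).
#' @param n cohort size per replicate (default 5000).
#' @param hr true hazard ratio per 1-SD exposure (default 1.5).
#' @param seed master seed.
#' @return list with `coverage` (fraction of 95% CIs containing log hr)
#'   and `n_replicates`.
#' @export
cox_coverage_benchmark <- function(n_replicates = 500L, n = 5000L, hr = 1.5,
                                   seed = 1L) {
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    x <- with_seed(derive_seed(seed, paste0("cx", r)), stats::rnorm(n))
    out <- simulate_outcomes(x, NULL,
                             outcome_spec("incident-survival",
                                          effect = log(hr), baseline = 0.05,
                                          censoring = 0.3,
                                          seed = derive_seed(seed, paste0("co", r))))
    fit <- fit_association(x, out, NULL, "cox")
    hits[r] <- abs(fit$effect - log(hr)) <= stats::qnorm(0.975) * fit$se
  }
  list(coverage = mean(hits), n_replicates = n_replicates)
}

mr_world <- function(n, m, true_slope, seed, h2_exposure = 0.25,
                     conf_exposure = 0.3, conf_outcome = 0.4) {
  g <- simulate_genotypes(n, m, seed = derive_seed(seed, "mr-g"))
  vg <- sum(2 * g$maf * (1 - g$maf))
  w <- rep(sqrt(h2_exposure / vg), m)
  arch <- trait_architecture(g$variant_ids, w,
                            residual_sd = sqrt(max(0.05, 1 - h2_exposure -
                                                     conf_exposure^2)),
                            confounder_loading = conf_exposure)
  ex <- simulate_trait(g, NULL, arch, seed = derive_seed(seed, "mr-e"))
  out <- simulate_outcomes(ex$trait, NULL,
                           outcome_spec("quantitative", effect = true_slope,
                                        baseline = 0,
                                        seed = derive_seed(seed, "mr-o")),
                           confounder = ex$confounder,
                           confounder_loading = conf_outcome)
  list(g = g, exposure = ex, outcome = out, conf_outcome = conf_outcome,
       conf_exposure = conf_exposure)
}

#' Mendelian-randomization recovery under planted confounding
#'
#' Builds a genotype -> exposure -> outcome chain with a latent confounder
#' loading on both exposure and outcome. GWAS + significance selection run
#' on one half of the cohort; the PRS built from those weights instruments
#' the other half (disjoint participants), where the 2SLS estimate is
#' compared with the naive observational regression.
#'
#' @param n total cohort size (default 2e4, split in half).
#' @param m instrument variants (default 30).
#' @param true_slope causal effect per 1-SD exposure (default 0.3).
#' @param seed master seed.
#' @return list with `mr_estimate`, `mr_se`, `naive_estimate`,
#'   `expected_naive_bias` (analytic, from the planted loadings),
#'   `first_stage_f`, `n_eval`.
#' @export
mr_benchmark <- function(n = 20000L, m = 30L, true_slope = 0.3, seed = 1L) {
  w <- mr_world(n, m, true_slope, seed)
  half <- seq_len(n %/% 2)
  g_tr <- structure(list(dosages = w$g$dosages[half, , drop = FALSE],
                         maf = w$g$maf, variant_ids = w$g$variant_ids),
                    class = "genotype_matrix")
  g_te <- structure(list(dosages = w$g$dosages[-half, , drop = FALSE],
                         maf = w$g$maf, variant_ids = w$g$variant_ids),
                    class = "genotype_matrix")
  gw <- gwas_scan(g_tr, w$exposure$trait[half], NULL, maf_min = 0.001)
  pm <- suppressWarnings(select_significant(gw, 5e-8))
  if (length(pm$variants) == 0) stopf("no genome-wide-significant instruments")
  score <- build_prs(g_te, pm)
  mr <- one_sample_mr(score, w$exposure$trait[-half], w$outcome$value[-half],
                      NULL)
  naive <- fit_association(w$exposure$trait[-half], w$outcome$value[-half],
                           NULL, "linear")
  # exposure is standardized, so cov(U, exposure) equals the exposure-side
  # loading divided by the raw SD (~1 by construction)
  expected_bias <- w$conf_outcome * w$conf_exposure /
    stats::sd(w$exposure$raw)
  list(mr_estimate = mr$estimate, mr_se = mr$se,
       naive_estimate = naive$effect, expected_naive_bias = expected_bias,
       first_stage_f = mr$first_stage_f, n_eval = length(score),
       n_instruments = length(pm$variants))
}

#' Null-effect coverage of the MR confidence interval
#'
#' @param n_replicates replicates (default 500).
#' @param n cohort size per replicate (default 1500).
#' @param m instrument variants (default 40).
#' @param seed master seed.
#' @return list with `coverage` and `n_replicates`.
#' @export
mr_null_coverage <- function(n_replicates = 500L, n = 1500L, m = 40L,
                             seed = 1L) {
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    w <- mr_world(n, m, 0, derive_seed(seed, paste0("mrnull", r)))
    vg <- sum(2 * w$g$maf * (1 - w$g$maf))
    pm <- structure(list(variants = w$g$variant_ids,
                         weights = rep(sqrt(0.25 / vg), m),
                         provenance = list(threshold = NA, n_selected = m,
                                           pruning = "generative-weights")),
                    class = "prs_model")
    score <- build_prs(w$g, pm)
    mr <- one_sample_mr(score, w$exposure$trait, w$outcome$value, NULL)
    hits[r] <- abs(mr$estimate) <= stats::qnorm(0.975) * mr$se
  }
  list(coverage = mean(hits), n_replicates = n_replicates)
}

#' Pipeline determinism audit
#'
#' Runs the demo pipeline twice from one config (fresh output directories)
#' and compares the manifest output hashes.
#'
#' @param config pipeline config; `out_dir` is overridden.
#' @param base_dir scratch directory for the two runs.
#' @return list with `identical` (logical) and the two hash vectors.
#' @export
pipeline_determinism_audit <- function(config = default_run_config(),
                                       base_dir = tempfile("retivasc-audit")) {
  h <- list()
  for (run in 1:2) {
    cfg <- config
    cfg$out_dir <- file.path(base_dir, paste0("run", run))
    man <- suppressMessages(run_pipeline(cfg))
    h[[run]] <- manifest_hashes(man)
  }
  list(identical = identical(h[[1]], h[[2]]), run1 = h[[1]], run2 = h[[2]])
}
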