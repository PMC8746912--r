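test_that("gwas_scan equals the closed-form simple regression without covariates", {
  g <- simulate_genotypes(800, 12, seed = 50L)
  tr <- simulate_trait(g, NULL, trait_architecture(), seed = 51L)
  rows <- gwas_scan(g, tr$trait, NULL, maf_min = 0)
  for (v in c("rs000001", "rs000007")) {
    gv <- g$dosages[, v]
    expect_equal(rows$beta[rows$variant == v],
                 cov(gv, tr$trait) / var(gv), tolerance = 1e-6)
    sm <- summary(lm(tr$trait ~ gv))$coefficients
    expect_equal(rows$se[rows$variant == v], sm[2, 2], tolerance = 1e-10)
    expect_equal(rows$p[rows$variant == v], sm[2, 4], tolerance = 1e-10)
  }
})

test_that("gwas_scan agrees with per-variant lm under covariate adjustment", {
  g <- simulate_genotypes(600, 6, seed = 52L)
  covs <- simulate_covariates(600, seed = 53L)
  tr <- simulate_trait(g, covs, trait_architecture(), seed = 54L)
  rows <- gwas_scan(g, tr$trait, covs, maf_min = 0)
  gv <- g$dosages[, "rs000003"]
  full <- summary(lm(tr$trait ~ gv + age + age2 + sex + smoking + pc1 + pc2 +
                       pc3 + pc4 + pc5 + pc6 + pc7 + pc8 + pc9 + pc10 + array,
                     data = covs))$coefficients
  expect_equal(rows$beta[rows$variant == "rs000003"], full["gv", 1],
               tolerance = 1e-8)
  expect_equal(rows$se[rows$variant == "rs000003"], full["gv", 2],
               tolerance = 1e-8)
})

test_that("gwas_scan applies the MAF filter and drops constant dosages", {
  g <- simulate_genotypes(400, 10, maf_range = c(0.002, 0.4), seed = 55L)
  g$dosages[, 2] <- 1L  # constant column
  tr <- simulate_trait(g, NULL, trait_architecture(), seed = 56L)
  expect_message(rows <- gwas_scan(g, tr$trait, NULL, maf_min = 0.01),
                 "constant")
  expect_true(all(rows$maf > 0.01))
  expect_false("rs000002" %in% rows$variant)
  expect_equal(rows$variant, sort(rows$variant))
})

test_that("significance selection matches a brute-force filter", {
  rows <- data.frame(variant = sprintf("rs%02d", 1:20), effect_allele = "ALT",
                     beta = rnorm(20), se = 1,
                     p = c(1e-10, 1e-9, runif(18, 0.1, 1)),
                     maf = 0.3, n = 100)
  pm <- select_significant(rows, 5e-8)
  expect_setequal(pm$variants, rows$variant[rows$p < 5e-8])
  expect_equal(pm$weights, rows$beta[match(pm$variants, rows$variant)])

  pm_all <- select_significant(rows, 1.0)
  expect_equal(length(pm_all$variants), 20L)
  expect_warning(empty <- select_significant(rows, 1e-20), "empty")
  expect_length(empty$variants, 0L)
})

test_that("PRS scores are the weighted dosage sums, linear in the weights", {
  g <- simulate_genotypes(200, 6, seed = 57L)
  mk <- function(w) structure(list(variants = g$variant_ids,
                                   weights = w,
                                   provenance = list(threshold = NA,
                                                     n_selected = 6,
                                                     pruning = "fixture")),
                              class = "prs_model")
  expect_equal(build_prs(g, mk(rep(0, 6))), rep(0, 200))
  w1 <- c(1, 0, 0, 0, 0, 0)
  expect_equal(build_prs(g, mk(w1)), as.numeric(g$dosages[, 1]))
  set.seed(58)
  wa <- rnorm(6); wb <- rnorm(6)
  expect_equal(build_prs(g, mk(wa)) + build_prs(g, mk(wb)),
               build_prs(g, mk(wa + wb)), tolerance = 1e-12)

  bad <- mk(rep(1, 6)); bad$variants[1] <- "rs_missing"
  expect_error(build_prs(g, bad), "rs_missing")

  # missing dosages are mean-imputed per variant
  g2 <- g
  g2$dosages[1:10, 2] <- NA
  sc <- build_prs(g2, mk(c(0, 1, 0, 0, 0, 0)))
  expect_equal(sc[1], mean(g2$dosages[-(1:10), 2]))
})

test_that("2SLS via PRS recovers causal effects despite planted confounding", {
  n <- 6000
  g <- simulate_genotypes(n, 30, seed = 60L)
  vg <- sum(2 * g$maf * (1 - g$maf))
  w <- rep(sqrt(0.25 / vg), 30)
  arch <- trait_architecture(g$variant_ids, w,
                             residual_sd = sqrt(0.75 - 0.09),
                             confounder_loading = 0.3)
  ex <- simulate_trait(g, NULL, arch, seed = 61L)
  out <- simulate_outcomes(ex$trait, NULL,
                           outcome_spec("quantitative", effect = 0.3,
                                        baseline = 0, seed = 62L),
                           confounder = ex$confounder,
                           confounder_loading = 0.4)
  pm <- structure(list(variants = g$variant_ids, weights = w,
                       provenance = list(threshold = NA, n_selected = 30,
                                         pruning = "truth-weights")),
                  class = "prs_model")
  score <- build_prs(g, pm)
  mr <- one_sample_mr(score, ex$trait, out$value, NULL)
  expect_equal(mr$estimate, 0.3, tolerance = 4 * mr$se / 0.3)
  expect_gt(mr$first_stage_f, 100)
  expect_length(mr$flags, 0)

  naive <- fit_association(ex$trait, out$value, NULL, "linear")
  expect_gt(naive$effect - 0.3, 0.05)  # biased upward by the confounder

  # linear rescaling: per-10-unit estimate is 10x the per-unit estimate
  mr10 <- one_sample_mr(score, ex$trait, out$value, NULL, exposure_scale = 10)
  expect_equal(mr10$estimate, 10 * mr$estimate, tolerance = 1e-12)
  expect_equal(mr10$se, 10 * mr$se, tolerance = 1e-12)

  # weak instruments are flagged
  weak <- one_sample_mr(rnorm(n), ex$trait, out$value, NULL)
  expect_true("weak-instrument" %in% weak$flags)
  expect_error(one_sample_mr(rep(1, n), ex$trait, out$value, NULL),
               "zero variance")
})

test_that("PRS-PheWAS ranks a planted outcome first and validates the score", {
  n <- 4000
  g <- simulate_genotypes(n, 20, seed = 63L)
  vg <- sum(2 * g$maf * (1 - g$maf))
  w <- rep(sqrt(0.3 / vg), 20)
  pm <- structure(list(variants = g$variant_ids, weights = w,
                       provenance = list(threshold = NA, n_selected = 20,
                                         pruning = "truth-weights")),
                  class = "prs_model")
  score <- build_prs(g, pm)
  z <- (score - mean(score)) / sd(score)
  panel <- simulate_phenotype_panel(z, 10L, "prevalent-binary",
                                    effects = c("1" = log(1.6)),
                                    baseline = 0.15, seed = 64L)
  res <- prs_phewas(score, panel, NULL)
  expect_equal(res$outcome_id[which.min(res$p)], "phe001")
  expect_equal(res$effect_decrease, -res$effect)
  expect_error(prs_phewas(rep(0, n), panel, NULL), "zero variance")
})
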