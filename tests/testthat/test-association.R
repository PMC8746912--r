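test_that("logistic fits reproduce the closed-form 2x2 odds ratio", {
  exposure <- rep(c(1, 0), each = 100)
  case <- c(rep(1, 40), rep(0, 60), rep(1, 20), rep(0, 80))
  r <- fit_association(exposure, case, NULL, "logistic")
  expect_equal(r$effect, log((40 * 80) / (60 * 20)), tolerance = 1e-4 / 0.98)
  expect_equal(exp(r$effect), 2.667, tolerance = 1e-3)
  expect_equal(r$effect_decrease, -r$effect)
  expect_equal(r$exposure_scale, "flag")
  expect_equal(r$n, 200L)
})

test_that("linear fits recover noiseless slopes and standardize exposures", {
  x <- seq(-2, 2, length.out = 50)
  r <- suppressWarnings(fit_association(x, 2 * x, NULL, "linear"))
  # beta per 1 SD of x equals 2 * sd(x)
  expect_equal(r$effect, 2 * sd(x), tolerance = 1e-10)
  expect_lt(r$p, 1e-12)
  expect_error(fit_association(rep(1, 50), 2 * x, NULL, "linear"), "variance")
})

test_that("cox fits recover a planted hazard ratio with covariates", {
  g <- simulate_genotypes(4000, 2, seed = 20L)
  covs <- simulate_covariates(4000, seed = 21L)
  tr <- simulate_trait(g, covs, trait_architecture(), seed = 22L)
  out <- simulate_outcomes(tr$trait, covs,
                           outcome_spec("incident-survival",
                                        effect = log(1.5), baseline = 0.05,
                                        censoring = 0.3, seed = 23L))
  r <- fit_association(tr$trait, out, covs, "cox")
  expect_equal(r$effect, log(1.5), tolerance = 3 * r$se / log(1.5))
  expect_equal(r$events, sum(out$event))
  expect_length(r$flags, 0)
})

test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(29)
  for (rep in 1:20) {
    p <- runif(100)^2
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 1.4)), "0, 1")
})

test_that("phewas_scan fits per-outcome models with scan-wide FDR", {
  g <- simulate_genotypes(1500, 2, seed = 30L)
  tr <- simulate_trait(g, NULL, trait_architecture(), seed = 31L)
  panel <- simulate_phenotype_panel(tr$trait, 12L, "prevalent-binary",
                                    effects = c("1" = 0.8), baseline = 0.15,
                                    seed = 32L)
  res <- phewas_scan(tr$trait, panel, NULL)
  expect_equal(nrow(res), 12L)
  expect_equal(res$fdr_q, bh_fdr(res$p))
  expect_equal(res$outcome_id[which.min(res$p)], "phe001")

  # rare outcomes are skipped with a reason, not silently dropped
  rare <- simulate_phenotype_panel(tr$trait, 2L, "prevalent-binary",
                                   baseline = 0.005, seed = 33L)
  res2 <- phewas_scan(tr$trait, c(panel[1:3], rare), NULL)
  sk <- attr(res2, "skipped")
  expect_true(all(c("phe001", "phe002") %in% sk$outcome_id) || nrow(sk) >= 1)
  expect_equal(nrow(res2) + nrow(sk), 5L)
})

test_that("incident scans exclude prevalent cases from the risk set", {
  g <- simulate_genotypes(2000, 2, seed = 34L)
  tr <- simulate_trait(g, NULL, trait_architecture(), seed = 35L)
  out <- simulate_outcomes(tr$trait, NULL,
                           outcome_spec("incident-survival", effect = 0,
                                        baseline = 0.05, seed = 36L))
  prevalent <- as.integer(seq_len(2000) <= 300)
  panel <- list(list(id = "phe001", kind = "incident-survival",
                     time = out$time, event = out$event,
                     prevalent = prevalent))
  res <- phewas_scan(tr$trait, panel, NULL)
  expect_equal(res$n, 1700L)
})

test_that("Cochran Q and stratified fits detect planted heterogeneity", {
  expect_error(stratified_association(rnorm(50), rnorm(50), NULL,
                                      rep("a", 50), "linear"), "2 strata")

  q0 <- cochran_q(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)
  # hand-computed fixture
  qh <- cochran_q(c(0.2, 0.6), c(0.1, 0.2))
  w <- c(100, 25)
  bw <- sum(w * c(0.2, 0.6)) / sum(w)
  expect_equal(qh$Q, sum(w * (c(0.2, 0.6) - bw)^2))
  expect_equal(qh$df, 1L)

  # planted: null in stratum A, strong effect in stratum B
  set.seed(40)
  n <- 3000
  strata <- rep(c("A", "B"), each = n / 2)
  x <- rnorm(n)
  lp <- ifelse(strata == "B", 0.6 * x, 0)
  time <- rexp(n, 0.05 * exp(lp))
  cens <- runif(n, 0, quantile(time, 0.9))
  out <- data.frame(time = pmin(time, cens), event = as.integer(time <= cens))
  sr <- stratified_association(x, out, NULL, strata, "cox")
  expect_lt(sr$heterogeneity_p, 0.01)
  expect_lt(abs(sr$strata$A$effect), 0.15)
  expect_gt(sr$strata$B$effect, 0.4)
  expect_false(sr$partial)
})

test_that("Cochran Q agrees with the fixed-effect meta-analysis Q", {
  skip_if_not_installed("metafor")
  set.seed(47)
  eff <- rnorm(5, 0.3, 0.2)
  ses <- runif(5, 0.05, 0.3)
  q <- cochran_q(eff, ses)
  rma <- metafor::rma(yi = eff, sei = ses, method = "FE")
  expect_equal(q$Q, rma$QE, tolerance = 1e-10)
  expect_equal(q$p, rma$QEp, tolerance = 1e-10)
})

test_that("interaction-term heterogeneity agrees with Q on planted effects", {
  set.seed(53)
  n <- 2000
  strata <- rep(c("A", "B"), each = n / 2)
  x <- rnorm(n)
  y <- ifelse(strata == "B", 0.8 * x, 0) + rnorm(n)
  sr_q <- stratified_association(x, y, NULL, strata, "linear")
  sr_i <- stratified_association(x, y, NULL, strata, "linear",
                                 method = "interaction")
  expect_lt(sr_q$heterogeneity_p, 1e-6)
  expect_lt(sr_i$heterogeneity_p, 1e-6)
  expect_equal(sr_i$method, "interaction")

  # null heterogeneity: both tests are non-significant
  y0 <- 0.3 * x + rnorm(n)
  s0_q <- stratified_association(x, y0, NULL, strata, "linear")
  s0_i <- stratified_association(x, y0, NULL, strata, "linear",
                                 method = "interaction")
  expect_gt(s0_q$heterogeneity_p, 0.001)
  expect_gt(s0_i$heterogeneity_p, 0.001)
})
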