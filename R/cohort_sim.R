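# Cohort simulator: genotypes, covariates, quantitative vascular traits and
# prevalent/incident outcomes with known effects, so every association and
# genetics routine has an analytic ground truth. Variants are independent
# (Hardy-Weinberg, no LD) and event times exponential (constant hazard), so
# PRS/MR truths are analytic and proportional hazards holds exactly.

#' Simulate a genotype dosage matrix
#'
#' Dosages are drawn independently as Binomial(2, MAF_j) per variant
#' (Hardy-Weinberg equilibrium, linkage equilibrium).
#'
#' @param n participants.
#' @param m variants.
#' @param maf_range range the per-variant minor-allele frequencies are drawn
#'   from (uniformly); must lie within (0, 0.5].
#' @param seed integer seed.
#' @return object of class `genotype_matrix`: list with `dosages` (n x m
#'   integer matrix), `maf` (generating frequencies), `variant_ids`.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1L) {
  if (n < 1 || m < 1) stopf("n and m must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stopf("maf_range must lie within (0, 0.5]")
  }
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    dos <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    ids <- sprintf("rs%06d", seq_len(m))
    colnames(dos) <- ids
    structure(list(dosages = dos, maf = maf, variant_ids = ids),
              class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d participants x %d variants, MAF %.3f-%.3f\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Simulate a covariate table
#'
#' Age (years), age squared, sex, a 3-level smoking status, the first 10
#' synthetic ancestry components, and a genotyping-array indicator — the
#' adjustment set used throughout the association and genetics modules.
#'
#' @param n participants.
#' @param seed integer seed.
#' @return data frame with columns `age`, `age2`, `sex` (0/1), `smoking`
#'   (factor never/previous/current), `pc1`..`pc10`, `array` (0/1).
#' @export
simulate_covariates <- function(n, seed = 1L) {
  with_seed(seed, {
    age <- stats::runif(n, 40, 70)
    cov <- data.frame(age = age, age2 = age^2,
                      sex = stats::rbinom(n, 1, 0.5),
                      smoking = factor(sample(c("never", "previous", "current"),
                                              n, TRUE, c(0.55, 0.3, 0.15)),
                                       levels = c("never", "previous", "current")))
    pcs <- matrix(stats::rnorm(n * 10), n, 10)
    colnames(pcs) <- paste0("pc", 1:10)
    cov <- cbind(cov, as.data.frame(pcs))
    cov$array <- stats::rbinom(n, 1, 0.5)
    cov
  })
}

#' Trait architecture for the quantitative exposure simulator
#'
#' @param causal_ids variant ids with nonzero effects.
#' @param effects per-allele effects, in (pre-standardization) trait SD
#'   units, aligned with `causal_ids`.
#' @param residual_sd residual noise SD (> 0).
#' @param confounder_loading loading of a shared latent confounder on the
#'   trait (the same latent can be passed to [simulate_outcomes()] to plant
#'   confounding).
#' @param covariate_effects named list of linear covariate effects (e.g.
#'   `list(age = -0.01)`); defaults to none.
#' @return object of class `trait_architecture`.
#' @export
trait_architecture <- function(causal_ids = character(0), effects = numeric(0),
                               residual_sd = 1, confounder_loading = 0,
                               covariate_effects = list()) {
  stopifnot(length(causal_ids) == length(effects), residual_sd > 0,
            all(is.finite(effects)))
  structure(list(causal_ids = causal_ids, effects = effects,
                 residual_sd = residual_sd,
                 confounder_loading = confounder_loading,
                 covariate_effects = covariate_effects),
            class = "trait_architecture")
}

#' Simulate a standardized quantitative trait with known genetics
#'
#' trait* = sum_j beta_j (g_j - 2 maf_j) + covariate terms + lambda U +
#' N(0, residual_sd); the returned trait is standardized to mean 0, SD 1,
#' and the truth record carries everything needed to reproduce it.
#'
#' @param genotypes a [simulate_genotypes()] object.
#' @param covariates data frame from [simulate_covariates()] (or `NULL`).
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @param confounder optional numeric latent confounder vector; if `NULL`
#'   and `confounder_loading != 0`, one is drawn N(0,1) and returned.
#' @return list with `trait` (standardized), `raw`, `confounder`, and
#'   `truth` (the architecture plus the achieved scaling factor).
#' @export
simulate_trait <- function(genotypes, covariates = NULL,
                           arch = trait_architecture(), seed = 1L,
                           confounder = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  miss <- setdiff(arch$causal_ids, genotypes$variant_ids)
  if (length(miss)) stopf("causal ids not in genotypes: %s",
                          paste(miss, collapse = ", "))
  n <- nrow(genotypes$dosages)
  with_seed(seed, {
    g <- numeric(n)
    if (length(arch$causal_ids)) {
      idx <- match(arch$causal_ids, genotypes$variant_ids)
      centered <- sweep(genotypes$dosages[, idx, drop = FALSE], 2L,
                        2 * genotypes$maf[idx], "-")
      g <- as.numeric(centered %*% arch$effects)
    }
    cvt <- numeric(n)
    for (nm in names(arch$covariate_effects)) {
      cvt <- cvt + arch$covariate_effects[[nm]] * as.numeric(covariates[[nm]])
    }
    if (is.null(confounder)) {
      confounder <- if (arch$confounder_loading != 0) stats::rnorm(n) else numeric(n)
    }
    raw <- g + cvt + arch$confounder_loading * confounder +
      stats::rnorm(n, sd = arch$residual_sd)
    scl <- stats::sd(raw)
    list(trait = (raw - mean(raw)) / scl, raw = raw, confounder = confounder,
         truth = list(arch = arch, seed = seed, scale = scl,
                      center = mean(raw)))
  })
}

#' Outcome specification for the outcome simulator
#'
#' @param kind `"prevalent-binary"`, `"incident-survival"` or
#'   `"quantitative"`.
#' @param effect true effect per 1-SD exposure: log OR (prevalent), log HR
#'   (incident) or beta (quantitative).
#' @param baseline baseline prevalence in (0,1) (prevalent), baseline
#'   hazard per unit time (incident), or intercept (quantitative).
#' @param censoring target censored fraction in \[0, 1) (incident only).
#' @param noise_sd residual SD for quantitative outcomes.
#' @param seed integer seed.
#' @return object of class `outcome_spec`.
#' @export
outcome_spec <- function(kind = c("prevalent-binary", "incident-survival",
                                  "quantitative"),
                         effect = 0, baseline = 0.1, censoring = 0.3,
                         noise_sd = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "prevalent-binary" && (baseline <= 0 || baseline >= 1)) {
    stopf("baseline prevalence must lie in (0, 1)")
  }
  if (censoring < 0 || censoring >= 1) stopf("censoring must lie in [0, 1)")
  structure(list(kind = kind, effect = effect, baseline = baseline,
                 censoring = censoring, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "outcome_spec")
}

# uniform-censoring horizon giving the target null censored fraction for an
# exponential event time with rate lambda: solve P(C < T) = rate
uniform_censor_horizon <- function(lambda, rate) {
  if (rate <= 0) return(Inf)
  # P(censored) = P(C < T) = E[exp(-lambda C)] for C ~ U(0, cmax)
  f <- function(cmax) (1 - exp(-lambda * cmax)) / (lambda * cmax) - rate
  stats::uniroot(f, c(1e-8 / lambda, 1e6 / lambda), tol = 1e-10)$root
}

#' Simulate outcomes from a standardized exposure
#'
#' Prevalent binary outcomes use a logistic link with the stated log OR per
#' 1-SD exposure; incident outcomes use exponential event times with the
#' stated log HR and independent Uniform(0, c_max) censoring, with c_max
#' solved so the null censored fraction equals `censoring`; quantitative
#' outcomes are linear with Gaussian noise. An optional latent confounder
#' (shared with [simulate_trait()]) enters the linear predictor — the
#' generative direction is strictly exposure -> outcome, so causal truths
#' are well-defined.
#'
#' @param exposure standardized numeric exposure.
#' @param covariates optional covariate data frame (used only through
#'   `covariate_effects`).
#' @param spec an [outcome_spec()].
#' @param confounder optional latent vector with `confounder_loading`.
#' @param confounder_loading loading of the latent on the outcome's linear
#'   predictor.
#' @param covariate_effects named list of covariate effects on the linear
#'   predictor.
#' @return data frame: prevalent — `case` (0/1); incident — `time`,
#'   `event` (1 = event, 0 = censored); quantitative — `value`. The spec is
#'   attached as attribute `truth`.
#' @export
simulate_outcomes <- function(exposure, covariates = NULL, spec,
                              confounder = NULL, confounder_loading = 0,
                              covariate_effects = list()) {
  stopifnot(inherits(spec, "outcome_spec"))
  n <- length(exposure)
  lp_extra <- numeric(n)
  for (nm in names(covariate_effects)) {
    lp_extra <- lp_extra + covariate_effects[[nm]] * as.numeric(covariates[[nm]])
  }
  if (!is.null(confounder)) lp_extra <- lp_extra + confounder_loading * confounder
  out <- with_seed(spec$seed, {
    if (spec$kind == "prevalent-binary") {
      lp <- stats::qlogis(spec$baseline) + spec$effect * exposure + lp_extra
      data.frame(case = stats::rbinom(n, 1, stats::plogis(lp)))
    } else if (spec$kind == "incident-survival") {
      rate <- spec$baseline * exp(spec$effect * exposure + lp_extra)
      t_event <- stats::rexp(n, rate)
      cmax <- uniform_censor_horizon(spec$baseline, spec$censoring)
      c_cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
      data.frame(time = pmin(t_event, c_cens),
                 event = as.integer(t_event <= c_cens))
    } else {
      data.frame(value = spec$baseline + spec$effect * exposure + lp_extra +
                   stats::rnorm(n, sd = spec$noise_sd))
    }
  })
  attr(out, "truth") <- list(spec = spec,
                             confounder_loading = confounder_loading,
                             covariate_effects = covariate_effects)
  out
}

#' Simulate a phenotype panel for PheWAS-style scans
#'
#' Builds `n_outcomes` outcomes of the given class from a standardized
#' exposure; all are null except those named in `effects` (outcome index ->
#' true effect). Returns the panel structure [phewas_scan()] consumes.
#'
#' @param exposure standardized exposure vector.
#' @param n_outcomes number of outcomes.
#' @param kind outcome class for the whole panel.
#' @param effects named numeric vector, e.g. `c("1" = 0.4)`: true effect
#'   for outcome 1, others null.
#' @param baseline baseline prevalence / hazard.
#' @param censoring censored fraction for survival outcomes.
#' @param seed integer seed.
#' @return list of outcomes; each element has `id`, `kind`, and the outcome
#'   columns (`case`, or `time` + `event`, or `value`).
#' @export
simulate_phenotype_panel <- function(exposure, n_outcomes = 100L,
                                     kind = "prevalent-binary",
                                     effects = numeric(0), baseline = 0.1,
                                     censoring = 0.3, seed = 1L) {
  lapply(seq_len(n_outcomes), function(i) {
    eff <- if (as.character(i) %in% names(effects)) {
      effects[[as.character(i)]]
    } else {
      0
    }
    sp <- outcome_spec(kind, effect = eff, baseline = baseline,
                       censoring = censoring,
                       seed = derive_seed(seed, paste0("out", i)))
    tab <- simulate_outcomes(exposure, spec = sp)
    c(list(id = sprintf("phe%03d", i), kind = kind), as.list(tab))
  })
}

#' Write a simulated cohort to TSV files
#'
#' Genotypes as a variants x participants dosage TSV, covariates and traits
#' as column-documented TSVs, plus a truth TSV sufficient to re-run the
#' simulation bit-identically.
#'
#' @param genotypes,covariates,trait outputs of the simulators above.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(genotypes, covariates, trait, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- t(genotypes$dosages)
  gdf <- data.frame(variant = genotypes$variant_ids, maf = genotypes$maf)
  gdf <- cbind(gdf, as.data.frame(gt))
  names(gdf)[-(1:2)] <- sprintf("id%05d", seq_len(nrow(genotypes$dosages)))
  f1 <- file.path(dir, "genotypes.tsv")
  utils::write.table(gdf, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  f2 <- file.path(dir, "covariates.tsv")
  utils::write.table(cbind(id = sprintf("id%05d", seq_len(nrow(covariates))),
                           covariates),
                     f2, sep = "\t", row.names = FALSE, quote = FALSE)
  f3 <- file.path(dir, "trait.tsv")
  utils::write.table(data.frame(id = sprintf("id%05d",
                                             seq_along(trait$trait)),
                                trait = trait$trait),
                     f3, sep = "\t", row.names = FALSE, quote = FALSE)
  f4 <- file.path(dir, "truth.tsv")
  ar <- trait$truth$arch
  if (length(ar$causal_ids) == 0) {
    ar$causal_ids <- NA_character_
    ar$effects <- NA_real_
  }
  utils::write.table(data.frame(variant = ar$causal_ids, effect = ar$effects,
                                residual_sd = ar$residual_sd,
                                confounder_loading = ar$confounder_loading,
                                seed = trait$truth$seed,
                                scale = trait$truth$scale),
                     f4, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3, f4))
}

#' Minimal VCF writer for simulated genotypes
#'
#' GT-only, diploid, unphased; dosage d becomes 0/0, 0/1 or 1/1 on a dummy
#' single contig. Provided for interoperability with standard tooling.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output `.vcf` path (uncompressed).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  n <- nrow(genotypes$dosages)
  ids <- sprintf("id%05d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes$dosages))) {
    row <- paste(c("1", j, genotypes$variant_ids[j], "A", "G", ".", "PASS",
                   ".", "GT", gtmap[genotypes$dosages[, j] + 1L]),
                 collapse = "\t")
    writeLines(row, con)
  }
  invisible(path)
}

#' Minimal VCF reader for GT-only diploid genotypes
#'
#' Parses an uncompressed VCF with GT as the first FORMAT field and counts
#' ALT alleles per genotype (unphased `/` or phased `|` separators;
#' genotypes with a missing allele become `NA`). Returns the same
#' `genotype_matrix` structure the simulators produce, with per-variant
#' empirical allele frequencies in `maf`.
#'
#' @param path path to an uncompressed `.vcf`.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10 || header[1] != "#CHROM" || header[9] != "FORMAT") {
    stopf("not a genotype VCF: need #CHROM..FORMAT + sample columns")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[[`, "", 3L)
  n <- length(header) - 9L
  dos <- matrix(NA_integer_, n, length(rows))
  for (j in seq_along(rows)) {
    gt <- sub(":.*$", "", rows[[j]][10:(9L + n)])
    alleles <- strsplit(gt, "[/|]")
    dos[, j] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, 0L)
  }
  colnames(dos) <- ids
  af <- colMeans(dos, na.rm = TRUE) / 2
  structure(list(dosages = dos, maf = pmin(af, 1 - af), variant_ids = ids),
            class = "genotype_matrix")
}
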