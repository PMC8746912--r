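# Desk-scale genetics: per-variant linear-regression GWAS, polygenic score
# construction, PRS-PheWAS, and one-sample Mendelian randomization via
# two-stage least squares with a PRS instrument.

covariate_model_matrix <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
}

#' Per-variant GWAS scan (linear regression)
#'
#' For each variant, ordinary least squares of the standardized trait on
#' dosage plus covariates. Implemented by the Frisch-Waugh-Lovell
#' residualization: trait and dosages are residualized on the covariates
#' once, and each variant's beta, SE and p follow from the residual simple
#' regression with the covariate degrees of freedom removed — algebraically
#' identical to the full joint fit. Variants with empirical MAF at or below
#' `maf_min` are dropped and counted; constant-dosage variants are dropped
#' with a log entry.
#'
#' @param genotypes a `genotype_matrix`.
#' @param trait standardized numeric trait.
#' @param covariates covariate data frame (or `NULL`).
#' @param maf_min minimum minor-allele frequency (default 0.001).
#' @return data frame sorted by variant id: variant, effect_allele, beta,
#'   se, p, maf, n. Attributes `n_dropped_maf` and `dropped_constant`
#'   record the filters.
#' @export
gwas_scan <- function(genotypes, trait, covariates = NULL, maf_min = 0.001) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$dosages
  n <- nrow(g)
  stopifnot(length(trait) == n)
  if (maf_min < 0) stopf("maf_min must be >= 0")
  emp_af <- colMeans(g) / 2
  emp_maf <- pmin(emp_af, 1 - emp_af)
  const <- apply(g, 2, function(v) stats::var(v) == 0)
  keep_maf <- emp_maf > maf_min
  keep <- keep_maf & !const
  n_dropped_maf <- sum(!keep_maf)
  dropped_constant <- colnames(g)[const & keep_maf]
  if (length(dropped_constant)) {
    message(sprintf("gwas_scan: dropped %d constant-dosage variant(s)",
                    length(dropped_constant)))
  }
  gk <- g[, keep, drop = FALSE]
  cm <- covariate_model_matrix(covariates, n)
  qc <- qr(cm)
  ry <- qr.resid(qc, trait)
  rg <- qr.resid(qc, gk)
  sxx <- colSums(rg^2)
  sxy <- as.numeric(crossprod(rg, ry))
  beta <- sxy / sxx
  df <- n - ncol(cm) - 1L
  rss <- sum(ry^2) - beta * sxy   # residual SS of the full model, per variant
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(variant = colnames(gk), effect_allele = "ALT",
                    beta = beta, se = se, p = p, maf = emp_maf[keep], n = n,
                    row.names = NULL)
  out <- out[order(out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_maf") <- n_dropped_maf
  attr(out, "dropped_constant") <- dropped_constant
  out
}

#' Select genome-wide-significant variants into a PRS model
#'
#' Variants with p below the threshold are kept with their effect-allele
#' betas as weights. Under the simulator's linkage equilibrium, independence
#' pruning is a no-op and is recorded as such in the provenance; a greedy
#' |r| pruner for real (correlated) genotypes is available via `prune_r`.
#'
#' @param rows GWAS summary rows from [gwas_scan()].
#' @param threshold p-value threshold (default 5e-8).
#' @param prune_r optional n x m dosage matrix; when supplied, selected
#'   variants correlated at |r| > 0.1 with an already-kept variant are
#'   greedily dropped (strongest-p first).
#' @return object of class `prs_model`: `variants`, `weights`,
#'   `provenance`. Empty selection yields an empty model with a warning.
#' @export
select_significant <- function(rows, threshold = 5e-8, prune_r = NULL) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  sel <- rows[rows$p < threshold, , drop = FALSE]
  pruned <- character(0)
  if (!is.null(prune_r) && nrow(sel) > 1) {
    sel <- sel[order(sel$p), , drop = FALSE]
    kept <- logical(nrow(sel))
    for (i in seq_len(nrow(sel))) {
      gi <- prune_r[, sel$variant[i]]
      ok <- TRUE
      for (j in which(kept)) {
        if (abs(stats::cor(gi, prune_r[, sel$variant[j]])) > 0.1) {
          ok <- FALSE
          break
        }
      }
      kept[i] <- ok
    }
    pruned <- sel$variant[!kept]
    sel <- sel[kept, , drop = FALSE]
  }
  if (nrow(sel) == 0) warnf("no variants pass p < %g; empty PRS model", threshold)
  structure(list(variants = sel$variant, weights = sel$beta,
                 provenance = list(threshold = threshold,
                                   n_selected = nrow(sel),
                                   pruning = if (is.null(prune_r))
                                     "no-op (linkage equilibrium)" else
                                       sprintf("greedy |r|>0.1, %d pruned",
                                               length(pruned)))),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> %d variants (p < %g; pruning: %s)\n",
              length(x$variants), x$provenance$threshold,
              x$provenance$pruning))
  invisible(x)
}

#' Read / write a PRS model as a two-column TSV (variant, weight)
#' @param model a `prs_model`.
#' @param path file path.
#' @return `write_prs_model` returns `path` invisibly; `read_prs_model` a
#'   `prs_model`.
#' @export
write_prs_model <- function(model, path) {
  utils::write.table(data.frame(variant = model$variants,
                                weight = model$weights),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prs_model
#' @export
read_prs_model <- function(path) {
  d <- utils::read.delim(path)
  structure(list(variants = d$variant, weights = d$weight,
                 provenance = list(threshold = NA, n_selected = nrow(d),
                                   pruning = "loaded from file")),
            class = "prs_model")
}

#' Per-participant polygenic score
#'
#' score_i = sum_j w_j * dosage_ij over the model's variants. Missing
#' dosages are mean-imputed per variant.
#'
#' @param genotypes a `genotype_matrix`.
#' @param model a `prs_model`.
#' @return numeric score vector (length n).
#' @export
build_prs <- function(genotypes, model) {
  stopifnot(inherits(model, "prs_model"))
  if (length(model$variants) == 0) return(numeric(nrow(genotypes$dosages)))
  miss <- setdiff(model$variants, genotypes$variant_ids)
  if (length(miss)) stopf("PRS variants missing from genotypes: %s",
                          paste(miss, collapse = ", "))
  d <- genotypes$dosages[, model$variants, drop = FALSE]
  if (anyNA(d)) {
    for (j in seq_len(ncol(d))) {
      mj <- is.na(d[, j])
      if (any(mj)) d[mj, j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  as.numeric(d %*% model$weights)
}

#' One-sample Mendelian randomization (two-stage least squares)
#'
#' Stage 1 regresses the exposure on the PRS instrument plus covariates;
#' stage 2 regresses the outcome on the stage-1 fitted exposure plus
#' covariates, with the standard 2SLS variance (structural residuals
#' evaluated at the observed exposure). The estimate is rescaled to
#' `exposure_scale` exposure units (e.g. 10 for "per 10 mm Hg"; use
#' `log(2)` on a genetic log-odds exposure for "per 2-fold higher genetic
#' risk"). The first-stage partial F statistic for the instrument is
#' reported; results below `weak_f` are flagged.
#'
#' @param score PRS instrument vector.
#' @param exposure exposure measured in the same participants.
#' @param outcome numeric outcome vector.
#' @param covariates covariate data frame (or `NULL`).
#' @param exposure_scale exposure units the effect is reported per
#'   (default 1).
#' @param weak_f weak-instrument flag floor for the first-stage F
#'   (default 10).
#' @return object of class `mr_estimate`: `estimate` (outcome units per
#'   `exposure_scale` exposure units), `se`, `p`, `first_stage_f`,
#'   `exposure_scale`, `flags`, `n`.
#' @export
one_sample_mr <- function(score, exposure, outcome, covariates = NULL,
                          exposure_scale = 1, weak_f = 10) {
  n <- length(exposure)
  stopifnot(length(score) == n, length(outcome) == n)
  if (stats::sd(score) == 0) stopf("instrument (PRS) has zero variance")
  cm <- covariate_model_matrix(covariates, n)
  w1 <- cbind(score = score, cm)
  f1 <- stats::lm.fit(w1, exposure)
  xhat <- exposure - f1$residuals
  # first-stage partial F for the instrument
  f0 <- stats::lm.fit(cm, exposure)
  rss1 <- sum(f1$residuals^2)
  rss0 <- sum(f0$residuals^2)
  df2 <- n - ncol(w1)
  fstat <- (rss0 - rss1) / (rss1 / df2)
  w2 <- cbind(xhat = xhat, cm)
  f2 <- stats::lm.fit(w2, outcome)
  b <- f2$coefficients["xhat"]
  # 2SLS variance: residuals at the observed exposure, not the fitted one
  coefs <- f2$coefficients
  coefs[is.na(coefs)] <- 0
  resid_struct <- outcome - cbind(exposure, cm) %*% coefs
  sigma2 <- sum(resid_struct^2) / (n - ncol(w2))
  xtx_inv <- chol2inv(chol(crossprod(w2)))
  se <- sqrt(sigma2 * xtx_inv[1, 1])
  est <- unname(b) * exposure_scale
  se_s <- se * abs(exposure_scale)
  p <- 2 * stats::pnorm(abs(est / se_s), lower.tail = FALSE)
  flags <- if (fstat < weak_f) "weak-instrument" else character(0)
  structure(list(estimate = est, se = se_s, p = p, first_stage_f = fstat,
                 exposure_scale = exposure_scale, flags = flags, n = n),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(paste0("<mr_estimate> %.4f (SE %.4f) per %g exposure unit(s),",
                     " p = %.3g, first-stage F = %.1f%s\n"),
              x$estimate, x$se, x$exposure_scale, x$p, x$first_stage_f,
              if (length(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' PRS-PheWAS: associate a polygenic score with a phenotype panel
#'
#' The score is standardized and scanned against the panel exactly like a
#' measured exposure (logistic / Cox / linear with covariates, BH-FDR
#' across the scan); effects are reported per 1-SD score in both
#' directions.
#'
#' @param score PRS vector (must have nonzero variance).
#' @param panel phenotype panel as in [phewas_scan()].
#' @param covariates covariate data frame (or `NULL`).
#' @param min_cases minimum case count per outcome.
#' @return data frame as from [phewas_scan()].
#' @export
prs_phewas <- function(score, panel, covariates = NULL, min_cases = 20L) {
  if (stats::sd(score) == 0) stopf("PRS has zero variance")
  z <- (score - mean(score)) / stats::sd(score)
  phewas_scan(z, panel, covariates, min_cases)
}

#' Write GWAS summary statistics as TSV
#'
#' Columns variant, effect_allele, beta, se, p, maf, n — the common
#' summary-statistics convention.
#'
#' @param rows data frame from [gwas_scan()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_gwas_sumstats <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
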