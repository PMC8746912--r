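# The PheWAS engine: covariate-adjusted logistic (prevalent), Cox
# (incident) and linear (quantitative) association fits, BH-FDR across a
# scan, and stratified analysis with Cochran-Q heterogeneity.

default_covariate_formula <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) return("1")
  paste(colnames(covariates), collapse = " + ")
}

flag_fit_problems <- function(fit, kind) {
  flags <- character(0)
  if (kind == "logistic") {
    if (!isTRUE(fit$converged)) flags <- c(flags, "non-convergence")
    if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      flags <- c(flags, "possible-separation")
    }
  } else if (kind == "cox") {
    if (!is.null(fit$info) && grepl("infinite", fit$info %||% "")) {
      flags <- c(flags, "non-convergence")
    }
    if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      flags <- c(flags, "possible-separation")
    }
  }
  flags
}

#' Fit one exposure-outcome association with covariate adjustment
#'
#' Prevalent binary outcomes use logistic regression (effect = log OR),
#' incident outcomes a Cox proportional-hazards model with Efron tie
#' handling (effect = log HR), and quantitative outcomes ordinary least
#' squares (effect = beta). Continuous exposures are analysed per 1 SD
#' (standardized internally unless already standardized); binary 0/1
#' exposures are analysed per flag. The negated effect is reported too, so
#' "per 1-SD decrease" effects are available without re-fitting.
#'
#' @param exposure numeric exposure (continuous, or 0/1 flag).
#' @param outcome for `kind = "logistic"` a 0/1 vector; for `"cox"` a data
#'   frame/list with `time` and `event`; for `"linear"` a numeric vector.
#' @param covariates data frame of adjustment covariates (or `NULL`).
#' @param kind `"logistic"`, `"cox"` or `"linear"`.
#' @param outcome_id identifier carried into the result.
#' @return object of class `assoc_result`: `effect` (per 1-SD increase or
#'   per flag), `effect_decrease` (= -effect), `se`, `p`, `n`, `events`
#'   (Cox only), `kind`, `flags` (character vector; empty when clean).
#' @export
fit_association <- function(exposure, outcome, covariates = NULL,
                            kind = c("logistic", "cox", "linear"),
                            outcome_id = "outcome") {
  kind <- match.arg(kind)
  if (stats::sd(exposure, na.rm = TRUE) == 0) stopf("exposure has zero variance")
  is_flag <- all(exposure %in% c(0, 1, NA))
  x <- if (is_flag) {
    as.numeric(exposure)
  } else {
    s <- stats::sd(exposure, na.rm = TRUE)
    if (s == 0) stopf("exposure has zero variance")
    (exposure - mean(exposure, na.rm = TRUE)) / s
  }
  dat <- data.frame(.x = x)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  rhs <- paste(c(".x", if (!is.null(covariates)) colnames(covariates)),
               collapse = " + ")
  if (kind == "cox") {
    dat$.time <- outcome$time
    dat$.event <- outcome$event
    cc <- stats::complete.cases(dat)
    dat <- dat[cc, , drop = FALSE]
    if (any(dat$.time < 0)) stopf("negative survival times")
    n_par <- length(attr(stats::terms(
      stats::as.formula(paste("~", rhs))), "term.labels")) + 1L
    if (nrow(dat) < 10 * n_par) stopf("fewer than 10 complete cases per parameter")
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
      data = dat, ties = "efron")
    sm <- summary(fit)$coefficients
    eff <- sm[".x", "coef"]; se <- sm[".x", "se(coef)"]
    p <- sm[".x", "Pr(>|z|)"]
    events <- sum(dat$.event)
  } else {
    dat$.y <- as.numeric(if (is.data.frame(outcome)) outcome[[1]] else outcome)
    cc <- stats::complete.cases(dat)
    dat <- dat[cc, , drop = FALSE]
    fml <- stats::as.formula(paste(".y ~", rhs))
    if (nrow(dat) < 10 * (ncol(dat))) stopf("fewer than 10 complete cases per parameter")
    fit <- if (kind == "logistic") {
      stats::glm(fml, data = dat, family = stats::binomial())
    } else {
      stats::lm(fml, data = dat)
    }
    sm <- summary(fit)$coefficients
    eff <- sm[".x", 1]; se <- sm[".x", 2]; p <- sm[".x", 4]
    events <- NA_integer_
  }
  flags <- if (kind == "linear") character(0) else flag_fit_problems(fit, kind)
  structure(list(outcome_id = outcome_id, kind = kind,
                 effect = unname(eff), effect_decrease = -unname(eff),
                 se = unname(se), p = unname(p), n = nrow(dat),
                 events = events, exposure_scale = if (is_flag) "flag" else "per-sd",
                 flags = flags),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s [%s]: effect %.4f (SE %.4f), p = %.3g, n = %d%s%s\n",
              x$outcome_id, x$kind, x$effect, x$se, x$p, x$n,
              if (!is.na(x$events)) sprintf(", events = %d", x$events) else "",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving with respect to input
#' positions. Thin validated wrapper over the standard step-up procedure.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Phenome-wide association scan
#'
#' One fit per outcome in the panel: prevalent -> logistic, incident -> Cox
#' (participants whose first diagnosis of that outcome predates acquisition
#' are excluded from its risk set), quantitative -> linear. BH-FDR is
#' applied across the scan (per exposure). Outcomes with fewer than
#' `min_cases` cases/events are skipped and recorded in the `skipped`
#' attribute.
#'
#' @param exposure numeric exposure (standardized internally when
#'   continuous).
#' @param panel list of outcomes as from [simulate_phenotype_panel()]: each
#'   element needs `id`, `kind` (`"prevalent-binary"`, `"incident-survival"`
#'   or `"quantitative"`), and its outcome columns (`case`; `time`+`event`
#'   with optional `prevalent` exclusion flag; `value`).
#' @param covariates covariate data frame (or `NULL`).
#' @param min_cases minimum case/event count per binary/survival outcome
#'   (default 20).
#' @return data frame, one row per outcome: outcome_id, kind, effect,
#'   effect_decrease, se, p, n, events, fdr_q, flags. Attribute `skipped`
#'   lists skipped outcome ids with reasons.
#' @export
phewas_scan <- function(exposure, panel, covariates = NULL, min_cases = 20L) {
  rows <- list()
  skipped <- list()
  for (out in panel) {
    kind <- switch(out$kind,
                   "prevalent-binary" = "logistic",
                   "incident-survival" = "cox",
                   "quantitative" = "linear",
                   stopf("unknown outcome kind '%s'", out$kind))
    expo <- exposure
    res <- tryCatch({
      if (kind == "logistic") {
        if (sum(out$case) < min_cases) stopf("fewer than %d cases", min_cases)
        fit_association(expo, out$case, covariates, "logistic", out$id)
      } else if (kind == "cox") {
        keep <- rep(TRUE, length(expo))
        if (!is.null(out$prevalent)) keep <- !(out$prevalent > 0)
        tab <- list(time = out$time[keep], event = out$event[keep])
        if (sum(tab$event) < min_cases) stopf("fewer than %d events", min_cases)
        fit_association(expo[keep], tab,
                        if (is.null(covariates)) NULL else
                          covariates[keep, , drop = FALSE],
                        "cox", out$id)
      } else {
        fit_association(expo, out$value, covariates, "linear", out$id)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(outcome_id = out$id, reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(outcome_id = res$outcome_id, kind = res$kind,
                   effect = res$effect, effect_decrease = res$effect_decrease,
                   se = res$se, p = res$p, n = res$n, events = res$events,
                   flags = paste(res$flags, collapse = ";"))
    }
  }
  out_tbl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(outcome_id = character(0), kind = character(0),
               effect = numeric(0), effect_decrease = numeric(0),
               se = numeric(0), p = numeric(0), n = integer(0),
               events = integer(0), flags = character(0))
  if (nrow(out_tbl)) out_tbl$fdr_q <- bh_fdr(out_tbl$p)
  attr(out_tbl, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(outcome_id = character(0), reason = character(0))
  out_tbl
}

#' Cochran's Q heterogeneity across stratum effects
#'
#' Q = sum w_i (b_i - b_w)^2 with inverse-variance weights w_i = 1/SE_i^2;
#' the p-value is from a chi-square with (strata - 1) degrees of freedom.
#'
#' @param effects stratum effect estimates.
#' @param ses stratum standard errors.
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(effects, ses) {
  stopifnot(length(effects) == length(ses), all(ses > 0))
  w <- 1 / ses^2
  bw <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - bw)^2)
  df <- length(effects) - 1L
  list(Q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

# joint likelihood-ratio test of all exposure x stratum interaction terms
interaction_heterogeneity <- function(exposure, outcome, covariates, strata,
                                      kind) {
  dat <- data.frame(.x = exposure, .s = as.factor(strata))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  cov_rhs <- if (is.null(covariates)) character(0) else colnames(covariates)
  rhs0 <- paste(c(".x", ".s", cov_rhs), collapse = " + ")
  rhs1 <- paste(c(".x * .s", cov_rhs), collapse = " + ")
  if (kind == "cox") {
    dat$.time <- outcome$time
    dat$.event <- outcome$event
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    f0 <- survival::coxph(stats::as.formula(
      paste("survival::Surv(.time, .event) ~", rhs0)), data = dat,
      ties = "efron")
    f1 <- survival::coxph(stats::as.formula(
      paste("survival::Surv(.time, .event) ~", rhs1)), data = dat,
      ties = "efron")
    stat <- 2 * (f1$loglik[2] - f0$loglik[2])
  } else {
    dat$.y <- as.numeric(if (is.data.frame(outcome)) outcome[[1]] else outcome)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fam <- if (kind == "logistic") stats::binomial() else stats::gaussian()
    f0 <- stats::glm(stats::as.formula(paste(".y ~", rhs0)), data = dat,
                     family = fam)
    f1 <- stats::glm(stats::as.formula(paste(".y ~", rhs1)), data = dat,
                     family = fam)
    stat <- if (kind == "logistic") {
      f0$deviance - f1$deviance
    } else {
      # Gaussian: LRT on the profile likelihood
      nrow(dat) * (log(sum(stats::resid(f0)^2)) -
                     log(sum(stats::resid(f1)^2)))
    }
  }
  df <- nlevels(as.factor(strata)) - 1L
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Stratified association with heterogeneity test
#'
#' Fits the association separately within each stratum and tests
#' between-stratum heterogeneity of the effects. The default test is
#' Cochran's Q on the per-stratum estimates; `method = "interaction"`
#' instead performs a joint likelihood-ratio test of the exposure-by-
#' stratum interaction terms in the pooled model (both conventions exist
#' in the literature and agree asymptotically here). If any stratum fails
#' to fit, the result is flagged `partial` and Q is computed over the
#' strata that did fit.
#'
#' @param exposure exposure vector (e.g. a low-FD flag).
#' @param outcome outcome as in [fit_association()].
#' @param covariates covariate data frame (or `NULL`).
#' @param strata factor/vector of stratum labels (>= 2 strata).
#' @param kind model kind as in [fit_association()].
#' @param method `"cochran-q"` (default) or `"interaction"`.
#' @return object of class `stratified_result`: `strata` (named list of
#'   `assoc_result`), `Q`, `df`, `heterogeneity_p` (from the chosen
#'   method), `method`, `partial`.
#' @export
stratified_association <- function(exposure, outcome, covariates = NULL,
                                   strata,
                                   kind = c("logistic", "cox", "linear"),
                                   method = c("cochran-q", "interaction")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  strata <- as.factor(strata)
  if (nlevels(strata) < 2) stopf("need at least 2 strata")
  fits <- list()
  partial <- FALSE
  for (lev in levels(strata)) {
    sel <- strata == lev
    res <- tryCatch({
      out_s <- if (kind == "cox") {
        list(time = outcome$time[sel], event = outcome$event[sel])
      } else if (is.data.frame(outcome)) {
        outcome[sel, 1]
      } else {
        outcome[sel]
      }
      fit_association(exposure[sel], out_s,
                      if (is.null(covariates)) NULL else
                        covariates[sel, , drop = FALSE],
                      kind, outcome_id = lev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      partial <- TRUE
    } else {
      fits[[lev]] <- res
    }
  }
  if (length(fits) < 2) stopf("fewer than 2 strata could be fitted")
  qq <- cochran_q(vapply(fits, `[[`, 0.0, "effect"),
                  vapply(fits, `[[`, 0.0, "se"))
  het_p <- if (method == "interaction") {
    interaction_heterogeneity(exposure, outcome, covariates, strata, kind)$p
  } else {
    qq$p
  }
  structure(list(strata = fits, Q = qq$Q, df = qq$df,
                 heterogeneity_p = het_p, method = method,
                 partial = partial),
            class = "stratified_result")
}

#' @export
print.stratified_result <- function(x, ...) {
  cat(sprintf("<stratified_result> %d strata, Q = %.3f (df %d), p_het = %.3g%s\n",
              length(x$strata), x$Q, x$df, x$heterogeneity_p,
              if (x$partial) " [partial]" else ""))
  for (f in x$strata) print(f)
  invisible(x)
}
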