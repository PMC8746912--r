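# Vascular quantification: box-counting fractal dimension, vascular density,
# per-participant eye aggregation, laterality statistics, cohort z-scoring.

#' Configuration for box-counting fractal dimension
#'
#' Box sizes are the dyadic set \{2, 4, ..., s_max\} with s_max the largest
#' power of two not exceeding `min(H, W) / 4`; at least `min_sizes` distinct
#' sizes are required for the log-log fit. With the default origin-aligned
#' grid, dyadic boxes nest, which guarantees the box count N(s) is
#' non-increasing in s. `offset_policy = "best-of-offsets"` instead takes,
#' for each size, the minimum count over 4 half-box grid shifts (a common
#' variance-reduction variant).
#'
#' @param offset_policy `"origin"` (default) or `"best-of-offsets"`.
#' @param min_sizes minimum number of distinct box sizes (default 4).
#' @param skeletonize if `TRUE`, thin the mask to a 1-pixel skeleton before
#'   counting (default `FALSE`: FD is computed on the full-width mask).
#' @return object of class `fd_config`.
#' @export
fd_config <- function(offset_policy = c("origin", "best-of-offsets"),
                      min_sizes = 4L, skeletonize = FALSE) {
  structure(list(offset_policy = match.arg(offset_policy),
                 min_sizes = as.integer(min_sizes),
                 skeletonize = isTRUE(skeletonize)),
            class = "fd_config")
}

#' Morphological skeletonization (Zhang–Suen thinning)
#'
#' Iteratively peels boundary pixels while preserving connectivity until
#' the mask is a 1-pixel-wide skeleton. Used by the optional
#' skeletonize-before-FD configuration.
#'
#' @param mask H x W logical mask.
#' @return logical mask of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  m <- mask > 0
  shift <- function(x, dr, dc) {
    h <- nrow(x); w <- ncol(x)
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # clockwise 8-neighbourhood starting north
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      if (sub == 1) {
        c1 <- !(p2 & p4 & p6); c2 <- !(p4 & p6 & p8)
      } else {
        c1 <- !(p2 & p4 & p8); c2 <- !(p2 & p6 & p8)
      }
      del <- m & b >= 2 & b <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

box_sizes_for <- function(h, w) {
  s_max <- 2^floor(log2(min(h, w) / 4))
  if (s_max < 2) return(integer(0))
  2^(1:log2(s_max))
}

count_boxes <- function(coords, h, w, s, offsets = list(c(0L, 0L))) {
  best <- Inf
  for (off in offsets) {
    ri <- (coords[, 1] - 1L + off[1]) %/% s
    ci <- (coords[, 2] - 1L + off[2]) %/% s
    n <- length(unique(ri * (((w + s) %/% s) + 2L) + ci))
    if (n < best) best <- n
  }
  best
}

#' Box-counting (Minkowski–Bouligand) fractal dimension of a vessel mask
#'
#' For each box size s, N(s) is the number of s x s grid cells containing at
#' least one vessel pixel; the dimension is the ordinary-least-squares slope
#' of log N(s) on log(1/s). Expected range for retinal vessel masks is
#' roughly 1 (a single vessel) to 2 (a space-filling network).
#'
#' @param mask H x W logical vessel mask.
#' @param fov optional H x W logical field of view; vessel pixels outside it
#'   are ignored.
#' @param config an [fd_config()].
#' @return object of class `fd_result`: list with `fd`, `r2` of the log-log
#'   fit, and `counts` (data frame of s and N(s), returned for audit).
#' @export
box_counting_fd <- function(mask, fov = NULL, config = fd_config()) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (!is.null(fov)) mask <- mask & fov
  if (!any(mask)) stopf("FD undefined: empty vessel mask")
  if (config$skeletonize) {
    mask <- skeletonize_mask(mask)
  }
  h <- nrow(mask); w <- ncol(mask)
  sizes <- box_sizes_for(h, w)
  if (length(sizes) < config$min_sizes) {
    stopf("only %d usable box sizes (need >= %d); mask too small",
          length(sizes), config$min_sizes)
  }
  coords <- which(mask, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    offs <- if (config$offset_policy == "origin") {
      list(c(0L, 0L))
    } else {
      hs <- as.integer(s %/% 2)
      list(c(0L, 0L), c(hs, 0L), c(0L, hs), c(hs, hs))
    }
    count_boxes(coords, h, w, s, offs)
  }, 0)
  if (config$offset_policy == "origin" && any(diff(counts) > 0)) {
    stopf("internal error: N(s) not non-increasing in s")  # nocov
  }
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  # a perfect log-log line (e.g. an exact 1-D fixture) is legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(fd = unname(stats::coef(fit)[2]),
                 r2 = r2,
                 counts = data.frame(s = sizes, n = counts)),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> fd = %.4f (log-log R^2 = %.4f, %d box sizes)\n",
              x$fd, x$r2, nrow(x$counts)))
  invisible(x)
}

#' Vascular density within the field of view
#'
#' Density is the number of segmented vessel pixels under a consistent field
#' of view; it is reported both as the raw count and as the fraction of FOV
#' pixels (the two are proportional at fixed FOV; downstream analyses use
#' the fraction).
#'
#' @param mask H x W logical vessel mask.
#' @param fov H x W logical field-of-view mask (must be nonempty).
#' @return list with `count` and `fraction`.
#' @export
vascular_density <- function(mask, fov) {
  stopifnot(identical(dim(mask), dim(fov)))
  nf <- sum(fov)
  if (nf == 0) stopf("empty field of view")
  cnt <- sum(mask & fov)
  list(count = cnt, fraction = cnt / nf)
}

#' Per-eye vascular metrics for one image
#'
#' @param mask,fov as in [vascular_density()].
#' @param participant,eye identifiers carried into the output row.
#' @param fd_cfg an [fd_config()].
#' @return one-row data frame: participant, eye, fd, fd_r2, density,
#'   vessel_px, fov_px.
#' @export
eye_metrics <- function(mask, fov, participant, eye, fd_cfg = fd_config()) {
  fd <- box_counting_fd(mask, fov, fd_cfg)
  dn <- vascular_density(mask, fov)
  data.frame(participant = participant, eye = eye, fd = fd$fd, fd_r2 = fd$r2,
             density = dn$fraction, vessel_px = dn$count, fov_px = sum(fov))
}

#' Aggregate per-eye metrics to per-participant means
#'
#' Arithmetic mean of FD and density over the available eyes (1 or 2);
#' single-eye participants keep their single value. Participants with
#' duplicate eye labels are an input error; participants with zero eyes are
#' simply absent from the input and hence the output.
#'
#' @param eye_tbl data frame as produced by rbind-ing [eye_metrics()] rows.
#' @return data frame: participant, fd_mean, density_mean, n_eyes.
#' @export
aggregate_eyes <- function(eye_tbl) {
  stopifnot(all(c("participant", "eye", "fd", "density") %in% names(eye_tbl)))
  dup <- duplicated(eye_tbl[, c("participant", "eye")])
  if (any(dup)) {
    stopf("duplicate eye label for participant(s): %s",
          paste(unique(eye_tbl$participant[dup]), collapse = ", "))
  }
  sp <- split(eye_tbl, eye_tbl$participant)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(participant = d$participant[1],
               fd_mean = mean(d$fd), density_mean = mean(d$density),
               n_eyes = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$participant), , drop = FALSE]
}

#' Right-versus-left laterality statistics
#'
#' Spearman correlation between paired right- and left-eye values, and a
#' paired t test on (right - left).
#'
#' @param right,left numeric vectors, paired by participant (same order).
#' @return list with `spearman_rho`, `spearman_p`, `mean_difference`
#'   (right minus left), `t_p`, `n_pairs`.
#' @export
laterality_stats <- function(right, left) {
  ok <- stats::complete.cases(right, left)
  right <- right[ok]; left <- left[ok]
  if (length(right) < 3) stopf("need at least 3 complete right/left pairs")
  sp <- suppressWarnings(
    stats::cor.test(right, left, method = "spearman", exact = FALSE))
  d <- right - left
  if (stats::sd(d) == 0) {
    # zero-variance differences: the paired t is degenerate
    tt <- list(estimate = mean(d), p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt0 <- stats::t.test(right, left, paired = TRUE)
    tt <- list(estimate = unname(tt0$estimate), p.value = tt0$p.value)
  }
  list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       mean_difference = tt$estimate, t_p = tt$p.value,
       n_pairs = length(right))
}

#' Cohort z-scores and low-value flags
#'
#' Standardizes values over the analysis cohort (sample SD, n - 1
#' denominator) and flags values at or below `mean - k * SD` — the "low"
#' tail convention used for dichotomized-exposure analyses (default k = 2).
#'
#' @param x numeric vector (>= 2 distinct values).
#' @param k SD multiplier for the low flag.
#' @return list with `z`, `low` (logical), `mean`, `sd`, `k`.
#' @export
normalize_and_flag <- function(x, k = 2) {
  if (length(unique(x[is.finite(x)])) < 2) {
    stopf("z-scores undefined: fewer than 2 distinct values")
  }
  mu <- mean(x); sdv <- stats::sd(x)
  if (sdv == 0) stopf("z-scores undefined: zero variance")
  list(z = (x - mu) / sdv, low = x <= mu - k * sdv, mean = mu, sd = sdv, k = k)
}

#' Full participant-metrics table from per-eye metrics
#'
#' Aggregates eyes, z-scores FD and density over the cohort, and sets the
#' low-FD / low-density flags at `mean - k * SD`.
#'
#' @param eye_tbl per-eye metrics table.
#' @param k SD multiplier for the low flags (default 2).
#' @return data frame: participant, fd_mean, density_mean, n_eyes, fd_z,
#'   density_z, low_fd, low_density.
#' @export
participant_metrics <- function(eye_tbl, k = 2) {
  agg <- aggregate_eyes(eye_tbl)
  fdn <- normalize_and_flag(agg$fd_mean, k)
  dnn <- normalize_and_flag(agg$density_mean, k)
  agg$fd_z <- fdn$z
  agg$density_z <- dnn$z
  agg$low_fd <- fdn$low
  agg$low_density <- dnn$low
  agg
}
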