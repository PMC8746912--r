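# Vessel segmentation: an ensemble of U-Nets trained on image/mask pairs,
# ensemble-averaged probability maps, binarization, and overlap metrics.

#' Segmentation ensemble configuration
#'
#' Members share architecture and data and differ only by seed and shuffle
#' order; the ensemble prediction is the arithmetic mean of the member
#' probability maps. The training patch size must be a multiple of
#' `2^depth`.
#'
#' @param ensemble_size number of U-Net members K (>= 1, default 3).
#' @param depth U-Net depth (number of poolings, default 3).
#' @param base base channel count (default 8).
#' @param patch patch size for random-crop training (default 64).
#' @param epochs passes over the training set per member (default 3).
#' @param lr Adam learning rate.
#' @param pos_weight vessel-pixel weight in the binary cross-entropy
#'   (vessels are the minority class).
#' @param augment if `TRUE`, random flips and 90-degree rotations.
#' @param seeds optional integer vector of per-member seeds (default
#'   `1:K`).
#' @return object of class `seg_config`.
#' @export
seg_config <- function(ensemble_size = 3L, depth = 3L, base = 8L,
                       patch = 64L, epochs = 3L, lr = 1e-3, pos_weight = 2,
                       augment = TRUE, seeds = NULL) {
  if (ensemble_size < 1) stopf("ensemble_size must be >= 1")
  if (patch %% 2^depth != 0) {
    stopf("patch size (%d) must be a multiple of 2^depth (%d)", patch, 2^depth)
  }
  if (is.null(seeds)) seeds <- seq_len(ensemble_size)
  stopifnot(length(seeds) == ensemble_size)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 depth = as.integer(depth), base = as.integer(base),
                 patch = as.integer(patch), epochs = as.integer(epochs),
                 lr = lr, pos_weight = pos_weight, augment = isTRUE(augment),
                 seeds = as.integer(seeds)),
            class = "seg_config")
}

# standardized green channel as a 1-channel array
seg_preprocess <- function(image) {
  px <- if (inherits(image, "fundus_image")) image$pixels else image
  if (length(dim(px)) == 3) px <- px[, , 2]
  s <- stats::sd(px)
  array((px - mean(px)) / if (s > 0) s else 1, c(dim(px), 1L))
}

seg_augment <- function(x, t, code) {
  # code 0..7: 4 rotations x optional horizontal flip, applied to both
  rot90a <- function(a) {
    d <- dim(a)
    array(aperm(a[d[1]:1, , , drop = FALSE], c(2, 1, 3)), c(d[2], d[1], d[3]))
  }
  if (code %% 2 == 1) {
    x <- x[, dim(x)[2]:1, , drop = FALSE]
    t <- t[, dim(t)[2]:1, , drop = FALSE]
  }
  for (i in seq_len(code %/% 2)) {
    x <- rot90a(x); t <- rot90a(t)
  }
  list(x = x, t = t)
}

#' Train an ensemble of U-Net vessel segmenters
#'
#' K members are trained on identical data with distinct seeds and shuffle
#' orders, each with Adam on weighted pixel-wise binary cross-entropy over
#' random patches (with flip/rotation augmentation when enabled). Training
#' is deterministic given the config (which carries the member seeds).
#'
#' @param images list of `fundus_image` objects or arrays.
#' @param masks list of logical ground-truth vessel masks, same shapes.
#' @param config a [seg_config()].
#' @return object of class `seg_ensemble`: member parameter sets, per-member
#'   loss traces, and the shared preprocessing/architecture contract.
#' @export
train_segmentation_ensemble <- function(images, masks, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  if (length(images) != length(masks)) stopf("images and masks differ in length")
  if (length(images) < 4) stopf("need at least 4 training pairs")
  xs <- lapply(images, seg_preprocess)
  ts <- lapply(masks, function(m) array(as.numeric(m), c(dim(m)[1:2], 1L)))
  for (i in seq_along(xs)) {
    if (!identical(dim(xs[[i]])[1:2], dim(ts[[i]])[1:2])) {
      stopf("image/mask shape mismatch at pair %d", i)
    }
    if (any(dim(xs[[i]])[1:2] < config$patch)) {
      stopf("pair %d smaller than the training patch (%d)", i, config$patch)
    }
  }
  members <- vector("list", config$ensemble_size)
  traces <- vector("list", config$ensemble_size)
  for (k in seq_len(config$ensemble_size)) {
    fitted <- with_seed(config$seeds[k], {
      params <- unet_init(1L, config$base, config$depth)
      opt <- nn_adam_init(params)
      trace <- numeric(config$epochs)
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(length(xs))
        tot <- 0
        for (i in ord) {
          d <- dim(xs[[i]])
          r0 <- sample.int(d[1] - config$patch + 1L, 1L)
          c0 <- sample.int(d[2] - config$patch + 1L, 1L)
          xi <- xs[[i]][r0:(r0 + config$patch - 1L),
                        c0:(c0 + config$patch - 1L), , drop = FALSE]
          ti <- ts[[i]][r0:(r0 + config$patch - 1L),
                        c0:(c0 + config$patch - 1L), , drop = FALSE]
          if (config$augment) {
            au <- seg_augment(xi, ti, sample.int(8L, 1L) - 1L)
            xi <- au$x; ti <- au$t
          }
          fw <- unet_forward(params, xi, cache = TRUE)
          bl <- nn_bce(fw$prob, ti, pos_weight = config$pos_weight)
          gr <- unet_backward(params, fw$cache, bl$glogit)
          st <- nn_adam_step(params, gr, opt, lr = config$lr)
          params <- st$params; opt <- st$state
          tot <- tot + bl$loss
        }
        trace[ep] <- tot / length(xs)
      }
      list(params = params, trace = trace)
    })
    members[[k]] <- fitted$params
    traces[[k]] <- fitted$trace
  }
  structure(list(members = members, loss_traces = traces, config = config,
                 fingerprints = lapply(members, nn_fingerprint)),
            class = "seg_ensemble")
}

#' @export
print.seg_ensemble <- function(x, ...) {
  cat(sprintf("<seg_ensemble> K=%d U-Nets (depth %d, base %d), patch %d\n",
              x$config$ensemble_size, x$config$depth, x$config$base,
              x$config$patch))
  invisible(x)
}

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  nh <- ceiling(d[1] / m) * m
  nw <- ceiling(d[2] / m) * m
  if (nh == d[1] && nw == d[2]) return(list(x = x, h = d[1], w = d[2]))
  out <- array(0, c(nh, nw, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = out, h = d[1], w = d[2])
}

member_prob <- function(params, x, depth) {
  pd <- pad_to_multiple(x, 2^depth)
  pr <- unet_forward(params, pd$x)
  pr[seq_len(pd$h), seq_len(pd$w), 1, drop = TRUE]
}

#' Ensemble vessel-probability map for an image
#'
#' The output is the arithmetic mean of the member probability maps
#' (pixel-wise), values in \[0, 1\], same H x W as the input.
#'
#' @param ensemble a trained [train_segmentation_ensemble()] object.
#' @param image a `fundus_image` or image array.
#' @return H x W numeric probability map.
#' @export
segment <- function(ensemble, image) {
  stopifnot(inherits(ensemble, "seg_ensemble"))
  x <- seg_preprocess(image)
  maps <- lapply(ensemble$members, member_prob, x = x,
                 depth = ensemble$config$depth)
  Reduce(`+`, maps) / length(maps)
}

#' @export
predict.seg_ensemble <- function(object, newdata, ...) segment(object, newdata)

#' Pixel-wise disagreement across ensemble members
#'
#' @param ensemble a `seg_ensemble`.
#' @param image an image.
#' @return H x W map of the member standard deviation (0 everywhere for
#'   K = 1).
#' @export
segment_disagreement <- function(ensemble, image) {
  x <- seg_preprocess(image)
  maps <- lapply(ensemble$members, member_prob, x = x,
                 depth = ensemble$config$depth)
  k <- length(maps)
  if (k == 1) return(maps[[1]] * 0)
  mu <- Reduce(`+`, maps) / k
  sq <- Reduce(`+`, lapply(maps, function(m) (m - mu)^2)) / (k - 1)
  sqrt(sq)
}

#' Binarize a probability map within the field of view
#'
#' A pixel is vessel iff its probability is at or above the threshold and it
#' lies inside the FOV.
#'
#' @param prob H x W probability map.
#' @param threshold in \[0, 1\] (default 0.5).
#' @param fov optional H x W logical FOV mask.
#' @return H x W logical vessel mask.
#' @export
binarize <- function(prob, threshold = 0.5, fov = NULL) {
  if (threshold < 0 || threshold > 1) stopf("threshold must lie in [0, 1]")
  m <- prob >= threshold
  if (!is.null(fov)) m <- m & fov
  m
}

# rank-based (Mann-Whitney) area under the ROC curve
auc_rank <- function(score, truth) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Segmentation accuracy metrics over the field of view
#'
#' Dice = 2|P∩T| / (|P| + |T|); pixel accuracy = (TP + TN) / N; AUC is the
#' rank-based area under the ROC of the probability map against truth. All
#' computed over FOV pixels only. An empty truth with an empty prediction
#' yields Dice 1 with `empty_flag = TRUE`; empty truth with a nonempty
#' prediction yields Dice 0.
#'
#' @param prob H x W probability map (used for AUC; may be `NULL`).
#' @param pred H x W logical predicted mask.
#' @param truth H x W logical ground-truth mask.
#' @param fov H x W logical FOV mask (default: all pixels).
#' @return object of class `seg_metrics`: dice, pixel_accuracy, auc,
#'   empty_flag.
#' @export
segmentation_metrics <- function(prob, pred, truth, fov = NULL) {
  stopifnot(identical(dim(pred), dim(truth)))
  if (is.null(fov)) fov <- array(TRUE, dim(pred))
  p <- pred[fov]; t <- truth[fov]
  np <- sum(p); nt <- sum(t)
  empty_flag <- FALSE
  dice <- if (np + nt == 0) {
    empty_flag <- TRUE
    1.0
  } else {
    2 * sum(p & t) / (np + nt)
  }
  acc <- mean(p == t)
  auc <- if (is.null(prob)) NA_real_ else auc_rank(prob[fov], t > 0)
  structure(list(dice = dice, pixel_accuracy = acc, auc = auc,
                 empty_flag = empty_flag),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> dice %.4f, accuracy %.4f, auc %s%s\n",
              x$dice, x$pixel_accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc),
              if (x$empty_flag) " [both masks empty]" else ""))
  invisible(x)
}
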