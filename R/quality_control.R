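# Automated image quality control: a small convolutional classifier that
# flags poor-quality fundus images before segmentation.

qc_input_size <- 64L

# green channel, resized to the model's input size and standardized
qc_preprocess <- function(image) {
  px <- if (inherits(image, "fundus_image")) image$pixels else image
  if (length(dim(px)) == 3) px <- px[, , 2]
  if (!all(dim(px) == qc_input_size)) {
    px <- EBImage::resize(EBImage::Image(px), w = qc_input_size,
                          h = qc_input_size)
    px <- matrix(as.numeric(px), qc_input_size, qc_input_size)
  }
  s <- stats::sd(px)
  arr <- (px - mean(px)) / if (s > 0) s else 1
  array(arr, c(qc_input_size, qc_input_size, 1L))
}

qc_net_init <- function(base = 8L) {
  params <- list(c1 = nn_conv3_init(1L, base),
                 c2 = nn_conv3_init(base, 2L * base),
                 c3 = nn_conv3_init(2L * base, 4L * base),
                 fc = list(W = matrix(stats::rnorm(4L * base, sd = sqrt(2 / (4 * base))),
                                      4L * base, 1L),
                           b = 0))
  attr(params, "base") <- base
  params
}

qc_net_forward <- function(params, x, cache = FALSE) {
  a1 <- nn_conv3_fwd(x, params$c1); r1 <- nn_relu(a1$out)
  p1 <- nn_pool2_fwd(r1)
  a2 <- nn_conv3_fwd(p1$out, params$c2); r2 <- nn_relu(a2$out)
  p2 <- nn_pool2_fwd(r2)
  a3 <- nn_conv3_fwd(p2$out, params$c3); r3 <- nn_relu(a3$out)
  p3 <- nn_pool2_fwd(r3)
  d <- dim(p3$out)
  gap <- colMeans(matrix(p3$out, d[1] * d[2], d[3]))
  logit <- sum(gap * params$fc$W) + params$fc$b
  prob <- nn_sigmoid(logit)
  if (!cache) return(prob)
  list(prob = prob,
       cache = list(x = x, a1 = a1, r1 = r1, p1 = p1, a2 = a2, r2 = r2,
                    p2 = p2, a3 = a3, r3 = r3, p3 = p3, gap = gap,
                    pool_dim = d))
}

qc_net_backward <- function(params, cache, glogit) {
  d <- cache$pool_dim
  gW_fc <- matrix(cache$gap * glogit, ncol = 1)
  ggap <- as.numeric(params$fc$W) * glogit
  gpool <- array(rep(ggap, each = d[1] * d[2]) / (d[1] * d[2]), d)
  g <- nn_pool2_bwd(gpool, cache$p3$arg, dim(cache$r3))
  g <- nn_relu_bwd(cache$r3, g)
  b3 <- nn_conv3_bwd(cache$a3$cols, params$c3, g, dim(cache$r3)[1],
                     dim(cache$r3)[2], dim(cache$p2$out)[3])
  g <- nn_pool2_bwd(b3$gx, cache$p2$arg, dim(cache$r2))
  g <- nn_relu_bwd(cache$r2, g)
  b2 <- nn_conv3_bwd(cache$a2$cols, params$c2, g, dim(cache$r2)[1],
                     dim(cache$r2)[2], dim(cache$p1$out)[3])
  g <- nn_pool2_bwd(b2$gx, cache$p1$arg, dim(cache$r1))
  g <- nn_relu_bwd(cache$r1, g)
  b1 <- nn_conv3_bwd(cache$a1$cols, params$c1, g, dim(cache$r1)[1],
                     dim(cache$r1)[2], 1L)
  list(c1 = list(W = b1$gW, b = b1$gb),
       c2 = list(W = b2$gW, b = b2$gb),
       c3 = list(W = b3$gW, b = b3$gb),
       fc = list(W = gW_fc, b = glogit))
}

#' Train the image quality-control classifier
#'
#' A compact convolutional network (3 conv blocks with 2x2 max pooling,
#' global average pooling, linear head) trained with Adam on binary
#' good/poor labels. Images are reduced to their standardized green channel
#' at 64 x 64. Training is a pure function of the data, config and seed.
#'
#' @param images list of `fundus_image` objects (or H x W x 3 arrays).
#' @param labels character/factor vector of `"good"` / `"poor"` (or logical
#'   `TRUE` = poor), one per image.
#' @param config list of training knobs: `epochs` (default 10), `lr`
#'   (default 1e-3), `base` channels (default 8).
#' @param seed integer seed.
#' @return object of class `qc_model` with the trained parameters, the
#'   per-epoch training-loss trace, the input-size contract, and a config
#'   fingerprint.
#' @export
train_qc <- function(images, labels, config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(epochs = 10L, lr = 2e-3, base = 8L), config)
  if (length(images) == 0) stopf("empty training set")
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "poor"
  }
  labels <- as.logical(labels)
  stopifnot(length(images) == length(labels))
  if (length(unique(labels)) < 2 || min(table(labels)) < 2) {
    stopf("need at least 2 examples of each class (good/poor)")
  }
  xs <- lapply(images, qc_preprocess)
  with_seed(seed, {
    params <- qc_net_init(cfg$base)
    opt <- nn_adam_init(params)
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(xs))
      tot <- 0
      for (i in ord) {
        fw <- qc_net_forward(params, xs[[i]], cache = TRUE)
        bl <- nn_bce(fw$prob, as.numeric(labels[i]))
        gr <- qc_net_backward(params, fw$cache, bl$glogit)
        st <- nn_adam_step(params, gr, opt, lr = cfg$lr)
        params <- st$params; opt <- st$state
        tot <- tot + bl$loss
      }
      trace[ep] <- tot / length(xs)
    }
    structure(list(params = params, loss_trace = trace,
                   input_size = qc_input_size,
                   config = cfg, seed = as.integer(seed),
                   fingerprint = nn_fingerprint(params)),
              class = "qc_model")
  })
}

#' @export
print.qc_model <- function(x, ...) {
  cat(sprintf("<qc_model> %d-channel conv net, input %dx%d, final loss %.4f\n",
              x$config$base, x$input_size, x$input_size,
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Poor-quality probability for an image
#'
#' @param model a trained [train_qc()] model.
#' @param image a `fundus_image` or H x W x 3 array.
#' @return probability in \[0, 1\] that the image is poor quality;
#'   deterministic given the model and image.
#' @export
predict_qc <- function(model, image) {
  stopifnot(inherits(model, "qc_model"))
  if (!inherits(image, "fundus_image") &&
      !(is.array(image) && length(dim(image)) %in% c(2, 3))) {
    stopf("predict_qc expects a fundus_image or an image array")
  }
  qc_net_forward(model$params, qc_preprocess(image))
}

#' @export
predict.qc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "fundus_image") || !is.list(newdata)) {
    predict_qc(object, newdata)
  } else {
    vapply(newdata, function(im) predict_qc(object, im), 0.0)
  }
}

#' Sensitivity/specificity of QC predictions at a threshold
#'
#' An image is called "poor" when its probability is at or above the
#' threshold. Metrics come from the 2 x 2 confusion table; if a metric's
#' denominator is empty (all-one-class labels) it is reported as `NA`, not 0.
#'
#' @param probs numeric vector of poor-quality probabilities.
#' @param labels `"good"`/`"poor"` (or logical, `TRUE` = poor).
#' @param threshold decision threshold (default 0.5).
#' @return object of class `qc_metrics`: sensitivity, specificity,
#'   threshold, and the confusion counts TP/FP/TN/FN.
#' @export
evaluate_qc <- function(probs, labels, threshold = 0.5) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "poor"
  }
  labels <- as.logical(labels)
  stopifnot(length(probs) == length(labels))
  call_poor <- probs >= threshold
  tp <- sum(call_poor & labels); fn <- sum(!call_poor & labels)
  tn <- sum(!call_poor & !labels); fp <- sum(call_poor & !labels)
  structure(list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf(paste0("<qc_metrics> sensitivity %.3f, specificity %.3f",
                     " @ threshold %.2f (TP %d FP %d TN %d FN %d)\n"),
              x$sensitivity, x$specificity, x$threshold,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Save / load a QC model as a self-describing text file
#'
#' Serialized as JSON (weights flattened with dimensions recorded), so the
#' model file is portable plain text.
#'
#' @param model a `qc_model`.
#' @param path file path.
#' @return `save_qc_model` returns `path` invisibly; `load_qc_model` the
#'   restored model.
#' @export
save_qc_model <- function(model, path) {
  ser <- list(config = model$config, seed = model$seed,
              input_size = model$input_size, loss_trace = model$loss_trace,
              params = lapply(model$params, function(p) {
                lapply(p, function(v) list(dim = dim(v) %||% length(v),
                                           data = as.numeric(v)))
              }),
              base = attr(model$params, "base"))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_qc_model
#' @export
load_qc_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p) {
    lapply(p, function(v) {
      if (length(v$dim) == 2) matrix(v$data, v$dim[1], v$dim[2]) else v$data
    })
  })
  attr(params, "base") <- ser$base
  structure(list(params = params, loss_trace = ser$loss_trace,
                 input_size = ser$input_size, config = as.list(ser$config),
                 seed = ser$seed, fingerprint = nn_fingerprint(params)),
            class = "qc_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
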