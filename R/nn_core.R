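# Compact CPU convolution/backprop engine.
#
# Feature maps are base-R arrays (H, W, C); 3x3 convolutions are computed as
# im2col matrix products so the heavy lifting is a single BLAS gemm per layer.
# This is deliberately small: stride-1 'same' 3x3 convs, 1x1 convs, 2x2 max
# pooling, nearest-neighbour 2x upsampling, ReLU/sigmoid, and Adam — exactly
# what the quality-control classifier and the U-Net segmenters need.

nn_pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

# (H*W) x (9*C) patch matrix; offset order is fixed and shared with col2im
nn_im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cc <- d[3]
  xp <- nn_pad1(x)
  cols <- matrix(0, h * w, 9L * cc)
  k <- 0L
  for (dx in -1:1) {
    for (dy in -1:1) {
      slab <- xp[(1:h) + 1L + dy, (1:w) + 1L + dx, , drop = FALSE]
      cols[, k * cc + seq_len(cc)] <- matrix(slab, h * w, cc)
      k <- k + 1L
    }
  }
  cols
}

nn_col2im3 <- function(gcols, h, w, cc) {
  gxp <- array(0, c(h + 2L, w + 2L, cc))
  k <- 0L
  for (dx in -1:1) {
    for (dy in -1:1) {
      slab <- array(gcols[, k * cc + seq_len(cc)], c(h, w, cc))
      gxp[(1:h) + 1L + dy, (1:w) + 1L + dx, ] <-
        gxp[(1:h) + 1L + dy, (1:w) + 1L + dx, , drop = FALSE] + slab
      k <- k + 1L
    }
  }
  gxp[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

# weight: (9*C_in) x C_out, He-initialised
nn_conv3_init <- function(c_in, c_out) {
  list(W = matrix(stats::rnorm(9L * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                  9L * c_in, c_out),
       b = numeric(c_out))
}

nn_conv3_fwd <- function(x, p) {
  d <- dim(x)
  cols <- nn_im2col3(x)
  out <- sweep(cols %*% p$W, 2L, p$b, "+")
  list(out = array(out, c(d[1], d[2], ncol(p$W))), cols = cols)
}

nn_conv3_bwd <- function(cache_cols, p, gout, h, w, c_in) {
  g <- matrix(gout, h * w, ncol(p$W))
  list(gW = crossprod(cache_cols, g),
       gb = colSums(g),
       gx = nn_col2im3(tcrossprod(g, p$W), h, w, c_in))
}

nn_conv1_init <- function(c_in, c_out) {
  list(W = matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       b = numeric(c_out))
}

nn_conv1_fwd <- function(x, p) {
  d <- dim(x)
  out <- sweep(matrix(x, d[1] * d[2], d[3]) %*% p$W, 2L, p$b, "+")
  array(out, c(d[1], d[2], ncol(p$W)))
}

nn_conv1_bwd <- function(x, p, gout) {
  d <- dim(x)
  g <- matrix(gout, d[1] * d[2], ncol(p$W))
  xm <- matrix(x, d[1] * d[2], d[3])
  list(gW = crossprod(xm, g), gb = colSums(g),
       gx = array(tcrossprod(g, p$W), d))
}

nn_relu <- function(x) {
  x[x < 0] <- 0
  x
}

nn_relu_bwd <- function(act, g) {
  g[act <= 0] <- 0
  g
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# 2x2 max pooling; H and W must be even. Returns the argmax quadrant (1..4)
# for the backward scatter; ties resolve to the first quadrant.
nn_pool2_fwd <- function(x) {
  d <- dim(x)
  oi <- seq(1L, d[1], by = 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], by = 2L); ej <- oj + 1L
  q <- list(x[oi, oj, , drop = FALSE], x[ei, oj, , drop = FALSE],
            x[oi, ej, , drop = FALSE], x[ei, ej, , drop = FALSE])
  m <- q[[1]]
  k <- array(1L, dim(m))
  for (i in 2:4) {
    sel <- q[[i]] > m
    m[sel] <- q[[i]][sel]
    k[sel] <- i
  }
  list(out = m, arg = k)
}

nn_pool2_bwd <- function(g, arg, d_in) {
  gx <- array(0, d_in)
  oi <- seq(1L, d_in[1], by = 2L); ei <- oi + 1L
  oj <- seq(1L, d_in[2], by = 2L); ej <- oj + 1L
  idx <- list(list(oi, oj), list(ei, oj), list(oi, ej), list(ei, ej))
  for (i in 1:4) {
    gq <- g
    gq[arg != i] <- 0
    gx[idx[[i]][[1]], idx[[i]][[2]], ] <-
      gx[idx[[i]][[1]], idx[[i]][[2]], , drop = FALSE] + gq
  }
  gx
}

nn_up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

nn_up2_bwd <- function(g) {
  d <- dim(g)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  g[oi, oj, , drop = FALSE] + g[oi + 1L, oj, , drop = FALSE] +
    g[oi, oj + 1L, , drop = FALSE] + g[oi + 1L, oj + 1L, , drop = FALSE]
}

nn_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# ---- Adam over a flat list of {W, b} layer parameter pairs ----------------

nn_adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(v) v * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
          (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# Weighted binary cross-entropy on probabilities; returns loss and the
# gradient with respect to the pre-sigmoid logits (numerically stable form).
nn_bce <- function(prob, target, pos_weight = 1) {
  w <- ifelse(target > 0.5, pos_weight, 1)
  eps <- 1e-7
  p <- pmin(1 - eps, pmax(eps, prob))
  loss <- -sum(w * (target * log(p) + (1 - target) * log(1 - p))) / sum(w)
  glogit <- w * (p - target) / sum(w)
  list(loss = loss, glogit = glogit)
}

# Deterministic fingerprint of a parameter list (layer-wise sums of weights),
# used for reproducibility contracts on trained models.
nn_fingerprint <- function(params) {
  vapply(params, function(p) sum(vapply(p, sum, 0.0)), 0.0)
}
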