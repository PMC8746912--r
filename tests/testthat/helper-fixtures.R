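# Shared fixtures and independent oracles, all built in code at test time.

# Sierpinski carpet: depth-d mask on a 3^d x 3^d grid (dimension log 8 / log 3)
sierpinski_carpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    n <- nrow(m)
    out <- matrix(FALSE, 3 * n, 3 * n)
    for (bi in 0:2) {
      for (bj in 0:2) {
        if (bi == 1 && bj == 1) next
        out[bi * n + 1:n, bj * n + 1:n] <- m
      }
    }
    m <- out
  }
  m
}

# Brute-force box counter: explicit double loop over grid cells
oracle_box_count <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  cnt <- 0L
  for (i0 in seq(1L, h, by = s)) {
    for (j0 in seq(1L, w, by = s)) {
      blk <- mask[i0:min(i0 + s - 1L, h), j0:min(j0 + s - 1L, w)]
      if (any(blk)) cnt <- cnt + 1L
    }
  }
  cnt
}

# Brute-force AUC: all case/control pairs
oracle_auc <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force BH step-up: q_i = min_{j >= i} m * p_(j) / j at sorted position
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force Spearman rho from the rank definition (Pearson on ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# One-segment tree builder for rasterization oracles
straight_tree <- function(x0, y0, x1, y1, width, canvas = c(128L, 128L)) {
  tp <- tree_params(generations = 0L, n_roots = 1L, tortuosity_amp = 0,
                    width_root_px = width, canvas = canvas)
  structure(list(segments = data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                                       width = width, gen = 0L,
                                       tort_phase = 0, tort_cycles = 1),
                 params = tp),
            class = "vascular_tree")
}

# A small cached image set shared by the lighter unit tests
small_image_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) {
      pool <<- simulate_image_set(8L, canvas = c(64L, 64L),
                                  degraded_fraction = 0.5, seed = 424L)
    }
    pool
  }
})

total_gradient_energy <- function(px) {
  g <- px[, , 2]
  sum(abs(diff(g))) + sum(abs(t(diff(t(g)))))
}
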