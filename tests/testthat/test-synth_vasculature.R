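test_that("tree generation follows the binary-bifurcation contract", {
  # no branching: one trunk only
  t0 <- generate_tree(tree_params(generations = 0L, n_roots = 1L))
  expect_equal(nrow(t0$segments), 1L)

  # full binary tree: 2^(g+1) - 1 segments per root
  for (g in c(1L, 3L, 5L)) {
    tg <- generate_tree(tree_params(generations = g, n_roots = 1L, seed = g))
    expect_equal(nrow(tg$segments), 2^(g + 1L) - 1L)
  }
  t2 <- generate_tree(tree_params(generations = 4L, n_roots = 3L))
  expect_equal(nrow(t2$segments), 3L * (2^5 - 1L))
})

test_that("tree generation is deterministic and validates parameters", {
  p <- tree_params(generations = 4L, seed = 77L)
  expect_identical(generate_tree(p)$segments, generate_tree(p)$segments)
  expect_error(tree_params(generations = 13L), "raster blow-up")
  expect_error(tree_params(length_ratio = 1.2), "length_ratio")
  expect_error(tree_params(width_root_px = 0.5), "width_root_px")
})

test_that("children start at parent ends and widths shrink with generation", {
  tr <- generate_tree(tree_params(generations = 5L, seed = 3L))
  segs <- tr$segments
  for (g in sort(unique(segs$gen))) {
    if (g == 0) next
    kids <- segs[segs$gen == g, ]
    parents <- segs[segs$gen == g - 1L, ]
    for (i in seq_len(nrow(kids))) {
      d <- sqrt((parents$x1 - kids$x0[i])^2 + (parents$y1 - kids$y0[i])^2)
      expect_lt(min(d), 1e-9)
    }
    expect_lt(max(kids$width), min(parents$width) + 1e-12)
  }
})

test_that("rasterization clips to the FOV and honours segment geometry", {
  # empty tree -> all-zero mask (with warning)
  tp <- tree_params(generations = 0L, n_roots = 1L)
  empty <- structure(list(segments = data.frame(x0 = numeric(0), y0 = numeric(0),
                                                x1 = numeric(0), y1 = numeric(0),
                                                width = numeric(0), gen = integer(0),
                                                tort_phase = numeric(0),
                                                tort_cycles = numeric(0)),
                          params = tp),
                     class = "vascular_tree")
  expect_warning(r0 <- rasterize_tree(empty, c(64L, 64L)), "empty")
  expect_equal(sum(r0$mask), 0L)

  # one axis-aligned width-1 segment of length 50 -> ~50 pixels
  tr <- straight_tree(30, 64, 80, 64, width = 1)
  r1 <- rasterize_tree(tr, c(128L, 128L))
  expect_true(abs(sum(r1$mask) - 50) <= 1)

  # clipping contract: mask & !fov is empty, for several random trees
  for (s in 1:4) {
    tr2 <- generate_tree(tree_params(generations = 6L, seed = s))
    r2 <- rasterize_tree(tr2)
    expect_equal(sum(r2$mask & !r2$fov), 0L)
  }
  # a tree wholly outside the canvas warns about an empty mask
  far <- straight_tree(500, 500, 600, 600, 1)
  expect_warning(rasterize_tree(far, c(128L, 128L)), "empty")
  expect_error(rasterize_tree(tr, c(32L, 32L)), "64x64")
})

test_that("fundus rendering darkens vessels in the green channel, deterministically", {
  tr <- generate_tree(tree_params(generations = 5L, seed = 8L))
  ras <- rasterize_tree(tr)
  img <- render_fundus(ras$mask, ras$fov, seed = 5L)
  g <- img$pixels[, , 2]
  expect_lt(mean(g[ras$mask]), mean(g[ras$fov & !ras$mask]))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  img2 <- render_fundus(ras$mask, ras$fov, seed = 5L)
  expect_identical(img$pixels, img2$pixels)

  # no vessels: no pixel approaches vessel-level darkness inside the FOV
  blank <- render_fundus(ras$mask & FALSE, ras$fov, seed = 5L)
  expect_gt(min(blank$pixels[, , 2][ras$fov]), 0.15)
})

test_that("degradations are identity at severity 0 and corrupt monotonically", {
  tr <- generate_tree(tree_params(generations = 5L, seed = 9L))
  ras <- rasterize_tree(tr)
  img <- render_fundus(ras$mask, ras$fov, seed = 2L)

  for (mode in c("blur", "occlusion", "exposure")) {
    out <- degrade_image(img, degrade_spec(mode, 0, seed = 1L))
    expect_identical(out$pixels, img$pixels)
  }
  expect_error(degrade_spec("vignette", 0.5), "arg")

  # occlusion at severity 1 replaces (almost) the whole FOV with one value
  occ <- degrade_image(img, degrade_spec("occlusion", 1, seed = 3L))
  gv <- occ$pixels[, , 2][img$fov]
  expect_gte(mean(gv == stats::median(gv)), 0.95)

  # blur reduces total gradient energy, monotonically in severity
  e_clean <- total_gradient_energy(img$pixels)
  energies <- sapply(c(0.2, 0.5, 0.8), function(s) {
    total_gradient_energy(degrade_image(img, degrade_spec("blur", s, 1L))$pixels)
  })
  expect_lt(energies[3], e_clean)
  expect_true(all(diff(energies) < 0))

  # FOV preserved: outside pixels stay black
  for (mode in c("blur", "occlusion", "exposure")) {
    out <- degrade_image(img, degrade_spec(mode, 0.9, seed = 4L))
    expect_true(all(out$pixels[!array(img$fov, dim(out$pixels))] == 0))
    expect_identical(out$fov, img$fov)
  }
})

test_that("image sets round-trip through PNG + manifest", {
  set <- simulate_image_set(2L, canvas = c(64L, 64L), degraded_fraction = 0.5,
                            seed = 31L)
  dir <- withr::local_tempdir()
  man <- write_image_set(set, dir)
  expect_equal(nrow(man), 4L)
  back <- read_image_set(dir)
  expect_equal(length(back), 4L)
  expect_identical(back[[1]]$mask, set[[1]]$mask)
  expect_identical(back[[3]]$eye, set[[3]]$eye)
  # 8-bit quantization only
  expect_lt(max(abs(back[[2]]$image$pixels - set[[2]]$image$pixels)), 1 / 254)
})
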