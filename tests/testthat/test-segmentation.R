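tiny_seg_cfg <- function(k = 1L, seeds = NULL) {
  seg_config(ensemble_size = k, depth = 2L, base = 4L, patch = 32L,
             epochs = 1L, seeds = seeds)
}

tiny_pairs <- function(n = 4L) {
  pool <- small_image_pool()
  clean <- Filter(function(r) !r$degraded, pool)[seq_len(n)]
  list(images = lapply(clean, `[[`, "image"),
       masks = lapply(clean, `[[`, "mask"),
       fovs = lapply(clean, `[[`, "fov"))
}

test_that("segmentation config enforces the patch/depth contract", {
  expect_error(seg_config(patch = 50L, depth = 3L), "multiple")
  expect_error(seg_config(ensemble_size = 0L), ">= 1")
  expect_silent(seg_config(patch = 48L, depth = 4L))
})

test_that("training validates shapes and pair counts", {
  p <- tiny_pairs(4L)
  expect_error(train_segmentation_ensemble(p$images[1:3], p$masks[1:3]),
               "at least 4")
  bad_masks <- p$masks
  bad_masks[[2]] <- bad_masks[[2]][1:32, 1:32]
  expect_error(train_segmentation_ensemble(p$images, bad_masks, tiny_seg_cfg()),
               "pair 2")
})

test_that("the ensemble mean equals the member average and K=1 is the member", {
  p <- tiny_pairs(4L)
  ens2 <- train_segmentation_ensemble(p$images, p$masks,
                                      tiny_seg_cfg(2L, seeds = c(11L, 12L)))
  img <- p$images[[1]]
  pr <- segment(ens2, img)
  x <- retivasc:::seg_preprocess(img)
  m1 <- retivasc:::member_prob(ens2$members[[1]], x, ens2$config$depth)
  m2 <- retivasc:::member_prob(ens2$members[[2]], x, ens2$config$depth)
  expect_equal(pr, (m1 + m2) / 2, tolerance = 1e-12)

  ens1 <- train_segmentation_ensemble(p$images, p$masks,
                                      tiny_seg_cfg(1L, seeds = 11L))
  pr1 <- segment(ens1, img)
  expect_equal(pr1,
               retivasc:::member_prob(ens1$members[[1]], x, ens1$config$depth),
               tolerance = 1e-15)

  # K = 1 disagreement is identically zero; K = 2 is |m1 - m2| / sqrt(2)
  expect_true(all(segment_disagreement(ens1, img) == 0))
  expect_equal(segment_disagreement(ens2, img), abs(m1 - m2) / sqrt(2),
               tolerance = 1e-12)
})

test_that("training is deterministic given config seeds", {
  p <- tiny_pairs(4L)
  a <- train_segmentation_ensemble(p$images, p$masks, tiny_seg_cfg(1L, 42L))
  b <- train_segmentation_ensemble(p$images, p$masks, tiny_seg_cfg(1L, 42L))
  expect_identical(a$fingerprints, b$fingerprints)
  expect_identical(segment(a, p$images[[2]]), segment(b, p$images[[2]]))
})

test_that("probability maps are valid on degenerate inputs", {
  p <- tiny_pairs(4L)
  ens <- train_segmentation_ensemble(p$images, p$masks, tiny_seg_cfg())
  flat <- array(0, c(64, 64, 3))
  pr <- segment(ens, flat)
  expect_false(any(is.na(pr)))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(dim(pr), c(64L, 64L))
  # non-multiple-of-2^depth sizes are padded and cropped back
  odd <- array(runif(70 * 70 * 3), c(70, 70, 3))
  expect_equal(dim(segment(ens, odd)), c(70L, 70L))
})

test_that("binarization applies the >= rule inside the FOV only", {
  prob <- matrix(0.7, 32, 32)
  fov <- matrix(FALSE, 32, 32)
  fov[8:24, 8:24] <- TRUE
  expect_true(all(binarize(prob, 0.5, fov)[fov]))
  expect_true(all(binarize(prob, 0.7, fov)[fov]))  # boundary: >= keeps
  expect_false(any(binarize(prob, 0.71, fov)))
  expect_false(any(binarize(prob, 0.5, fov)[!fov]))
  expect_error(binarize(prob, 1.5), "threshold")
})

test_that("overlap metrics match their definitions and oracles", {
  t <- matrix(FALSE, 20, 20); t[5:10, 5:10] <- TRUE
  m_same <- segmentation_metrics(NULL, t, t)
  expect_equal(m_same$dice, 1)
  expect_equal(m_same$pixel_accuracy, 1)

  # |P|=2, |T|=2, |P∩T|=1 -> dice 0.5
  p2 <- matrix(FALSE, 4, 4); p2[1, 1:2] <- TRUE
  t2 <- matrix(FALSE, 4, 4); t2[1, 2:3] <- TRUE
  expect_equal(segmentation_metrics(NULL, p2, t2)$dice, 0.5)

  # empty-truth conventions
  e <- matrix(FALSE, 4, 4)
  both <- segmentation_metrics(NULL, e, e)
  expect_equal(both$dice, 1)
  expect_true(both$empty_flag)
  expect_equal(segmentation_metrics(NULL, p2, e)$dice, 0)

  # dice is symmetric and jointly translation invariant
  set.seed(13)
  a <- matrix(runif(400) < 0.3, 20, 20)
  b <- matrix(runif(400) < 0.3, 20, 20)
  expect_equal(segmentation_metrics(NULL, a, b)$dice,
               segmentation_metrics(NULL, b, a)$dice)
  a2 <- matrix(FALSE, 20, 20); a2[6:20, ] <- a[1:15, ]
  b2 <- matrix(FALSE, 20, 20); b2[6:20, ] <- b[1:15, ]
  expect_equal(segmentation_metrics(NULL, a2[6:20, ], b2[6:20, ])$dice,
               segmentation_metrics(NULL, a[1:15, ], b[1:15, ])$dice)

  # rank AUC equals the brute-force pairwise oracle (with ties)
  set.seed(17)
  prob <- matrix(round(runif(900), 2), 30, 30)
  truth <- matrix(runif(900) < 0.2, 30, 30)
  got <- segmentation_metrics(prob, truth, truth)$auc
  expect_equal(got, oracle_auc(as.numeric(prob), as.logical(truth)),
               tolerance = 1e-12)

  # a prob map ranking all truth above all background has AUC 1
  perfect <- matrix(0.1, 30, 30); perfect[truth] <- 0.9
  expect_equal(segmentation_metrics(perfect, truth, truth)$auc, 1)
})
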