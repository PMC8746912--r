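# Synthetic fundus simulator: branching vascular trees with ground-truth
# masks, fundus-style rendering, and controlled degradations.
#
# Coordinate convention: pixel-centre coordinates, origin at the top-left,
# row-major; a point is (x = column, y = row) in pixel units.

#' Parameters for a synthetic vascular tree
#'
#' The tree is a recursive binary bifurcation: every segment of generation
#' `g < generations` spawns exactly two children at its distal end. Child
#' calibers follow a Murray-type split, `w_child = w_parent * 2^(-1/murray_exponent)`
#' (`murray_exponent = 3` is Murray's law). Branch angles and segment lengths
#' carry Gaussian jitter; tortuosity is a smooth sinusoidal perturbation of
#' each segment path that leaves the endpoints fixed. This is a geometric
#' fixture whose box-counting dimension and density respond smoothly to
#' branching depth — not a biophysical model of retinal angiogenesis.
#'
#' @param generations number of bifurcation generations (0 = trunks only,
#'   maximum 12; deeper trees blow up the raster).
#' @param branch_angle_deg mean half-angle between a parent and each child,
#'   degrees.
#' @param length_ratio child/parent segment length, in (0, 1).
#' @param width_root_px trunk caliber in pixels (>= 1).
#' @param murray_exponent caliber-split exponent.
#' @param tortuosity_amp amplitude (pixels) of the sinusoidal path
#'   perturbation; 0 gives straight segments.
#' @param n_roots number of trunks emanating from the optic-disc point.
#' @param root_length_px trunk length in pixels.
#' @param canvas integer (H, W) the tree is laid out for; trunks start near
#'   the nasal optic-disc position (0.78 W, 0.5 H).
#' @param seed integer seed; the tree is a pure function of its parameters.
#' @return an object of class `tree_params`.
#' @export
tree_params <- function(generations = 6L, branch_angle_deg = 32,
                        length_ratio = 0.78, width_root_px = 4,
                        murray_exponent = 3, tortuosity_amp = 1.2,
                        n_roots = 4L, root_length_px = 46,
                        canvas = c(256L, 256L), seed = 1L) {
  if (generations < 0) stopf("generations must be >= 0")
  if (generations > 12) stopf("generations > 12 refused: raster blow-up")
  if (length_ratio <= 0 || length_ratio >= 1) {
    stopf("length_ratio must lie in (0, 1)")
  }
  if (width_root_px < 1) stopf("width_root_px must be >= 1")
  if (n_roots < 1) stopf("n_roots must be >= 1")
  structure(list(generations = as.integer(generations),
                 branch_angle_deg = branch_angle_deg,
                 length_ratio = length_ratio,
                 width_root_px = width_root_px,
                 murray_exponent = murray_exponent,
                 tortuosity_amp = tortuosity_amp,
                 n_roots = as.integer(n_roots),
                 root_length_px = root_length_px,
                 canvas = as.integer(canvas),
                 seed = as.integer(seed)),
            class = "tree_params")
}

#' Generate a synthetic vascular tree
#'
#' @param params a [tree_params()] object.
#' @return an object of class `vascular_tree`: a list with `segments` (data
#'   frame with columns `x0, y0, x1, y1, width, gen, tort_phase, tort_cycles`)
#'   and the generating `params`. Child segments start exactly at their
#'   parent's end; widths are non-increasing with generation.
#' @export
generate_tree <- function(params) {
  stopifnot(inherits(params, "tree_params"))
  with_seed(params$seed, {
    h <- params$canvas[1]; w <- params$canvas[2]
    disc <- c(0.78 * w, 0.5 * h)
    half <- params$branch_angle_deg * pi / 180
    shrink <- 2^(-1 / params$murray_exponent)
    rows <- vector("list", 0L)
    # iterative frontier expansion, one generation at a time
    root_dirs <- pi + seq(-0.9, 0.9, length.out = params$n_roots) +
      stats::rnorm(params$n_roots, sd = 0.06)
    frontier <- lapply(seq_len(params$n_roots), function(i) {
      list(x = disc[1], y = disc[2], ang = root_dirs[i],
           len = params$root_length_px * exp(stats::rnorm(1, sd = 0.05)),
           width = params$width_root_px, gen = 0L)
    })
    for (gen in 0:params$generations) {
      nxt <- list()
      for (s in frontier) {
        x1 <- s$x + s$len * cos(s$ang)
        y1 <- s$y + s$len * sin(s$ang)
        rows[[length(rows) + 1L]] <-
          data.frame(x0 = s$x, y0 = s$y, x1 = x1, y1 = y1,
                     width = s$width, gen = gen,
                     tort_phase = stats::runif(1, 0, 2 * pi),
                     tort_cycles = stats::runif(1, 0.6, 1.6))
        if (gen < params$generations) {
          for (side in c(-1, 1)) {
            ang <- s$ang + side * (half + stats::rnorm(1, sd = 0.12))
            nxt[[length(nxt) + 1L]] <-
              list(x = x1, y = y1, ang = ang,
                   len = s$len * params$length_ratio *
                     exp(stats::rnorm(1, sd = 0.08)),
                   width = s$width * shrink, gen = gen + 1L)
          }
        }
      }
      frontier <- nxt
    }
    structure(list(segments = do.call(rbind, rows), params = params),
              class = "vascular_tree")
  })
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf("<vascular_tree> %d segments, %d generations, %d root(s)\n",
              nrow(x$segments), x$params$generations, x$params$n_roots))
  invisible(x)
}

#' Rasterize a vascular tree to a binary vessel mask
#'
#' Segments are drawn as hard binary strokes (no anti-aliasing: fractal
#' dimension and density are defined on binary segmentations) with
#' per-segment width, the sinusoidal tortuosity applied along each path, and
#' the result clipped to a circular field of view.
#'
#' @param tree a `vascular_tree`.
#' @param canvas integer (H, W), each >= 64.
#' @param fov_radius field-of-view disc radius in pixels; default
#'   `0.48 * min(canvas)`.
#' @return list with `mask` (H x W logical vessel mask) and `fov`
#'   (H x W logical disc mask). Warns if the tree rasterizes to an empty
#'   mask.
#' @export
rasterize_tree <- function(tree, canvas = c(256L, 256L),
                           fov_radius = 0.48 * min(canvas)) {
  stopifnot(inherits(tree, "vascular_tree"))
  h <- as.integer(canvas[1]); w <- as.integer(canvas[2])
  if (h < 64 || w < 64) stopf("canvas must be at least 64x64")
  fov <- disc_mask(h, w, w / 2 + 0.5, h / 2 + 0.5, fov_radius)
  mask <- matrix(FALSE, h, w)
  segs <- tree$segments
  amp <- tree$params$tortuosity_amp
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
    len <- sqrt(dx^2 + dy^2)
    if (len < 1e-9) next
    nsamp <- max(2L, ceiling(len / 0.4))
    t <- seq(0, 1, length.out = nsamp)
    # sinusoidal bump perpendicular to the chord, zero at both endpoints
    bump <- amp * sin(pi * t * s$tort_cycles * 2) * sin(pi * t) *
      sin(s$tort_phase + 2 * pi * t * s$tort_cycles) / max(1, s$tort_cycles)
    nx <- -dy / len; ny <- dx / len
    px <- s$x0 + t * dx + bump * nx
    py <- s$y0 + t * dy + bump * ny
    r <- max(s$width / 2, 0.5)
    off <- expand.grid(ox = seq(-ceiling(r), ceiling(r)),
                       oy = seq(-ceiling(r), ceiling(r)))
    off <- off[off$ox^2 + off$oy^2 <= r^2 | (abs(off$ox) < 1 & abs(off$oy) < 1), ]
    cols <- as.integer(outer(round(px), off$ox, "+"))
    rws <- as.integer(outer(round(py), off$oy, "+"))
    keep <- cols >= 1L & cols <= w & rws >= 1L & rws <= h
    mask[cbind(rws[keep], cols[keep])] <- TRUE
  }
  mask <- mask & fov
  if (!any(mask)) warnf("tree rasterized to an empty mask (outside canvas?)")
  list(mask = mask, fov = fov)
}

#' Render a fundus-style photograph from a vessel mask
#'
#' Produces an RGB raster in \[0, 1\]: a warm background with a smooth radial
#' gradient, a bright optic-disc region, per-pixel Gaussian noise, and the
#' vessels rendered darker than the background — most strongly in the green
#' channel, where retinal vessel contrast is highest. Black outside the FOV.
#'
#' @param mask H x W logical vessel mask.
#' @param fov H x W logical field-of-view mask.
#' @param appearance list of rendering knobs: `vessel_contrast` (fractional
#'   green-channel darkening at vessel pixels, default 0.55), `noise_sd`
#'   (default 0.02).
#' @param seed integer seed (noise is the only stochastic element).
#' @param eye `"right"` or `"left"`; stored in `meta`.
#' @param participant participant identifier; stored in `meta`.
#' @return object of class `fundus_image`: list with `pixels` (H x W x 3
#'   array in \[0,1\]), `fov`, and `meta`.
#' @export
render_fundus <- function(mask, fov, appearance = list(), seed = 1L,
                          eye = "right", participant = "P1") {
  stopifnot(identical(dim(mask), dim(fov)))
  ap <- utils::modifyList(list(vessel_contrast = 0.55, noise_sd = 0.02),
                          appearance)
  h <- nrow(mask); w <- ncol(mask)
  with_seed(seed, {
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    cx <- w / 2 + 0.5; cy <- h / 2 + 0.5
    r2 <- ((xs - cx)^2 + (ys - cy)^2) / (min(h, w) / 2)^2
    shade <- 1 - 0.35 * r2
    # bright optic disc at the nasal root position
    dx <- 0.78 * w; dyp <- 0.5 * h
    discg <- exp(-(((xs - dx)^2 + (ys - dyp)^2)) / (2 * (0.045 * min(h, w))^2))
    base <- c(0.85, 0.46, 0.13)
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      v <- base[ch] * shade + 0.35 * discg * c(0.6, 1.0, 0.8)[ch]
      contr <- ap$vessel_contrast * c(0.45, 1.0, 0.3)[ch]
      v[mask] <- v[mask] * (1 - contr)
      v <- v + stats::rnorm(h * w, sd = ap$noise_sd)
      v[!fov] <- 0
      px[, , ch] <- clamp01(v)
    }
    structure(list(pixels = px, fov = fov,
                   meta = list(eye = match.arg(eye, c("right", "left")),
                               participant = participant)),
              class = "fundus_image")
  })
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %dx%d, eye=%s, participant=%s\n",
              d[1], d[2], x$meta$eye, x$meta$participant))
  invisible(x)
}

#' Specification of a controlled image degradation
#'
#' @param mode one of `"blur"`, `"occlusion"`, `"exposure"`.
#' @param severity corruption severity in \[0, 1\]; 0 is the identity.
#' @param seed integer seed for any stochastic placement.
#' @return object of class `degrade_spec`.
#' @export
degrade_spec <- function(mode = c("blur", "occlusion", "exposure"),
                         severity = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (severity < 0 || severity > 1) stopf("severity must lie in [0, 1]")
  structure(list(mode = mode, severity = severity, seed = as.integer(seed)),
            class = "degrade_spec")
}

#' Apply a controlled degradation to a fundus image
#'
#' The three modes emulate the dominant real-world quality failures:
#' defocus `blur` (Gaussian, sigma proportional to severity), lens/lid
#' `occlusion` (a uniform patch whose FOV coverage grows with severity;
#' severity 1 covers the whole FOV), and over-`exposure` (gain + offset that
#' washes out vessel contrast). Severity 0 returns the input unchanged and
#' the FOV mask is always preserved.
#'
#' @param image a `fundus_image`.
#' @param spec a [degrade_spec()].
#' @return a degraded `fundus_image`; `meta$degradation` records the spec.
#' @export
degrade_image <- function(image, spec) {
  stopifnot(inherits(image, "fundus_image"), inherits(spec, "degrade_spec"))
  if (spec$severity == 0) return(image)
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  fov <- image$fov
  out <- with_seed(spec$seed, {
    if (spec$mode == "blur") {
      blurred <- EBImage::gblur(px, sigma = 0.5 + 5.5 * spec$severity)
      array(blurred, dim(px))
    } else if (spec$mode == "occlusion") {
      # uniform grey patch; area scales with severity so coverage is monotone
      fr <- 0.48 * min(h, w)
      rad <- 1.05 * fr * sqrt(spec$severity)
      cx <- w / 2 + 0.5 + stats::rnorm(1, sd = (1 - spec$severity) * 0.05 * w)
      cy <- h / 2 + 0.5 + stats::rnorm(1, sd = (1 - spec$severity) * 0.05 * h)
      patch <- disc_mask(h, w, cx, cy, rad)
      val <- stats::runif(1, 0.35, 0.65)
      for (ch in 1:3) {
        sl <- px[, , ch]
        sl[patch] <- val
        px[, , ch] <- sl
      }
      px
    } else {  # exposure
      clamp01(px * (1 + 1.6 * spec$severity) + 0.22 * spec$severity)
    }
  })
  for (ch in 1:3) {
    sl <- out[, , ch]
    sl[!fov] <- 0
    out[, , ch] <- sl
  }
  res <- image
  res$pixels <- clamp01(out)
  res$meta$degradation <- spec
  res
}

#' Simulate a labelled set of fundus images with ground-truth masks
#'
#' One participant contributes right and left eyes (independent trees). A
#' `degraded_fraction` of images receives a random degradation with severity
#' drawn from `severity_range`; the rest are clean. Truth parameters, eye
#' labels and degradation records are returned alongside, so every
#' downstream stage (QC, segmentation, quantification) can be scored.
#'
#' @param n_participants number of participants (2 images each).
#' @param canvas integer (H, W).
#' @param base_params `tree_params` template; per-image seeds and small
#'   per-participant jitter of `length_ratio` are applied on top.
#' @param degraded_fraction fraction of images degraded.
#' @param severity_range range the degradation severity is drawn from.
#' @param seed master seed.
#' @return list of image records: each has `image` (`fundus_image`), `mask`,
#'   `fov`, `participant`, `eye`, `degraded` (logical), `mode`, `severity`,
#'   and the generating tree `params`.
#' @export
simulate_image_set <- function(n_participants = 25L, canvas = c(128L, 128L),
                               base_params = tree_params(canvas = canvas),
                               degraded_fraction = 0, severity_range = c(0.4, 1),
                               seed = 1L) {
  with_seed(seed, {
    recs <- list()
    n_img <- 2L * n_participants
    degr <- rep(FALSE, n_img)
    if (degraded_fraction > 0) {
      degr[sample.int(n_img, round(degraded_fraction * n_img))] <- TRUE
    }
    modes <- c("blur", "occlusion", "exposure")
    k <- 0L
    for (p in seq_len(n_participants)) {
      lr <- min(0.92, max(0.6, base_params$length_ratio +
                            stats::rnorm(1, sd = 0.015)))
      for (eye in c("right", "left")) {
        k <- k + 1L
        tp <- base_params
        tp$length_ratio <- lr
        tp$canvas <- as.integer(canvas)
        tp$root_length_px <- base_params$root_length_px *
          min(canvas) / min(base_params$canvas)
        tp$width_root_px <- max(1.5, base_params$width_root_px *
                                  min(canvas) / min(base_params$canvas))
        tp$seed <- derive_seed(seed, paste0("tree", k))
        tree <- generate_tree(tp)
        ras <- rasterize_tree(tree, canvas = canvas)
        img <- render_fundus(ras$mask, ras$fov,
                             seed = derive_seed(seed, paste0("render", k)),
                             eye = eye, participant = sprintf("P%04d", p))
        sev <- 0; mode <- NA_character_
        if (degr[k]) {
          mode <- modes[1L + (k %% 3L)]
          sev <- stats::runif(1, severity_range[1], severity_range[2])
          img <- degrade_image(img, degrade_spec(mode, sev,
                                                 derive_seed(seed, paste0("deg", k))))
        }
        recs[[k]] <- list(image = img, mask = ras$mask, fov = ras$fov,
                          participant = sprintf("P%04d", p), eye = eye,
                          degraded = degr[k], mode = mode, severity = sev,
                          params = tp)
      }
    }
    recs
  })
}

#' Write an image set to disk as PNGs with a TSV manifest
#'
#' Images are written as 8-bit RGB PNGs, masks and FOVs as single-channel
#' PNGs with values in \{0, 255\}. The manifest maps each file to its
#' participant id, eye, degradation record and truth tree parameters.
#'
#' @param set output of [simulate_image_set()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame (also written as
#'   `manifest.tsv`).
#' @export
write_image_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(set), function(i) {
    r <- set[[i]]
    stem <- sprintf("img%04d_%s_%s", i, r$participant, r$eye)
    png::writePNG(r$image$pixels, file.path(dir, paste0(stem, ".png")))
    png::writePNG(matrix(as.numeric(r$mask), nrow(r$mask)),
                  file.path(dir, paste0(stem, "_mask.png")))
    png::writePNG(matrix(as.numeric(r$fov), nrow(r$fov)),
                  file.path(dir, paste0(stem, "_fov.png")))
    data.frame(file = paste0(stem, ".png"),
               mask_file = paste0(stem, "_mask.png"),
               fov_file = paste0(stem, "_fov.png"),
               participant = r$participant, eye = r$eye,
               degraded = r$degraded, mode = r$mode, severity = r$severity,
               generations = r$params$generations,
               length_ratio = r$params$length_ratio,
               tree_seed = r$params$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read an image set written by [write_image_set()]
#'
#' @param dir directory containing `manifest.tsv` and the PNGs.
#' @return list of records shaped like [simulate_image_set()] output (tree
#'   parameters reduced to the manifest columns).
#' @export
read_image_set <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    px <- png::readPNG(file.path(dir, m$file))
    fov <- png::readPNG(file.path(dir, m$fov_file)) > 0.5
    mask <- png::readPNG(file.path(dir, m$mask_file)) > 0.5
    img <- structure(list(pixels = px, fov = fov,
                          meta = list(eye = m$eye, participant = m$participant)),
                     class = "fundus_image")
    list(image = img, mask = mask, fov = fov, participant = m$participant,
         eye = m$eye, degraded = isTRUE(m$degraded), mode = m$mode,
         severity = m$severity)
  })
}
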