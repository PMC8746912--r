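# Pipeline orchestration: simulate -> QC -> segment -> quantify ->
# associate/gwas/prs/mr from a single config, with per-stage seeding, a
# structured log and a hash manifest for reproducibility audits.

#' Default pipeline configuration
#'
#' A complete, schema-valid config for a small demonstration run: 50 images
#' (25 participants, two eyes) through QC, segmentation and quantification,
#' and an n = 2000 simulated cohort through the PheWAS, GWAS, PRS and MR
#' stages. Every stage seed derives deterministically from the global seed.
#'
#' @return nested list; see the fields themselves for the schema.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "retivasc_run",
    stages = list(images = TRUE, cohort = TRUE, qc = TRUE, segment = TRUE,
                  quantify = TRUE, phewas = TRUE, gwas = TRUE, prs = TRUE,
                  mr = TRUE),
    images = list(n_participants = 25L, canvas = c(128L, 128L),
                  degraded_fraction = 0.3),
    qc = list(epochs = 6L, lr = 2e-3, threshold = 0.5,
              poor_severity = 0.4),
    segment = list(ensemble_size = 1L, depth = 3L, base = 8L, patch = 64L,
                   epochs = 2L, lr = 1e-3, train_images = 16L,
                   threshold = 0.5),
    quantify = list(k = 2),
    cohort = list(n_participants = 2000L, n_variants = 200L, n_causal = 5L,
                  h2 = 0.2, confounding = 0.3),
    phewas = list(n_outcomes = 20L, kind = "prevalent-binary",
                  baseline = 0.1, effect_on_first = 0.4, min_cases = 20L),
    gwas = list(maf_min = 0.001),
    prs = list(threshold = 5e-8),
    mr = list(true_slope = 0.3, exposure_scale = 1)
  )
}

#' Load a pipeline config from YAML, merged over the defaults
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return validated config list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  need <- names(default_run_config())
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("config missing key(s): %s", paste(miss, collapse = ", "))
  st <- cfg$stages
  downstream_of_images <- c("qc", "segment", "quantify")
  for (s in downstream_of_images) {
    if (isTRUE(st[[s]]) && !isTRUE(st$images)) {
      stopf("stage '%s' enabled but its upstream 'images' stage is disabled", s)
    }
  }
  for (s in c("phewas", "gwas", "prs", "mr")) {
    if (isTRUE(st[[s]]) && !isTRUE(st$cohort)) {
      stopf("stage '%s' enabled but its upstream 'cohort' stage is disabled", s)
    }
  }
  if (isTRUE(st$segment) && !isTRUE(st$qc)) {
    stopf("stage 'segment' requires the 'qc' stage (filter-then-analyze order)")
  }
  if (isTRUE(st$quantify) && !isTRUE(st$segment)) {
    stopf("stage 'quantify' requires the 'segment' stage")
  }
  if ((isTRUE(st$prs) || isTRUE(st$mr)) && !isTRUE(st$gwas)) {
    stopf("stages 'prs'/'mr' require the 'gwas' stage")
  }
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

hash_files <- function(files) {
  h <- tools::md5sum(files)
  stats::setNames(as.character(h), basename(names(h)))
}

#' Run the full pipeline from a config
#'
#' Stages execute in dependency order; QC-rejected images are excluded from
#' segmentation and quantification (filter-then-analyze). Every stage
#' writes its outputs under `out_dir` and records parameters, input/output
#' file hashes and timings in the run manifest (`manifest.json`). Re-running
#' an identical config reproduces identical output hashes.
#'
#' @param config config list from [load_run_config()] /
#'   [default_run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list())
  st <- config$stages
  seed <- config$seed
  canvas <- as.integer(unlist(config$images$canvas))

  add_stage <- function(name, params, files, counts, elapsed) {
    manifest$stages[[name]] <<- list(params = params,
                                     outputs = as.list(hash_files(files)),
                                     counts = counts, seconds = elapsed)
  }

  recs <- NULL
  if (isTRUE(st$images)) {
    t0 <- proc.time()[3]
    recs <- simulate_image_set(config$images$n_participants, canvas,
                               degraded_fraction = config$images$degraded_fraction,
                               seed = derive_seed(seed, "images"))
    img_dir <- file.path(out_dir, "images")
    write_image_set(recs, img_dir)
    files <- list.files(img_dir, full.names = TRUE)
    stage_log("images", "wrote %d images to %s", length(recs), img_dir)
    add_stage("images", config$images, files,
              list(images = length(recs)), proc.time()[3] - t0)
  }

  kept <- seq_along(recs)
  if (isTRUE(st$qc)) {
    t0 <- proc.time()[3]
    labels <- ifelse(vapply(recs, function(r)
      r$severity >= config$qc$poor_severity, TRUE), "poor", "good")
    qm <- train_qc(lapply(recs, `[[`, "image"), labels,
                   config = list(epochs = config$qc$epochs, lr = config$qc$lr),
                   seed = derive_seed(seed, "qc"))
    probs <- vapply(recs, function(r) predict_qc(qm, r$image), 0.0)
    keep <- probs < config$qc$threshold
    kept <- which(keep)
    qtab <- data.frame(index = seq_along(recs),
                       participant = vapply(recs, `[[`, "", "participant"),
                       eye = vapply(recs, `[[`, "", "eye"),
                       poor_prob = probs, keep = keep)
    fq <- file.path(out_dir, "qc.tsv")
    utils::write.table(qtab, fq, sep = "\t", row.names = FALSE, quote = FALSE)
    fm <- file.path(out_dir, "qc_model.json")
    save_qc_model(qm, fm)
    stage_log("qc", "removed %d/%d images (%.1f%%)",
              sum(!keep), length(recs), 100 * mean(!keep))
    add_stage("qc", config$qc, c(fq, fm),
              list(images_in = length(recs), kept = sum(keep),
                   removed_fraction = mean(!keep)),
              proc.time()[3] - t0)
  }

  ens <- NULL
  seg_masks <- NULL
  if (isTRUE(st$segment)) {
    t0 <- proc.time()[3]
    if (length(kept) < 4) stopf("segment: fewer than 4 images survived QC")
    tr_idx <- kept[seq_len(min(config$segment$train_images, length(kept)))]
    scfg <- seg_config(ensemble_size = config$segment$ensemble_size,
                       depth = config$segment$depth,
                       base = config$segment$base,
                       patch = config$segment$patch,
                       epochs = config$segment$epochs, lr = config$segment$lr,
                       seeds = derive_seed(seed, "segment") +
                         seq_len(config$segment$ensemble_size))
    ens <- train_segmentation_ensemble(lapply(recs[tr_idx], `[[`, "image"),
                                       lapply(recs[tr_idx], `[[`, "mask"),
                                       scfg)
    seg_dir <- file.path(out_dir, "segmentation")
    dir.create(seg_dir, showWarnings = FALSE)
    seg_masks <- vector("list", length(recs))
    mrows <- list()
    for (i in kept) {
      pr <- segment(ens, recs[[i]]$image)
      bm <- binarize(pr, config$segment$threshold, recs[[i]]$fov)
      seg_masks[[i]] <- bm
      stem <- sprintf("img%04d", i)
      png::writePNG(pr, file.path(seg_dir, paste0(stem, "_prob.png")))
      png::writePNG(matrix(as.numeric(bm), nrow(bm)),
                    file.path(seg_dir, paste0(stem, "_pred.png")))
      met <- segmentation_metrics(pr, bm, recs[[i]]$mask, recs[[i]]$fov)
      mrows[[length(mrows) + 1L]] <-
        data.frame(index = i, dice = met$dice,
                   pixel_accuracy = met$pixel_accuracy, auc = met$auc)
    }
    mtab <- do.call(rbind, mrows)
    fmet <- file.path(out_dir, "segmentation_metrics.tsv")
    utils::write.table(mtab, fmet, sep = "\t", row.names = FALSE, quote = FALSE)
    stage_log("segment", "K=%d ensemble, mean dice %.3f over %d images",
              config$segment$ensemble_size, mean(mtab$dice), nrow(mtab))
    add_stage("segment", config$segment,
              c(list.files(seg_dir, full.names = TRUE), fmet),
              list(trained_on = length(tr_idx), segmented = length(kept),
                   mean_dice = mean(mtab$dice)),
              proc.time()[3] - t0)
  }

  if (isTRUE(st$quantify)) {
    t0 <- proc.time()[3]
    eye_rows <- lapply(kept, function(i) {
      tryCatch(
        eye_metrics(seg_masks[[i]], recs[[i]]$fov, recs[[i]]$participant,
                    recs[[i]]$eye),
        error = function(e) {
          stage_log("quantify", "skipping image %d: %s", i,
                    conditionMessage(e))
          NULL
        })
    })
    eye_tbl <- do.call(rbind, eye_rows)
    if (is.null(eye_tbl) || nrow(eye_tbl) == 0) {
      stopf("quantify: no usable segmented masks")
    }
    ptab <- participant_metrics(eye_tbl, k = config$quantify$k)
    f1 <- file.path(out_dir, "eye_metrics.tsv")
    f2 <- file.path(out_dir, "participant_metrics.tsv")
    utils::write.table(eye_tbl, f1, sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(ptab, f2, sep = "\t", row.names = FALSE, quote = FALSE)
    stage_log("quantify", "%d eyes -> %d participants", nrow(eye_tbl),
              nrow(ptab))
    add_stage("quantify", config$quantify, c(f1, f2),
              list(eyes = nrow(eye_tbl), participants = nrow(ptab)),
              proc.time()[3] - t0)
  }

  geno <- covs <- trait <- NULL
  if (isTRUE(st$cohort)) {
    t0 <- proc.time()[3]
    cc <- config$cohort
    geno <- simulate_genotypes(cc$n_participants, cc$n_variants,
                               seed = derive_seed(seed, "geno"))
    covs <- simulate_covariates(cc$n_participants,
                                seed = derive_seed(seed, "covs"))
    causal <- geno$variant_ids[seq_len(cc$n_causal)]
    # per-allele effects sized so the causal variants explain ~h2 of variance
    vg <- sum(2 * geno$maf[seq_len(cc$n_causal)] *
                (1 - geno$maf[seq_len(cc$n_causal)]))
    eff <- rep(sqrt(cc$h2 / vg), cc$n_causal)
    arch <- trait_architecture(causal, eff, residual_sd = sqrt(1 - cc$h2),
                               confounder_loading = cc$confounding)
    trait <- simulate_trait(geno, covs, arch,
                            seed = derive_seed(seed, "trait"))
    cdir <- file.path(out_dir, "cohort")
    files <- write_cohort(geno, covs, trait, cdir)
    stage_log("cohort", "n=%d, m=%d, %d causal variants",
              cc$n_participants, cc$n_variants, cc$n_causal)
    add_stage("cohort", cc, files,
              list(n = cc$n_participants, m = cc$n_variants),
              proc.time()[3] - t0)
  }

  if (isTRUE(st$phewas)) {
    t0 <- proc.time()[3]
    pc <- config$phewas
    effects <- if (pc$effect_on_first != 0) {
      stats::setNames(pc$effect_on_first, "1")
    } else {
      numeric(0)
    }
    panel <- simulate_phenotype_panel(trait$trait, pc$n_outcomes, pc$kind,
                                      effects = effects,
                                      baseline = pc$baseline,
                                      seed = derive_seed(seed, "panel"))
    res <- phewas_scan(trait$trait, panel, covs, min_cases = pc$min_cases)
    fp <- file.path(out_dir, "phewas.tsv")
    utils::write.table(res, fp, sep = "\t", row.names = FALSE, quote = FALSE)
    sk <- attr(res, "skipped")
    stage_log("phewas", "%d outcomes fit, %d skipped", nrow(res), nrow(sk))
    add_stage("phewas", pc, fp,
              list(fit = nrow(res), skipped = nrow(sk)),
              proc.time()[3] - t0)
  }

  gw <- NULL
  if (isTRUE(st$gwas)) {
    t0 <- proc.time()[3]
    gw <- gwas_scan(geno, trait$trait, covs, maf_min = config$gwas$maf_min)
    fg <- file.path(out_dir, "gwas_sumstats.tsv")
    write_gwas_sumstats(gw, fg)
    stage_log("gwas", "%d variants scanned, min p = %.2e", nrow(gw),
              min(gw$p))
    add_stage("gwas", config$gwas, fg, list(variants = nrow(gw)),
              proc.time()[3] - t0)
  }

  prs_score <- NULL
  if (isTRUE(st$prs)) {
    t0 <- proc.time()[3]
    pm <- suppressWarnings(select_significant(gw, config$prs$threshold))
    prs_score <- build_prs(geno, pm)
    fpm <- file.path(out_dir, "prs_model.tsv")
    write_prs_model(pm, fpm)
    fsc <- file.path(out_dir, "prs_scores.tsv")
    utils::write.table(data.frame(id = sprintf("id%05d", seq_along(prs_score)),
                                  score = prs_score),
                       fsc, sep = "\t", row.names = FALSE, quote = FALSE)
    stage_log("prs", "%d variants selected", length(pm$variants))
    add_stage("prs", config$prs, c(fpm, fsc),
              list(variants = length(pm$variants)), proc.time()[3] - t0)
  }

  if (isTRUE(st$mr)) {
    t0 <- proc.time()[3]
    mc <- config$mr
    ospec <- outcome_spec("quantitative", effect = mc$true_slope,
                          baseline = 0, seed = derive_seed(seed, "mrout"))
    mout <- simulate_outcomes(trait$trait, covs, ospec,
                              confounder = trait$confounder,
                              confounder_loading = config$cohort$confounding)
    if (is.null(prs_score) || stats::sd(prs_score) == 0) {
      stage_log("mr", "skipped: empty or constant PRS instrument")
      add_stage("mr", mc, character(0), list(skipped = TRUE),
                proc.time()[3] - t0)
    } else {
      mr <- one_sample_mr(prs_score, trait$trait, mout$value, covs,
                          exposure_scale = mc$exposure_scale)
      naive <- fit_association(trait$trait, mout$value, covs, "linear",
                               "mr-naive")
      fmr <- file.path(out_dir, "mr.tsv")
      utils::write.table(
        data.frame(what = c("mr_2sls", "naive_observational", "true_slope"),
                   estimate = c(mr$estimate, naive$effect, mc$true_slope),
                   se = c(mr$se, naive$se, NA),
                   p = c(mr$p, naive$p, NA),
                   first_stage_f = c(mr$first_stage_f, NA, NA)),
        fmr, sep = "\t", row.names = FALSE, quote = FALSE)
      stage_log("mr", "2SLS %.3f (truth %.3f), naive %.3f", mr$estimate,
                mc$true_slope, naive$effect)
      add_stage("mr", mc, fmr, list(n = mr$n), proc.time()[3] - t0)
    }
  }

  fman <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, fman, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Output hashes of a pipeline manifest (timings excluded)
#'
#' Convenience accessor for determinism audits: re-running an identical
#' config must reproduce these hashes exactly.
#'
#' @param manifest list returned by [run_pipeline()].
#' @return named character vector of md5 hashes.
#' @export
manifest_hashes <- function(manifest) {
  unlist(lapply(manifest$stages, function(s) unlist(s$outputs)))
}
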