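#' Pipeline configuration
#'
#' A single document of paths and parameters driving the three training
#' phases plus inference and evaluation. All randomness flows from one
#' root seed, split deterministically per phase.
#'
#' @param out_dir artifact directory (created on demand).
#' @param seed root seed.
#' @param cohort_dir directory of slides + truth + manifest; defaults to
#'   `<out_dir>/cohort` (written by the simulate phase).
#' @param simulate list of [make_cohort()] arguments.
#' @param tiling list: `patch_size`, `min_tissue_fraction`,
#'   `mask_downsample`.
#' @param network a `pcead_config`, or a list of [network_config()]
#'   arguments.
#' @param schedule per-level image budget for training.
#' @param reconstructor `"gan"` (trained progressive GAN) or `"oracle"`
#'   (deterministic stand-in; no training phase needed).
#' @param oracle list of [oracle_reconstructor()] arguments.
#' @param q normal-pixel exceedance fraction for threshold calibration.
#' @param segmentation list: `min_area`, `closing_radius`.
#' @param evaluation list: `downsample`, `region` (`"tissue-bbox"` or a
#'   4-vector).
#' @return A `pcead_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort_dir = NULL,
                            simulate = list(), tiling = list(),
                            network = list(), schedule = 2000,
                            reconstructor = c("gan", "oracle"),
                            oracle = list(), q = 0.05,
                            segmentation = list(), evaluation = list()) {
  tiling <- utils::modifyList(
    list(patch_size = 64L, min_tissue_fraction = 0.5,
         mask_downsample = 16L), tiling)
  segmentation <- utils::modifyList(
    list(min_area = 256, closing_radius = 0), segmentation)
  evaluation <- utils::modifyList(
    list(downsample = 2L, region = "tissue-bbox"), evaluation)
  if (!inherits(network, "pcead_config"))
    network <- do.call(network_config, network)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_dir = cohort_dir %||% file.path(out_dir, "cohort"),
                 simulate = simulate, tiling = tiling, network = network,
                 schedule = schedule,
                 reconstructor = match.arg(reconstructor),
                 oracle = oracle, q = q, segmentation = segmentation,
                 evaluation = evaluation),
            class = "pcead_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys mirror [pipeline_config()]
#'   arguments. Unknown keys are rejected.
#' @return A `pcead_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, doc)
}

PHASE_ORDER <- c("simulate", "tile", "train", "fit-nerd", "calibrate",
                 "infer", "evaluate")

#' Run the training/inference pipeline
#'
#' Executes the requested phases in canonical order (simulate, tile,
#' train, fit-nerd, calibrate, infer, evaluate). Each phase writes its
#' artifacts under `config$out_dir` plus a completion marker recording
#' MD5 hashes of its inputs; re-running a completed phase with unchanged
#' inputs is a no-op unless `force = TRUE`. A phase whose upstream
#' artifacts are missing fails with a message naming the phase to run
#' first.
#'
#' @param config a `pcead_pipeline_config`.
#' @param phases subset of the canonical phases.
#' @param force re-run phases even when markers are up to date.
#' @param verbose print progress.
#' @return List of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, phases = PHASE_ORDER, force = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pcead_pipeline_config"))
  phases <- match.arg(phases, PHASE_ORDER, several.ok = TRUE)
  phases <- PHASE_ORDER[PHASE_ORDER %in% phases]
  if (config$reconstructor == "oracle")
    phases <- setdiff(phases, c("tile", "train"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "markers"), showWarnings = FALSE)
  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(
    c(unclass(config), list(package_version =
        as.character(utils::packageVersion("pcead")))),
    cfg_json, digits = I(17), auto_unbox = TRUE, force = TRUE)
  paths <- pipeline_paths(config)
  say <- function(...) if (verbose) message(sprintf(...))
  for (ph in phases) {
    inputs <- phase_inputs(config, ph, paths)
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) {
      need <- phase_producing(config, missing, paths)
      stop(sprintf(
        "phase '%s' is missing input(s) %s; run phase '%s' first",
        ph, paste(basename(missing), collapse = ", "), need))
    }
    marker <- file.path(out, "markers", paste0(ph, ".json"))
    hashes <- unname(tools::md5sum(inputs))
    if (!force && file.exists(marker)) {
      old <- jsonlite::fromJSON(marker)
      if (identical(unname(old$hashes), hashes) &&
          identical(old$seed, config$seed)) {
        say("phase '%s' up to date; skipping", ph)
        next
      }
    }
    say("running phase '%s'", ph)
    run_phase(config, ph, paths)
    jsonlite::write_json(
      list(phase = ph, seed = config$seed, inputs = inputs,
           hashes = hashes, time = format(Sys.time())),
      marker, auto_unbox = TRUE)
  }
  invisible(paths)
}

pipeline_paths <- function(config) {
  out <- config$out_dir
  list(cohort = config$cohort_dir,
       manifest = file.path(config$cohort_dir, "manifest.json"),
       records = file.path(out, "records"),
       model = file.path(out, "model.rds"),
       nerd = file.path(out, "nerd.json"),
       threshold = file.path(out, "threshold.json"),
       preds = file.path(out, "preds"),
       report = file.path(out, "report"))
}

phase_inputs <- function(config, ph, paths) {
  gan <- config$reconstructor == "gan"
  switch(ph,
    simulate = character(0),
    tile = paths$manifest,
    train = c(paths$manifest, first_shard(paths$records)),
    `fit-nerd` = c(paths$manifest, if (gan) paths$model),
    calibrate = c(paths$manifest, paths$nerd, if (gan) paths$model),
    infer = c(paths$manifest, paths$nerd, paths$threshold,
              if (gan) paths$model),
    evaluate = c(paths$manifest, file.path(paths$preds, "index.json")))
}

first_shard <- function(records_dir) {
  sh <- if (dir.exists(records_dir)) list_record_shards(records_dir)
  else character(0)
  if (length(sh)) sh[1] else file.path(records_dir, "missing.rec")
}

phase_producing <- function(config, missing, paths) {
  m <- missing[1]
  if (m == paths$manifest) return("simulate")
  if (dirname(m) == paths$records) return("tile")
  if (m == paths$model) return("train")
  if (m == paths$nerd) return("fit-nerd")
  if (m == paths$threshold) return("calibrate")
  "infer"
}

load_reconstructor <- function(config, paths) {
  if (config$reconstructor == "oracle")
    do.call(oracle_reconstructor, config$oracle)
  else load_model(paths$model)
}

slide_patches <- function(config, slide) {
  t <- config$tiling
  mask <- compute_tissue_mask(slide, t$mask_downsample)
  list(mask = mask,
       patches = extract_patches(slide, mask, t$patch_size,
                                 t$min_tissue_fraction))
}

# Downscale a patch to the model's working resolution when needed.
to_model_res <- function(patch, model) {
  mx <- if (inherits(model, "pcead_model"))
    model$config$max_resolution else Inf
  if (patch$size > mx) {
    pyr <- build_resolution_pyramid(patch, min_size = mx)
    pyr[[length(pyr)]]
  } else patch
}

run_phase <- function(config, ph, paths) {
  manifest <- if (ph != "simulate") read_cohort(config$cohort_dir)
  switch(ph,
    simulate = {
      do.call(make_cohort, c(list(out_dir = config$cohort_dir,
                                  seed = config$seed),
                             config$simulate))
    },
    tile = {
      sl <- manifest$slides
      sel <- sl[sl$phase == "phase1", , drop = FALSE]
      unlink(paths$records, recursive = TRUE)
      for (i in seq_len(nrow(sel))) {
        slide <- read_slide(file.path(config$cohort_dir, sel$file[i]),
                            id = sel$id[i])
        sp <- slide_patches(config, slide)
        all_levels <- unlist(lapply(sp$patches, build_resolution_pyramid),
                             recursive = FALSE)
        write_record_shards(all_levels, paths$records)
      }
    },
    train = {
      model <- train_phase1(paths$records, config$network,
                            config$schedule, seed = config$seed + 1L)
      save_model(model, paths$model)
    },
    `fit-nerd` = {
      model <- load_reconstructor(config, paths)
      acc <- nerd_accumulator()
      sl <- manifest$slides
      sel <- sl[sl$phase == "phase2", , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        slide <- read_slide(file.path(config$cohort_dir, sel$file[i]),
                            id = sel$id[i])
        sp <- slide_patches(config, slide)
        for (p in sp$patches) {
          p <- to_model_res(p, model)
          err <- reconstruction_error(p, reconstruct(model, p))
          tis <- patch_tissue_mask(p, sp$mask$threshold)
          if (!any(tis)) next
          acc <- nerd_update(
            acc, matrix(err$err, ncol = 3L)[as.vector(tis), ,
                                            drop = FALSE])
        }
      }
      write_nerd(fit_nerd(acc), paths$nerd)
    },
    calibrate = {
      model <- load_reconstructor(config, paths)
      nerd <- read_nerd(paths$nerd)$nerd
      dvals <- list()
      sl <- manifest$slides
      sel <- sl[sl$phase == "phase3", , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        slide <- read_slide(file.path(config$cohort_dir, sel$file[i]),
                            id = sel$id[i])
        sp <- slide_patches(config, slide)
        for (p in sp$patches) {
          p <- to_model_res(p, model)
          err <- reconstruction_error(p, reconstruct(model, p))
          tis <- patch_tissue_mask(p, sp$mask$threshold)
          if (!any(tis)) next
          dvals[[length(dvals) + 1L]] <-
            mahalanobis_map(err, nerd)[tis]
        }
      }
      tau <- calibrate_threshold(unlist(dvals), q = config$q)
      jsonlite::write_json(list(tau = tau$tau, q = tau$q, n = tau$n),
                           paths$threshold, digits = I(17),
                           auto_unbox = TRUE)
    },
    infer = {
      model <- load_reconstructor(config, paths)
      nerd <- read_nerd(paths$nerd)$nerd
      th <- jsonlite::fromJSON(paths$threshold)
      tau <- structure(list(tau = th$tau, q = th$q, n = th$n),
                       class = "pcead_threshold")
      dir.create(paths$preds, showWarnings = FALSE)
      sl <- manifest$slides
      sel <- sl[sl$phase == "inference", , drop = FALSE]
      index <- vector("list", nrow(sel))
      for (i in seq_len(nrow(sel))) {
        slide <- read_slide(file.path(config$cohort_dir, sel$file[i]),
                            id = sel$id[i])
        pred <- segment_slide(
          slide, model, nerd, tau,
          patch_size = config$tiling$patch_size,
          min_tissue_fraction = config$tiling$min_tissue_fraction,
          mask_downsample = config$tiling$mask_downsample,
          min_area = config$segmentation$min_area,
          closing_radius = config$segmentation$closing_radius)
        pf <- file.path(paths$preds, paste0(sel$id[i], ".geojson"))
        write_polygons(pred, pf)
        index[[i]] <- list(id = sel$id[i], pred = basename(pf),
                           call = slide_level_call(pred),
                           tissue_bbox = attr(pred, "tissue_bbox"))
      }
      jsonlite::write_json(index, file.path(paths$preds, "index.json"),
                           digits = I(17), auto_unbox = TRUE)
    },
    evaluate = {
      dir.create(paths$report, showWarnings = FALSE)
      index <- jsonlite::fromJSON(file.path(paths$preds, "index.json"),
                                  simplifyVector = FALSE)
      sl <- manifest$slides
      mets <- list()
      for (entry in index) {
        id <- entry$id
        row <- sl[sl$id == id, , drop = FALSE]
        pred <- read_polygons(file.path(paths$preds, entry$pred))
        truth <- read_polygons(file.path(config$cohort_dir, row$truth[1]))
        truth$slide <- id; pred$slide <- id
        region <- if (identical(config$evaluation$region, "tissue-bbox"))
          as.numeric(unlist(entry$tissue_bbox))
        else as.numeric(config$evaluation$region)
        conf <- pixel_confusion(pred, truth, region,
                                config$evaluation$downsample)
        mets[[length(mets) + 1L]] <- confusion_metrics(conf, slide = id)
      }
      rep_ <- summarize_cohort(mets)
      rep_$table$call <- vapply(index, function(e) e$call, "")
      utils::write.csv(rep_$table,
                       file.path(paths$report, "per_slide.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(summary = rep_$summary,
             slide_level_positive =
               sum(rep_$table$call == "positive") / nrow(rep_$table)),
        file.path(paths$report, "cohort.json"),
        digits = I(17), auto_unbox = TRUE, dataframe = "rows")
    })
  invisible(NULL)
}
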