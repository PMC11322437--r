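# allowed run-configuration keys, per stage
.run_config_schema <- list(
  top = c("stage", "seed", "out_dir", "scene", "patches", "train",
          "detect", "quantify"),
  scene = c("n_scenes", "height_px", "width_px", "pixel_size_um",
            "reporter", "n_cells", "foreground_background_ratio",
            "gaussian_noise_sd", "poisson_scale", "psf_sigma_px",
            "min_center_separation_px"),
  patches = c("n_neuron", "n_background"),
  train = c("epochs", "learning_rate", "batch_size", "n_train_per_class"),
  detect = c("stride", "min_pixels"),
  quantify = c("tolerance_px"))

#' Read and validate a run configuration
#'
#' Flat YAML with a `stage`, a `seed`, an `out_dir` and per-stage
#' parameter blocks mirroring the package defaults.  Unknown keys are
#' rejected (a typo must not silently fall back to a default).
#'
#' @param path YAML file path.
#' @return A validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a configuration list (as from `yaml::read_yaml`).
#' @export
validateRunConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), .run_config_schema$top)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (block in intersect(names(cfg), names(.run_config_schema))) {
    if (block == "top") next
    bad <- setdiff(names(cfg[[block]]), .run_config_schema[[block]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s' block: %s", block,
                   paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$stage)) cfg$stage <- "run"
  cfg
}

cfgGet <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

#' Run the end-to-end detection pipeline from a configuration
#'
#' Simulate scenes, build and train the classifier, detect neurons on a
#' held-out scene, match against ground truth and write metrics -- all
#' driven from one config and one seed, with every output checksummed
#' into a manifest so identical configurations produce identical
#' manifests.  A stage failure aborts with the stage name and persists
#' the partial manifest.
#'
#' @param cfg a configuration list (see [readRunConfig()]).
#' @return The manifest list, invisibly; files are written to
#'   `cfg$out_dir`.
#' @export
runPipeline <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  out_dir <- cfg$out_dir %||% stop("configuration must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "rvquant",
                   version = as.character(utils::packageVersion("rvquant")),
                   seed = seed, parameters = cfg, outputs = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  persist <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      persist()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
    })
  }
  record <- function(path) {
    manifest$outputs[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }

  scene_cfgs <- run_stage("simulate", {
    n_scenes <- cfgGet(cfg, "scene", "n_scenes", 3L)
    lapply(seq_len(n_scenes), function(i) {
      sceneConfig(
        height_px = cfgGet(cfg, "scene", "height_px", 192L),
        width_px = cfgGet(cfg, "scene", "width_px", 192L),
        pixel_size_um = cfgGet(cfg, "scene", "pixel_size_um", 0.65),
        reporter = cfgGet(cfg, "scene", "reporter", "nuclear"),
        n_cells = cfgGet(cfg, "scene", "n_cells", 8L),
        foreground_background_ratio =
          cfgGet(cfg, "scene", "foreground_background_ratio", 5),
        gaussian_noise_sd = cfgGet(cfg, "scene", "gaussian_noise_sd", 0.05),
        poisson_scale = cfgGet(cfg, "scene", "poisson_scale", 200),
        psf_sigma_px = cfgGet(cfg, "scene", "psf_sigma_px", 1),
        min_center_separation_px =
          cfgGet(cfg, "scene", "min_center_separation_px", 20),
        seed = deriveSeed(seed, paste0("scene-", i)))
    })
  })

  model <- run_stage("train", {
    ds <- renderPatchDataset(
      scene_cfgs[-length(scene_cfgs)],
      n_neuron = cfgGet(cfg, "patches", "n_neuron", 12L),
      n_background = cfgGet(cfg, "patches", "n_background", 12L),
      seed = deriveSeed(seed, "patches"))
    ds <- splitDataset(ds,
                       n_train_per_class =
                         cfgGet(cfg, "train", "n_train_per_class", 8L),
                       seed = deriveSeed(seed, "split"))
    m <- buildModel(modelSpec(), seed = deriveSeed(seed, "model"))
    trainModel(m, ds,
               epochs = cfgGet(cfg, "train", "epochs", 10L),
               learning_rate = cfgGet(cfg, "train", "learning_rate", 0.001),
               batch_size = cfgGet(cfg, "train", "batch_size", 128L),
               seed = deriveSeed(seed, "train"))
  })
  model_path <- file.path(out_dir, "model.json")
  writeTrainedModel(model, model_path)
  record(model_path)

  metrics <- run_stage("detect", {
    test_cfg <- scene_cfgs[[length(scene_cfgs)]]
    sc <- renderScene(test_cfg)
    img_path <- file.path(out_dir, "scene.tif")
    writeImageTiff(sc$image * 1000, img_path)
    record(img_path)
    truth_path <- file.path(out_dir, "truth.json")
    writeGroundTruth(sc$truth, truth_path)
    record(truth_path)
    mask <- detectMask(model, sc$image,
                       stride = cfgGet(cfg, "detect", "stride", 2L))
    det <- isolateNeurons(mask,
                          min_pixels = cfgGet(cfg, "detect", "min_pixels",
                                              20L))
    det_path <- file.path(out_dir, "components.csv")
    writeTableCsv(det, det_path)
    record(det_path)
    tol <- cfgGet(cfg, "quantify", "tolerance_px",
                  1.5 * mean(test_cfg@nucleus_radius_um) /
                    test_cfg@pixel_size_um)
    match <- matchDetections(det, sc$truth, tolerance_px = tol)
    detectionMetrics(match)
  })

  metrics_path <- file.path(out_dir, "metrics.csv")
  write.csv(data.frame(scene = length(scene_cfgs),
                       detection_fraction = metrics$detection_fraction,
                       detection_accuracy = metrics$detection_accuracy,
                       n_truth = metrics$n_truth,
                       n_detected = metrics$n_detected,
                       n_correct = metrics$n_correct),
            metrics_path, row.names = FALSE)
  record(metrics_path)
  manifest$metrics <- metrics
  persist()
  invisible(manifest)
}
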