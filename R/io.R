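#' Read a TIFF image or stack
#'
#' Single-page TIFFs are returned as a numeric matrix of non-negative
#' intensities; multi-page TIFFs as an [ImageStack-class].  Integer TIFFs
#' (8 or 16 bit) are read as raw integer counts.  The frame interval of a
#' stack is taken from `frame_interval_s`, or from a JSON sidecar
#' `<path>.meta.json` with fields `frame_interval_s` / `pixel_size_um`.
#'
#' @param path TIFF file path.
#' @param frame_interval_s,pixel_size_um stack calibration overrides.
#' @return A matrix or an [ImageStack-class].
#' @export
readImageTiff <- function(path, frame_interval_s = NULL,
                          pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("no such image file: '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  depth <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(depth) && !depth %in% c(8, 16, 32)) {
    stop(sprintf("unsupported TIFF bit depth: %d", depth))
  }
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      stop("multi-channel TIFF not supported; provide single-channel images")
    }
    matrix(as.numeric(p), nrow = nrow(p))
  })
  if (length(mats) == 1) return(mats[[1]])
  sidecar <- paste0(path, ".meta.json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  dt <- frame_interval_s %||% meta$frame_interval_s %||% 1
  ps <- pixel_size_um %||% meta$pixel_size_um %||% 1
  new("ImageStack", frames = mats, frame_interval_s = dt,
      pixel_size_um = ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image or stack as TIFF
#'
#' Integer intensities are written losslessly at the requested bit depth
#' (values are clamped to the representable range); an [ImageStack-class]
#' becomes a multi-page TIFF and its calibration is stored in a JSON
#' sidecar `<path>.meta.json`.
#'
#' @param image numeric matrix or [ImageStack-class].
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @return The path, invisibly.
#' @export
writeImageTiff <- function(image, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  to01 <- function(m) pmin(pmax(round(m), 0), maxval) / maxval
  if (is(image, "ImageStack")) {
    tiff::writeTIFF(lapply(image@frames, to01), path,
                    bits.per.sample = bits, compression = "none")
    jsonlite::write_json(list(frame_interval_s = image@frame_interval_s,
                              pixel_size_um = image@pixel_size_um),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    tiff::writeTIFF(to01(image), path, bits.per.sample = bits,
                    compression = "none")
  }
  invisible(path)
}

#' Write ground truth as JSON
#'
#' Versioned schema (`schema: 1`): neurons, particles, spines and plaque
#' keyed by object id.
#'
#' @param truth a [GroundTruth-class].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  obj <- list(schema = 1,
              dims = truth@dims,
              neurons = truth@neurons,
              particles = truth@particles,
              spines = truth@spines,
              plaque = as.list(truth@plaque),
              path_length_um = truth@path_length_um)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [writeGroundTruth()]
#'
#' Masks and trajectories are not serialized; centroid-level truth is.
#'
#' @param path JSON path.
#' @return A [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != 1) {
    stop("unknown ground-truth schema version")
  }
  truth <- emptyGroundTruth(as.integer(obj$dims))
  asdf <- function(x, template) {
    if (is.null(x) || !length(x)) template else as.data.frame(x)
  }
  truth@neurons <- asdf(obj$neurons, truth@neurons)
  truth@particles <- asdf(obj$particles, truth@particles)
  truth@spines <- asdf(obj$spines, truth@spines)
  if (length(obj$plaque)) truth@plaque <- unlist(obj$plaque)
  if (length(obj$path_length_um)) truth@path_length_um <- obj$path_length_um
  truth
}

#' Write ground truth as a flat CSV (one row per object)
#'
#' @param truth a [GroundTruth-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeGroundTruthCsv <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  rows <- list()
  if (nrow(truth@neurons)) {
    rows$neurons <- data.frame(type = "neuron", id = truth@neurons$id,
                               v1 = truth@neurons$centroid_row,
                               v2 = truth@neurons$centroid_col)
  }
  if (nrow(truth@particles)) {
    rows$particles <- data.frame(type = "particle",
                                 id = truth@particles$id,
                                 v1 = truth@particles$true_area_um2, v2 = NA)
  }
  if (nrow(truth@spines)) {
    rows$spines <- data.frame(type = "spine",
                              id = seq_len(nrow(truth@spines)),
                              v1 = truth@spines$position_um,
                              v2 = truth@spines$distance_um)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), id = integer(0), v1 = numeric(0),
               v2 = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a trained model to a portable JSON file
#'
#' The architecture, training log and all weights are stored as one JSON
#' document (numbers at full precision), so a model round-trips exactly.
#'
#' @param model a [TrainedModel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeTrainedModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  s <- model@spec
  obj <- list(
    format = "rvquant-model", version = 1,
    spec = list(kernel_sizes = s@kernel_sizes,
                filters_per_conv = s@filters_per_conv,
                pool_size = s@pool_size, pool_stride = s@pool_stride,
                input_shape = s@input_shape),
    trained = model@trained,
    train_log = model@train_log,
    params = lapply(model@params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
      else list(dim = length(p), values = as.numeric(p))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [writeTrainedModel()]
#'
#' @param path JSON path.
#' @return A [TrainedModel-class].
#' @export
readTrainedModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "rvquant-model") {
    stop("not an rvquant model file")
  }
  spec <- modelSpec(kernel_sizes = obj$spec$kernel_sizes,
                    filters_per_conv = obj$spec$filters_per_conv,
                    pool_size = obj$spec$pool_size,
                    pool_stride = obj$spec$pool_stride,
                    input_shape = obj$spec$input_shape)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$values, p$dim[1], p$dim[2])
    else as.numeric(p$values)
  })
  log <- obj$train_log
  if (length(log)) log$epochs <- as.integer(log$epochs)
  new("TrainedModel", spec = spec, params = params,
      train_log = if (length(log)) log else list(),
      trained = isTRUE(obj$trained))
}

#' Write a detection set or particle table as CSV
#'
#' @param x a [DetectionSet-class] or [ParticleTable-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTableCsv <- function(x, path) {
  df <- if (is(x, "DetectionSet")) components(x)
        else if (is(x, "ParticleTable")) particleData(x)
        else stop("unsupported object for CSV export")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
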