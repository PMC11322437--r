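#' @describeIn sceneConfig display method
#' @param object a `SceneConfig`
#' @export
setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px (%.2f um/px), reporter=%s, %d cells, seed=%d\n",
              object@height_px, object@width_px, object@pixel_size_um,
              object@reporter, object@n_cells, object@seed))
  cat(sprintf("  contrast %.1f, psf %.1f px, noise sd %.3f, poisson scale %.0f\n",
              object@foreground_background_ratio, object@psf_sigma_px,
              object@gaussian_noise_sd, object@poisson_scale))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d neurons, %d particles, %d spines%s\n",
              nrow(object@neurons), nrow(object@particles),
              nrow(object@spines),
              if (length(object@plaque)) ", 1 plaque" else ""))
  invisible(NULL)
})

setMethod("show", "PatchDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf("PatchDataset: %d patches (%d neuron, %d background), %s, %s\n",
              dim(object@patches)[3], tab[["neuron"]], tab[["background"]],
              if (object@normalized) "normalized" else "raw",
              if (length(object@split))
                sprintf("split %d/%d", length(object@split$train),
                        length(object@split$validation)) else "unsplit"))
  invisible(NULL)
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: 12 layers, conv %dx%d (%d filters) and %dx%d (%d filters), input %s\n",
              object@kernel_sizes[1], object@kernel_sizes[1],
              object@filters_per_conv[1], object@kernel_sizes[2],
              object@kernel_sizes[2], object@filters_per_conv[2],
              paste(object@input_shape, collapse = "x")))
  invisible(NULL)
})

setMethod("show", "TrainedModel", function(object) {
  if (object@trained) {
    cat(sprintf("TrainedModel: %d epochs, lr %g, validation accuracy %.4f\n",
                object@train_log$epochs, object@train_log$learning_rate,
                object@train_log$validation_accuracy))
  } else {
    cat("TrainedModel: untrained (initial weights)\n")
  }
  show(object@spec)
  invisible(NULL)
})

setMethod("show", "DetectionMask", function(object) {
  cat(sprintf("DetectionMask: %d x %d, %.2f%% positive, border %d px, stride %d\n",
              nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask), object@border_margin_px,
              object@stride))
  invisible(NULL)
})

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet: %d components (>= %d px) in %d x %d image\n",
              nrow(object@components), object@min_pixels, object@dims[1],
              object@dims[2]))
  invisible(NULL)
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d pairs, %d unmatched detections, %d unmatched truths (tol %.1f px)\n",
              nrow(object@pairs), length(object@unmatched_detections),
              length(object@unmatched_truth), object@tolerance_px))
  invisible(NULL)
})

setMethod("show", "TestResult", function(object) {
  extra <- if (object@n_total > 0)
    sprintf(" (%d/%d arrangements)", object@n_extreme, object@n_total) else ""
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s, n = %s\n", object@method,
              object@statistic, object@p_value, extra,
              paste(object@n_per_group, collapse = ",")))
  invisible(NULL)
})

setMethod("show", "ParticleTable", function(object) {
  cat(sprintf("ParticleTable: %d particles at %.3f um/px", nrow(object@particles),
              object@pixel_size_um))
  if (length(object@filter_log))
    cat(sprintf(" (filtered %g-%g um2: kept %d, excluded %d)",
                object@filter_log$min_area, object@filter_log$max_area,
                object@filter_log$n_kept, object@filter_log$n_excluded))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageStack: %d frames of %d x %d, dt = %.3f s, %.3f um/px\n",
              length(object@frames), d[1], d[2], object@frame_interval_s,
              object@pixel_size_um))
  invisible(NULL)
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks, dt = %.3f s, %.3f um/px\n",
              nrow(object@tracks), object@frame_interval_s,
              object@pixel_size_um))
  invisible(NULL)
})

# ---- accessors -------------------------------------------------------------

#' Accessors for rvquant containers
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `neurons()`, `particleData()`, `components()`, `matchedPairs()`,
#' `trainLog()`, `stackFrames()`.
#'
#' @param x the container object.
#' @return The underlying data.frame or list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("neurons", function(x) standardGeneric("neurons"))
#' @rdname accessors
#' @export
setMethod("neurons", "GroundTruth", function(x) x@neurons)

#' @rdname accessors
#' @export
setGeneric("particleData", function(x) standardGeneric("particleData"))
#' @rdname accessors
#' @export
setMethod("particleData", "ParticleTable", function(x) x@particles)
#' @rdname accessors
#' @export
setMethod("particleData", "GroundTruth", function(x) x@particles)

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setMethod("components", "DetectionSet", function(x) x@components)

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setMethod("matchedPairs", "MatchResult", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))
#' @rdname accessors
#' @export
setMethod("trainLog", "TrainedModel", function(x) x@train_log)

#' @rdname accessors
#' @export
setGeneric("stackFrames", function(x) standardGeneric("stackFrames"))
#' @rdname accessors
#' @export
setMethod("stackFrames", "ImageStack", function(x) x@frames)
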