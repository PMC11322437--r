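#' Render a synthetic fluorescence scene with ground truth
#'
#' Draws `n_cells` neurons at random non-overlapping positions, renders the
#' reporter-dependent fluorescence (nuclei only for nuclear reporters; soma
#' plus neurites for cytoplasmic; a membrane annulus for membrane), applies
#' Gaussian PSF blur and then Poisson-Gaussian camera noise, and returns
#' both the image and per-neuron ground truth.  Background intensity is 1;
#' labeled structures plateau at `foreground_background_ratio`.
#'
#' Geometry and noise are drawn from separate substreams of `config@seed`,
#' so re-rendering the same configuration with noise disabled
#' (`gaussian_noise_sd = 0`, `poisson_scale = 0`) reproduces the identical
#' noise-free geometry.
#'
#' @param config a [SceneConfig-class].
#' @return A list with `image` (numeric matrix) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' sc <- renderScene(sceneConfig(height_px = 128, width_px = 128,
#'                               n_cells = 2, seed = 7))
#' dim(sc$image)
#' neurons(sc$truth)
#' @export
renderScene <- function(config) {
  validObject(config)
  H <- config@height_px; W <- config@width_px
  ps <- config@pixel_size_um
  n <- config@n_cells
  amp <- config@foreground_background_ratio - 1

  geom <- withSeed(deriveSeed(config@seed, "scene-geometry"), {
    placeCells(config)
  })

  canvas <- matrix(0, H, W)
  nucleus_masks <- vector("list", n)
  soma_masks <- vector("list", n)
  if (n > 0) {
    for (i in seq_len(n)) {
      r0 <- geom$pos[i, 1]; c0 <- geom$pos[i, 2]
      rn <- geom$nucleus_px[i]; rs <- geom$soma_px[i]
      if (config@reporter == "nuclear") {
        # amplitude calibrated so the post-PSF mean over the nucleus mask
        # equals the configured plateau
        canvas <- stampDisk(canvas, r0, c0, rn,
                            amp / blurredDiskMaskMean(rn, config@psf_sigma_px))
      } else if (config@reporter == "cytoplasmic") {
        canvas <- stampDisk(canvas, r0, c0, rs,
                            amp / blurredDiskMaskMean(rs, config@psf_sigma_px))
        canvas <- stampNeurites(canvas, geom$neurites[[i]], 0.6 * amp)
      } else { # membrane: annulus of ~1.5 px at the soma boundary
        canvas <- stampDisk(canvas, r0, c0, rs, amp)
        canvas <- stampDisk(canvas, r0, c0, rs - 1.5, -amp)
      }
      nucleus_masks[[i]] <- diskIndices(c(H, W), r0, c0, rn)
      soma_masks[[i]] <- diskIndices(c(H, W), r0, c0, rs)
    }
  }
  img <- blurPSF(1 + canvas, config@psf_sigma_px)
  img <- withSeed(deriveSeed(config@seed, "scene-noise"), {
    applyNoise(img, config@gaussian_noise_sd, config@poisson_scale)
  })

  truth <- emptyGroundTruth(c(H, W))
  truth@neurons <- data.frame(
    id = seq_len(n),
    centroid_row = if (n) geom$pos[, 1] else numeric(0),
    centroid_col = if (n) geom$pos[, 2] else numeric(0),
    nucleus_radius_px = geom$nucleus_px, soma_radius_px = geom$soma_px)
  truth@nucleus_masks <- nucleus_masks
  truth@soma_masks <- soma_masks
  validObject(truth)
  list(image = img, truth = truth)
}

# sample cell centers (integer pixel positions), radii and neurite paths.
# Placement keeps whole somata inside the image and leaves at least a
# 29-px margin so every centroid supports a full 56x56 centred patch.
placeCells <- function(config) {
  H <- config@height_px; W <- config@width_px
  ps <- config@pixel_size_um
  n <- config@n_cells
  soma_max_px <- config@soma_radius_um[2] / ps
  margin <- max(29, ceiling(soma_max_px) + 2)
  if (n > 0 && (H - 2 * margin < 1 || W - 2 * margin < 1)) {
    stop("image too small to place cells with the required margin")
  }
  pos <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      cand <- c(round(runif(1, margin, H - margin)),
                round(runif(1, margin, W - margin)))
      if (!nrow(pos) ||
          min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
            config@min_center_separation_px) {
        pos <- rbind(pos, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place cell %d of %d at separation ",
                          ">= %.1f px within 1000 attempts; ",
                          "configuration is overcrowded"),
                   i, n, config@min_center_separation_px))
    }
  }
  nucleus_px <- runif(n, config@nucleus_radius_um[1],
                      config@nucleus_radius_um[2]) / ps
  soma_px <- pmax(runif(n, config@soma_radius_um[1],
                        config@soma_radius_um[2]) / ps, nucleus_px)
  neurites <- vector("list", n)
  if (config@reporter == "cytoplasmic" && n > 0) {
    len_px <- config@neurite_length_um / ps
    for (i in seq_len(n)) {
      neurites[[i]] <- lapply(seq_len(config@neurites_per_cell), function(k) {
        neuritePath(pos[i, ], soma_px[i], len_px, c(H, W))
      })
    }
  }
  list(pos = pos, nucleus_px = nucleus_px, soma_px = soma_px,
       neurites = neurites)
}

# smoothed random-walk polyline from the soma edge outward; returns a
# matrix of (row, col) points sampled every ~0.5 px
neuritePath <- function(center, soma_px, length_px, dims) {
  theta <- runif(1, 0, 2 * pi)
  step <- 2
  n_steps <- max(1, ceiling(length_px / step))
  pts <- matrix(NA_real_, n_steps + 1, 2)
  pts[1, ] <- center + soma_px * c(sin(theta), cos(theta))
  for (s in seq_len(n_steps)) {
    theta <- theta + rnorm(1, 0, 0.3)
    pts[s + 1, ] <- pts[s, ] + step * c(sin(theta), cos(theta))
  }
  # resample densely for stamping
  dense <- apply(pts, 2, function(x) {
    approx(seq_len(nrow(pts)), x, n = 4 * nrow(pts))$y
  })
  dense[dense[, 1] >= 1 & dense[, 1] <= dims[1] &
        dense[, 2] >= 1 & dense[, 2] <= dims[2], , drop = FALSE]
}

# stamp a neurite polyline of ~1.5 px thickness; max-composited so
# overlapping samples do not add up
stampNeurites <- function(canvas, paths, amp) {
  if (is.null(paths) || !length(paths)) return(canvas)
  layer <- matrix(0, nrow(canvas), ncol(canvas))
  for (path in paths) {
    if (is.null(path) || !nrow(path)) next
    for (k in seq_len(nrow(path))) {
      r0 <- path[k, 1]; c0 <- path[k, 2]
      rr <- max(1, floor(r0 - 1.5)):min(nrow(canvas), ceiling(r0 + 1.5))
      cc <- max(1, floor(c0 - 1.5)):min(ncol(canvas), ceiling(c0 + 1.5))
      d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
      cov <- pmin(1, pmax(0, 0.75 + 0.5 - d))
      layer[rr, cc] <- pmax(layer[rr, cc], amp * cov)
    }
  }
  canvas + layer
}

#' @importFrom stats approx
NULL

# mean coverage of a PSF-blurred unit-amplitude disk over its own mask
# (dist <= radius): the fraction of the plateau surviving edge blur.
# Computed on a small template through the identical stamp/blur code path
# and cached by (radius, sigma) rounded to 0.01 px.
.disk_mean_cache <- new.env(parent = emptyenv())

blurredDiskMaskMean <- function(radius, sigma) {
  if (sigma <= 0) return(1)
  key <- sprintf("%.2f_%.2f", radius, sigma)
  hit <- .disk_mean_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- ceiling(radius + 4 * sigma) + 2
  n <- 2 * half + 1
  tmpl <- stampDisk(matrix(0, n, n), half + 1, half + 1, radius, 1)
  tmpl <- blurPSF(tmpl, sigma)
  idx <- diskIndices(c(n, n), half + 1, half + 1, radius)
  val <- mean(tmpl[idx])
  .disk_mean_cache[[key]] <- val
  val
}
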