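# shared renderer for mitochondria fields: draws particles as disks of the
# requested physical area with sub-pixel antialiasing, PSF blur and
# camera noise
renderMitoFrame <- function(pos, radii_px, H, W, amp, psf, noise_sd,
                            poisson_scale) {
  canvas <- matrix(0, H, W)
  for (i in seq_len(nrow(pos))) {
    canvas <- stampDisk(canvas, pos[i, 1], pos[i, 2], radii_px[i], amp)
  }
  blurPSF(1 + canvas, psf)
}

# lognormal areas with the requested mean and coefficient of variation
drawAreas <- function(n, mean_um2, cv) {
  if (cv == 0) return(rep(mean_um2, n))
  sigma2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean_um2) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Render a time-lapse sequence of moving mitochondria
#'
#' Places `n_particles` punctae with lognormal areas; a `motile_fraction`
#' subset translocates at `speed_um_per_s` along a fixed (per-particle)
#' axis, reflecting at the field border, while the remaining particles
#' stay stationary up to sub-pixel jitter (at most 0.5 px per frame).
#' Ground truth records every particle's true area and per-frame centroid.
#'
#' @param config a [MotilityConfig-class].
#' @return A list with `stack` ([ImageStack-class]) and `truth`
#'   ([GroundTruth-class] with `particles` and `trajectories`).
#' @export
renderMitoSequence <- function(config) {
  validObject(config)
  ps <- config@pixel_size_um
  H <- config@height_px; W <- config@width_px
  n <- config@n_particles
  step_px <- config@speed_um_per_s * config@frame_interval_s / ps

  geom <- withSeed(deriveSeed(config@seed, "mito-geometry"), {
    areas <- drawAreas(n, config@area_mean_um2, config@area_cv)
    radii_px <- sqrt(areas / pi) / ps
    margin <- max(radii_px) + 3
    pos <- placePoints(n, H, W, margin, config@min_separation_px)
    n_motile <- round(config@motile_fraction * n)
    motile <- seq_len(n) <= n_motile  # first particles are the motile ones
    dirs <- matrix(0, n, 2)
    if (n_motile > 0) {
      ang <- runif(n_motile, 0, 2 * pi)
      dirs[seq_len(n_motile), ] <- cbind(sin(ang), cos(ang))
    }
    list(areas = areas, radii_px = radii_px, pos = pos, motile = motile,
         dirs = dirs, margin = margin)
  })

  if (n > 1) {
    dmin <- min(dist(geom$pos))
    if (step_px > dmin / 2) {
      stop(sprintf(paste0("per-frame displacement %.2f px exceeds half the ",
                          "minimum particle spacing %.2f px; tracking would ",
                          "be ambiguous"), step_px, dmin / 2))
    }
  }

  traj <- withSeed(deriveSeed(config@seed, "mito-motion"), {
    out <- lapply(seq_len(n), function(i) matrix(NA_real_, config@frames, 2))
    cur <- geom$pos
    dirs <- geom$dirs
    for (f in seq_len(config@frames)) {
      for (i in seq_len(n)) {
        if (f > 1) {
          if (geom$motile[i]) {
            cand <- cur[i, ] + step_px * dirs[i, ]
            # reflect at the margins so long runs stay in the field
            for (k in 1:2) {
              lim <- if (k == 1) H else W
              if (cand[k] < geom$margin || cand[k] > lim - geom$margin) {
                dirs[i, k] <- -dirs[i, k]
                cand <- cur[i, ] + step_px * dirs[i, ]
              }
            }
            cur[i, ] <- cand
          } else {
            # jitter radius <= 0.25 px about the base position, so the
            # frame-to-frame displacement never exceeds 0.5 px
            ang <- runif(1, 0, 2 * pi)
            rad <- runif(1, 0, 0.25)
            cur[i, ] <- geom$pos[i, ] + rad * c(sin(ang), cos(ang))
          }
        }
        out[[i]][f, ] <- cur[i, ]
      }
    }
    out
  })

  amp <- config@foreground_background_ratio - 1
  frames <- withSeed(deriveSeed(config@seed, "mito-noise"), {
    lapply(seq_len(config@frames), function(f) {
      pos_f <- do.call(rbind, lapply(traj, function(t) t[f, ]))
      img <- renderMitoFrame(pos_f, geom$radii_px, H, W, amp,
                             config@psf_sigma_px, config@gaussian_noise_sd,
                             config@poisson_scale)
      applyNoise(img, config@gaussian_noise_sd, config@poisson_scale)
    })
  })

  truth <- emptyGroundTruth(c(H, W))
  truth@particles <- data.frame(id = seq_len(n),
                                true_area_um2 = geom$areas)
  truth@trajectories <- traj
  stack <- new("ImageStack", frames = frames,
               frame_interval_s = config@frame_interval_s,
               pixel_size_um = ps)
  list(stack = stack, truth = truth)
}

#' Render a static field of mitochondria-like particles
#'
#' Single-frame convenience renderer for morphometry studies: particles
#' with lognormal areas of the requested mean and CV, no motion.
#'
#' @param n_particles number of particles.
#' @param area_mean_um2,area_cv area distribution (mean in um^2, CV).
#' @param height_px,width_px,pixel_size_um field geometry.
#' @param foreground_background_ratio,psf_sigma_px,gaussian_noise_sd,poisson_scale
#'   rendering and noise parameters.
#' @param min_separation_px minimum particle spacing.
#' @param seed RNG seed.
#' @return A list with `image` and `truth` (particle areas and positions).
#' @export
renderMitoField <- function(n_particles = 50L, area_mean_um2 = 0.7,
                            area_cv = 0.3, height_px = 256L,
                            width_px = 256L, pixel_size_um = 0.16,
                            foreground_background_ratio = 8,
                            psf_sigma_px = 0.6, gaussian_noise_sd = 0.03,
                            poisson_scale = 500, min_separation_px = 12,
                            seed = 1L) {
  geom <- withSeed(deriveSeed(seed, "mito-field"), {
    areas <- drawAreas(n_particles, area_mean_um2, area_cv)
    radii_px <- sqrt(areas / pi) / pixel_size_um
    margin <- max(radii_px) + 3
    pos <- placePoints(n_particles, height_px, width_px, margin,
                       min_separation_px)
    list(areas = areas, radii_px = radii_px, pos = pos)
  })
  img <- renderMitoFrame(geom$pos, geom$radii_px, height_px, width_px,
                         foreground_background_ratio - 1, psf_sigma_px,
                         gaussian_noise_sd, poisson_scale)
  img <- withSeed(deriveSeed(seed, "mito-field-noise"), {
    applyNoise(img, gaussian_noise_sd, poisson_scale)
  })
  truth <- emptyGroundTruth(c(height_px, width_px))
  truth@particles <- data.frame(id = seq_len(n_particles),
                                true_area_um2 = geom$areas)
  truth@trajectories <- lapply(seq_len(n_particles), function(i) {
    matrix(geom$pos[i, ], 1, 2)
  })
  list(image = img, truth = truth)
}

# rejection-sampled point placement with minimum spacing
placePoints <- function(n, H, W, margin, min_sep) {
  pos <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(2000)) {
      cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      if (!nrow(pos) ||
          min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
            min_sep) {
        pos <- rbind(pos, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place particles at the requested spacing")
  }
  pos
}

#' @importFrom stats dist
NULL
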