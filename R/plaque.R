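#' Render a dendrite-and-plaque scene with spine ground truth
#'
#' Emulates sparse labeling of a dendrite passing an amyloid plaque:
#' spines are placed along the dendrite by an inhomogeneous Poisson point
#' process whose intensity (spines per um) depends on the distance to the
#' plaque center, so distance-dependent spine loss can be planted and
#' recovered.  Ground truth records every spine's position along the
#' dendrite and its distance to the plaque center.
#'
#' The dendrite is a straight path of `dendrite_length_um`; the plaque
#' center sits on it at `plaque_center_um` from its start, so the distance
#' of a spine to the plaque center equals the along-path distance.
#'
#' @param dendrite_length_um dendrite length (um).
#' @param plaque_center_um plaque center position along the dendrite (um).
#' @param plaque_radius_um plaque radius (um).
#' @param density_profile function mapping distance-to-plaque (um) to
#'   expected spines per um (vectorized, non-negative).
#' @param pixel_size_um pixel size for the rendered image.
#' @param seed RNG seed.
#' @param render_image set FALSE to skip rasterizing the image (the point
#'   process and truth are unaffected); useful in simulation loops.
#' @return A list with `image` (matrix or NULL) and `truth`
#'   ([GroundTruth-class] with `spines`, `plaque`, `path` filled).
#' @export
renderPlaqueScene <- function(dendrite_length_um = 120,
                              plaque_center_um = 40,
                              plaque_radius_um = 15,
                              density_profile = function(d) rep(0.5, length(d)),
                              pixel_size_um = 0.2, seed = 1L,
                              render_image = TRUE) {
  stopifnot(dendrite_length_um > 0, plaque_radius_um > 0)
  grid_pos <- seq(0, dendrite_length_um, by = 0.1)
  grid_dist <- abs(grid_pos - plaque_center_um)
  lam <- density_profile(grid_dist)
  if (any(lam < 0)) stop("spine density profile must be non-negative")
  lam_max <- max(lam)

  spines <- withSeed(deriveSeed(seed, "spine-process"), {
    if (lam_max == 0) {
      data.frame(position_um = numeric(0), distance_um = numeric(0))
    } else {
      # Poisson thinning of a homogeneous process at rate lam_max
      n_cand <- rpois(1, lam_max * dendrite_length_um)
      pos <- runif(n_cand, 0, dendrite_length_um)
      d <- abs(pos - plaque_center_um)
      keep <- runif(n_cand) < density_profile(d) / lam_max
      pos <- sort(pos[keep])
      data.frame(position_um = pos,
                 distance_um = abs(pos - plaque_center_um))
    }
  })

  # image geometry: dendrite along the horizontal mid-line
  margin_um <- 6
  H <- ceiling(2 * margin_um / pixel_size_um) + 1
  W <- ceiling((dendrite_length_um + 2 * margin_um) / pixel_size_um)
  r_mid <- (H + 1) / 2
  c_of <- function(pos_um) (pos_um + margin_um) / pixel_size_um + 1

  img <- NULL
  if (render_image) {
    canvas <- matrix(0, H, W)
    # dendrite shaft ~0.6 um thick
    for (pos in seq(0, dendrite_length_um, by = pixel_size_um / 2)) {
      canvas <- stampDisk(canvas, r_mid, c_of(pos), 0.3 / pixel_size_um, 2)
    }
    canvas <- pmin(canvas, 2)
    # spines: bright puncta offset perpendicular to the shaft
    side <- withSeed(deriveSeed(seed, "spine-side"), {
      sample(c(-1, 1), nrow(spines), replace = TRUE)
    })
    if (nrow(spines)) {
      for (i in seq_len(nrow(spines))) {
        canvas <- stampDisk(canvas,
                            r_mid + side[i] * 0.8 / pixel_size_um,
                            c_of(spines$position_um[i]),
                            0.25 / pixel_size_um, 4)
      }
    }
    # faint plaque halo
    canvas <- stampDisk(canvas, r_mid, c_of(plaque_center_um),
                        plaque_radius_um / pixel_size_um, 0.5)
    img <- blurPSF(1 + canvas, 1)
    img <- withSeed(deriveSeed(seed, "plaque-noise"), {
      applyNoise(img, 0.03, 500)
    })
  }

  truth <- emptyGroundTruth(c(H, W))
  truth@spines <- spines
  truth@plaque <- c(center_row = r_mid, center_col = c_of(plaque_center_um),
                    radius_um = plaque_radius_um)
  truth@path <- cbind(position_um = grid_pos, distance_um = grid_dist)
  truth@path_length_um <- dendrite_length_um
  list(image = img, truth = truth)
}

#' Normalized spine counts over three distance segments
#'
#' Splits each replicate's dendrite into three distance-to-plaque bins,
#' computes the spine density (spines per um of dendrite falling in the
#' bin) and normalizes per replicate by the across-segment total, so the
#' three values of a replicate sum to 1.  Segments are then compared with
#' the Kruskal-Wallis test across replicates ([kruskalWallisExact()]).
#'
#' @param replicates list of [GroundTruth-class] objects from
#'   [renderPlaqueScene()] (each with `spines` and `path` filled).
#' @param boundaries numeric length-4 vector of distance breaks (um)
#'   partitioning `[boundaries[1], boundaries[4]]` into the proximal,
#'   middle and distal segments.
#' @return A list with `shares` (replicates x 3 matrix of normalized
#'   values), `densities` (spines per um before normalization) and `test`
#'   (a [TestResult-class]); replicates with zero spines in range are
#'   dropped with a warning.
#' @export
spineSegmentStatistic <- function(replicates, boundaries) {
  stopifnot(length(boundaries) == 4, !is.unsorted(boundaries))
  if (is(replicates, "GroundTruth")) replicates <- list(replicates)
  shares <- matrix(NA_real_, 0, 3)
  dens_all <- matrix(NA_real_, 0, 3)
  dropped <- 0L
  for (truth in replicates) {
    stopifnot(is(truth, "GroundTruth"))
    d <- truth@spines$distance_um
    path_d <- truth@path[, "distance_um"]
    # dendrite length inside each bin, from the dense path sampling
    step <- truth@path_length_um / (length(path_d) - 1)
    counts <- numeric(3); lens <- numeric(3)
    for (s in 1:3) {
      lo <- boundaries[s]; hi <- boundaries[s + 1]
      inb <- if (s == 3) d >= lo & d <= hi else d >= lo & d < hi
      counts[s] <- sum(inb)
      inp <- if (s == 3) path_d >= lo & path_d <= hi else
        path_d >= lo & path_d < hi
      lens[s] <- sum(inp) * step
    }
    if (sum(counts) == 0) {
      dropped <- dropped + 1L
      next
    }
    dens <- ifelse(lens > 0, counts / lens, 0)
    shares <- rbind(shares, dens / sum(dens))
    dens_all <- rbind(dens_all, dens)
  }
  if (dropped > 0) {
    warning(sprintf("%d replicate(s) with zero spines dropped", dropped))
  }
  if (!nrow(shares)) stop("no replicate with spines in the given range")
  colnames(shares) <- colnames(dens_all) <-
    c("proximal", "middle", "distal")
  test <- if (nrow(shares) >= 2) {
    kruskalWallisExact(list(shares[, 1], shares[, 2], shares[, 3]))
  } else NULL
  list(shares = shares, densities = dens_all, test = test)
}
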