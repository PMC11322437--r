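#' Scene configuration for the synthetic microscopy generator
#'
#' Full parameterization of one synthetic fluorescence scene.  The reporter
#' determines where signal is rendered: `"nuclear"` confines fluorescence to
#' compact nuclei (nuclear-localization-signal reporters label no neurites),
#' `"cytoplasmic"` fills the whole soma and sends signal down neurites, and
#' `"membrane"` labels an annulus at the soma boundary.  All geometric
#' quantities are in micrometres and converted to pixels via
#' `pixel_size_um`.
#'
#' @slot height_px,width_px image dimensions in pixels.
#' @slot pixel_size_um physical pixel size (um per px).
#' @slot reporter one of `"nuclear"`, `"cytoplasmic"`, `"membrane"`.
#' @slot n_cells number of neurons to place.
#' @slot nucleus_radius_um,soma_radius_um `(min, max)` radius ranges (um).
#' @slot neurites_per_cell,neurite_length_um neurite count and length; only
#'   rendered for non-nuclear reporters.
#' @slot foreground_background_ratio plateau intensity of labeled structures
#'   relative to background (> 1).
#' @slot psf_sigma_px Gaussian point-spread sigma in pixels.
#' @slot gaussian_noise_sd,poisson_scale camera noise: additive Gaussian sd
#'   (intensity units) and photon scaling (counts per intensity unit; 0
#'   disables shot noise).
#' @slot min_center_separation_px minimum distance between cell centers.
#' @slot seed integer RNG seed; identical config + seed is bit-reproducible.
#' @export
setClass("SceneConfig", representation(
  height_px = "integer", width_px = "integer", pixel_size_um = "numeric",
  reporter = "character", n_cells = "integer",
  nucleus_radius_um = "numeric", soma_radius_um = "numeric",
  neurites_per_cell = "integer", neurite_length_um = "numeric",
  foreground_background_ratio = "numeric", psf_sigma_px = "numeric",
  gaussian_noise_sd = "numeric", poisson_scale = "numeric",
  min_center_separation_px = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character(0)
  if (object@height_px < 1 || object@width_px < 1)
    msg <- c(msg, "image dimensions must be positive")
  if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
  if (!object@reporter %in% c("nuclear", "cytoplasmic", "membrane"))
    msg <- c(msg, "reporter must be nuclear, cytoplasmic or membrane")
  if (object@n_cells < 0) msg <- c(msg, "n_cells must be >= 0")
  if (length(object@nucleus_radius_um) != 2 ||
      any(object@nucleus_radius_um <= 0) ||
      diff(object@nucleus_radius_um) < 0)
    msg <- c(msg, "nucleus_radius_um must be an increasing positive pair")
  if (length(object@soma_radius_um) != 2 || any(object@soma_radius_um <= 0) ||
      diff(object@soma_radius_um) < 0)
    msg <- c(msg, "soma_radius_um must be an increasing positive pair")
  if (object@reporter %in% c("cytoplasmic", "membrane") &&
      object@nucleus_radius_um[2] > object@soma_radius_um[1])
    msg <- c(msg, "nucleus radius max must not exceed soma radius min")
  if (object@foreground_background_ratio <= 1)
    msg <- c(msg, "foreground_background_ratio must be > 1")
  if (object@psf_sigma_px < 0 || object@gaussian_noise_sd < 0 ||
      object@poisson_scale < 0 || object@min_center_separation_px < 0)
    msg <- c(msg, "psf/noise/separation parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a scene configuration
#'
#' Defaults emulate a 10x slide-scanner acquisition of a brain section with
#' retrogradely labeled neurons: 1024x1024 px at 0.65 um/px, nuclei of
#' radius 3-5 um, somata 6-10 um, labeled structures five times brighter
#' than background, 1 px PSF, Poisson-Gaussian camera noise.
#'
#' @param height_px,width_px image size (px).
#' @param pixel_size_um um per pixel.
#' @param reporter `"nuclear"`, `"cytoplasmic"` or `"membrane"`.
#' @param n_cells number of neurons.
#' @param nucleus_radius_um,soma_radius_um radius ranges `(min, max)` in um.
#' @param neurites_per_cell,neurite_length_um neurite geometry (ignored for
#'   nuclear reporters, whose neurite amplitude is zero).
#' @param foreground_background_ratio plateau-to-background intensity ratio.
#' @param psf_sigma_px point-spread sigma (px).
#' @param gaussian_noise_sd additive read-noise sd (intensity units, where
#'   background is 1).
#' @param poisson_scale photon counts per intensity unit (0 = no shot noise).
#' @param min_center_separation_px minimal distance between cell centers.
#' @param seed RNG seed.
#' @return A [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig(height_px = 128, width_px = 128, n_cells = 3)
#' @export
sceneConfig <- function(height_px = 1024L, width_px = 1024L,
                        pixel_size_um = 0.65, reporter = "nuclear",
                        n_cells = 40L, nucleus_radius_um = c(3, 5),
                        soma_radius_um = c(6, 10), neurites_per_cell = 3L,
                        neurite_length_um = 80,
                        foreground_background_ratio = 5, psf_sigma_px = 1,
                        gaussian_noise_sd = 0.05, poisson_scale = 200,
                        min_center_separation_px = 20, seed = 1L) {
  new("SceneConfig", height_px = as.integer(height_px),
      width_px = as.integer(width_px), pixel_size_um = pixel_size_um,
      reporter = reporter, n_cells = as.integer(n_cells),
      nucleus_radius_um = as.numeric(nucleus_radius_um),
      soma_radius_um = as.numeric(soma_radius_um),
      neurites_per_cell = as.integer(neurites_per_cell),
      neurite_length_um = neurite_length_um,
      foreground_background_ratio = foreground_background_ratio,
      psf_sigma_px = psf_sigma_px, gaussian_noise_sd = gaussian_noise_sd,
      poisson_scale = poisson_scale,
      min_center_separation_px = min_center_separation_px,
      seed = as.integer(seed))
}

#' Ground-truth annotations for a synthetic scene
#'
#' The oracle against which detections and measurements are scored.
#' Coordinates are 1-based `(row, col)` pixel indices with pixel centers at
#' integers.  Depending on which generator produced the object, some slots
#' are empty.
#'
#' @slot neurons data.frame with columns `id`, `centroid_row`,
#'   `centroid_col`, `nucleus_radius_px`, `soma_radius_px`.
#' @slot nucleus_masks,soma_masks per-neuron lists of 1-based column-major
#'   pixel indices.
#' @slot particles data.frame with `id`, `true_area_um2`.
#' @slot trajectories per-particle matrices of per-frame `(row, col)`
#'   centroids (px).
#' @slot spines data.frame with `position_um` (along the dendrite path) and
#'   `distance_um` (to the plaque center).
#' @slot plaque numeric `(center_row, center_col, radius_um)` or empty.
#' @slot path matrix of dendrite path samples: `position_um`, `distance_um`.
#' @slot path_length_um dendrite length (um).
#' @slot dims image dimensions `(rows, cols)`.
#' @export
setClass("GroundTruth", representation(
  neurons = "data.frame", nucleus_masks = "list", soma_masks = "list",
  particles = "data.frame", trajectories = "list", spines = "data.frame",
  plaque = "numeric", path = "matrix", path_length_um = "numeric",
  dims = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (nrow(object@neurons)) {
    if (anyDuplicated(object@neurons$id)) msg <- c(msg, "neuron ids not unique")
    if (length(object@dims) == 2 &&
        (any(object@neurons$centroid_row < 1) ||
         any(object@neurons$centroid_row > object@dims[1]) ||
         any(object@neurons$centroid_col < 1) ||
         any(object@neurons$centroid_col > object@dims[2])))
      msg <- c(msg, "neuron centroids out of image bounds")
  }
  if (nrow(object@particles) && any(object@particles$true_area_um2 <= 0))
    msg <- c(msg, "particle true areas must be positive")
  if (length(msg)) msg else TRUE
})

emptyGroundTruth <- function(dims = integer(0)) {
  new("GroundTruth",
      neurons = data.frame(id = integer(0), centroid_row = numeric(0),
                           centroid_col = numeric(0),
                           nucleus_radius_px = numeric(0),
                           soma_radius_px = numeric(0)),
      nucleus_masks = list(), soma_masks = list(),
      particles = data.frame(id = integer(0), true_area_um2 = numeric(0)),
      trajectories = list(),
      spines = data.frame(position_um = numeric(0), distance_um = numeric(0)),
      plaque = numeric(0),
      path = matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("position_um", "distance_um"))),
      path_length_um = numeric(0), dims = as.integer(dims))
}

#' Configuration for synthetic mitochondria time-lapse sequences
#'
#' Emulates time-lapse imaging of mitochondrially targeted reporters in
#' axons: bright punctae on a dark background, a motile subset translocating
#' at constant speed along a fixed axis, the rest stationary up to sub-pixel
#' jitter.  The default frame interval of 1/3 s matches movies recorded at
#' approximately three frames per second.
#'
#' @slot n_particles number of mitochondria.
#' @slot motile_fraction fraction (0-1) moving at `speed_um_per_s`.
#' @slot speed_um_per_s translocation speed of motile particles.
#' @slot frames,frame_interval_s stack length and frame spacing (s).
#' @slot area_mean_um2,area_cv lognormal particle-area distribution: mean
#'   (um^2) and coefficient of variation.
#' @slot height_px,width_px,pixel_size_um field geometry.
#' @slot foreground_background_ratio,psf_sigma_px,gaussian_noise_sd,poisson_scale
#'   rendering and noise parameters as in [sceneConfig()].
#' @slot min_separation_px minimum spacing between initial positions.
#' @slot seed RNG seed.
#' @export
setClass("MotilityConfig", representation(
  n_particles = "integer", motile_fraction = "numeric",
  speed_um_per_s = "numeric", frames = "integer",
  frame_interval_s = "numeric", area_mean_um2 = "numeric",
  area_cv = "numeric", height_px = "integer", width_px = "integer",
  pixel_size_um = "numeric", foreground_background_ratio = "numeric",
  psf_sigma_px = "numeric", gaussian_noise_sd = "numeric",
  poisson_scale = "numeric", min_separation_px = "numeric",
  seed = "integer"))

setValidity("MotilityConfig", function(object) {
  msg <- character(0)
  if (object@frames < 2) msg <- c(msg, "frames must be >= 2")
  if (object@frame_interval_s <= 0) msg <- c(msg, "frame_interval_s must be > 0")
  if (object@motile_fraction < 0 || object@motile_fraction > 1)
    msg <- c(msg, "motile_fraction must be in [0, 1]")
  if (object@speed_um_per_s <= 0) msg <- c(msg, "speed_um_per_s must be > 0")
  if (object@area_mean_um2 <= 0 || object@area_cv < 0)
    msg <- c(msg, "area parameters must be positive")
  if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a motility configuration
#'
#' @param n_particles,motile_fraction,speed_um_per_s,frames,frame_interval_s
#'   see [MotilityConfig-class]; the defaults correspond to a one-minute
#'   movie at about three frames per second.
#' @param area_mean_um2,area_cv particle-area distribution.
#' @param height_px,width_px,pixel_size_um field geometry (0.16 um/px is a
#'   typical 60x confocal sampling).
#' @param foreground_background_ratio,psf_sigma_px,gaussian_noise_sd,poisson_scale
#'   rendering and noise.
#' @param min_separation_px minimum initial spacing.
#' @param seed RNG seed.
#' @return A [MotilityConfig-class] object.
#' @export
motilityConfig <- function(n_particles = 30L, motile_fraction = 0.2,
                           speed_um_per_s = 2, frames = 180L,
                           frame_interval_s = 1 / 3, area_mean_um2 = 0.7,
                           area_cv = 0.3, height_px = 256L, width_px = 256L,
                           pixel_size_um = 0.16,
                           foreground_background_ratio = 8,
                           psf_sigma_px = 0.6, gaussian_noise_sd = 0.03,
                           poisson_scale = 500, min_separation_px = 12,
                           seed = 1L) {
  new("MotilityConfig", n_particles = as.integer(n_particles),
      motile_fraction = motile_fraction, speed_um_per_s = speed_um_per_s,
      frames = as.integer(frames), frame_interval_s = frame_interval_s,
      area_mean_um2 = area_mean_um2, area_cv = area_cv,
      height_px = as.integer(height_px), width_px = as.integer(width_px),
      pixel_size_um = pixel_size_um,
      foreground_background_ratio = foreground_background_ratio,
      psf_sigma_px = psf_sigma_px, gaussian_noise_sd = gaussian_noise_sd,
      poisson_scale = poisson_scale, min_separation_px = min_separation_px,
      seed = as.integer(seed))
}

#' An ordered stack of equally sized intensity frames
#'
#' @slot frames list of non-negative intensity matrices, all of equal size.
#' @slot frame_interval_s time between frames (s).
#' @slot pixel_size_um physical pixel size.
#' @export
setClass("ImageStack", representation(
  frames = "list", frame_interval_s = "numeric", pixel_size_um = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character(0)
  if (!length(object@frames)) msg <- c(msg, "stack must contain frames")
  dims <- lapply(object@frames, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
    msg <- c(msg, "all frames must share dimensions")
  if (any(vapply(object@frames, function(f) any(f < 0), logical(1))))
    msg <- c(msg, "intensities must be >= 0")
  if (object@frame_interval_s <= 0) msg <- c(msg, "frame_interval_s must be > 0")
  if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
  if (length(msg)) msg else TRUE
})

#' Labeled 56x56 patch dataset for classifier training
#'
#' @slot patches numeric array `56 x 56 x n`.
#' @slot labels factor with levels `background`, `neuron`.
#' @slot split list with integer vectors `train` and `validation`
#'   (disjoint, together exhaustive) or empty before [splitDataset()].
#' @slot normalized logical: whether patches are z-scored and clipped.
#' @export
setClass("PatchDataset", representation(
  patches = "array", labels = "factor", split = "list",
  normalized = "logical"))

setValidity("PatchDataset", function(object) {
  msg <- character(0)
  d <- dim(object@patches)
  if (length(d) != 3 || d[1] != 56 || d[2] != 56)
    msg <- c(msg, "patches must be a 56 x 56 x n array")
  if (length(object@labels) != d[3])
    msg <- c(msg, "labels length must equal patch count")
  if (!identical(levels(object@labels), c("background", "neuron")))
    msg <- c(msg, "labels must have levels background, neuron")
  if (length(object@split)) {
    tr <- object@split$train; va <- object@split$validation
    if (length(intersect(tr, va)))
      msg <- c(msg, "train/validation splits overlap")
    if (!setequal(c(tr, va), seq_len(d[3])))
      msg <- c(msg, "splits must together cover all patches")
  }
  if (length(msg)) msg else TRUE
})

#' Architecture of the 12-layer patch classifier
#'
#' The layer sequence is fixed: input, conv (first kernel), batch norm, max
#' pool, ReLU, conv (second kernel), batch norm, max pool, ReLU, fully
#' connected (2 outputs), softmax, classification -- 12 layers in all, with
#' each convolution followed by batch normalization, max pooling and ReLU
#' in that order.
#'
#' @slot kernel_sizes ordered pair of conv kernel sizes, default `(14, 7)`.
#' @slot filters_per_conv filters in each conv layer, default `(16, 32)`.
#' @slot pool_size,pool_stride max-pool geometry, default 2 and 2.
#' @slot n_outputs number of classes (2).
#' @slot input_shape `(56, 56, 3)`.
#' @export
setClass("ModelSpec", representation(
  kernel_sizes = "integer", filters_per_conv = "integer",
  pool_size = "integer", pool_stride = "integer", n_outputs = "integer",
  input_shape = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (length(object@kernel_sizes) != 2 || any(object@kernel_sizes < 1))
    msg <- c(msg, "kernel_sizes must be two positive integers")
  if (length(object@filters_per_conv) != 2 ||
      any(object@filters_per_conv < 1))
    msg <- c(msg, "filters_per_conv must be two positive integers")
  if (object@pool_size != 2L || object@pool_stride != 2L)
    msg <- c(msg, "only 2x2 stride-2 max pooling is supported")
  if (object@n_outputs != 2L) msg <- c(msg, "n_outputs must be 2")
  if (length(object@input_shape) != 3)
    msg <- c(msg, "input_shape must have 3 entries")
  # the layer sequence must be realisable: conv/pool geometry stays positive
  h <- object@input_shape[1]
  h1 <- h - object@kernel_sizes[1] + 1
  if (h1 < 2) msg <- c(msg, "first conv kernel too large for input")
  h1p <- h1 %/% 2
  h2 <- h1p - object@kernel_sizes[2] + 1
  if (h2 < 2) msg <- c(msg, "second conv kernel too large for pooled map")
  if (length(msg)) msg else TRUE
})

#' Construct a model specification
#'
#' @param kernel_sizes conv kernel sizes, `(14, 7)` by default.
#' @param filters_per_conv filters per conv layer, `(16, 32)` by default.
#' @param pool_size,pool_stride pooling geometry (2x2, stride 2).
#' @param input_shape input patch shape, `(56, 56, 3)`.
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(kernel_sizes = c(14L, 7L),
                      filters_per_conv = c(16L, 32L), pool_size = 2L,
                      pool_stride = 2L, input_shape = c(56L, 56L, 3L)) {
  new("ModelSpec", kernel_sizes = as.integer(kernel_sizes),
      filters_per_conv = as.integer(filters_per_conv),
      pool_size = as.integer(pool_size),
      pool_stride = as.integer(pool_stride), n_outputs = 2L,
      input_shape = as.integer(input_shape))
}

#' A (possibly trained) patch classifier
#'
#' @slot spec the [ModelSpec-class].
#' @slot params named list of weight matrices and batch-norm statistics.
#' @slot train_log list with `epochs`, `learning_rate`, `epoch_loss`,
#'   `validation_accuracy` (empty until trained).
#' @slot trained logical.
#' @export
setClass("TrainedModel", representation(
  spec = "ModelSpec", params = "list", train_log = "list",
  trained = "logical"))

#' Binary detection mask from sliding-window classification
#'
#' @slot mask logical matrix, the size of the source image; all pixels
#'   within `border_margin_px` of an edge are FALSE.
#' @slot border_margin_px excluded margin (28 px: half the patch size).
#' @slot stride sliding-window stride used (1 = exact per-pixel contract).
#' @export
setClass("DetectionMask", representation(
  mask = "matrix", border_margin_px = "integer", stride = "integer"))

setValidity("DetectionMask", function(object) {
  m <- object@border_margin_px
  msk <- object@mask
  if (m > 0 && (nrow(msk) > 2 * m) && (ncol(msk) > 2 * m)) {
    border <- msk
    border[(m + 1):(nrow(msk) - m), (m + 1):(ncol(msk) - m)] <- FALSE
    if (any(border)) return("mask has positive pixels inside the border margin")
  }
  TRUE
})

#' Isolated neuron components from a detection mask
#'
#' @slot components data.frame with `id`, `centroid_row`, `centroid_col`,
#'   `pixel_count` (8-connected components, unweighted centroids).
#' @slot dims source image dimensions.
#' @slot min_pixels minimum component size applied.
#' @export
setClass("DetectionSet", representation(
  components = "data.frame", dims = "integer", min_pixels = "integer"))

#' One-to-one matching of detections to ground truth
#'
#' @slot pairs data.frame `detection_id`, `truth_id`, `distance_px` of the
#'   minimum-total-distance assignment within tolerance.
#' @slot unmatched_detections,unmatched_truth leftover ids.
#' @slot tolerance_px matching tolerance (px).
#' @export
setClass("MatchResult", representation(
  pairs = "data.frame", unmatched_detections = "integer",
  unmatched_truth = "integer", tolerance_px = "numeric"))

setValidity("MatchResult", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@pairs$detection_id) ||
      anyDuplicated(object@pairs$truth_id))
    msg <- c(msg, "each detection/truth may appear in at most one pair")
  if (nrow(object@pairs) &&
      any(object@pairs$distance_px > object@tolerance_px + 1e-9))
    msg <- c(msg, "pair distances exceed tolerance")
  if (length(msg)) msg else TRUE
})

#' Result of an exact or approximate rank test
#'
#' For exact methods the p-value is a ratio of integer arrangement counts,
#' recorded in `n_extreme` / `n_total`.
#'
#' @slot statistic test statistic (U for Mann-Whitney, H for
#'   Kruskal-Wallis).
#' @slot p_value two-sided (MW) or upper-tail (KW) p-value.
#' @slot method one of `mann_whitney_exact`, `kruskal_wallis_exact`,
#'   `kruskal_wallis_chi2`.
#' @slot n_per_group group sizes.
#' @slot n_extreme,n_total integer arrangement counts (exact methods; 0
#'   otherwise).
#' @export
setClass("TestResult", representation(
  statistic = "numeric", p_value = "numeric", method = "character",
  n_per_group = "integer", n_extreme = "numeric", n_total = "numeric"))

setValidity("TestResult", function(object) {
  if (object@p_value < 0 || object@p_value > 1) "p_value outside [0, 1]"
  else TRUE
})

#' Per-particle morphometry table
#'
#' @slot particles data.frame: `id`, `area_um2`, `perimeter_um`,
#'   `centroid_row`, `centroid_col`, `image_id`.
#' @slot pixel_size_um physical pixel size used for calibration.
#' @slot filter_log list recording any area filtering applied
#'   (`min_area`, `max_area`, `n_kept`, `n_excluded`).
#' @export
setClass("ParticleTable", representation(
  particles = "data.frame", pixel_size_um = "numeric", filter_log = "list"))

setValidity("ParticleTable", function(object) {
  msg <- character(0)
  need <- c("id", "area_um2", "perimeter_um", "centroid_row", "centroid_col",
            "image_id")
  if (!all(need %in% names(object@particles)))
    msg <- c(msg, "particles is missing required columns")
  if (nrow(object@particles) && any(object@particles$perimeter_um <= 0))
    msg <- c(msg, "perimeters must be positive")
  if (length(msg)) msg else TRUE
})

#' A set of linked particle tracks from a time-lapse stack
#'
#' @slot tracks data.frame: `id`, `n_frames`, `start_frame`,
#'   `path_length_um`, `speed_um_per_s`, `net_speed_um_per_s`.
#' @slot positions per-track matrices with columns `frame`, `row`, `col`.
#' @slot frame_interval_s,pixel_size_um calibration.
#' @export
setClass("TrackSet", representation(
  tracks = "data.frame", positions = "list", frame_interval_s = "numeric",
  pixel_size_um = "numeric"))
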