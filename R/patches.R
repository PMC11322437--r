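#' Z-score normalize a patch, clipping negatives to zero
#'
#' Each patch is standardized to zero mean and unit standard deviation
#' (population convention, i.e. dividing by n) and every negative value is
#' then clipped to 0, so the minimum of a normalized patch is always >= 0.
#' A constant patch (zero standard deviation) maps to all zeros.
#'
#' @param patch a 56 x 56 numeric matrix (raw intensities).
#' @return The normalized 56 x 56 matrix.
#' @examples
#' p <- matrix(c(0, 2), 56, 56)
#' range(normalizePatch(p))  # 0 and 1
#' @export
normalizePatch <- function(patch) {
  if (!is.matrix(patch) || !all(dim(patch) == c(56, 56))) {
    stop("patch must be a 56 x 56 matrix")
  }
  mu <- mean(patch)
  sdev <- sqrt(mean((patch - mu)^2))
  if (sdev == 0) return(matrix(0, 56, 56))
  pmax((patch - mu) / sdev, 0)
}

#' Embed a patch into a 3-channel image (red channel)
#'
#' The classifier input is a 56 x 56 x 3 array whose red (first) channel
#' holds the patch and whose remaining channels are zero.
#'
#' @param patch a normalized 56 x 56 matrix.
#' @return A 56 x 56 x 3 numeric array.
#' @export
toThreeChannel <- function(patch) {
  if (!is.matrix(patch) || !all(dim(patch) == c(56, 56))) {
    stop("patch must be a 56 x 56 matrix")
  }
  out <- array(0, c(56, 56, 3))
  out[, , 1] <- patch
  out
}

#' Build a labeled patch dataset from synthetic scenes
#'
#' Renders the given scenes and extracts `n_neuron` patches centred on
#' ground-truth centroids (label `neuron`) and `n_background` patches whose
#' centers are far from every cell (label `background`): at least one
#' nucleus diameter from any centroid and outside every dilated soma mask.
#' Patches are 56 x 56, single channel, raw (unnormalized); the patch
#' center sits at matrix index (29, 29), covering rows/cols
#' `center - 28 ... center + 27`.
#'
#' @param scene_configs a [SceneConfig-class] or list of them.
#' @param n_neuron,n_background patch counts per class.
#' @param seed RNG seed for sampling centroids and background positions.
#' @return A [PatchDataset-class] (unsplit, unnormalized).
#' @export
renderPatchDataset <- function(scene_configs, n_neuron, n_background,
                               seed = 1L) {
  if (is(scene_configs, "SceneConfig")) scene_configs <- list(scene_configs)
  scenes <- lapply(scene_configs, renderScene)
  total_neurons <- sum(vapply(scenes, function(s) nrow(neurons(s$truth)),
                              integer(1)))
  if (n_neuron > total_neurons) {
    stop(sprintf("scenes contain %d neurons but %d neuron patches requested",
                 total_neurons, n_neuron))
  }
  withSeed(deriveSeed(seed, "patch-sampling"), {
    patches <- array(0, c(56, 56, n_neuron + n_background))
    k <- 0L
    # neuron patches: sample among all centroids without replacement
    cand <- do.call(rbind, lapply(seq_along(scenes), function(si) {
      nd <- neurons(scenes[[si]]$truth)
      if (!nrow(nd)) return(NULL)
      cbind(si, nd$centroid_row, nd$centroid_col)
    }))
    if (n_neuron > 0) {
      sel <- if (nrow(cand) == n_neuron) seq_len(n_neuron) else
        sample.int(nrow(cand), n_neuron)
      for (idx in sel) {
        si <- cand[idx, 1]
        k <- k + 1L
        patches[, , k] <- extractPatch(scenes[[si]]$image, cand[idx, 2],
                                       cand[idx, 3])
      }
    }
    # background patches: round-robin over scenes
    if (n_background > 0) {
      per_scene <- tabulate(rep(seq_along(scenes), length.out = n_background),
                            nbins = length(scenes))
      for (si in seq_along(scenes)) {
        if (per_scene[si] == 0) next
        img <- scenes[[si]]$image
        cfg <- scene_configs[[si]]
        nd <- neurons(scenes[[si]]$truth)
        ps <- cfg@pixel_size_um
        # exclusion radius: one nucleus diameter, and the dilated soma
        excl <- max(2 * cfg@nucleus_radius_um[2] / ps,
                    cfg@soma_radius_um[2] / ps + 3)
        H <- nrow(img); W <- ncol(img)
        got <- 0L
        for (attempt in seq_len(200 * per_scene[si])) {
          r0 <- sample(29:(H - 28), 1)
          c0 <- sample(29:(W - 28), 1)
          if (nrow(nd)) {
            d <- sqrt((nd$centroid_row - r0)^2 + (nd$centroid_col - c0)^2)
            if (min(d) <= excl) next
          }
          k <- k + 1L; got <- got + 1L
          patches[, , k] <- extractPatch(img, r0, c0)
          if (got == per_scene[si]) break
        }
        if (got < per_scene[si]) {
          stop(sprintf(paste0("scene %d has insufficient background area: ",
                              "placed %d of %d background patches"),
                       si, got, per_scene[si]))
        }
      }
    }
    labels <- factor(rep(c("neuron", "background"),
                         c(n_neuron, n_background)),
                     levels = c("background", "neuron"))
    new("PatchDataset", patches = patches, labels = labels, split = list(),
        normalized = FALSE)
  })
}

extractPatch <- function(image, r0, c0) {
  if (r0 < 29 || c0 < 29 || r0 > nrow(image) - 27 || c0 > ncol(image) - 27) {
    stop("patch center too close to the image border")
  }
  image[(r0 - 28):(r0 + 27), (c0 - 28):(c0 + 27)]
}

#' Normalize every patch of a dataset
#'
#' Applies [normalizePatch()] to each patch; a no-op on datasets already
#' normalized.
#'
#' @param dataset a [PatchDataset-class].
#' @return The normalized dataset.
#' @export
normalizeDataset <- function(dataset) {
  stopifnot(is(dataset, "PatchDataset"))
  if (dataset@normalized) return(dataset)
  d <- dim(dataset@patches)
  # vectorized over patches: one column per patch
  m <- matrix(dataset@patches, d[1] * d[2], d[3])
  mu <- colMeans(m)
  m <- sweep(m, 2, mu)
  sdp <- sqrt(colMeans(m^2))
  m <- sweep(m, 2, ifelse(sdp > 0, sdp, 1), "/")
  m[m < 0] <- 0
  if (any(sdp == 0)) m[, sdp == 0] <- 0   # constant patches map to zeros
  dataset@patches <- array(m, d)
  dataset@normalized <- TRUE
  dataset
}

#' Split a dataset into training and validation indices
#'
#' Randomly selects `n_train_per_class` patches of each class for training;
#' all remaining patches form the validation set (the protocol used here
#' selects 900 + 900 for training and validates on the remainder).
#'
#' @param dataset a [PatchDataset-class].
#' @param n_train_per_class training patches per class (default 900).
#' @param seed RNG seed for the random selection.
#' @return The dataset with its `split` slot filled.
#' @export
splitDataset <- function(dataset, n_train_per_class = 900L, seed = 1L) {
  stopifnot(is(dataset, "PatchDataset"))
  idx_n <- which(dataset@labels == "neuron")
  idx_b <- which(dataset@labels == "background")
  if (length(idx_n) < n_train_per_class ||
      length(idx_b) < n_train_per_class) {
    stop("not enough patches of each class for the requested training size")
  }
  withSeed(deriveSeed(seed, "train-split"), {
    tr <- c(sample(idx_n, n_train_per_class),
            sample(idx_b, n_train_per_class))
    dataset@split <- list(train = sort(tr),
                          validation = setdiff(seq_along(dataset@labels),
                                               tr))
  })
  validObject(dataset)
  dataset
}
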