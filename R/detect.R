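#' Sliding-window neuron detection over a whole image
#'
#' Every interior pixel (excluding the 28-px margin at each edge, half the
#' 56-px patch size) centers a 56 x 56 patch that is z-scored, clipped at
#' zero, embedded in the red channel and classified; the pixel is set in
#' the binary mask iff its patch classifies as neuron.  At `stride > 1`
#' only a regular grid of centers is classified and the remaining interior
#' pixels take the class of their nearest classified center.
#'
#' Patches are classified in batches (several thousand forward passes per
#' call into compiled code), so stride-1 detection on moderate images is
#' feasible on a single CPU.
#'
#' @param model a trained [TrainedModel-class].
#' @param image numeric intensity matrix, at least 57 x 57.
#' @param stride center-grid stride in pixels (default 1, the exact
#'   per-pixel contract).
#' @param batch_size patches per compiled batch (default 4096).
#' @return A [DetectionMask-class].
#' @export
detectMask <- function(model, image, stride = 1L, batch_size = 4096L) {
  stopifnot(is(model, "TrainedModel"), is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  if (H < 57 || W < 57) {
    stop("image must be at least 57 x 57 to host 56 x 56 patches")
  }
  stride <- as.integer(stride)
  rows <- seq.int(29L, H - 28L, by = stride)
  cols <- seq.int(29L, W - 28L, by = stride)
  centers <- expand.grid(r = rows, c = cols)
  s <- model@spec
  post <- .cnn_classify_centers_cpp(image, centers$r - 1L, centers$c - 1L,
                                    model@params, 28L, 56L,
                                    s@kernel_sizes[1], s@kernel_sizes[2],
                                    as.integer(batch_size))
  cls <- matrix(post > 0.5, nrow = length(rows))
  mask <- matrix(FALSE, H, W)
  if (stride == 1L) {
    mask[rows, cols] <- cls
  } else {
    # nearest classified center fills the off-grid interior pixels
    all_r <- 29L:(H - 28L)
    all_c <- 29L:(W - 28L)
    ridx <- pmin(pmax(round((all_r - 29L) / stride) + 1L, 1L), length(rows))
    cidx <- pmin(pmax(round((all_c - 29L) / stride) + 1L, 1L), length(cols))
    mask[all_r, all_c] <- cls[ridx, cidx, drop = FALSE]
  }
  new("DetectionMask", mask = mask, border_margin_px = 28L, stride = stride)
}

#' Isolate individual neurons from a detection mask
#'
#' Connected components (8-connectivity) of the binary mask with at least
#' `min_pixels` pixels, each summarized by its unweighted centroid and
#' pixel count.  The default minimum of 20 px suppresses single-pixel
#' noise components (about 8.5 um^2 at 0.65 um/px, a small nucleus).
#'
#' @param mask a [DetectionMask-class] or logical matrix.
#' @param min_pixels minimum component size (px).
#' @return A [DetectionSet-class].
#' @export
isolateNeurons <- function(mask, min_pixels = 20L) {
  m <- if (is(mask, "DetectionMask")) mask@mask else mask
  stopifnot(is.matrix(m))
  lab <- .label_components_cpp(m > 0, 8L)
  n <- max(lab)
  if (n == 0) {
    comp <- data.frame(id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), pixel_count = integer(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rr <- (idx - 1L) %% nrow(m) + 1L
    cc <- (idx - 1L) %/% nrow(m) + 1L
    count <- tabulate(l, n)
    comp <- data.frame(
      id = seq_len(n),
      centroid_row = as.numeric(tapply(rr, l, mean)),
      centroid_col = as.numeric(tapply(cc, l, mean)),
      pixel_count = count)
    comp <- comp[comp$pixel_count >= min_pixels, , drop = FALSE]
    comp$id <- seq_len(nrow(comp))
    rownames(comp) <- NULL
  }
  new("DetectionSet", components = comp, dims = c(nrow(m), ncol(m)),
      min_pixels = as.integer(min_pixels))
}
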