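#' Rolling-ball style background subtraction
#'
#' Estimates the slowly varying background as the grayscale morphological
#' opening of the image by a disc structuring element of the given radius
#' and subtracts it (white top-hat).  Structures smaller than the disc are
#' preserved; a flat image maps to zero.  The operation is idempotent.
#'
#' @param image numeric intensity matrix.
#' @param radius_px structuring-element radius in pixels (default 50, the
#'   conventional default of interactive tools).
#' @return Background-subtracted image (all values >= 0).
#' @export
subtractBackground <- function(image, radius_px = 50) {
  stopifnot(is.matrix(image), radius_px >= 1)
  size <- 2 * floor(radius_px) + 1
  brush <- EBImage::makeBrush(size, shape = "disc")
  # grayscale morphology operates on [0, 1]; rescale around the opening
  scale <- max(image, 1e-12)
  bg <- EBImage::opening(image / scale, brush)
  out <- image - scale * matrix(as.numeric(bg), nrow = nrow(image))
  pmax(out, 0)
}

#' Threshold an image into a binary mask
#'
#' Either Otsu's method (reproducible stand-in for interactive threshold
#' adjustment) or a fixed level.  The threshold actually used is recorded
#' in the attributes of the returned mask (`threshold`, `method`).
#'
#' @param image numeric intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return Logical matrix (`image > threshold`) with attributes
#'   `threshold` and `method`.
#' @export
binarizeImage <- function(image, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "fixed") {
    if (is.null(level)) stop("fixed thresholding requires a level")
    th <- level
  } else {
    rng <- range(image)
    if (diff(rng) == 0) {
      stop("image has no contrast; Otsu thresholding is undefined - use method = 'fixed'")
    }
    v <- (image - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
    th <- rng[1] + th01 * diff(rng)
  }
  mask <- image > th
  attr(mask, "threshold") <- th
  attr(mask, "method") <- method
  mask
}

# Crofton-style perimeter: pi/4 times the number of fore/background
# transitions along rows and columns (including image borders), per label
croftonPerimeter <- function(lab, n) {
  nr <- nrow(lab); nc <- ncol(lab)
  padded <- matrix(0L, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- lab
  counts <- numeric(n)
  for (shift in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    nb <- padded[2:(nr + 1) + shift[1], 2:(nc + 1) + shift[2]]
    diffidx <- which(lab > 0 & nb != lab)
    if (length(diffidx)) {
      tb <- tabulate(lab[diffidx], n)
      counts <- counts + tb
    }
  }
  pi / 4 * counts
}

#' Measure particles in a binary mask
#'
#' Labels 8-connected foreground components and reports per-particle area
#' (pixel count times the squared pixel size), Crofton-style perimeter
#' (boundary crossings scaled to physical units) and unweighted centroid.
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_size_um physical pixel size (um per px).
#' @param image_id identifier recorded with each particle (e.g. the cell
#'   or frame the mask came from).
#' @return A [ParticleTable-class].
#' @examples
#' m <- matrix(FALSE, 16, 16); m[5:8, 5:8] <- TRUE
#' particleData(measureParticles(m, 0.5))  # one particle of 4 um^2
#' @export
measureParticles <- function(mask, pixel_size_um, image_id = "image") {
  stopifnot(pixel_size_um > 0)
  m <- mask > 0
  lab <- .label_components_cpp(m, 8L)
  n <- max(lab)
  if (n == 0) {
    tab <- data.frame(id = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), image_id = character(0))
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rr <- (idx - 1L) %% nrow(m) + 1L
    cc <- (idx - 1L) %/% nrow(m) + 1L
    count <- tabulate(l, n)
    tab <- data.frame(
      id = seq_len(n),
      area_um2 = count * pixel_size_um^2,
      perimeter_um = croftonPerimeter(lab, n) * pixel_size_um,
      centroid_row = as.numeric(tapply(rr, l, mean)),
      centroid_col = as.numeric(tapply(cc, l, mean)),
      image_id = image_id)
  }
  new("ParticleTable", particles = tab, pixel_size_um = pixel_size_um,
      filter_log = list())
}

#' Filter particles by physical area
#'
#' Retains particles with `min_area <= area <= max_area` (both bounds
#' inclusive; values exactly at a bound are kept).  The default bounds of
#' 0.1 and 2.4 um^2 exclude debris and merged clusters from mitochondrial
#' statistics.  Kept and excluded counts are recorded in the table's
#' `filter_log`.
#'
#' @param table a [ParticleTable-class].
#' @param min_area,max_area inclusive area bounds (um^2).
#' @return The filtered [ParticleTable-class].
#' @export
filterParticles <- function(table, min_area = 0.1, max_area = 2.4) {
  stopifnot(is(table, "ParticleTable"), min_area < max_area)
  keep <- table@particles$area_um2 >= min_area &
    table@particles$area_um2 <= max_area
  out <- table@particles[keep, , drop = FALSE]
  rownames(out) <- NULL
  table@filter_log <- list(min_area = min_area, max_area = max_area,
                           n_kept = sum(keep), n_excluded = sum(!keep))
  table@particles <- out
  table
}

#' Combine several particle tables
#'
#' @param tables list of [ParticleTable-class] with equal pixel size.
#' @return A single [ParticleTable-class].
#' @export
bindParticleTables <- function(tables) {
  stopifnot(length(tables) > 0)
  ps <- unique(vapply(tables, function(t) t@pixel_size_um, numeric(1)))
  stopifnot(length(ps) == 1)
  new("ParticleTable",
      particles = do.call(rbind, lapply(tables, particleData)),
      pixel_size_um = ps, filter_log = list())
}

#' Summarize particle areas by group and compare two groups
#'
#' Reports mean area with its standard error per group, aggregating either
#' over individual particles or over cell means (`image_id` identifies the
#' cell).  With exactly two groups the aggregation-unit values are
#' compared by the exact Mann-Whitney test when both group sizes are
#' within the enumeration regime (<= 12), and the percent reduction of the
#' smaller-mean group relative to the larger is reported.
#'
#' @param tables named list of [ParticleTable-class], one per group.
#' @param aggregation `"particle"` or `"cell"`.
#' @return A list with `summary` (data.frame: group, n, mean_area_um2,
#'   sem_area_um2), `test` (a [TestResult-class] or NULL) and
#'   `percent_reduction` (NULL unless two groups).
#' @export
summarizeGroups <- function(tables, aggregation = c("particle", "cell")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  unit_values <- lapply(tables, function(t) {
    df <- particleData(t)
    if (aggregation == "cell") {
      if (!nrow(df)) stop("empty particle table in group summary")
      if (length(unique(df$image_id)) < 1) {
        stop("cell aggregation requires image_id per particle")
      }
      as.numeric(tapply(df$area_um2, df$image_id, mean))
    } else {
      df$area_um2
    }
  })
  summary <- data.frame(
    group = names(tables),
    n = vapply(unit_values, length, integer(1)),
    mean_area_um2 = vapply(unit_values, mean, numeric(1)),
    sem_area_um2 = vapply(unit_values, function(v) {
      sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL)
  test <- NULL
  percent_reduction <- NULL
  if (length(tables) == 2) {
    means <- summary$mean_area_um2
    big <- which.max(means)
    percent_reduction <- 100 * (means[big] - means[-big]) / means[big]
    if (all(lengths(unit_values) <= 12)) {
      test <- exactMannWhitney(unit_values[[1]], unit_values[[2]])
    }
  }
  list(summary = summary, test = test,
       percent_reduction = percent_reduction)
}
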