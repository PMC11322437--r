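# Seed discipline: every stochastic operation takes an explicit seed and
# evaluates under it without disturbing the caller's RNG state.  Named
# substreams are derived arithmetically so that stages of a pipeline do not
# share streams.

withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed for a named stream
#'
#' Folds a base seed and a stream label into a new seed in `[1, 2^31 - 2]`.
#' Used so that, e.g., scene geometry and pixel noise, or the stages of a
#' pipeline, draw from distinct but reproducible streams of a single
#' user-facing seed.
#'
#' @param seed integer base seed.
#' @param stream character label of the substream.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(stream))
  v <- utf8ToInt(stream)
  h <- sum(as.numeric(v) * seq_along(v) * 131)
  as.integer(((abs(as.numeric(seed)) %% 2147480000) * 48271 + h * 8191 + 1) %%
               2147483629)
}

# uniform-coverage disk stamp: adds `amp * coverage` for a disk of radius
# `radius` (px) centred at (r0, c0) (1-based, possibly fractional) onto
# `canvas`, with a half-pixel antialiased rim
stampDisk <- function(canvas, r0, c0, radius, amp) {
  if (radius <= 0 || amp == 0) return(canvas)
  rr <- max(1L, floor(r0 - radius - 1)):min(nrow(canvas), ceiling(r0 + radius + 1))
  cc <- max(1L, floor(c0 - radius - 1)):min(ncol(canvas), ceiling(c0 + radius + 1))
  if (!length(rr) || !length(cc)) return(canvas)
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  cov <- pmin(1, pmax(0, radius + 0.5 - d))
  canvas[rr, cc] <- canvas[rr, cc] + amp * cov
  canvas
}

# indices (1-based, column-major) of pixels within `radius` of (r0, c0)
diskIndices <- function(dims, r0, c0, radius) {
  rr <- max(1L, floor(r0 - radius)):min(dims[1], ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(dims[2], ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  if (!nrow(inside)) return(integer(0))
  as.integer(rr[inside[, 1]] + (cc[inside[, 2]] - 1) * dims[1])
}

# Poisson-Gaussian camera noise applied in place; both components optional
applyNoise <- function(img, gaussian_sd, poisson_scale) {
  if (poisson_scale > 0) {
    img[] <- rpois(length(img), lambda = pmax(img, 0) * poisson_scale) /
      poisson_scale
  }
  if (gaussian_sd > 0) {
    img[] <- img + rnorm(length(img), 0, gaussian_sd)
  }
  pmax(img, 0)
}

# Gaussian PSF blur (EBImage); no-op at sigma 0
blurPSF <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- EBImage::gblur(img, sigma = sigma)
  matrix(as.numeric(out), nrow = nrow(img))
}
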