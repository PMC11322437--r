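test_that("background subtraction removes flat offsets and keeps small objects", {
  expect_equal(max(abs(subtractBackground(matrix(3, 64, 64), 10))), 0)
  img <- rvquant:::stampDisk(matrix(1, 64, 64), 32, 32, 4, 5)
  sb <- subtractBackground(img, 15)
  expect_gt(max(sb), 5 * 0.95)            # disk amplitude preserved
  expect_lt(max(sb[1:10, 1:10]), 1e-9)    # background removed
  expect_true(all(sb >= 0))
  # white top-hat is idempotent
  expect_lt(max(abs(subtractBackground(sb, 15) - sb)), 1e-6)
})

test_that("thresholding behaves for two-level, fixed and blank inputs", {
  img <- matrix(10, 40, 40)
  img[10:20, 10:20] <- 200
  bw <- binarizeImage(img, "otsu")
  th <- attr(bw, "threshold")
  expect_gt(th, 10); expect_lt(th, 200)
  expect_identical(as.vector(bw), as.vector(img > th))
  expect_true(all(bw[10:20, 10:20]))
  bw0 <- binarizeImage(img, "fixed", level = 0)
  expect_true(all(bw0))
  expect_error(binarizeImage(matrix(5, 10, 10), "otsu"), "fixed")
  expect_error(binarizeImage(img, "fixed"), "level")
})

test_that("otsu segmentation of a rendered field recovers the planted area", {
  f <- renderMitoField(n_particles = 40, seed = 2)
  bw <- binarizeImage(subtractBackground(f$image, 50), "otsu")
  measured_px <- sum(bw)
  true_px <- sum(particleData(f$truth)$true_area_um2) / 0.16^2
  expect_lt(abs(measured_px - true_px) / true_px, 0.20)
})

test_that("particle measurement reports calibrated area and perimeter", {
  m <- matrix(FALSE, 16, 16); m[5:8, 5:8] <- TRUE
  tab <- particleData(measureParticles(m, 0.5))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$area_um2, 4)            # 16 px * 0.25 um^2
  expect_gt(tab$perimeter_um, 0)
  expect_equal(tab$centroid_row, 6.5)
  expect_identical(nrow(particleData(measureParticles(matrix(FALSE, 8, 8),
                                                      1))), 0L)
  # Crofton perimeter of a digital disk matches the circle through the
  # digitized boundary (effective radius R + 1/2)
  disk <- matrix(FALSE, 64, 64)
  disk[which(outer((1:64 - 32)^2, (1:64 - 32)^2, "+") <= 10^2)] <- TRUE
  p <- particleData(measureParticles(disk, 1))$perimeter_um
  expect_lt(abs(p - 2 * pi * 10.5) / (2 * pi * 10.5), 0.02)
})

test_that("measured ellipse areas converge to pi*a*b as pixels shrink", {
  a_um <- 0.9; b_um <- 0.45   # ellipse half-axes, area ~1.27 um^2
  errs <- vapply(c(0.2, 0.1, 0.05), function(ps) {
    nr <- ceiling(2.5 * a_um / ps) * 2 + 1
    ctr <- (nr + 1) / 2
    d <- outer(((1:nr - ctr) * ps / a_um)^2, ((1:nr - ctr) * ps / b_um)^2,
               "+")
    tab <- particleData(measureParticles(d <= 1, ps))
    abs(tab$area_um2 - pi * a_um * b_um) / (pi * a_um * b_um)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))   # monotone improvement
  expect_lt(errs[2], 0.10)           # within 10% at supersampled rendering
})

test_that("the area filter keeps inclusive bounds and conserves counts", {
  mk <- function(areas) {
    n <- length(areas)
    new("ParticleTable",
        particles = data.frame(id = seq_len(n), area_um2 = areas,
                               perimeter_um = rep(1, n),
                               centroid_row = rep(1, n),
                               centroid_col = rep(1, n),
                               image_id = rep("x", n)),
        pixel_size_um = 0.1, filter_log = list())
  }
  f <- filterParticles(mk(c(0.05, 0.5, 3.0)))
  expect_equal(particleData(f)$area_um2, 0.5)
  fb <- filterParticles(mk(c(0.1, 2.4)))
  expect_identical(nrow(particleData(fb)), 2L)      # bounds inclusive
  fe <- filterParticles(mk(numeric(0)))
  expect_identical(nrow(particleData(fe)), 0L)
  withr::with_seed(3, {
    for (trial in 1:10) {
      areas <- rlnorm(sample(1:40, 1), log(0.5), 1)
      ft <- filterParticles(mk(areas))
      expect_identical(ft@filter_log$n_kept + ft@filter_log$n_excluded,
                       length(areas))
      expect_identical(nrow(particleData(ft)), ft@filter_log$n_kept)
    }
  })
})

test_that("noise-free rendered particles are recovered within 10% area error", {
  # supersampled rendering (0.06 um/px), half-max threshold
  for (A in c(0.2, 0.7, 2.2)) {
    f <- renderMitoField(n_particles = 12, area_mean_um2 = A, area_cv = 0,
                         seed = 7, pixel_size_um = 0.06, height_px = 448,
                         width_px = 448, psf_sigma_px = 0.6,
                         gaussian_noise_sd = 0, poisson_scale = 0,
                         min_separation_px = 36)
    sb <- subtractBackground(f$image, 60)
    bw <- binarizeImage(sb, "fixed", level = max(sb) / 2)
    tab <- particleData(filterParticles(measureParticles(bw, 0.06),
                                        0.1, 2.4))
    expect_identical(nrow(tab), 12L)
    expect_true(all(abs(tab$area_um2 / A - 1) <= 0.10))
  }
})

test_that("group summaries report mean, SEM and exact comparisons", {
  mk <- function(areas, cells = "c1") {
    n <- length(areas)
    new("ParticleTable",
        particles = data.frame(id = seq_len(n), area_um2 = areas,
                               perimeter_um = rep(1, n),
                               centroid_row = rep(1, n),
                               centroid_col = rep(1, n),
                               image_id = rep(cells, length.out = n)),
        pixel_size_um = 0.1, filter_log = list())
  }
  one <- summarizeGroups(list(g = mk(c(1, 2, 3))))
  expect_equal(one$summary$mean_area_um2, 2)
  expect_equal(one$summary$sem_area_um2, sd(c(1, 2, 3)) / sqrt(3),
               tolerance = 1e-9)
  two <- summarizeGroups(list(a = mk(c(1, 2, 3)), b = mk(c(1, 2, 3))))
  expect_equal(two$percent_reduction, 0)
  # cell-level aggregation uses per-cell means
  t1 <- mk(c(1, 1, 3, 3), cells = c("c1", "c1", "c2", "c2"))
  t2 <- mk(c(5, 7), cells = c("d1", "d2"))
  res <- summarizeGroups(list(a = t1, b = t2), aggregation = "cell")
  expect_equal(res$summary$n, c(2L, 2L))
  expect_equal(res$summary$mean_area_um2, c(2, 6))
  expect_identical(res$test@method, "mann_whitney_exact")
})
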