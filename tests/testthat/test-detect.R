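test_that("images smaller than the patch are rejected", {
  expect_error(detectMask(nuclearModel(), matrix(1, 50, 50)), "57")
})

test_that("the 28-px border is always background", {
  sc <- renderScene(sceneConfig(height_px = 100, width_px = 120,
                                n_cells = 1, seed = 8))
  mask <- detectMask(nuclearModel(), sc$image, stride = 2)
  m <- mask@mask
  expect_identical(mask@border_margin_px, 28L)
  expect_false(any(m[1:28, ]))
  expect_false(any(m[, 1:28]))
  expect_false(any(m[(nrow(m) - 27):nrow(m), ]))
  expect_false(any(m[, (ncol(m) - 27):ncol(m)]))
})

test_that("stride-1 detection equals independent per-pixel classification", {
  model <- nuclearModel()
  sc <- renderScene(sceneConfig(height_px = 80, width_px = 84,
                                n_cells = 1, seed = 13,
                                min_center_separation_px = 0))
  mask <- detectMask(model, sc$image, stride = 1)
  H <- nrow(sc$image); W <- ncol(sc$image)
  for (r in 29:(H - 28)) {
    for (cc in 29:(W - 28)) {
      patch <- sc$image[(r - 28):(r + 27), (cc - 28):(cc + 27)]
      lab <- classifyPatch(model, patch)$label
      expect_identical(unname(mask@mask[r, cc]), lab == "neuron")
    }
  }
})

test_that("a noise-only image produces an almost empty mask", {
  sc <- renderScene(sceneConfig(height_px = 140, width_px = 140,
                                n_cells = 0, seed = 3))
  mask <- detectMask(nuclearModel(), sc$image, stride = 2)
  expect_lte(mean(mask@mask), 0.01)
})

test_that("a single centred nucleus is captured by the largest component", {
  sc <- renderScene(sceneConfig(height_px = 160, width_px = 160,
                                n_cells = 1, seed = 44))
  mask <- detectMask(nuclearModel(), sc$image, stride = 1)
  det <- isolateNeurons(mask, min_pixels = 20)
  comp <- components(det)
  expect_gte(nrow(comp), 1)
  biggest <- comp[which.max(comp$pixel_count), ]
  ctr <- neurons(sc$truth)[1, ]
  expect_lt(sqrt((biggest$centroid_row - ctr$centroid_row)^2 +
                 (biggest$centroid_col - ctr$centroid_col)^2), 8)
})

test_that("component isolation follows 8-connectivity and size filtering", {
  expect_identical(nrow(components(isolateNeurons(matrix(FALSE, 60, 60)))),
                   0L)
  # two disjoint 3x3 squares: centroids at the square centers
  m <- matrix(FALSE, 60, 60)
  m[10:12, 10:12] <- TRUE
  m[30:32, 40:42] <- TRUE
  det <- components(isolateNeurons(m, min_pixels = 1))
  expect_identical(nrow(det), 2L)
  expect_equal(det$centroid_row, c(11, 31))
  expect_equal(det$centroid_col, c(11, 41))
  expect_equal(det$pixel_count, c(9L, 9L))
  # a 5x5 square plus an isolated pixel, min 2 px: one 25-px component
  m2 <- matrix(FALSE, 60, 60)
  m2[20:24, 20:24] <- TRUE
  m2[50, 50] <- TRUE
  det2 <- components(isolateNeurons(m2, min_pixels = 2))
  expect_identical(nrow(det2), 1L)
  expect_identical(det2$pixel_count, 25L)
  # diagonal touching merges under 8-connectivity
  m3 <- matrix(FALSE, 60, 60)
  m3[10:11, 10:11] <- TRUE
  m3[12, 12] <- TRUE
  expect_identical(nrow(components(isolateNeurons(m3, min_pixels = 1))), 1L)
})

test_that("translating the content translates the detections", {
  model <- nuclearModel()
  base <- renderScene(sceneConfig(height_px = 120, width_px = 120,
                                  n_cells = 1, seed = 55,
                                  gaussian_noise_sd = 0,
                                  poisson_scale = 0))$image
  k <- 6
  shifted <- matrix(1, 120, 120)
  shifted[(1 + k):120, (1 + k):120] <- base[1:(120 - k), 1:(120 - k)]
  d1 <- components(isolateNeurons(detectMask(model, base, stride = 1), 20))
  d2 <- components(isolateNeurons(detectMask(model, shifted, stride = 1),
                                  20))
  expect_identical(nrow(d1), 1L)
  expect_identical(nrow(d2), 1L)
  expect_lt(abs(d2$centroid_row - d1$centroid_row - k), 1)
  expect_lt(abs(d2$centroid_col - d1$centroid_col - k), 1)
})

test_that("strided detection fills interior pixels from the nearest center", {
  sc <- renderScene(sceneConfig(height_px = 140, width_px = 140,
                                n_cells = 2, seed = 66))
  m1 <- detectMask(nuclearModel(), sc$image, stride = 1)
  m3 <- detectMask(nuclearModel(), sc$image, stride = 3)
  expect_identical(m3@stride, 3L)
  # the strided mask stays close to the exact one
  interior <- m1@mask[29:112, 29:112]
  interior3 <- m3@mask[29:112, 29:112]
  expect_gt(mean(interior == interior3), 0.97)
})
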