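test_that("patch normalization is a clipped population z-score", {
  # constant patch: sd 0 convention maps to all zeros
  expect_identical(normalizePatch(matrix(7, 56, 56)), matrix(0, 56, 56))
  # two-valued patch, half 0 / half 2: mean 1, population sd 1, so the
  # pre-clip values are -1/+1 and the clipped output is {0, 1}
  p2 <- matrix(rep(c(0, 2), length.out = 56 * 56), 56, 56)
  out <- normalizePatch(p2)
  expect_setequal(unique(as.numeric(out)), c(0, 1))
  # general patches: output is the positive part of a zero-mean unit-sd
  # transform, hence min >= 0
  for (seed in 1:5) {
    p <- randomPatch(seed)
    z <- zscorePop(p)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
    expect_equal(normalizePatch(p), pmax(z, 0), tolerance = 1e-12)
    expect_gte(min(normalizePatch(p)), 0)
  }
  expect_error(normalizePatch(matrix(0, 10, 10)), "56")
})

test_that("three-channel embedding puts the patch in the red channel only", {
  p <- normalizePatch(randomPatch(3))
  arr <- toThreeChannel(p)
  expect_identical(dim(arr), c(56L, 56L, 3L))
  expect_identical(arr[, , 1], p)
  expect_identical(sum(arr[, , 2:3]), 0)
  expect_identical(toThreeChannel(matrix(0, 56, 56)),
                   array(0, c(56, 56, 3)))
})

test_that("patch datasets have the requested counts, labels and geometry", {
  cfgs <- lapply(1:2, function(i) {
    sceneConfig(height_px = 256, width_px = 256, n_cells = 20, seed = i)
  })
  ds <- renderPatchDataset(cfgs, n_neuron = 40, n_background = 35, seed = 5)
  expect_identical(dim(ds@patches), c(56L, 56L, 75L))
  expect_identical(as.integer(table(ds@labels)[c("neuron", "background")]),
                   c(40L, 35L))
  expect_false(ds@normalized)

  # neuron patches are centred on truth centroids: with every centroid
  # requested, the patch re-extracted at a centroid must appear verbatim
  sc <- renderScene(cfgs[[1]])
  ctr <- neurons(sc$truth)[1, ]
  patch <- sc$image[(ctr$centroid_row - 28):(ctr$centroid_row + 27),
                    (ctr$centroid_col - 28):(ctr$centroid_col + 27)]
  found <- any(vapply(which(ds@labels == "neuron"), function(i) {
    isTRUE(all.equal(ds@patches[, , i], patch))
  }, logical(1)))
  expect_true(found)
})

test_that("degenerate patch requests work or fail informatively", {
  cfg <- sceneConfig(height_px = 200, width_px = 200, n_cells = 3, seed = 9)
  ds0 <- renderPatchDataset(cfg, n_neuron = 0, n_background = 1, seed = 1)
  expect_identical(as.character(ds0@labels), "background")
  expect_error(renderPatchDataset(cfg, n_neuron = 10, n_background = 0,
                                  seed = 1), "3 neurons")
  # a crowded scene leaves no room for background patches
  crowded <- sceneConfig(height_px = 120, width_px = 120, n_cells = 18,
                         min_center_separation_px = 10, seed = 2)
  expect_error(renderPatchDataset(crowded, n_neuron = 0,
                                  n_background = 60, seed = 1),
               "scene 1")
})

test_that("background patch centers stay away from every cell", {
  cfg <- sceneConfig(height_px = 256, width_px = 256, n_cells = 10,
                     seed = 12, gaussian_noise_sd = 0, poisson_scale = 0)
  ds <- renderPatchDataset(cfg, n_neuron = 0, n_background = 40, seed = 3)
  # the patch *center* must sit outside every cell: with noise off the
  # central region of a background patch stays at the background level,
  # although a nucleus may intrude near the patch edge
  central <- apply(ds@patches[25:33, 25:33, , drop = FALSE], 3, max)
  expect_true(all(central < 2))
})

test_that("splitting is disjoint, exhaustive and class balanced", {
  cfgs <- lapply(1:2, function(i) {
    sceneConfig(height_px = 256, width_px = 256, n_cells = 20, seed = i)
  })
  ds <- renderPatchDataset(cfgs, 30, 30, seed = 5)
  ds <- splitDataset(ds, n_train_per_class = 20, seed = 2)
  tr <- ds@split$train; va <- ds@split$validation
  expect_length(intersect(tr, va), 0)
  expect_setequal(c(tr, va), seq_len(60))
  expect_identical(as.integer(table(ds@labels[tr])), c(20L, 20L))
  expect_error(splitDataset(ds, n_train_per_class = 50), "not enough")
})
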