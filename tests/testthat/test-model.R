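test_that("the architecture expands to the 12-layer sequence in order", {
  layers <- modelLayers(modelSpec())
  expect_identical(layers,
                   c("input", "conv_14x14", "batchnorm", "maxpool", "relu",
                     "conv_7x7", "batchnorm", "maxpool", "relu",
                     "fullyconnected_2", "softmax", "classification"))
  expect_length(layers, 12)
  # a kernel too large for the pooled map cannot realise the sequence
  expect_error(modelSpec(kernel_sizes = c(50L, 7L)), "conv kernel")
})

test_that("softmax outputs are a proper posterior and ties go to background", {
  m <- buildModel(seed = 3)
  for (seed in 1:4) {
    res <- classifyPatch(m, randomPatch(seed))
    expect_gte(res$posterior, 0.5)
    expect_lte(res$posterior, 1)
    expect_true(res$label %in% c("neuron", "background"))
  }
  # direct check of the two-way softmax on the compiled forward pass
  X <- matrix(pmax(rnorm(3136), 0), ncol = 1)
  probs <- rvquant:::.cnn_forward_cpp(X, 56L, 56L, 14L, 7L, m@params)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # the tie-break convention itself: equal posteriors classify background
  # (decision rule is p_neuron > 0.5)
  zero_fc <- m
  zero_fc@params$Wfc[] <- 0
  zero_fc@params$bfc[] <- 0
  res <- classifyPatch(zero_fc, randomPatch(1))
  expect_identical(res$label, "background")
  expect_equal(res$posterior, 0.5)
})

test_that("weight initialization and training are seed-reproducible", {
  expect_identical(buildModel(seed = 7)@params, buildModel(seed = 7)@params)
  expect_false(identical(buildModel(seed = 7)@params,
                         buildModel(seed = 8)@params))

  cfgs <- lapply(1:2, function(i) {
    sceneConfig(height_px = 256, width_px = 256, n_cells = 20, seed = i)
  })
  ds <- splitDataset(renderPatchDataset(cfgs, 30, 30, seed = 5), 20,
                     seed = 2)
  m1 <- trainModel(buildModel(seed = 1), ds, epochs = 2, seed = 4)
  m2 <- trainModel(buildModel(seed = 1), ds, epochs = 2, seed = 4)
  expect_identical(m1@params, m2@params)
  expect_identical(trainLog(m1)$epoch_loss, trainLog(m2)$epoch_loss)
})

test_that("zero training epochs leave the model at its initial accuracy", {
  cfgs <- lapply(1:2, function(i) {
    sceneConfig(height_px = 256, width_px = 256, n_cells = 20, seed = i)
  })
  ds <- splitDataset(renderPatchDataset(cfgs, 30, 30, seed = 5), 20,
                     seed = 2)
  m0 <- buildModel(seed = 1)
  trained0 <- trainModel(m0, ds, epochs = 0, seed = 4)
  expect_identical(trained0@params, m0@params)
  expect_equal(trainLog(trained0)$validation_accuracy,
               validationAccuracy(m0, ds))
})

test_that("training requires both classes and a split", {
  cfg <- sceneConfig(height_px = 200, width_px = 200, n_cells = 5, seed = 3)
  ds <- renderPatchDataset(cfg, 0, 30, seed = 1)
  expect_error(trainModel(buildModel(), ds), "split")
  ds@split <- list(train = 1:20, validation = 21:30)
  expect_error(trainModel(buildModel(), ds), "both classes")
})

test_that("a trained model recognises held-out truth-centred patches", {
  model <- nuclearModel()
  expect_gte(trainLog(model)$validation_accuracy, 0.99)
  # fresh scenes never seen in training
  hits <- unlist(lapply(41:42, function(s) {
    sc <- renderScene(sceneConfig(height_px = 256, width_px = 256,
                                  n_cells = 15, seed = s))
    nd <- neurons(sc$truth)
    vapply(seq_len(nrow(nd)), function(i) {
      patch <- sc$image[(nd$centroid_row[i] - 28):(nd$centroid_row[i] + 27),
                        (nd$centroid_col[i] - 28):(nd$centroid_col[i] + 27)]
      classifyPatch(model, patch)$label == "neuron"
    }, logical(1))
  }))
  expect_gte(mean(hits), 0.99)
})
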