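# fixtures shared across test files; expensive objects (trained models)
# are built once per test run and cached in this environment
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) {
    assign(name, force(expr), envir = .fixture_env)
  }
  .fixture_env[[name]]
}

# four moderate scenes per reporter: enough neurons for a 100+100 training
# split that separates cleanly, small enough to render in seconds
trainingConfigs <- function(reporter, seed0) {
  lapply(1:4, function(i) {
    sceneConfig(height_px = 320L, width_px = 320L, n_cells = 40L,
                reporter = reporter, seed = seed0 + i)
  })
}

# classifier trained on nuclear-reporter scenes (shared by detection and
# pipeline tests)
nuclearModel <- function() {
  fixture("nuclear_model", {
    ds <- renderPatchDataset(trainingConfigs("nuclear", 100), 150, 300,
                             seed = 100)
    ds <- splitDataset(ds, 100, seed = 100)
    trainModel(buildModel(seed = 100), ds, epochs = 10, seed = 109)
  })
}

cytoplasmicModel <- function() {
  fixture("cytoplasmic_model", {
    ds <- renderPatchDataset(trainingConfigs("cytoplasmic", 200), 150, 300,
                             seed = 200)
    ds <- splitDataset(ds, 100, seed = 200)
    trainModel(buildModel(seed = 200), ds, epochs = 10, seed = 209)
  })
}

# small raw patch with reproducible content
randomPatch <- function(seed = 1) {
  withr::with_seed(seed, matrix(abs(rnorm(56 * 56, 2, 1)), 56, 56))
}

# population-sd z-score used as the normalization oracle in tests
zscorePop <- function(p) (p - mean(p)) / sqrt(mean((p - mean(p))^2))
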