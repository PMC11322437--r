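# rvquant

Quantification of rabies-virus-labeled neurons and subcellular structures
in fluorescence microscopy, with a synthetic ground-truth generator that
makes every stage testable end to end.

Retrograde rabies tracing labels the presynaptic inputs of a circuit with
fluorescent reporters, and the readout is a count: how many labeled somata
in each region. How well automated counting works depends on the
reporter's subcellular localization — nuclear-localized reporters give
compact, well-separated blobs; cytoplasmic reporters also fill neurites,
which confuse soma detectors. `rvquant` implements this quantification
workflow:

* **Detection** — a 12-layer patch CNN (input; conv 14×14; batch-norm;
  max-pool; ReLU; conv 7×7; batch-norm; max-pool; ReLU; fully-connected
  with 2 outputs; softmax; classification) classifies the 56×56
  z-score-normalized patch centred on every pixel outside a 28-px border;
  neuron-classified pixels form a binary mask and 8-connected components
  are the detected neurons (`buildModel`, `trainModel`, `detectMask`,
  `isolateNeurons`).
* **Scoring** — optimal one-to-one matching of detections to annotations
  within a distance tolerance (Hungarian assignment), summarized as the
  *detection fraction* (matched truths / all truths) and *detection
  accuracy* (matched detections / all detections)
  (`matchDetections`, `detectionFraction`, `detectionAccuracy`).
* **Exact small-sample statistics** — Mann–Whitney and Kruskal–Wallis
  tests with p-values by full enumeration of group assignments
  (`exactMannWhitney`, `kruskalWallisExact`); for two groups of six with
  complete separation the exact two-sided floor is
  p = 2/924 = 0.0022.
* **Morphometry** — the mitochondria pipeline: rolling-ball-style
  background subtraction (grayscale opening), Otsu or fixed thresholding,
  8-connected particle analysis with physical-unit area and
  Crofton perimeter, and the inclusive 0.1–2.4 µm² area filter
  (`subtractBackground`, `binarizeImage`, `measureParticles`,
  `filterParticles`, `summarizeGroups`).
* **Motility** — nearest-neighbour particle tracking with gap closing and
  ambiguity rejection; speed = path length / elapsed time
  (`trackParticles`).
* **Spines** — inhomogeneous-Poisson spine placement along a dendrite
  near an amyloid plaque, and the three-segment normalized spine-share
  statistic with a Kruskal–Wallis comparison (`renderPlaqueScene`,
  `spineSegmentStatistic`).
* **Synthetic data** — seeded generators for nuclear / cytoplasmic /
  membrane reporter scenes, mitochondria fields and movies, and
  dendrite-plaque scenes, each returning full ground truth
  (`sceneConfig`, `renderScene`, `renderPatchDataset`,
  `renderMitoSequence`, `renderMitoField`).

## Worked example

Train the classifier on synthetic nuclear-reporter scenes, detect neurons
on a held-out scene and score against ground truth:

```r
library(rvquant)

cfgs <- lapply(1:4, function(i) {
  sceneConfig(height_px = 320, width_px = 320, n_cells = 40, seed = i)
})
ds <- renderPatchDataset(cfgs, n_neuron = 150, n_background = 300, seed = 1)
ds <- splitDataset(ds, n_train_per_class = 100, seed = 1)
model <- trainModel(buildModel(seed = 1), ds, epochs = 10,
                    learning_rate = 0.001, seed = 2)
trainLog(model)$validation_accuracy
#> [1] 1

sc  <- renderScene(sceneConfig(height_px = 200, width_px = 200,
                               n_cells = 8, seed = 99))
det <- isolateNeurons(detectMask(model, sc$image, stride = 3),
                      min_pixels = 20)
unlist(detectionMetrics(matchDetections(det, sc$truth,
                                        tolerance_px = 1.5 * 4 / 0.65)))
#> detection_fraction detection_accuracy            n_truth         n_detected
#>                  1                  1                  8                  8
#>          n_correct
#>                  8
```

(The tolerance is 1.5 x the 4 µm mean nucleus radius, converted to pixels
at 0.65 µm/px.)

The training reaches ceiling accuracy on the held-out patches (the
synthetic classes are clean and near-separable), all 8 planted neurons
are found and every detection is correct. On cytoplasmic-reporter scenes
the same protocol yields clearly lower detection accuracy — neurite
signal produces spurious soma detections — reproducing the practical
advantage of nuclear-localized reporters for automated counting. The
comparison of per-scene correct-detection rates between reporters uses
the exact Mann–Whitney test:

```r
exactMannWhitney(c(0.95, 0.97, 0.99, 1.0, 0.96, 0.98),
                 c(0.25, 0.30, 0.35, 0.28, 0.33, 0.31))
#> mann_whitney_exact: statistic = 36, p = 0.002165 (2/924 arrangements), n = 6,6
```

Rounded to four decimals this is the familiar p = 0.0022 floor.

See `vignettes/rvquant-methods.Rmd` for the model, the generator's
assumptions, and all numerical conventions.

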