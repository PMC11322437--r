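---
title: "Counting labeled neurons and measuring organelles: the rvquant methods"
author: "rvquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting labeled neurons and measuring organelles: the rvquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Retrograde viral tracers label presynaptic input neurons with fluorescent
reporters, and mapping a circuit then reduces to counting labeled somata
across brain regions. How countable the label is depends on where the
reporter accumulates: nuclear-localized reporters produce compact bright
nuclei with essentially no neurite signal, which is the easy regime for
automated counting, whereas cytoplasmic reporters fill somata *and*
neurites, and the neurite signal confuses soma detectors. `rvquant`
implements the quantification side of this workflow -- a patch-based CNN
soma detector, detection metrics against annotations, exact small-sample
rank tests, mitochondrial morphometry and motility, and plaque-adjacent
spine-density analysis -- together with a synthetic microscopy generator
that provides ground truth for every stage, so the whole pipeline is
testable without any imaging data.

# The detector

## Patch model

Detection is patch classification. Every candidate pixel centers a 56 x 56
patch (the center sits at patch index (29, 29) in 1-based coordinates);
the patch is z-score normalized with the *population* standard deviation
and negative values are clipped to zero (`normalizePatch()`); a constant
patch maps to all zeros by convention. The normalized patch is embedded in
the red channel of a 56 x 56 x 3 input whose other channels are zero
(`toThreeChannel()`); internally the zero channels are skipped, which is
mathematically identical and three times cheaper in the first convolution.

## Architecture

The classifier (`modelSpec()`, `buildModel()`) has exactly 12 layers:
input; a 14 x 14 convolution; batch normalization; 2 x 2 max pooling
(stride 2); ReLU; a 7 x 7 convolution; batch normalization; max pooling;
ReLU; a fully connected layer with two outputs; softmax; classification.
The block order conv -> batch-norm -> pool -> ReLU is implemented
literally in that order (for max pooling the pool/ReLU order is
mathematically irrelevant, since max commutes with monotone functions, but
the caches and gradients follow the stated order). Choices the
architecture text leaves open are filled with conventional defaults and
exposed in `modelSpec()`: 16 and 32 filters per convolution (small widths
that train to ceiling on separable patches in minutes), valid (no)
padding, and SGD with momentum 0.9 and mini-batch 128 as the optimizer.

## Training protocol

`trainModel()` follows the reference protocol: from a labeled pool, 900
neuron and 900 background patches are selected at random for training and
the remainder validates; 10 epochs at learning rate 0.001. The loss is
softmax cross-entropy; batch-norm layers use batch statistics during
training and exponentially tracked running statistics (momentum 0.1) at
inference. All randomness -- weight initialization, the training split,
mini-batch shuffling -- flows from explicit seeds through R's RNG, so
training is bit-reproducible.

## Whole-image inference

`detectMask()` excludes the 28-pixel margin at every edge (half the patch
size: a 56 x 56 patch cannot be centred closer to the border) and
classifies every interior pixel at stride 1; the neuron-classified pixels
form the binary detection mask. A `stride > 1` classifies a regular grid
and fills the remaining interior pixels from the nearest classified
center -- an approximation we use in tests to keep runtimes short (the
stride-1 path is verified exactly against per-pixel classification on
small images). Classification posteriors are computed in compiled code in
batches of several thousand patches. An exact softmax tie classifies as
background: when counting cells, the conservative side of a coin-flip is
to not count. `isolateNeurons()` extracts 8-connected components of at
least `min_pixels` (default 20 px, about 8.5 um^2 at 0.65 um/px -- a small
nucleus), reporting unweighted centroids.

# Scoring detections

`matchDetections()` pairs detections with ground-truth centroids by a
minimum-total-distance one-to-one assignment (Hungarian algorithm, not a
greedy heuristic), restricted to pairs within a tolerance; the default
tolerance used in the package's own studies is 1.5 x the mean nucleus
radius, so a detection sitting anywhere on the right nucleus matches.
Distance ties resolve to the lower truth id. Two ratios summarize a
match: the *detection fraction* (matched truths / all truths) and the
*detection accuracy* (matched detections / all detections); a "correct"
detection is defined as a matched one, which is the only self-consistent
reading of reporting both ratios. Undefined denominators yield `NA`
rather than 0.

# Exact rank tests

With three mice or six replicates per condition, asymptotic p-values are
the wrong tool, so both tests enumerate. `exactMannWhitney()` computes U
on mid-ranks and the exact two-sided p as the fraction of all
`choose(na+nb, na)` group assignments whose |U - E[U]| is at least the
observed one; under complete separation of two groups of six this is
2/924 = 0.0022, the smallest attainable two-sided p at those sizes.
`kruskalWallisExact()` computes the tie-corrected H and enumerates all
distinct assignments into the observed group sizes when the pooled n is at
most 12 (default), falling back to the chi-squared approximation above
that. For two groups the exact variants agree exactly, since H is then a
monotone function of |U - E[U]|. Exact p-values are always ratios of
integer counts, recorded in the result.

# Morphometry and motility

The mitochondria pipeline mirrors the standard interactive workflow, made
reproducible: `subtractBackground()` is a white top-hat (grayscale opening
by a disc, default radius 50 px, the conventional tool default);
`binarizeImage()` is Otsu's threshold (or a fixed level) with the chosen
threshold recorded; `measureParticles()` labels 8-connected components and
reports area (pixel count x pixel area) and a Crofton-style perimeter
(pi/4 x boundary crossings along rows and columns, which is exact in
expectation for smooth shapes and mildly underestimates polygons);
`filterParticles()` retains areas in [0.1, 2.4] um^2 with *inclusive*
bounds -- the exclusion rule is stated as strictly less/greater, so
equality stays. `summarizeGroups()` reports mean +- SEM per group at a
declared aggregation unit (particles or cells); because the choice is not
settled in the field, both are supported and the unit is explicit in the
result. Two groups are compared with the exact Mann-Whitney test on
cell-level means; a linear mixed model would be the alternative for
nested data, but with ten cells per group the exact rank test needs no
variance-structure assumptions, and the aggregation to cell means
addresses the pseudo-replication that motivates mixed models.

`trackParticles()` links per-frame detections by nearest neighbour with a
maximum link distance, closes single-frame gaps (at twice the link
radius), and *rejects* ambiguous links -- two candidates within 10% of the
same distance -- splitting the track instead of guessing; crossing
particles therefore cannot silently swap identities. Track speed is total
path length over elapsed time, the quantity a kymograph slope measures
for a motile organelle; the net-displacement speed is reported alongside
for transparency (a particle reflecting at the field border has a high
path speed but a low net speed).

# The synthetic-data generator

The generator is the package's study system, and its defaults are the
study conditions; they are chosen once, on physical grounds, and exposed
as configuration:

* **Neuron scenes** (`sceneConfig()`, `renderScene()`): 1024 x 1024 px at
  0.65 um/px (a 10x slide-scanner acquisition), nuclei of radius 3-5 um,
  somata 6-10 um, labeled plateau 5 x background, Gaussian PSF of 1 px,
  Poisson shot noise (200 counts per background unit) plus Gaussian read
  noise (sd 0.05). Nuclear reporters render *only* nuclei (zero neurite
  amplitude); cytoplasmic reporters fill the soma and send three smoothed
  random-walk neurites of ~1.5 px thickness and 60% amplitude outward,
  which suffices to create the soma/neurite confusion that lowers
  detection accuracy; membrane reporters render an annulus. Disk
  amplitudes are calibrated for the PSF: the stamped amplitude is divided
  by the mean PSF-blurred coverage over the object's own mask, so the
  *measured* mask-mean contrast equals the configured
  foreground/background ratio (without calibration the 1 px PSF depresses
  the measured ratio of a 6 px nucleus by ~10%). Geometry and noise come
  from separate seed substreams, so re-rendering with noise disabled
  reproduces the identical geometry.
* **Mitochondria** (`motilityConfig()`, `renderMitoSequence()`,
  `renderMitoField()`): punctae with lognormal areas (mean 0.7 um^2, CV
  0.3) at 0.16 um/px; the PSF default is 0.6 px, the diffraction-limited
  width of a high-NA 60x objective at that sampling -- at 1 px the extra
  blur biases Otsu-segmented areas upward by ~15%. A motile subset
  translocates at constant speed along a fixed axis (default 2 um/s,
  reflecting at the field border); stationary particles jitter within
  0.25 px of their base position, so no frame-to-frame truth displacement
  exceeds 0.5 px. Movies default to 180 frames at 1/3 s, a one-minute
  recording at about three frames per second. Configurations whose
  per-frame displacement exceeds half the minimum particle spacing are
  rejected: tracking ground truth would be ambiguous.
* **Dendrite/plaque scenes** (`renderPlaqueScene()`): spines are an
  inhomogeneous Poisson point process along a straight dendrite, with
  intensity an arbitrary non-negative function of distance to the plaque
  center (placed on the dendrite, so path distance equals plaque
  distance); `render_image = FALSE` skips rasterization for simulation
  loops. `spineSegmentStatistic()` bins spines into three distance
  segments, forms per-replicate densities (count per um of in-bin
  dendrite) and normalizes by the across-segment total so each
  replicate's three values sum to one -- the share convention is adopted
  because the three reported normalized segment values sum to ~1.

What the generator deliberately does not emulate: tissue autofluorescence
texture, out-of-focus light and z-structure, multi-channel bleed-through,
touching/overlapping somata, and real neurite morphology (branching,
varicosities). Passing tests therefore demonstrate that the *algorithms*
are implemented correctly and recover planted effects under controlled
conditions -- not that the detector would reach the same accuracy on real
tissue sections.

# Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col) with pixel centers at integers,
  matching R's indexing; the convention is stated once and used
  everywhere (ground truth, patches, components, matching).
* Patch normalization uses the population (divide-by-n) standard
  deviation; constant patches map to zeros; the normalization in compiled
  sliding-window code is the same function.
* An exact classifier tie (posterior 0.5) is background.
* Otsu on a contrast-free image is an error directing the caller to a
  fixed threshold, not a silent guess; blank masks measure to empty
  tables; an empty group or a zero-spine replicate raises an error or a
  logged drop, never a silent zero.
* Exact-test tail comparisons use a 1e-9 slack so floating-point rank
  arithmetic cannot drop arrangements that are tied with the observed
  statistic.
* The rejection-sampled placement gives each cell 1000 attempts to
  respect the minimum separation and errors out calling the
  configuration overcrowded rather than degrading silently.

# Problem sizes used in the tests

The test-suite runs everything at desk scale, chosen so the full suite
completes in minutes on one CPU: classifier fixtures train on four
320 x 320 scenes (150 neuron / 300 background patches, 100 + 100
training); the end-to-end detection properties use 200 x 200 scenes with
8 cells at stride 3 over 10 seeds; the training-protocol check runs the
full 1512/2348-patch, 900 + 900, 10-epoch protocol once; the area-recovery
check uses 10 cells x 50 particles per group over 3 seeds (the acceptance
script uses 5). The stride-1 contract is verified exhaustively on small
images and via the translation property; larger images use stride 3 with
nearest-center fill.

# Known limitations

* Stride-1 inference on a full 1024 x 1024 slide scan is ~1M forward
  passes (~15 min on one CPU at ~1 ms/patch); strided detection with
  nearest-center fill is the practical mode at that scale.
* The Crofton perimeter underestimates polygonal shapes by up to ~10%
  (pi/4 effect); areas, which drive all statistics here, are unbiased at
  the half-max contour and slightly overestimated (~5%) by Otsu on small
  blurred punctae.
* The exact Mann-Whitney enumerates up to `choose(24, 12)` assignments;
  beyond 12 per group it refuses rather than approximating silently.
* Track linking is nearest-neighbour with ambiguity rejection, not a
  global assignment across frames; it is designed for the sparse,
  well-separated punctae the generator produces.
* The synthetic scenes are far cleaner than tissue; absolute detection
  accuracies on them are ceiling-level and only the *orderings* (nuclear
  above cytoplasmic, degradation with noise) transfer qualitatively to
  real data.
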