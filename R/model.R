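#' Enumerate the 12 layers of a model specification
#'
#' @param spec a [ModelSpec-class].
#' @return Character vector of the 12 layer names in order.
#' @examples
#' modelLayers(modelSpec())
#' @export
modelLayers <- function(spec) {
  validObject(spec)
  k <- spec@kernel_sizes
  c("input",
    sprintf("conv_%dx%d", k[1], k[1]), "batchnorm", "maxpool", "relu",
    sprintf("conv_%dx%d", k[2], k[2]), "batchnorm", "maxpool", "relu",
    "fullyconnected_2", "softmax", "classification")
}

# feature-map geometry implied by the spec (valid conv, 2x2/2 pooling)
modelGeometry <- function(spec) {
  h <- spec@input_shape[1]
  o1 <- h - spec@kernel_sizes[1] + 1
  p1 <- o1 %/% 2
  o2 <- p1 - spec@kernel_sizes[2] + 1
  p2 <- o2 %/% 2
  list(o1 = o1, p1 = p1, o2 = o2, p2 = p2,
       fc_in = p2 * p2 * spec@filters_per_conv[2])
}

#' Build an untrained patch classifier
#'
#' Initializes the 12-layer network of `spec` with He-scaled Gaussian
#' weights (reproducible from `seed`), zero biases, and identity batch-norm
#' (gamma 1, beta 0, running mean 0, running variance 1).
#'
#' @param spec a [ModelSpec-class].
#' @param seed RNG seed controlling the weight initialization.
#' @return An untrained [TrainedModel-class].
#' @export
buildModel <- function(spec = modelSpec(), seed = 1L) {
  validObject(spec)
  if (length(modelLayers(spec)) != 12) {
    stop("specification does not expand to the 12-layer sequence")
  }
  k <- spec@kernel_sizes; f <- spec@filters_per_conv
  cin <- spec@input_shape[3]
  g <- modelGeometry(spec)
  fan1 <- k[1]^2 * cin
  fan2 <- k[2]^2 * f[1]
  params <- withSeed(deriveSeed(seed, "weight-init"), {
    list(
      W1 = matrix(rnorm(f[1] * fan1, 0, sqrt(2 / fan1)), f[1], fan1),
      b1 = numeric(f[1]), gamma1 = rep(1, f[1]), beta1 = numeric(f[1]),
      rmean1 = numeric(f[1]), rvar1 = rep(1, f[1]),
      W2 = matrix(rnorm(f[2] * fan2, 0, sqrt(2 / fan2)), f[2], fan2),
      b2 = numeric(f[2]), gamma2 = rep(1, f[2]), beta2 = numeric(f[2]),
      rmean2 = numeric(f[2]), rvar2 = rep(1, f[2]),
      Wfc = matrix(rnorm(2 * g$fc_in, 0, sqrt(2 / g$fc_in)), 2, g$fc_in),
      bfc = numeric(2))
  })
  new("TrainedModel", spec = spec, params = params, train_log = list(),
      trained = FALSE)
}

# stack normalized patches into the (h*w) x n input matrix the compiled
# forward pass consumes (single channel; the zero green/blue channels of
# the 3-channel embedding are implicit)
datasetMatrix <- function(dataset, indices) {
  d <- dim(dataset@patches)
  matrix(dataset@patches[, , indices, drop = FALSE], nrow = d[1] * d[2])
}

modelForward <- function(model, X) {
  s <- model@spec
  .cnn_forward_cpp(X, s@input_shape[1], s@input_shape[2],
                   s@kernel_sizes[1], s@kernel_sizes[2], model@params)
}

#' Train the patch classifier
#'
#' Stochastic gradient descent with momentum on softmax cross-entropy,
#' following the reference protocol: 10 epochs at learning rate 0.001 on
#' the training split, with the remaining patches used to compute the final
#' validation accuracy.  Training is bit-reproducible for a fixed seed.
#' Raw datasets are normalized (z-score, negative clip) automatically.
#'
#' @param model an untrained or trained [TrainedModel-class] (weights are
#'   the starting point).
#' @param dataset a [PatchDataset-class] with a training/validation split
#'   (see [splitDataset()]).
#' @param epochs training epochs (default 10).
#' @param learning_rate SGD learning rate (default 0.001).
#' @param seed RNG seed for minibatch shuffling.
#' @param batch_size minibatch size (default 128).
#' @param momentum SGD momentum (default 0.9).
#' @param bn_momentum running-statistics momentum of the batch-norm layers.
#' @return The trained model with `train_log` filled (per-epoch loss and
#'   final validation accuracy).
#' @export
trainModel <- function(model, dataset, epochs = 10L, learning_rate = 0.001,
                       seed = 1L, batch_size = 128L, momentum = 0.9,
                       bn_momentum = 0.1) {
  stopifnot(is(model, "TrainedModel"), is(dataset, "PatchDataset"))
  if (!length(dataset@split)) {
    stop("dataset has no training/validation split; call splitDataset()")
  }
  dataset <- normalizeDataset(dataset)
  tr <- dataset@split$train
  va <- dataset@split$validation
  y_tr <- as.integer(dataset@labels[tr] == "neuron")
  if (length(unique(y_tr)) < 2) {
    stop("training split must contain both classes")
  }
  s <- model@spec
  Xtr <- datasetMatrix(dataset, tr)
  params <- model@params
  losses <- numeric(0)
  if (epochs > 0) {
    order <- withSeed(deriveSeed(seed, "shuffle"), {
      vapply(seq_len(epochs), function(e) sample.int(length(tr)),
             integer(length(tr)))
    })
    fit <- .cnn_train_cpp(Xtr, y_tr, s@input_shape[1], s@input_shape[2],
                          s@kernel_sizes[1], s@kernel_sizes[2], params,
                          order, learning_rate, momentum,
                          as.integer(batch_size), bn_momentum)
    params <- fit$params
    losses <- as.numeric(fit$epoch_loss)
  }
  model@params <- params
  # validation accuracy with the final weights
  acc <- NA_real_
  if (length(va)) {
    Xva <- datasetMatrix(dataset, va)
    probs <- .cnn_forward_cpp(Xva, s@input_shape[1], s@input_shape[2],
                              s@kernel_sizes[1], s@kernel_sizes[2], params)
    pred <- probs[2, ] > 0.5   # tie classifies as background
    acc <- mean(pred == (dataset@labels[va] == "neuron"))
  }
  model@train_log <- list(epochs = as.integer(epochs),
                          learning_rate = learning_rate,
                          epoch_loss = losses, validation_accuracy = acc)
  model@trained <- TRUE
  model
}

#' Classify a single patch
#'
#' Normalizes the patch if needed, embeds it in the 3-channel input and
#' returns the argmax label with its posterior probability.  An exact tie
#' (both softmax outputs 0.5) classifies as background, the conservative
#' choice for counting.
#'
#' @param model a trained [TrainedModel-class].
#' @param patch a 56 x 56 matrix (raw or normalized) or a 56 x 56 x 3
#'   array (already embedded).
#' @param normalized set TRUE if a matrix patch is already normalized.
#' @return A list with `label` (`"neuron"` or `"background"`) and
#'   `posterior` (probability of the winning class, always in [0.5, 1]).
#' @export
classifyPatch <- function(model, patch, normalized = FALSE) {
  stopifnot(is(model, "TrainedModel"))
  if (is.matrix(patch)) {
    if (!normalized) patch <- normalizePatch(patch)
    X <- matrix(patch, ncol = 1)
  } else if (length(dim(patch)) == 3) {
    X <- matrix(patch, ncol = 1)
  } else {
    stop("patch must be a 56 x 56 matrix or 56 x 56 x 3 array")
  }
  probs <- modelForward(model, X)
  p_neuron <- probs[2, 1]
  if (p_neuron > 0.5) {
    list(label = "neuron", posterior = p_neuron)
  } else {
    list(label = "background", posterior = 1 - p_neuron)
  }
}

#' Validation accuracy of a model on a dataset's validation split
#'
#' @param model a [TrainedModel-class].
#' @param dataset a split [PatchDataset-class].
#' @return Fraction of correctly classified validation patches.
#' @export
validationAccuracy <- function(model, dataset) {
  stopifnot(is(model, "TrainedModel"), length(dataset@split) > 0)
  dataset <- normalizeDataset(dataset)
  va <- dataset@split$validation
  probs <- modelForward(model, datasetMatrix(dataset, va))
  mean((probs[2, ] > 0.5) == (dataset@labels[va] == "neuron"))
}
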