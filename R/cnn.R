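#' Convolutional layer specification
#'
#' @param num_kernels number of filters (N).
#' @param kernel_size square kernel size (M).
#' @param stride convolution stride.
#' @param pad zero padding on each border (valid convolutions, pad 0,
#'   by default).
#' @return A `conv_layer_spec` object.
#' @export
conv_layer_spec <- function(num_kernels, kernel_size, stride = 1L, pad = 0L) {
  if (num_kernels < 1 || kernel_size < 1 || stride < 1 || pad < 0)
    stopf("layer parameters must be positive (pad >= 0)")
  structure(list(num_kernels = as.integer(num_kernels),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "conv_layer_spec")
}

#' Spatial output size of a convolution or pooling layer
#'
#' Uses the standard valid-convolution convention
#' `(W + 2 pad - M) / stride + 1`.  With the default 64 x 64 input and
#' 5 x 5 kernels at stride 1 the network's spatial sizes run
#' 64 -> 60 -> 56 -> 28, the 2 x 2 stride-2 pool halving even inputs.
#'
#' @param input_w input spatial size.
#' @param layer a [conv_layer_spec()] (a pool is a layer with
#'   `kernel_size` 2 and `stride` 2).
#' @return Integer output size.
#' @export
feature_map_size <- function(input_w, layer) {
  stopifnot(inherits(layer, "conv_layer_spec"))
  num <- input_w + 2 * layer$pad - layer$kernel_size
  if (num < 0 || num %% layer$stride != 0)
    stopf("layer does not tile input of size %d (kernel %d, stride %d, pad %d)",
          input_w, layer$kernel_size, layer$stride, layer$pad)
  out <- num %/% layer$stride + 1L
  if (out <= 0)
    stopf("non-positive feature-map size for input %d", input_w)
  as.integer(out)
}

#' Four-layer network specification
#'
#' The default architecture: two 5 x 5 stride-1 valid convolutions with
#' 32 and 64 kernels (each followed by ReLU), a 2 x 2 stride-2 max
#' pool, fully connected layers of 1024 and 512 units (ReLU), dropout
#' 0.5 after the second fully connected layer, and a K = 2 way softmax
#' output.  Input patches are 64 x 64 x 3, mean-normalised.
#'
#' @param conv1,conv2 [conv_layer_spec()] objects.
#' @param pool_size,pool_stride max-pooling geometry.
#' @param fc_sizes integer vector of the two fully connected widths.
#' @param n_classes number of softmax outputs.
#' @param dropout_rate dropout probability after the second FC layer.
#' @param input_dim `c(H, W, C)` of the input patches.
#' @return A `network_spec` object.
#' @export
network_spec <- function(conv1 = conv_layer_spec(32, 5, 1, 0),
                         conv2 = conv_layer_spec(64, 5, 1, 0),
                         pool_size = 2L, pool_stride = 2L,
                         fc_sizes = c(1024L, 512L), n_classes = 2L,
                         dropout_rate = 0.5,
                         input_dim = c(64L, 64L, 3L)) {
  if (length(fc_sizes) != 2 || any(fc_sizes < 1))
    stopf("fc_sizes must give two positive layer widths")
  if (n_classes < 2) stopf("n_classes must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  spec <- structure(list(conv1 = conv1, conv2 = conv2,
                         pool_size = as.integer(pool_size),
                         pool_stride = as.integer(pool_stride),
                         fc_sizes = as.integer(fc_sizes),
                         n_classes = as.integer(n_classes),
                         dropout_rate = dropout_rate,
                         input_dim = as.integer(input_dim)),
                    class = "network_spec")
  cnn_activation_dims(spec)  # errors if any feature map is non-positive
  spec
}

#' Spatial activation sizes through the network
#'
#' @param spec a [network_spec()].
#' @return Named integer vector of spatial sizes: input, conv1, conv2,
#'   pool.
#' @export
cnn_activation_dims <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  s0 <- spec$input_dim[1]
  s1 <- feature_map_size(s0, spec$conv1)
  s2 <- feature_map_size(s1, spec$conv2)
  sp <- feature_map_size(s2, conv_layer_spec(1, spec$pool_size,
                                             spec$pool_stride, 0))
  c(input = s0, conv1 = s1, conv2 = s2, pool = sp)
}

arch_list <- function(spec) {
  list(H = spec$input_dim[1], W = spec$input_dim[2], C = spec$input_dim[3],
       N1 = spec$conv1$num_kernels, M1 = spec$conv1$kernel_size,
       S1 = spec$conv1$stride, P1 = spec$conv1$pad,
       N2 = spec$conv2$num_kernels, M2 = spec$conv2$kernel_size,
       S2 = spec$conv2$stride, P2 = spec$conv2$pad,
       PK = spec$pool_size, PS = spec$pool_stride,
       F1 = spec$fc_sizes[1], F2 = spec$fc_sizes[2], K = spec$n_classes)
}

#' Softmax over a logit vector
#'
#' Computes `exp(z_j) / sum_k exp(z_k)`, stabilised by subtracting the
#' maximum logit (the result is invariant under additive shifts).
#'
#' @param logits finite numeric vector.
#' @return List with `logits` and `probabilities` (non-negative, summing
#'   to 1).
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 1 || any(is.na(logits)) ||
      any(!is.finite(logits)))
    stopf("logits must be a finite numeric vector")
  e <- exp(logits - max(logits))
  list(logits = logits, probabilities = e / sum(e))
}

#' Build an untrained classifier
#'
#' Initialises weights with a fan-in-scaled (He) normal scheme under the
#' given seed; biases start at zero.  Two builds with the same spec and
#' seed produce identical models.
#'
#' @param spec a [network_spec()].
#' @param seed integer RNG seed for the weight initialisation.
#' @return An `ihc_cnn` model object (untrained).
#' @export
build_cnn <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  dims <- cnn_activation_dims(spec)
  k1 <- spec$input_dim[3] * spec$conv1$kernel_size^2
  k2 <- spec$conv1$num_kernels * spec$conv2$kernel_size^2
  flat <- spec$conv2$num_kernels * dims[["pool"]]^2
  f1 <- spec$fc_sizes[1]; f2 <- spec$fc_sizes[2]; k <- spec$n_classes
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  weights <- with_seed(seed, list(
    W1 = he(spec$conv1$num_kernels, k1), b1 = numeric(spec$conv1$num_kernels),
    W2 = he(spec$conv2$num_kernels, k2), b2 = numeric(spec$conv2$num_kernels),
    W3 = he(f1, flat), b3 = numeric(f1),
    W4 = he(f2, f1), b4 = numeric(f2),
    # output layer: unit-variance-preserving (Xavier) scale
    W5 = matrix(rnorm(k * f2, 0, sqrt(1 / f2)), k, f2), b5 = numeric(k)))
  structure(list(spec = spec, weights = weights, channel_means = NULL,
                 classes = NULL, seed = as.integer(seed), trained = FALSE,
                 train_log = NULL),
            class = "ihc_cnn")
}

#' Number of trainable parameters
#'
#' A pure function of the [network_spec()].
#'
#' @param model an `ihc_cnn` model.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "ihc_cnn"))
  sum(vapply(model$weights, length, 0L))
}

#' @export
print.ihc_cnn <- function(x, ...) {
  dims <- cnn_activation_dims(x$spec)
  cat(sprintf("<ihc_cnn> %s, %s parameters, spatial %s\n",
              if (x$trained) "trained" else "untrained",
              format(n_parameters(x), big.mark = ","),
              paste(dims, collapse = " -> ")))
  if (!is.null(x$classes))
    cat("  classes:", paste(x$classes, collapse = " / "), "\n")
  invisible(x)
}

#' Training configuration
#'
#' Defaults: stochastic gradient descent with learning rate 0.001 and
#' momentum 0.9, 15 epochs, batch size 25, cross-entropy loss over the
#' softmax output.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param seed seed controlling shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         epochs = 15L, batch_size = 25L, seed = 1L) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Normalise a patch array with stored per-channel means.
normalise_patches <- function(patches, means) {
  for (ch in seq_along(means)) patches[, , ch, ] <- patches[, , ch, ] - means[ch]
  patches
}

patchset_to_array <- function(x) {
  if (inherits(x, "patch_set")) x$patches else x
}

#' Train the classifier
#'
#' Mean normalisation subtracts the per-channel means of the training
#' set (stored with the model and re-applied at inference).  Training
#' minimises cross-entropy by SGD with momentum; dropout is active only
#' during training.
#'
#' @param model an `ihc_cnn` from [build_cnn()].
#' @param patchset a [patch_set()] containing exactly the model's two
#'   classes; the positive class (tumour / infiltrate) maps to the
#'   second softmax unit.
#' @param cfg a [train_config()].
#' @return The trained model, with a `train_log` data frame (epoch,
#'   loss, accuracy).
#' @export
train_cnn <- function(model, patchset, cfg = train_config()) {
  stopifnot(inherits(model, "ihc_cnn"), inherits(patchset, "patch_set"))
  n <- length.patch_set(patchset)
  if (n == 0) stopf("cannot train on an empty patch set")
  labs <- patchset$labels
  ulab <- unique(labs)
  if (length(ulab) != model$spec$n_classes)
    stopf("training set has %d class(es); the network expects %d",
          length(ulab), model$spec$n_classes)
  # order classes negative-first: the positive label, if recognisable,
  # goes last so its softmax unit is the final one
  pos <- intersect(c("tumour", "infiltrate"), ulab)
  classes <- if (length(pos) == 1) c(setdiff(ulab, pos), pos) else sort(ulab)
  y <- match(labs, classes) - 1L

  patches <- patchset_to_array(patchset)
  means <- vapply(1:3, function(ch) mean(patches[, , ch, ]), 0)
  patches <- normalise_patches(patches, means)
  fit <- cnn_train_cpp(patches, y, model$weights, arch_list(model$spec),
                       cfg$learning_rate, cfg$momentum, cfg$epochs,
                       cfg$batch_size, model$spec$dropout_rate, cfg$seed)
  model$weights <- fit$weights
  model$channel_means <- means
  model$classes <- classes
  model$trained <- TRUE
  model$train_log <- data.frame(epoch = seq_len(cfg$epochs),
                                loss = fit$loss, accuracy = fit$accuracy)
  model
}

#' Classify patches
#'
#' Inference is deterministic: dropout is disabled and repeated calls on
#' the same input return identical outputs.
#'
#' @param model a trained `ihc_cnn`.
#' @param patches an H x W x 3 x n array (or [patch_set()]) of raw
#'   `[0, 1]` RGB patches; the model's stored channel means are
#'   subtracted internally.
#' @return List with `logits` and `probabilities`, n x K matrices with
#'   columns named by class.
#' @export
predict_patches <- function(model, patches) {
  stopifnot(inherits(model, "ihc_cnn"))
  if (!model$trained) stopf("model has not been trained")
  patches <- patchset_to_array(patches)
  if (length(dim(patches)) == 3) patches <- array(patches, c(dim(patches), 1))
  din <- model$spec$input_dim
  if (length(dim(patches)) != 4 || any(dim(patches)[1:3] != din))
    stopf("patches must be %d x %d x %d (x n)", din[1], din[2], din[3])
  patches <- normalise_patches(patches, model$channel_means)
  out <- cnn_forward_cpp(patches, model$weights, arch_list(model$spec))
  colnames(out$logits) <- colnames(out$probabilities) <- model$classes
  out
}

#' Classify a single patch
#'
#' @param model a trained `ihc_cnn`.
#' @param patch an H x W x 3 RGB array in `[0, 1]`.
#' @return List with `logits` and `probabilities` vectors named by
#'   class (the softmax output).
#' @export
predict_patch <- function(model, patch) {
  out <- predict_patches(model, patch)
  list(logits = out$logits[1, ], probabilities = out$probabilities[1, ])
}

#' Save / load a trained model
#'
#' The model (spec, normalisation means, class labels and weights) is
#' serialised to a single file.
#'
#' @param model an `ihc_cnn`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "ihc_cnn"))
  # no compression: the 50M-parameter weight set compresses poorly and
  # slowly; plain serialisation is orders of magnitude faster
  saveRDS(model, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ihc_cnn")) stopf("'%s' does not hold an ihc_cnn", path)
  model
}
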