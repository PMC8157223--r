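#' Describe a 1-D CNN descriptor architecture
#'
#' Declarative specification of the two descriptor networks. Architecture A
#' has three convolution layers (kernels 11, 9, 9 along time, stride 1, no
#' padding), each followed by max-pooling (size 2; strides 4, 2, 2), then
#' four fully-connected layers where the penultimate one (FC3, the embedding)
#' has 256 units. Architecture B has five convolutions with larger initial
#' receptive fields (kernels 51, 17, 7, 7, 7), size-2 stride-2 max-pooling
#' after each, and a 4,096-unit embedding. A 10% dropout precedes the final
#' softmax classification layer. Filter counts and FC1/FC2 widths are
#' configurable (they are not part of the canonical layer geometry).
#'
#' @param name `"A"`, `"B"` or `"custom"`.
#' @param input_shape Integer pair (channels, window samples); the standard
#'   window is 12 s at 160 Hz = 1,920 samples.
#' @param n_classes Number of identities in the training gallery.
#' @param n_filters Filters per conv layer; defaults 96/128/256 (A) and
#'   96/128/128/256/256 (B).
#' @param fc_hidden Widths of FC1 and FC2; defaults 4096/1024 (A) and
#'   4096/4096 (B).
#' @param embedding_dim FC3 width; 256 for A and 4,096 for B.
#' @param dropout_rate Dropout before the classification layer, default 0.10.
#' @param conv_kernels,conv_strides,pool_sizes,pool_strides Layer geometry;
#'   only needed for `name = "custom"`.
#' @return Object of class `architecture_spec`.
#' @export
architecture_spec <- function(name = c("A", "B", "custom"),
                              input_shape = c(64, 1920),
                              n_classes = 109,
                              n_filters = NULL, fc_hidden = NULL,
                              embedding_dim = NULL, dropout_rate = 0.10,
                              conv_kernels = NULL, conv_strides = NULL,
                              pool_sizes = NULL, pool_strides = NULL) {
  name <- match.arg(name)
  if (name == "A") {
    conv_kernels <- conv_kernels %||% c(11, 9, 9)
    pool_strides <- pool_strides %||% c(4, 2, 2)
    pool_sizes <- pool_sizes %||% c(2, 2, 2)
    n_filters <- n_filters %||% c(96, 128, 256)
    fc_hidden <- fc_hidden %||% c(4096, 1024)
    embedding_dim <- embedding_dim %||% 256
  } else if (name == "B") {
    conv_kernels <- conv_kernels %||% c(51, 17, 7, 7, 7)
    pool_strides <- pool_strides %||% rep(2, 5)
    pool_sizes <- pool_sizes %||% rep(2, 5)
    n_filters <- n_filters %||% c(96, 128, 128, 256, 256)
    fc_hidden <- fc_hidden %||% c(4096, 4096)
    embedding_dim <- embedding_dim %||% 4096
  } else {
    if (is.null(conv_kernels) || is.null(pool_sizes) || is.null(pool_strides) ||
        is.null(n_filters) || is.null(fc_hidden) || is.null(embedding_dim)) {
      abort("custom architectures require explicit layer geometry and widths")
    }
  }
  conv_strides <- conv_strides %||% rep(1, length(conv_kernels))
  n_conv <- length(conv_kernels)
  stopifnot(
    length(pool_sizes) == n_conv, length(pool_strides) == n_conv,
    length(n_filters) == n_conv, length(fc_hidden) == 2,
    dropout_rate >= 0, dropout_rate < 1
  )
  if (name == "A" && n_conv != 3) abort("architecture A has exactly 3 conv layers")
  if (name == "B" && n_conv != 5) abort("architecture B has exactly 5 conv layers")
  structure(
    list(
      name = name, input_shape = as.integer(input_shape),
      n_classes = as.integer(n_classes),
      conv_kernels = as.integer(conv_kernels),
      conv_strides = as.integer(conv_strides),
      pool_sizes = as.integer(pool_sizes),
      pool_strides = as.integer(pool_strides),
      n_filters = as.integer(n_filters),
      fc_hidden = as.integer(fc_hidden),
      embedding_dim = as.integer(embedding_dim),
      dropout_rate = dropout_rate
    ),
    class = "architecture_spec"
  )
}

#' Temporal shape arithmetic for an architecture
#'
#' Applies the valid-convolution rule `out = floor((in - k) / stride) + 1`
#' layer by layer. For architecture A on a 1,920-sample window the temporal
#' lengths after conv1/pool1/conv2/pool2/conv3/pool3 are
#' 1910/478/470/235/227/113; architecture B ends at 52 after pool5.
#'
#' @param spec An [architecture_spec()].
#' @return Tibble with columns `layer`, `type`, `channels`, `length`.
#' @export
architecture_shapes <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  len <- spec$input_shape[2]
  ch <- spec$input_shape[1]
  rows <- list(tibble(layer = "input", type = "input", channels = ch, length = len))
  for (i in seq_along(spec$conv_kernels)) {
    len <- conv_out_len(len, spec$conv_kernels[i], spec$conv_strides[i])
    if (len < 1) {
      abort(sprintf("layer conv%d produces non-positive temporal length", i))
    }
    ch <- spec$n_filters[i]
    rows[[length(rows) + 1]] <- tibble(
      layer = paste0("conv", i), type = "conv", channels = ch, length = len
    )
    len <- conv_out_len(len, spec$pool_sizes[i], spec$pool_strides[i])
    if (len < 1) {
      abort(sprintf("layer pool%d produces non-positive temporal length", i))
    }
    rows[[length(rows) + 1]] <- tibble(
      layer = paste0("pool", i), type = "pool", channels = ch, length = len
    )
  }
  flat <- ch * len
  widths <- c(spec$fc_hidden, spec$embedding_dim, spec$n_classes)
  labs <- c("fc1", "fc2", "fc3", "fc4")
  for (i in seq_along(widths)) {
    rows[[length(rows) + 1]] <- tibble(
      layer = labs[i], type = "fc", channels = widths[i], length = 1L
    )
  }
  out <- bind_rows(rows)
  attr(out, "flatten_dim") <- flat
  out
}

#' Squeeze-and-excitation variant specification
#'
#' Five ways of merging SE channel-attention blocks into the base
#' architecture: (1) every convolution is replaced by an SE recalibration of
#' its incoming channels (pooling retained); (2) one SE block on the raw
#' input channels; (3) one SE block after the last pooling layer, before the
#' fully-connected stack; (4) both 2 and 3; (5) one SE block after every
#' convolution layer. The excitation bottleneck width is
#' `max(1, floor(C / r))` with reduction factor `r = 2^x`, x = 0..5.
#'
#' @param variant Integer 1..5.
#' @param r Reduction factor, one of 1, 2, 4, 8, 16, 32 (other positive
#'   integers are accepted).
#' @return Object of class `se_variant_spec`.
#' @export
se_variant_spec <- function(variant, r = 2) {
  if (!variant %in% 1:5) abort(paste0("unknown SE variant: ", variant))
  if (r < 1) abort("reduction factor r must be >= 1")
  structure(list(variant = as.integer(variant), r = as.integer(r)),
            class = "se_variant_spec")
}

#' Build a descriptor network
#'
#' Instantiates the layer stack with seeded scaled-uniform (fan-in) random
#' weights. With an `se` spec, SE blocks are merged per [se_variant_spec()].
#'
#' @param spec An [architecture_spec()].
#' @param se Optional [se_variant_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `eeg_cnn`.
#' @export
build_network <- function(spec, se = NULL, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (!is.null(se)) stopifnot(inherits(se, "se_variant_spec"))
  shapes <- architecture_shapes(spec)  # validates geometry
  set.seed(seed)
  layers <- list()
  ch <- spec$input_shape[1]
  len <- spec$input_shape[2]
  variant <- if (is.null(se)) 0L else se$variant
  if (variant %in% c(2L, 4L)) {
    layers[[length(layers) + 1]] <- layer_se(ch, se$r)
  }
  for (i in seq_along(spec$conv_kernels)) {
    if (variant == 1L) {
      # conv replaced by SE recalibration; channels and length unchanged
      layers[[length(layers) + 1]] <- layer_se(ch, se$r)
    } else {
      layers[[length(layers) + 1]] <- layer_conv(
        ch, spec$n_filters[i], spec$conv_kernels[i], spec$conv_strides[i]
      )
      ch <- spec$n_filters[i]
      len <- conv_out_len(len, spec$conv_kernels[i], spec$conv_strides[i])
      if (variant == 5L) {
        layers[[length(layers) + 1]] <- layer_se(ch, se$r)
      }
    }
    layers[[length(layers) + 1]] <- layer_pool(spec$pool_sizes[i], spec$pool_strides[i])
    len <- conv_out_len(len, spec$pool_sizes[i], spec$pool_strides[i])
  }
  if (variant %in% c(3L, 4L)) {
    layers[[length(layers) + 1]] <- layer_se(ch, se$r)
  }
  layers[[length(layers) + 1]] <- layer_flatten()
  flat <- ch * len
  layers[[length(layers) + 1]] <- layer_fc(flat, spec$fc_hidden[1], "relu")
  layers[[length(layers) + 1]] <- layer_fc(spec$fc_hidden[1], spec$fc_hidden[2], "relu")
  layers[[length(layers) + 1]] <- layer_fc(spec$fc_hidden[2], spec$embedding_dim, "relu")
  embedding_index <- length(layers)
  layers[[length(layers) + 1]] <- layer_dropout(spec$dropout_rate)
  layers[[length(layers) + 1]] <- layer_fc(spec$embedding_dim, spec$n_classes, "linear")
  structure(
    list(spec = spec, se = se, layers = layers,
         embedding_index = embedding_index,
         n_classes = spec$n_classes, class_levels = NULL),
    class = "eeg_cnn"
  )
}

#' @export
print.eeg_cnn <- function(x, ...) {
  n_se <- sum(vapply(x$layers, function(l) l$type == "se", logical(1)))
  cat(sprintf(
    "<eeg_cnn> architecture %s: input %d x %d, %d layers (%d SE), embedding %d, %d classes\n",
    x$spec$name, x$spec$input_shape[1], x$spec$input_shape[2],
    length(x$layers), n_se, x$spec$embedding_dim, x$n_classes
  ))
  invisible(x)
}

#' Merge SE blocks into a base architecture and build the network
#'
#' @param base An [architecture_spec()] (the base descriptor, typically A).
#' @param se An [se_variant_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `eeg_cnn`.
#' @export
build_se_variant <- function(base, se, seed = 1L) {
  build_network(base, se = se, seed = seed)
}

#' Count SE blocks in a built network
#' @param model An `eeg_cnn`.
#' @return Integer number of SE layers.
#' @export
count_se_blocks <- function(model) {
  sum(vapply(model$layers, function(l) l$type == "se", logical(1)))
}

#' Apply one squeeze-and-excitation block to a feature map
#'
#' Squeeze: per-channel temporal mean. Excitation: affine map to a bottleneck
#' of width `max(1, floor(C / r))` with rectifier, affine map back to C
#' channels with logistic squashing. The input is rescaled channel-wise by
#' the resulting gates in (0, 1).
#'
#' @param features Channels x time numeric matrix.
#' @param r Reduction factor >= 1.
#' @param weights Optional list with `W1`, `b1`, `W2`, `b2`; random seeded
#'   weights are drawn if omitted.
#' @param seed Seed for random weights when `weights` is NULL.
#' @return List with `out` (same-shape matrix), `gates` (length-C vector in
#'   (0, 1)) and the `weights` used.
#' @export
se_block <- function(features, r, weights = NULL, seed = 1L) {
  stopifnot(is.matrix(features), r >= 1, nrow(features) >= 1)
  C <- nrow(features)
  if (is.null(weights)) {
    set.seed(seed)
    lay <- layer_se(C, r)
  } else {
    lay <- list(type = "se", c_in = C, r = as.integer(r),
                hidden = nrow(weights$W1),
                W1 = weights$W1, b1 = weights$b1,
                W2 = weights$W2, b2 = weights$b2)
  }
  X <- array(features, c(C, ncol(features), 1))
  res <- forward_layer(lay, X)
  list(out = matrix(res$out, C, ncol(features)),
       gates = as.numeric(res$cache$g),
       weights = list(W1 = lay$W1, b1 = lay$b1, W2 = lay$W2, b2 = lay$b2))
}

#' Class probabilities for a batch of segments
#'
#' @param model An `eeg_cnn`.
#' @param X Array (channels, window, batch) or a single channels x window
#'   matrix.
#' @return Matrix n_classes x batch of softmax probabilities.
#' @export
predict_proba <- function(model, X) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1))
  check_input_shape(model, X)
  logits <- nn_forward(model, X, training = FALSE)$out
  softmax_cols(logits)
}

check_input_shape <- function(model, X) {
  d <- dim(X)
  if (d[1] != model$spec$input_shape[1] || d[2] != model$spec$input_shape[2]) {
    abort(sprintf(
      "segment shape (%d x %d) does not match model input (%d x %d)",
      d[1], d[2], model$spec$input_shape[1], model$spec$input_shape[2]
    ))
  }
  invisible(TRUE)
}

#' Extract the deep descriptor (FC3 embedding) of one segment
#'
#' Runs the network in inference mode (dropout inactive) up to the embedding
#' layer; the classification layers above it (dropout, FC4, softmax) play no
#' part, so the embedding is identical whether or not they are attached.
#'
#' @param model An `eeg_cnn`.
#' @param seg Channels x window numeric matrix.
#' @return Numeric vector of length `embedding_dim` (256 for architecture A,
#'   4,096 for B).
#' @export
extract_embedding <- function(model, seg) {
  stopifnot(inherits(model, "eeg_cnn"), is.matrix(seg))
  X <- array(seg, c(dim(seg), 1))
  check_input_shape(model, X)
  as.numeric(nn_forward(model, X, training = FALSE, upto = model$embedding_index)$out)
}

#' Embed every segment of a segment set
#'
#' @param model An `eeg_cnn`.
#' @param segs A [segment_set()].
#' @param batch_size Segments per forward pass.
#' @return Tibble with the segment metadata columns plus an `embedding`
#'   list-column of numeric vectors.
#' @export
embed_segments <- function(model, segs, batch_size = 100) {
  stopifnot(inherits(model, "eeg_cnn"), inherits(segs, "segment_set"))
  X <- segments_array(segs)
  check_input_shape(model, X)
  n <- dim(X)[3]
  embs <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- nn_forward(model, X[, , idx, drop = FALSE], training = FALSE,
                      upto = model$embedding_index)$out
    for (k in seq_along(idx)) embs[[idx[k]]] <- as.numeric(out[, k])
  }
  out <- as_tibble(segs)[, c("subject_id", "task", "run", "start_sample")]
  out$embedding <- embs
  out
}
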