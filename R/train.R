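#' Training configuration
#'
#' The standard recipe: stochastic gradient descent with momentum 0.9,
#' mini-batches of 100 segments reshuffled each epoch, and a two-phase
#' learning-rate schedule of 0.01 for 2 epochs then 0.001 for 18 epochs
#' (20 epochs total; training longer brings no improvement).
#'
#' @param lr_schedule Data frame with columns `lr` and `epochs`; executed in
#'   order.
#' @param momentum SGD momentum coefficient.
#' @param batch_size Segments per mini-batch.
#' @param shuffle Reshuffle the training order each epoch.
#' @param dropout_rate Dropout before the softmax layer (recorded here; the
#'   rate is wired into the architecture).
#' @param seed Integer seed making a run reproducible on one device.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr_schedule = data.frame(lr = c(0.01, 0.001),
                                                  epochs = c(2, 18)),
                         momentum = 0.9, batch_size = 100, shuffle = TRUE,
                         dropout_rate = 0.10, seed = 1L) {
  stopifnot(all(c("lr", "epochs") %in% names(lr_schedule)),
            all(lr_schedule$epochs >= 1), momentum >= 0, batch_size >= 1)
  structure(
    list(lr_schedule = as.data.frame(lr_schedule), momentum = momentum,
         batch_size = as.integer(batch_size), shuffle = shuffle,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "train_config"
  )
}

epoch_lrs <- function(cfg) {
  rep(cfg$lr_schedule$lr, cfg$lr_schedule$epochs)
}

param_names <- function(layer) {
  switch(layer$type,
    conv = c("W", "b"), fc = c("W", "b"),
    se = c("W1", "b1", "W2", "b2"),
    character(0)
  )
}

sgd_step <- function(model, grads, velocity, lr, momentum) {
  for (i in seq_along(model$layers)) {
    for (p in param_names(model$layers[[i]])) {
      g <- grads[[i]][[p]]
      v <- momentum * velocity[[i]][[p]] - lr * g
      velocity[[i]][[p]] <- v
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] + v
    }
  }
  list(model = model, velocity = velocity)
}

zero_velocity <- function(model) {
  lapply(model$layers, function(l) {
    vs <- list()
    for (p in param_names(l)) {
      d <- dim(l[[p]])
      vs[[p]] <- if (is.null(d)) numeric(length(l[[p]])) else array(0, d)
    }
    vs
  })
}

segment_labels <- function(segs, class_levels) {
  y <- match(segs$subject_id, class_levels)
  if (anyNA(y)) {
    missing <- unique(segs$subject_id[is.na(y)])
    abort(paste0("subject(s) absent from the training gallery: ",
                 paste(missing, collapse = ", ")))
  }
  y
}

#' Train the descriptor network as a closed-gallery classifier
#'
#' Cross-entropy on the softmax head, SGD with momentum, mini-batches
#' reshuffled per epoch, learning rate following the schedule exactly.
#' The gallery classes are the training subjects; validation subjects must
#' all appear in training.
#'
#' @param model An `eeg_cnn` whose head width equals the number of training
#'   subjects.
#' @param train,val [segment_set()]s; `val` may be NULL to skip validation
#'   metrics.
#' @param cfg A [train_config()].
#' @return List of class `eeg_training` with elements `model` (trained) and
#'   `history` (tibble: epoch, lr, train_loss, val_loss, val_accuracy).
#' @export
train_classifier <- function(model, train, val = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "eeg_cnn"), inherits(train, "segment_set"),
            inherits(cfg, "train_config"))
  if (nrow(train) == 0) abort("empty training set")
  if (!is.null(val) && nrow(val) == 0) abort("empty validation set")
  class_levels <- sort(unique(train$subject_id))
  if (length(class_levels) != model$n_classes) {
    abort(sprintf(
      "training gallery has %d subjects but the model head predicts %d classes",
      length(class_levels), model$n_classes
    ))
  }
  model$class_levels <- class_levels
  y_train <- segment_labels(train, class_levels)
  X_train <- segments_array(train)
  check_input_shape(model, X_train)
  if (!is.null(val)) {
    y_val <- segment_labels(val, class_levels)
    X_val <- segments_array(val)
  }

  set.seed(cfg$seed)
  lrs <- epoch_lrs(cfg)
  velocity <- zero_velocity(model)
  n <- dim(X_train)[3]
  hist_rows <- vector("list", length(lrs))
  for (epoch in seq_along(lrs)) {
    lr <- lrs[epoch]
    order <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    losses <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1, n)]
      Xb <- X_train[, , idx, drop = FALSE]
      fwd <- nn_forward(model, Xb, training = TRUE)
      sx <- softmax_xent(fwd$out, y_train[idx])
      grads <- nn_backward(model, fwd$caches, sx$dLogits)
      upd <- sgd_step(model, grads, velocity, lr, cfg$momentum)
      model <- upd$model
      velocity <- upd$velocity
      losses <- c(losses, sx$loss)
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(val)) {
      vout <- nn_forward(model, X_val, training = FALSE)$out
      vx <- softmax_xent(vout, y_val)
      val_loss <- vx$loss
      val_acc <- mean(max.col(t(vout), ties.method = "first") == y_val)
    }
    hist_rows[[epoch]] <- tibble(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_loss = val_loss, val_accuracy = val_acc
    )
  }
  structure(list(model = model, history = bind_rows(hist_rows)),
            class = "eeg_training")
}

#' @export
print.eeg_training <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<eeg_training> %d epochs; final train loss %.4f, val accuracy %s\n",
    nrow(x$history), last$train_loss,
    if (is.na(last$val_accuracy)) "NA" else sprintf("%.3f", last$val_accuracy)
  ))
  invisible(x)
}

#' @method tidy eeg_training
#' @export
tidy.eeg_training <- function(x, ...) x$history

#' @method glance eeg_training
#' @export
glance.eeg_training <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    n_epochs = nrow(x$history), final_train_loss = last$train_loss,
    final_val_loss = last$val_loss, final_val_accuracy = last$val_accuracy
  )
}

#' Learning curves of a training run
#'
#' @param object An `eeg_training`.
#' @param ... Ignored.
#' @return A ggplot of loss (train/validation) against epoch.
#' @method autoplot eeg_training
#' @export
autoplot.eeg_training <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Closed-gallery classification accuracy on a segment set
#'
#' @param model A trained `eeg_cnn` (with `class_levels` assigned).
#' @param segs A [segment_set()] whose subjects all belong to the gallery.
#' @return Proportion of segments whose argmax prediction matches the true
#'   subject.
#' @export
evaluate_classifier <- function(model, segs) {
  stopifnot(inherits(model, "eeg_cnn"), inherits(segs, "segment_set"))
  if (nrow(segs) == 0) abort("empty segment set")
  if (is.null(model$class_levels)) abort("model has no gallery (untrained head)")
  y <- segment_labels(segs, model$class_levels)
  X <- segments_array(segs)
  check_input_shape(model, X)
  out <- nn_forward(model, X, training = FALSE)$out
  mean(max.col(t(out), ties.method = "first") == y)
}
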