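# Training tests run on 3-second windows (480 samples) with narrow nets so a
# full 20-epoch schedule takes seconds; layer geometry mirrors architecture A.

micro_study <- function(n_subjects = 6, seed = 31, separability = 3,
                        stride = 60, task = "EO") {
  cfg <- synth_config(n_subjects = n_subjects, n_channels = 9, seed = seed,
                      separability = separability,
                      session_lengths = c(EO = 60, EC = 60))
  band <- analysis_band("30-50")
  sets <- lapply(generate_profiles(cfg), function(p) {
    rec <- bandpass(synthesize_recording(p, task, "R1", cfg), band)
    augment_sliding(rec, 480, stride)
  })
  bind_segments(sets)
}

test_that("the learning-rate schedule is followed exactly", {
  segs <- micro_study(n_subjects = 3, stride = 400)
  sp <- chronological_split(segs, 0.9)
  m <- build_network(micro_arch(n_classes = 3), seed = 1)
  fit <- train_classifier(m, sp$train, sp$validation,
                          train_config(batch_size = 20, seed = 2))
  expect_equal(nrow(fit$history), 20)
  expect_equal(fit$history$lr, rep(c(0.01, 0.001), c(2, 18)))
})

test_that("zero learning rate and momentum leave every weight untouched", {
  segs <- micro_study(n_subjects = 3, stride = 400)
  sp <- chronological_split(segs, 0.9)
  m <- build_network(micro_arch(n_classes = 3), seed = 4)
  cfg <- train_config(lr_schedule = data.frame(lr = 0, epochs = 3),
                      momentum = 0, batch_size = 20, seed = 5)
  fit <- train_classifier(m, sp$train, NULL, cfg)
  for (i in seq_along(m$layers)) {
    for (p in eegid:::param_names(m$layers[[i]])) {
      expect_identical(fit$model$layers[[i]][[p]], m$layers[[i]][[p]])
    }
  }
})

test_that("one SGD step matches a hand-computed momentum update", {
  # two-class logistic model: a single linear fc layer on 2 features
  model <- list(layers = list(eegid:::layer_fc(2, 2, "linear")))
  model$layers[[1]]$W <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  model$layers[[1]]$b <- c(0.05, -0.05)
  x <- matrix(c(1.5, -0.7), 2, 1)
  y <- 1L
  fwd <- eegid:::nn_forward(model, x)
  sx <- eegid:::softmax_xent(fwd$out, y)
  grads <- eegid:::nn_backward(model, fwd$caches, sx$dLogits)

  # closed-form softmax-regression gradient: (p - onehot) x^T
  z <- model$layers[[1]]$W %*% x + model$layers[[1]]$b
  p <- exp(z) / sum(exp(z))
  dlog <- p; dlog[y] <- dlog[y] - 1
  expect_equal(grads[[1]]$W, dlog %*% t(x), tolerance = 1e-12)
  expect_equal(grads[[1]]$b, as.numeric(dlog), tolerance = 1e-12)

  # momentum update v <- mu v - lr g starting from a non-zero velocity
  vel <- list(list(W = matrix(0.01, 2, 2), b = c(0.02, 0.02)))
  upd <- eegid:::sgd_step(model, grads, vel, lr = 0.1, momentum = 0.9)
  expect_equal(upd$model$layers[[1]]$W,
               model$layers[[1]]$W + 0.9 * vel[[1]]$W - 0.1 * (dlog %*% t(x)),
               tolerance = 1e-12)
  expect_equal(upd$velocity[[1]]$b, 0.9 * vel[[1]]$b - 0.1 * as.numeric(dlog),
               tolerance = 1e-12)
})

test_that("training is reproducible and validation classes must exist in train", {
  segs <- micro_study(n_subjects = 4, stride = 300)
  sp <- chronological_split(segs, 0.9)
  m <- build_network(micro_arch(n_classes = 4), seed = 6)
  cfg <- train_config(lr_schedule = data.frame(lr = 0.01, epochs = 2),
                      batch_size = 20, seed = 7)
  f1 <- train_classifier(m, sp$train, sp$validation, cfg)
  f2 <- train_classifier(m, sp$train, sp$validation, cfg)
  expect_identical(f1$history, f2$history)

  # validation containing a subject the gallery never saw
  bad_val <- sp$validation
  bad_val$subject_id[1] <- 99L
  expect_error(train_classifier(m, sp$train, bad_val, cfg), "absent")
  expect_error(train_classifier(m, sp$train[0, ], NULL, cfg), "empty")
})

test_that("training separates subjects; shuffled labels stay at chance", {
  # 3-s windows keep this fast; the full-window (12 s) accuracy bound is
  # asserted in the end-to-end acceptance run
  segs <- micro_study(n_subjects = 6, stride = 40, separability = 5)
  sp <- chronological_split(segs, 0.9)
  m <- build_network(micro_arch(n_classes = 6), seed = 8)
  fit <- train_classifier(m, sp$train, sp$validation,
                          train_config(batch_size = 25, seed = 9))
  acc <- fit$history$val_accuracy[20]
  expect_gt(acc, 0.7)

  # label-shuffled control: accuracy within 3 sigma of chance (1/6)
  shuf <- sp$train
  set.seed(10)
  shuf$subject_id <- sample(shuf$subject_id)
  # re-sort keeps the segment_set invariant while labels stay shuffled
  m2 <- build_network(micro_arch(n_classes = 6), seed = 8)
  fit2 <- train_classifier(m2, shuf, NULL, train_config(seed = 9))
  acc2 <- evaluate_classifier(fit2$model, sp$validation)
  n_val <- nrow(sp$validation)
  sigma <- sqrt((1 / 6) * (5 / 6) / n_val)
  expect_lt(abs(acc2 - 1 / 6), 3 * sigma + 0.02)
})

test_that("training loss decreases over the first schedule phase (median of 3 seeds)", {
  segs <- micro_study(n_subjects = 4, stride = 150)
  sp <- chronological_split(segs, 0.9)
  drops <- sapply(1:3, function(s) {
    m <- build_network(micro_arch(n_classes = 4), seed = s)
    fit <- train_classifier(m, sp$train, NULL,
                            train_config(lr_schedule = data.frame(lr = 0.01,
                                                                  epochs = 2),
                                         seed = s + 10))
    diff(fit$history$train_loss)  # epoch2 - epoch1
  })
  expect_lt(median(drops), 0)
})

test_that("classifier evaluation is order-invariant and bounded by chance", {
  segs <- micro_study(n_subjects = 5, stride = 150)
  m <- build_network(micro_arch(n_classes = 5), seed = 12)
  m$class_levels <- sort(unique(segs$subject_id))
  acc1 <- evaluate_classifier(m, segs)
  # permute rows: same accuracy
  perm <- segs[sample(nrow(segs)), ]
  class(perm) <- class(segs)
  attributes(perm)[c("window_samples", "sample_rate")] <-
    attributes(segs)[c("window_samples", "sample_rate")]
  expect_equal(evaluate_classifier(m, perm), acc1)

  # untrained network on balanced labels: within 3 sigma of chance
  n <- nrow(segs)
  sigma <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(acc1 - 0.2), 3 * sigma + 0.05)

  expect_error(evaluate_classifier(m, segs[0, ]), "empty")
})
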