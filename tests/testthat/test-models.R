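test_that("architecture A reproduces the canonical temporal lengths", {
  sh <- architecture_shapes(architecture_spec("A", input_shape = c(64, 1920)))
  lens <- sh$length[match(c("conv1", "pool1", "conv2", "pool2", "conv3", "pool3"),
                          sh$layer)]
  expect_equal(lens, c(1910L, 478L, 470L, 235L, 227L, 113L))
  expect_equal(sh$channels[sh$layer == "fc3"], 256L)
})

test_that("architecture B ends at 52 samples after pool5 and embeds in 4096", {
  sh <- architecture_shapes(architecture_spec("B", input_shape = c(64, 1920)))
  expect_equal(sh$length[sh$layer == "pool5"], 52L)
  expect_equal(sh$channels[sh$layer == "fc3"], 4096L)
})

test_that("impossible layer geometry raises a shape error naming the layer", {
  bad <- architecture_spec("B", input_shape = c(9, 40))  # kernel 51 > 40
  expect_error(architecture_shapes(bad), "conv1")
  expect_error(build_network(bad), "conv1")
})

test_that("shape arithmetic agrees with an explicit kernel-sliding simulator", {
  slide <- function(len, k, s) {
    # count positions by actually sliding the window
    count <- 0L; pos <- 1L
    while (pos + k - 1L <= len) { count <- count + 1L; pos <- pos + s }
    count
  }
  set.seed(42)
  for (rep in 1:20) {
    len <- sample(100:2000, 1)
    n_conv <- sample(1:4, 1)
    ks <- sample(3:30, n_conv, replace = TRUE)
    ps <- sample(2:4, n_conv, replace = TRUE)
    pstr <- sample(2:4, n_conv, replace = TRUE)
    spec <- architecture_spec("custom", input_shape = c(4, len), n_classes = 3,
                              conv_kernels = ks, pool_sizes = ps,
                              pool_strides = pstr,
                              n_filters = rep(4, n_conv), fc_hidden = c(8, 8),
                              embedding_dim = 8)
    expected <- len
    ok <- TRUE
    for (i in seq_len(n_conv)) {
      expected <- slide(expected, ks[i], 1)
      if (expected < 1) { ok <- FALSE; break }
      expected <- slide(expected, ps[i], pstr[i])
      if (expected < 1) { ok <- FALSE; break }
    }
    if (!ok) {
      expect_error(architecture_shapes(spec), "non-positive")
    } else {
      sh <- architecture_shapes(spec)
      expect_equal(sh$length[sh$layer == paste0("pool", n_conv)], expected)
    }
  }
})

test_that("the SE block matches a straight-line scalar oracle", {
  set.seed(7)
  C <- 6; T_ <- 40; r <- 2
  X <- matrix(rnorm(C * T_), C, T_)
  H <- C %/% r
  w <- list(W1 = matrix(rnorm(H * C, sd = 0.3), H, C), b1 = rnorm(H),
            W2 = matrix(rnorm(C * H, sd = 0.3), C, H), b2 = rnorm(C))
  res <- se_block(X, r, weights = w)

  # independent re-implementation: mean -> affine -> rectifier -> affine -> logistic
  squeeze <- sapply(seq_len(C), function(c) mean(X[c, ]))
  z <- as.numeric(w$W1 %*% squeeze + w$b1)
  a <- pmax(z, 0)
  g <- 1 / (1 + exp(-(as.numeric(w$W2 %*% a + w$b2))))
  expect_equal(res$gates, g, tolerance = 1e-12)
  expect_equal(res$out, X * g, tolerance = 1e-12)
})

test_that("SE gating is bounded and near-identity gates pass input through", {
  set.seed(8)
  X <- matrix(rnorm(5 * 30), 5, 30)
  res <- se_block(X, 2, seed = 3)
  expect_true(all(res$gates > 0 & res$gates < 1))
  expect_true(all(abs(res$out) <= abs(X) + 1e-12))

  # gates forced to ~1: zero excitation weights, huge positive output bias
  w1 <- list(W1 = matrix(0, 2, 5), b1 = rep(0, 2),
             W2 = matrix(0, 5, 2), b2 = rep(50, 5))
  res1 <- se_block(X, 2, weights = w1)
  expect_equal(res1$out, X, tolerance = 1e-12)

  # constant-in-time channels: squeeze equals the constant, so gates are
  # a deterministic function of the channel constants
  Xc <- matrix(rep(c(1, -2, 0.5), each = 30), 3, 30, byrow = TRUE)
  wc <- list(W1 = diag(3), b1 = rep(0, 3), W2 = diag(3), b2 = rep(0, 3))
  resc <- se_block(Xc, 1, weights = wc)
  expect_equal(resc$gates, 1 / (1 + exp(-pmax(c(1, -2, 0.5), 0))),
               tolerance = 1e-12)
})

test_that("SE variants insert the documented number of blocks", {
  base <- tiny_arch_A(n_classes = 4)
  counts <- sapply(1:5, function(v)
    count_se_blocks(build_se_variant(base, se_variant_spec(v, 2), seed = 1)))
  expect_equal(counts, c(3, 1, 1, 2, 3))
  expect_equal(counts[4], counts[2] + counts[3])
  # variant 1 really replaces the convolutions
  m1 <- build_se_variant(base, se_variant_spec(1, 2), seed = 1)
  expect_false(any(sapply(m1$layers, function(l) l$type == "conv")))
  expect_error(se_variant_spec(6, 2), "unknown SE variant")
})

test_that("the excitation bottleneck width is max(1, floor(C/r))", {
  spec64 <- architecture_spec("A", input_shape = c(64, 1920), n_classes = 5,
                              n_filters = c(8, 8, 8), fc_hidden = c(16, 16),
                              embedding_dim = 16)
  m <- build_se_variant(spec64, se_variant_spec(2, 2), seed = 1)
  se_layer <- m$layers[[which(sapply(m$layers, function(l) l$type == "se"))[1]]]
  expect_equal(se_layer$hidden, 32L)
  m64 <- build_se_variant(spec64, se_variant_spec(2, 64), seed = 1)
  se64 <- m64$layers[[which(sapply(m64$layers, function(l) l$type == "se"))[1]]]
  expect_equal(se64$hidden, 1L)
})

test_that("embeddings are deterministic and head-independent", {
  spec <- tiny_arch_A(n_classes = 4)
  m <- build_network(spec, seed = 5)
  set.seed(1)
  seg <- matrix(rnorm(9 * 1920), 9, 1920)
  e1 <- extract_embedding(m, seg)
  e2 <- extract_embedding(m, seg)
  expect_identical(e1, e2)
  expect_length(e1, 32)

  # stripping dropout + FC4 changes nothing about the embedding
  m_trunc <- m
  m_trunc$layers <- m$layers[seq_len(m$embedding_index)]
  full_fwd <- eegid:::nn_forward(m_trunc, array(seg, c(9, 1920, 1)))$out
  expect_equal(as.numeric(full_fwd), e1)

  expect_error(extract_embedding(m, matrix(0, 5, 1920)), "does not match")
})

test_that("the softmax head emits a probability distribution", {
  m <- build_network(tiny_arch_A(n_classes = 7), seed = 9)
  set.seed(2)
  X <- array(rnorm(9 * 1920 * 4), c(9, 1920, 4))
  P <- predict_proba(m, X)
  expect_true(all(P >= 0))
  expect_equal(colSums(P), rep(1, 4), tolerance = 1e-6)
})

test_that("canonical embeddings are 256 (A) and 4096 (B) dimensional", {
  mA <- build_network(architecture_spec("A", input_shape = c(9, 1920),
                                        n_classes = 3), seed = 1)
  set.seed(3)
  seg <- matrix(rnorm(9 * 1920), 9, 1920)
  expect_length(extract_embedding(mA, seg), 256)
  rm(mA); gc()
  mB <- build_network(architecture_spec("B", input_shape = c(9, 1920),
                                        n_classes = 3), seed = 1)
  expect_length(extract_embedding(mB, seg), 4096)
  rm(mB); gc()
})
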