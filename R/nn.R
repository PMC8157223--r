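# Minimal 1-D CNN engine: forward/backward passes for the layer types used by
# the descriptor architectures. Data flows as arrays (channels, time, batch)
# through conv/pool/SE layers and as matrices (features, batch) through the
# fully-connected stack. All heavy lifting is BLAS matrix multiplication.

conv_out_len <- function(len_in, kernel, stride) {
  as.integer((len_in - kernel) %/% stride + 1)
}

init_uniform <- function(n_out, n_in, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

layer_conv <- function(c_in, c_out, kernel, stride = 1L) {
  W <- array(init_uniform(c_out, c_in * kernel, c_in * kernel), c(c_out, c_in, kernel))
  list(type = "conv", c_in = c_in, c_out = c_out, kernel = as.integer(kernel),
       stride = as.integer(stride), W = W, b = numeric(c_out))
}

layer_pool <- function(size = 2L, stride = 2L) {
  list(type = "pool", size = as.integer(size), stride = as.integer(stride))
}

layer_se <- function(c_in, r) {
  H <- max(1L, c_in %/% r)
  list(type = "se", c_in = c_in, r = as.integer(r), hidden = H,
       W1 = init_uniform(H, c_in, c_in), b1 = numeric(H),
       W2 = init_uniform(c_in, H, H), b2 = numeric(c_in))
}

layer_flatten <- function() list(type = "flatten")

layer_fc <- function(n_in, n_out, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  list(type = "fc", n_in = n_in, n_out = n_out, activation = activation,
       W = init_uniform(n_out, n_in, n_in), b = numeric(n_out))
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate)

broadcast_gates <- function(g, T_) {
  # g: C x B -> array C x T x B
  C <- nrow(g); B <- ncol(g)
  aperm(array(g, c(C, B, T_)), c(1, 3, 2))
}

forward_layer <- function(layer, X, training = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(X)
      Tout <- conv_out_len(d[2], layer$kernel, layer$stride)
      if (Tout < 1) abort("conv layer produces non-positive temporal length")
      Z <- conv1d_forward(X, layer$W, layer$b, layer$stride)
      list(out = relu(Z),
           cache = list(X = X, mask = Z > 0, Tout = Tout))
    },
    pool = {
      d <- dim(X)
      Tout <- conv_out_len(d[2], layer$size, layer$stride)
      if (Tout < 1) abort("pool layer produces non-positive temporal length")
      starts <- seq(1L, by = layer$stride, length.out = Tout)
      cur <- X[, starts, , drop = FALSE]
      amax <- array(1L, dim(cur))
      if (layer$size > 1) {
        for (j in 2:layer$size) {
          cand <- X[, starts + j - 1L, , drop = FALSE]
          upd <- cand > cur
          cur[upd] <- cand[upd]
          amax[upd] <- j
        }
      }
      list(out = cur, cache = list(amax = amax, starts = starts, dim_in = d))
    },
    se = {
      d <- dim(X)
      s <- colMeans(aperm(X, c(2, 1, 3)))           # C x B temporal means
      s <- matrix(s, d[1], d[3])
      z <- layer$W1 %*% s + layer$b1
      a <- relu(z)
      u <- layer$W2 %*% a + layer$b2
      g <- sigmoid(u)                                # channel gates in (0,1)
      G <- broadcast_gates(g, d[2])
      list(out = X * G, cache = list(X = X, s = s, z = z, a = a, g = g, G = G))
    },
    flatten = {
      d <- dim(X)
      list(out = matrix(X, d[1] * d[2], d[3]), cache = list(dim_in = d))
    },
    fc = {
      Z <- layer$W %*% X + layer$b
      Y <- if (layer$activation == "relu") relu(Z) else Z
      list(out = Y, cache = list(X = X, mask = if (layer$activation == "relu") Z > 0))
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- (runif(length(X)) >= layer$rate) / (1 - layer$rate)
        mask <- array(keep, dim(X) %||% length(X))
        if (is.matrix(X)) mask <- matrix(keep, nrow(X), ncol(X))
        list(out = X * mask, cache = list(mask = mask))
      } else {
        list(out = X, cache = list(mask = NULL))
      }
    },
    abort(paste0("unknown layer type: ", layer$type))
  )
}

backward_layer <- function(layer, cache, dY) {
  switch(layer$type,
    conv = {
      dZ <- dY * cache$mask
      g <- conv1d_backward(cache$X, layer$W, dZ, layer$stride)
      list(dX = g$dX, grads = list(W = g$dW, b = as.numeric(g$db)))
    },
    pool = {
      dX <- array(0, cache$dim_in)
      for (j in seq_len(layer$size)) {
        sel <- cache$amax == j
        if (any(sel)) {
          contrib <- dY * sel
          cols <- cache$starts + j - 1L
          dX[, cols, ] <- dX[, cols, , drop = FALSE] + contrib
        }
      }
      list(dX = dX, grads = NULL)
    },
    se = {
      d <- dim(cache$X)
      dX <- dY * cache$G
      dg <- matrix(colSums(aperm(dY * cache$X, c(2, 1, 3))), d[1], d[3])
      du <- dg * cache$g * (1 - cache$g)
      dW2 <- du %*% t(cache$a)
      db2 <- rowSums(du)
      da <- t(layer$W2) %*% du
      dz <- da * (cache$z > 0)
      dW1 <- dz %*% t(cache$s)
      db1 <- rowSums(dz)
      ds <- t(layer$W1) %*% dz
      dX <- dX + broadcast_gates(ds / d[2], d[2])
      list(dX = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
    },
    flatten = {
      list(dX = array(dY, cache$dim_in), grads = NULL)
    },
    fc = {
      dZ <- if (layer$activation == "relu") dY * cache$mask else dY
      list(dX = crossprod(layer$W, dZ),
           grads = list(W = tcrossprod(dZ, cache$X), b = rowSums(dZ)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    }
  )
}

nn_forward <- function(model, X, training = FALSE, upto = length(model$layers)) {
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    res <- forward_layer(model$layers[[i]], X, training = training)
    X <- res$out
    caches[[i]] <- res$cache
  }
  list(out = X, caches = caches)
}

nn_backward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  dY <- dOut
  for (i in rev(seq_along(model$layers))) {
    res <- backward_layer(model$layers[[i]], caches[[i]], dY)
    grads[i] <- list(res$grads)  # plain [[<- would drop NULL entries
    dY <- res$dX
  }
  grads
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# cross-entropy loss and gradient wrt logits; y: integer class index per column
softmax_xent <- function(logits, y) {
  B <- ncol(logits)
  P <- softmax_cols(logits)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(y, seq_len(B))] + eps))
  dLogits <- P
  dLogits[cbind(y, seq_len(B))] <- dLogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dLogits = dLogits / B, probs = P)
}
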