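# Internal layer plumbing for the 1D convolutional network.
# Activation layout is channel-first: array (channels, length, batch);
# the compiled kernels in src/layers.cpp do convolution and max pooling.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

as_cube <- function(M) array(t(M), c(1L, ncol(M), nrow(M)))

# ---- batch normalization over conv activations (per channel) ----

bn_conv_fw <- function(Z, g, be, rm, rv, training) {
  if (training) {
    mu <- rowMeans(Z, dims = 1L)
    v <- pmax(rowMeans(Z * Z, dims = 1L) - mu^2, 0)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- (Z - mu) * invstd
    list(Y = g * xhat + be, xhat = xhat, invstd = invstd,
         rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu,
         rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v)
  } else {
    invstd <- 1 / sqrt(rv + BN_EPS)
    xhat <- (Z - rm) * invstd
    list(Y = g * xhat + be, xhat = xhat, invstd = invstd, rm = rm, rv = rv)
  }
}

bn_conv_bw <- function(dY, g, xhat, invstd) {
  N <- prod(dim(dY)[2:3])
  dg <- rowSums(dY * xhat, dims = 1L)
  dbe <- rowSums(dY, dims = 1L)
  dxhat <- dY * g
  m1 <- rowSums(dxhat, dims = 1L) / N
  m2 <- rowSums(dxhat * xhat, dims = 1L) / N
  list(dZ = invstd * (dxhat - m1 - xhat * m2), dg = dg, dbe = dbe)
}

# ---- batch normalization over fully connected features (per feature) ----

bn_fc_fw <- function(Z, g, be, rm, rv, training) {
  if (training && nrow(Z) > 1L) {
    mu <- colMeans(Z)
    v <- pmax(colMeans(Z * Z) - mu^2, 0)
  } else {
    mu <- rm; v <- rv
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(Z, 2L, mu, "-"), 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, g, "*"), 2L, be, "+")
  if (training && nrow(Z) > 1L) {
    rm <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
  }
  list(Y = Y, xhat = xhat, invstd = invstd, rm = rm, rv = rv)
}

bn_fc_bw <- function(dY, g, xhat, invstd) {
  dg <- colSums(dY * xhat)
  dbe <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dZ <- sweep(sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"),
              2L, invstd, "*")
  list(dZ = dZ, dg = dg, dbe = dbe)
}

# ---- parameter initialization (He for conv/FC weights) ----

nn_init <- function(spec) {
  p <- list(); r <- list()
  cin <- 1L
  for (b in seq_len(4L)) {
    co <- spec$block_channels[b]; k <- spec$block_kernels[b]
    p[[paste0("W_c", b)]] <- matrix(
      stats::rnorm(cin * k * co, 0, sqrt(2 / (cin * k))), cin * k, co)
    p[[paste0("b_c", b)]] <- rep(0, co)
    p[[paste0("g_c", b)]] <- rep(1, co)
    p[[paste0("be_c", b)]] <- rep(0, co)
    r[[paste0("rm_c", b)]] <- rep(0, co)
    r[[paste0("rv_c", b)]] <- rep(1, co)
    cin <- co
  }
  sizes <- c(spec$flatten, spec$fc_sizes, spec$n_classes)
  for (j in seq_len(3L)) {
    p[[paste0("W_f", j)]] <- matrix(
      stats::rnorm(sizes[j] * sizes[j + 1L], 0, sqrt(2 / sizes[j])),
      sizes[j], sizes[j + 1L])
    p[[paste0("b_f", j)]] <- rep(0, sizes[j + 1L])
    if (j < 3L) {
      p[[paste0("g_f", j)]] <- rep(1, sizes[j + 1L])
      p[[paste0("be_f", j)]] <- rep(0, sizes[j + 1L])
      r[[paste0("rm_f", j)]] <- rep(0, sizes[j + 1L])
      r[[paste0("rv_f", j)]] <- rep(1, sizes[j + 1L])
    }
  }
  list(params = p, running = r)
}

# ---- forward pass ----
# X: B x input_length matrix. Returns logits (B x K), updated running
# stats, the post-pool block-4 feature maps A4 (C4, L4, B), and, when
# `keep_cache`, everything backward needs.

nn_forward <- function(params, running, spec, X, training = FALSE,
                       keep_cache = FALSE) {
  A <- as_cube(X)
  cache <- list(blocks = vector("list", 4L))
  for (b in seq_len(4L)) {
    W <- params[[paste0("W_c", b)]]
    Z <- conv1d_fw(A, W, params[[paste0("b_c", b)]])
    bn <- bn_conv_fw(Z, params[[paste0("g_c", b)]],
                     params[[paste0("be_c", b)]],
                     running[[paste0("rm_c", b)]],
                     running[[paste0("rv_c", b)]], training)
    running[[paste0("rm_c", b)]] <- bn$rm
    running[[paste0("rv_c", b)]] <- bn$rv
    Yb <- pmax(bn$Y, 0)
    pool <- maxpool2_fw(Yb)
    if (keep_cache)
      cache$blocks[[b]] <- list(X = A, xhat = bn$xhat, invstd = bn$invstd,
                                mask = bn$Y > 0, argmax = pool$argmax,
                                L = dim(Yb)[2L])
    A <- pool$Y
  }
  A4 <- A
  B <- dim(A)[3L]
  V <- t(matrix(A, nrow = prod(dim(A)[1:2]), ncol = B)) # B x flatten
  fc <- list()
  H <- V
  for (j in 1:2) {
    Z <- sweep(H %*% params[[paste0("W_f", j)]], 2L,
               params[[paste0("b_f", j)]], "+")
    R <- pmax(Z, 0)
    bn <- bn_fc_fw(R, params[[paste0("g_f", j)]],
                   params[[paste0("be_f", j)]],
                   running[[paste0("rm_f", j)]],
                   running[[paste0("rv_f", j)]], training)
    running[[paste0("rm_f", j)]] <- bn$rm
    running[[paste0("rv_f", j)]] <- bn$rv
    D <- bn$Y
    dmask <- NULL
    if (training && spec$dropout_p > 0) {
      dmask <- matrix(stats::runif(length(D)) >= spec$dropout_p,
                      nrow(D), ncol(D)) / (1 - spec$dropout_p)
      D <- D * dmask
    }
    if (keep_cache)
      fc[[j]] <- list(X = H, mask = Z > 0, xhat = bn$xhat,
                      invstd = bn$invstd, dmask = dmask)
    H <- D
  }
  logits <- sweep(H %*% params$W_f3, 2L, params$b_f3, "+")
  if (keep_cache) {
    cache$fc <- fc
    cache$fc3_in <- H
    cache$A4dim <- dim(A4)
  }
  list(logits = logits, running = running, A4 = A4, cache = cache)
}

# ---- backward pass: dlogits (B x K) -> gradients for every parameter ----

nn_backward <- function(params, spec, cache, dlogits) {
  g <- list()
  g$W_f3 <- t(cache$fc3_in) %*% dlogits
  g$b_f3 <- colSums(dlogits)
  dH <- dlogits %*% t(params$W_f3)
  for (j in 2:1) {
    fc <- cache$fc[[j]]
    if (!is.null(fc$dmask)) dH <- dH * fc$dmask
    bn <- bn_fc_bw(dH, params[[paste0("g_f", j)]], fc$xhat, fc$invstd)
    g[[paste0("g_f", j)]] <- bn$dg
    g[[paste0("be_f", j)]] <- bn$dbe
    dZ <- bn$dZ * fc$mask
    g[[paste0("W_f", j)]] <- t(fc$X) %*% dZ
    g[[paste0("b_f", j)]] <- colSums(dZ)
    dH <- dZ %*% t(params[[paste0("W_f", j)]])
  }
  dA <- array(t(dH), cache$A4dim)
  for (b in 4:1) {
    blk <- cache$blocks[[b]]
    dY <- maxpool2_bw(dA, blk$argmax, blk$L)
    dY <- dY * blk$mask
    bn <- bn_conv_bw(dY, params[[paste0("g_c", b)]], blk$xhat, blk$invstd)
    g[[paste0("g_c", b)]] <- bn$dg
    g[[paste0("be_c", b)]] <- bn$dbe
    cv <- conv1d_bw(blk$X, params[[paste0("W_c", b)]], bn$dZ, b > 1L)
    g[[paste0("W_c", b)]] <- cv$dW
    g[[paste0("b_c", b)]] <- cv$db
    dA <- cv$dX
  }
  g
}

# ---- losses ----

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# weighted cross-entropy on softmax logits; y integer 1..K, w per-class
ce_loss_grad <- function(logits, y, w) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  wi <- w[y]
  sw <- sum(wi)
  idx <- cbind(seq_len(n), y)
  loss <- sum(wi * -log(pmax(p[idx], 1e-12))) / sw
  one <- matrix(0, n, ncol(logits)); one[idx] <- 1
  list(loss = loss, dlogits = (p - one) * (wi / sw))
}

# literal mode: per-class log-sigmoid output + weighted NLL of true class
logsig_loss_grad <- function(logits, y, w) {
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  zy <- logits[idx]
  sig <- 1 / (1 + exp(-zy))
  wi <- w[y]
  sw <- sum(wi)
  loss <- sum(wi * -log(pmax(sig, 1e-12))) / sw
  d <- matrix(0, n, ncol(logits))
  d[idx] <- wi * (sig - 1) / sw
  list(loss = loss, dlogits = d)
}

# ---- rectified Adam ----

radam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

radam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  rho_inf <- 2 / (1 - beta2) - 1
  b2t <- beta2^t
  rho_t <- rho_inf - 2 * t * b2t / (1 - b2t)
  bc1 <- 1 - beta1^t
  rect <- rho_t > 5
  if (rect)
    r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                ((rho_inf - 4) * (rho_inf - 2) * rho_t))
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gnm
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gnm * gnm
    mhat <- opt$m[[nm]] / bc1
    if (rect) {
      vhat <- sqrt(opt$v[[nm]] / (1 - b2t))
      params[[nm]] <- params[[nm]] - lr * r * mhat / (vhat + eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * mhat
    }
  }
  list(opt = opt, params = params)
}
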