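# Minimal seeded CNN engine used by the print-quality classifier.
#
# Design notes:
# * Activations for a batch of N square images (side H, C channels) are
#   stored as an (N*H*H) x C matrix; row index = (n-1)*H*H + (x-1)*H + y.
#   Convolutions become one GEMM per layer via im2col, so the heavy
#   arithmetic runs in BLAS; the gather/scatter kernels (im2col/col2im,
#   2x2 max-pooling) are compiled (src/kernels.cpp).
# * 3x3 convolutions use zero ("same") padding; each conv block is
#   conv -> batchnorm -> ReLU -> 2x2 maxpool.
# * All randomness (init, shuffling, dropout, augmentation) flows through
#   R's RNG so a single seed makes training bit-reproducible; the
#   compiled kernels are deterministic.

# broadcast a per-channel vector across the rows of an (n x C) matrix
bcol <- function(v, n) rep.int(v, rep.int(n, length(v)))

relu <- function(X) X * (X > 0)

flatten_fwd <- function(A, P2, N, C) {
  B <- array(A, dim = c(P2, N, C))
  t(matrix(aperm(B, c(1, 3, 2)), P2 * C, N))
}

flatten_bwd <- function(dF, P2, N, C) {
  G <- array(t(dF), dim = c(P2, C, N))
  matrix(aperm(G, c(1, 3, 2)), P2 * N, C)
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# Forward pass. images: H x H x N array. Returns probabilities and, when
# train = TRUE, the caches needed for backprop.
cnn_forward <- function(model, images, train = FALSE, dropout_mask = NULL) {
  H <- dim(images)[1]
  N <- dim(images)[3]
  P <- model$params
  depths <- model$depths
  X <- matrix(as.numeric(images), H * H * N, 1)
  # rows arrive as (y, x, n) column-major = (n-1)*HW + (x-1)*H + y: matches layout
  caches <- list()
  side <- H
  momentum <- 0.9
  eps <- 1e-5
  for (l in seq_along(depths)) {
    Cin <- if (l == 1) 1 else depths[l - 1]
    key <- paste0("c", l)
    Pm <- cpp_im2col(X, side, N)
    Z <- Pm %*% P[[paste0(key, "_W")]]
    # conv bias is mathematically absorbed by the batchnorm mean shift
    # (its gradient is identically zero); it is kept as a parameter for
    # architectural faithfulness but never enters the computation
    if (train) {
      m <- colMeans(Z)
      v <- pmax(colMeans(Z * Z) - m * m, 0)
      run <- model$running[[key]]
      run$mean <- momentum * run$mean + (1 - momentum) * m
      run$var <- momentum * run$var + (1 - momentum) * v
      model$running[[key]] <- run
    } else {
      m <- model$running[[key]]$mean
      v <- model$running[[key]]$var
    }
    ivar <- 1 / sqrt(v + eps)
    A <- cpp_bn_relu_fwd(Z, P[[paste0(key, "_g")]], P[[paste0(key, "_beta")]],
                         m, ivar)
    pool <- cpp_pool_fwd(A, side, N)
    if (train) {
      caches[[key]] <- list(X = X, Z = Z, A = A, m = m, ivar = ivar,
                            win = pool$win, side = side, Cin = Cin)
    }
    X <- pool$out
    side <- side %/% 2
  }
  P2 <- side * side
  Cf <- depths[length(depths)]
  Fm <- flatten_fwd(X, P2, N, Cf)
  Z1 <- Fm %*% P$d1_W + bcol(P$d1_b, N)
  A1 <- relu(Z1)
  if (train) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix((runif(length(A1)) > model$dropout) /
                               (1 - model$dropout), nrow(A1), ncol(A1))
    }
    A1d <- A1 * dropout_mask
  } else {
    A1d <- A1
  }
  Z2 <- A1d %*% P$d2_W + P$d2_b
  prob <- sigmoid(Z2)
  if (!train) return(list(prob = drop(prob)))
  list(prob = drop(prob), caches = caches, Fm = Fm, Z1 = Z1, A1 = A1,
       A1d = A1d, dropout_mask = dropout_mask, P2 = P2, Cf = Cf, N = N,
       running = model$running)
}

# Backward pass; returns gradient list matching model$params.
cnn_backward <- function(model, fwd, labels, weights) {
  P <- model$params
  depths <- model$depths
  N <- fwd$N
  grads <- list()
  dZ2 <- matrix((fwd$prob - labels) * weights / N, N, 1)
  grads$d2_W <- crossprod(fwd$A1d, dZ2)
  grads$d2_b <- sum(dZ2)
  dA1d <- tcrossprod(dZ2, P$d2_W)
  dA1 <- dA1d * fwd$dropout_mask
  dZ1 <- dA1 * (fwd$Z1 > 0)
  grads$d1_W <- crossprod(fwd$Fm, dZ1) + model$l2 * P$d1_W
  grads$d1_b <- colSums(dZ1)
  dF <- tcrossprod(dZ1, P$d1_W)
  dX <- flatten_bwd(dF, fwd$P2, N, fwd$Cf)
  for (l in rev(seq_along(depths))) {
    key <- paste0("c", l)
    cc <- fwd$caches[[key]]
    dA <- cpp_pool_bwd(dX, cc$win, cc$side, N)
    bnb <- cpp_bn_relu_bwd(dA, cc$A, cc$Z, P[[paste0(key, "_g")]],
                           cc$m, cc$ivar)
    grads[[paste0(key, "_g")]] <- bnb$dg
    grads[[paste0(key, "_beta")]] <- bnb$db
    dZ <- bnb$dX
    Pm <- cpp_im2col(cc$X, cc$side, N)
    grads[[paste0(key, "_W")]] <- crossprod(Pm, dZ)
    # conv bias: gradient is exactly zero (absorbed by batchnorm)
    grads[[paste0(key, "_b")]] <- numeric(depths[l])
    if (l > 1) {
      dP <- tcrossprod(dZ, P[[paste0(key, "_W")]])
      dX <- cpp_col2im(dP, cc$side, N, cc$Cin)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

weighted_bce <- function(prob, labels, weights = 1) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  mean(-weights * (labels * log(p) + (1 - labels) * log(1 - p)))
}
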