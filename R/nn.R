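# Minimal CNN engine: forward/backward passes for the layer types the
# three-conv-block classifier needs.  Activations are arrays of dim
# (H, W, C, N); fully-connected activations are matrices (features, N).
# The convolutional-block kernels (im2col convolution, 2-D batch norm,
# ReLU, max pooling) are compiled (src/nn_kernels.cpp); pure-R reference
# implementations (`*_ref`) of the conv/pool kernels are kept for
# cross-checking in the test suite.

conv_out_dim <- function(input, k, s, p) (input + 2L * p - k) %/% s + 1L

conv_forward <- function(A, W, b, k, s, p) {
  r <- .conv_fwd_cpp(A, dim(A), W, b, k, s, p)
  list(out = r$out,
       cache = list(Cmat = r$Cmat, dims = dim(A), k = k, s = s, p = p,
                    W = W))
}

conv_backward <- function(dY, cache) {
  r <- .conv_bwd_cpp(dY, cache$Cmat, cache$W, cache$dims,
                     cache$k, cache$s, cache$p)
  list(dA = r$dA, dW = r$dW, db = as.numeric(r$db))
}

maxpool_forward <- function(A) {
  r <- .pool_fwd_cpp(A, dim(A))
  list(out = r$out, cache = list(arg = r$arg, dims = dim(A)))
}

maxpool_backward <- function(dY, cache) {
  .pool_bwd_cpp(dY, cache$arg, cache$dims)
}

relu_forward <- function(A) .relu_fwd_cpp(A)
relu_backward <- function(dY, A) .relu_bwd_cpp(dY, A)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Channel-wise batch normalization: over (H, W, N) for 4-d activations
# (compiled path), over N for 2-d (features x N) activations (R path).
bn_forward <- function(X, gamma, beta, state, training, stats_env = NULL,
                       stats_key = NULL) {
  if (!is.matrix(X)) {
    d <- dim(X)
    m <- as.numeric(d[1]) * d[2] * d[4]
    if (training) {
      st <- .bn2d_stats_cpp(X, d)
      mu <- st$mean; v <- st$var
      state$running_mean <- (1 - BN_MOMENTUM) * state$running_mean +
        BN_MOMENTUM * mu
      ub <- if (m > 1) v * m / (m - 1) else v
      state$running_var <- (1 - BN_MOMENTUM) * state$running_var +
        BN_MOMENTUM * ub
      if (!is.null(stats_env)) {
        acc <- stats_env[[stats_key]] %||% list(sum = 0, sumsq = 0, n = 0)
        stats_env[[stats_key]] <- list(
          sum = acc$sum + mu * m,
          sumsq = acc$sumsq + (v + mu^2) * m,
          n = acc$n + m)
      }
    } else {
      mu <- state$running_mean
      v <- state$running_var
    }
    ap <- .bn2d_apply_cpp(X, d, gamma, beta, mu, v, BN_EPS, TRUE)
    return(list(out = ap$out, state = state,
                cache = list(is2d = TRUE, xhat = ap$xhat, dims = d,
                             var = v, gamma = gamma, training = training)))
  }
  M <- X
  m <- ncol(M)
  if (training) {
    mu <- rowMeans(M)
    v <- pmax(rowMeans(M * M) - mu^2, 0)
    state$running_mean <- (1 - BN_MOMENTUM) * state$running_mean +
      BN_MOMENTUM * mu
    ub <- if (m > 1) v * m / (m - 1) else v
    state$running_var <- (1 - BN_MOMENTUM) * state$running_var +
      BN_MOMENTUM * ub
    if (!is.null(stats_env)) {
      acc <- stats_env[[stats_key]] %||% list(sum = 0, sumsq = 0, n = 0)
      stats_env[[stats_key]] <- list(sum = acc$sum + rowSums(M),
                                     sumsq = acc$sumsq + rowSums(M * M),
                                     n = acc$n + m)
    }
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  sdv <- sqrt(v + BN_EPS)
  xhat <- (M - mu) / sdv
  Y <- gamma * xhat + beta
  list(out = Y, state = state,
       cache = list(is2d = FALSE, xhat = xhat, sdv = sdv, gamma = gamma,
                    training = training))
}

# In training mode the batch statistics depend on the input, giving the
# usual mean/variance correction terms; in inference mode the layer is a
# frozen affine map and the gradient is a per-channel rescaling (this is
# the path Grad-CAM differentiates through).
bn_backward <- function(dY, cache) {
  if (isTRUE(cache$is2d)) {
    if (!cache$training) {
      C <- cache$dims[3]
      scale <- cache$gamma / sqrt(cache$var + BN_EPS)
      dA <- .bn2d_apply_cpp(dY, cache$dims, scale, numeric(C), numeric(C),
                            rep(1 - BN_EPS, C), BN_EPS, FALSE)$out
      return(list(dA = dA,
                  dgamma = as.numeric(.bn2d_stats_cpp(
                    dY * cache$xhat, cache$dims)$mean) *
                    (as.numeric(cache$dims[1]) * cache$dims[2] *
                       cache$dims[4]),
                  dbeta = as.numeric(.bn2d_stats_cpp(
                    dY, cache$dims)$mean) *
                    (as.numeric(cache$dims[1]) * cache$dims[2] *
                       cache$dims[4])))
    }
    r <- .bn2d_bwd_cpp(dY, cache$xhat, cache$dims, cache$gamma, cache$var,
                       BN_EPS)
    return(list(dA = r$dA, dgamma = as.numeric(r$dgamma),
                dbeta = as.numeric(r$dbeta)))
  }
  D <- dY
  xhat <- cache$xhat
  if (!cache$training) {
    return(list(dA = (cache$gamma / cache$sdv) * D,
                dgamma = rowSums(D * xhat),
                dbeta = rowSums(D)))
  }
  list(dA = (cache$gamma / cache$sdv) *
         (D - rowMeans(D) - xhat * rowMeans(D * xhat)),
       dgamma = rowSums(D * xhat),
       dbeta = rowSums(D))
}

fc_forward <- function(X, W, b) {
  list(out = W %*% X + b, cache = list(X = X, W = W))
}

fc_backward <- function(dY, cache) {
  list(dA = crossprod(cache$W, dY),
       dW = tcrossprod(dY, cache$X),
       db = rowSums(dY))
}

flatten_forward <- function(A) {
  d <- dim(A)
  list(out = matrix(A, nrow = prod(d[1:3])), cache = d)
}

flatten_backward <- function(dY, dims) array(dY, dims)

# ---- pure-R reference kernels (used as oracles in the test suite) -------

.nn_cache <- new.env(parent = emptyenv())

conv_index_tables <- function(H, W, C, N, k, s, p) {
  key <- paste("conv", H, W, C, N, k, s, p, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  oh <- conv_out_dim(H, k, s, p); ow <- conv_out_dim(W, k, s, p)
  d <- c(k, k, C, oh, ow, N)
  z <- array(0L, d)
  KI <- slice.index(z, 1L); KJ <- slice.index(z, 2L)
  CH <- slice.index(z, 3L); I <- slice.index(z, 4L)
  J <- slice.index(z, 5L); NN <- slice.index(z, 6L)
  gather <- ((I - 1L) * s + KI) +
    (((J - 1L) * s + KJ) - 1L) * Hp +
    (CH - 1L) * (Hp * Wp) +
    (NN - 1L) * (Hp * Wp * C)
  dim(gather) <- NULL
  out <- list(Hp = Hp, Wp = Wp, oh = oh, ow = ow, gather = gather)
  .nn_cache[[key]] <- out
  out
}

pad_input <- function(A, p) {
  if (p == 0L) return(A)
  d <- dim(A)
  Ap <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  Ap[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- A
  Ap
}

conv_forward_ref <- function(A, W, b, k, s, p) {
  d <- dim(A)
  ix <- conv_index_tables(d[1], d[2], d[3], d[4], k, s, p)
  Ap <- pad_input(A, p)
  Cmat <- matrix(Ap[ix$gather], nrow = k * k * d[3])
  Y <- W %*% Cmat + b
  dim(Y) <- c(nrow(W), ix$oh, ix$ow, d[4])
  aperm(Y, c(2, 3, 1, 4))
}

maxpool_forward_ref <- function(A) {
  d <- dim(A)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  out <- array(0, c(H2, W2, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (j in seq_len(W2)) for (i in seq_len(H2))
      out[i, j, c, n] <- max(A[2 * i - 1L:0, 2 * j - 1L:0, c, n])
  out
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1, beta2, eps) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
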