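# The three-conv-block binary classifier (CNN3) and its training loop.

#' Architecture settings for the three-conv-block classifier
#'
#' Three blocks of `[6x6 conv, stride 2, padding 2] -> BatchNorm -> ReLU ->
#' 2x2 max pool`, then three fully connected layers (BatchNorm + ReLU after
#' each hidden layer) ending in one sigmoid output.  Kernel 6, stride 2 and
#' padding 2 are fixed architectural constants; channel widths and FC sizes
#' are tunable.
#'
#' @param conv_channels output channels of the three conv blocks.
#' @param fc_sizes sizes of the fully connected layers; the last must be 1.
#' @return A `model_config` list (kernel = 6, stride = 2, padding = 2,
#'   pool_kernel = 2 fixed).
#' @export
model_config <- function(conv_channels = c(16L, 32L, 64L),
                         fc_sizes = c(256L, 64L, 1L)) {
  if (length(conv_channels) != 3L || any(conv_channels < 1L))
    stopf("`conv_channels` must be three positive counts")
  if (tail(fc_sizes, 1L) != 1L) stopf("the last fully connected size must be 1")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = 6L, stride = 2L, padding = 2L, pool_kernel = 2L,
                 fc_sizes = as.integer(fc_sizes)),
            class = "model_config")
}

#' Training settings
#'
#' Binary cross-entropy loss with the Adam optimizer
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`).
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size (a trailing singleton batch is dropped
#'   so batch statistics stay defined).
#' @param seed integer seed covering initialization and data order.
#' @param pos_weight weight on the positive class in the loss (1 = none).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 30L, batch_size = 32L,
                         seed = 0L, pos_weight = 1) {
  if (learning_rate <= 0) stopf("`learning_rate` must be positive")
  structure(list(learning_rate = learning_rate, beta1 = 0.9, beta2 = 0.999,
                 epsilon = 1e-8, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 pos_weight = pos_weight),
            class = "train_config")
}

#' Shapes of every stage of the classifier for a given input size
#'
#' Closed-form convolution arithmetic: each conv stage maps extent `n` to
#' `floor((n + 2*padding - kernel) / stride) + 1`, and each pool stage to
#' `floor(n / 2)`.
#'
#' @param config a [model_config()].
#' @param input_h,input_w spatial extent of the network input.
#' @return data.frame with one row per stage (stage, h, w, channels).
#' @export
model_shapes <- function(config, input_h, input_w) {
  h <- as.integer(input_h); w <- as.integer(input_w)
  rows <- list(data.frame(stage = "input", h = h, w = w, channels = 1L))
  cin <- 1L
  for (i in 1:3) {
    h <- conv_out_dim(h, config$kernel, config$stride, config$padding)
    w <- conv_out_dim(w, config$kernel, config$stride, config$padding)
    if (h < 1L || w < 1L) stopf("input too small for conv stage %d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      stage = sprintf("conv%d", i), h = h, w = w,
      channels = config$conv_channels[i])
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1L || w < 1L) stopf("input too small for pool stage %d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      stage = sprintf("pool%d", i), h = h, w = w,
      channels = config$conv_channels[i])
  }
  do.call(rbind, rows)
}

#' Build an untrained classifier
#'
#' Weights use He (fan-in) initialization; BatchNorm scales start at 1 with
#' zero shift.  The model is a pure value: training returns a new model.
#'
#' @param config a [model_config()].
#' @param input_h,input_w input dimensions; must admit the three
#'   conv+pool stages.
#' @param seed integer seed for the weight draw.
#' @return A `cnn3_model` object.
#' @export
build_model <- function(config = model_config(), input_h, input_w, seed = 0L) {
  shapes <- model_shapes(config, input_h, input_w)
  k <- config$kernel
  cc <- config$conv_channels
  flat <- with(tail(shapes, 1L), h * w * channels)
  fcs <- config$fc_sizes
  params <- list(); layers <- list(); state <- list()
  with_seed(seed, {
    cin <- 1L
    for (i in 1:3) {
      fan_in <- k * k * cin
      params[[sprintf("conv%d_W", i)]] <-
        matrix(rnorm(cc[i] * fan_in, 0, sqrt(2 / fan_in)), cc[i], fan_in)
      params[[sprintf("conv%d_b", i)]] <- numeric(cc[i])
      params[[sprintf("bn%d_gamma", i)]] <- rep(1, cc[i])
      params[[sprintf("bn%d_beta", i)]] <- numeric(cc[i])
      state[[sprintf("bn%d", i)]] <-
        list(running_mean = numeric(cc[i]), running_var = rep(1, cc[i]))
      layers[[length(layers) + 1L]] <- list(type = "conv", id = i)
      layers[[length(layers) + 1L]] <- list(type = "bn", id = i)
      layers[[length(layers) + 1L]] <- list(type = "relu", block = i)
      layers[[length(layers) + 1L]] <- list(type = "pool", block = i)
      cin <- cc[i]
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    fin <- flat
    for (j in seq_along(fcs)) {
      params[[sprintf("fc%d_W", j)]] <-
        matrix(rnorm(fcs[j] * fin, 0, sqrt(2 / fin)), fcs[j], fin)
      params[[sprintf("fc%d_b", j)]] <- numeric(fcs[j])
      layers[[length(layers) + 1L]] <- list(type = "fc", id = j)
      if (j < length(fcs)) {
        params[[sprintf("fcbn%d_gamma", j)]] <- rep(1, fcs[j])
        params[[sprintf("fcbn%d_beta", j)]] <- numeric(fcs[j])
        state[[sprintf("fcbn%d", j)]] <-
          list(running_mean = numeric(fcs[j]), running_var = rep(1, fcs[j]))
        layers[[length(layers) + 1L]] <- list(type = "fcbn", id = j)
        layers[[length(layers) + 1L]] <- list(type = "relu", block = NA)
      }
      fin <- fcs[j]
    }
  })
  structure(list(config = config, input_h = as.integer(input_h),
                 input_w = as.integer(input_w), layers = layers,
                 params = params, state = state, shapes = shapes,
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "cnn3_model")
}

#' @export
print.cnn3_model <- function(x, ...) {
  cat(sprintf("<cnn3_model %dx%d input, conv %s, fc %s, %s; %d parameters>\n",
              x$input_h, x$input_w,
              paste(x$config$conv_channels, collapse = "-"),
              paste(x$config$fc_sizes, collapse = "-"),
              if (x$trained) "trained" else "untrained",
              n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `cnn3_model`.
#' @return Integer count over all weights, biases and BatchNorm affines.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# Forward pass through the layer list.  Returns logits (1 x N), updated BN
# state, and (optionally) per-layer caches and outputs for the backward
# pass and Grad-CAM.
model_forward <- function(model, X, training = FALSE, keep_cache = FALSE,
                          stats_env = NULL) {
  p <- model$params; st <- model$state; cfg <- model$config
  caches <- if (keep_cache) vector("list", length(model$layers))
  outs <- if (keep_cache) vector("list", length(model$layers))
  A <- X
  for (li in seq_along(model$layers)) {
    lay <- model$layers[[li]]
    r <- switch(lay$type,
      conv = conv_forward(A, p[[sprintf("conv%d_W", lay$id)]],
                          p[[sprintf("conv%d_b", lay$id)]],
                          cfg$kernel, cfg$stride, cfg$padding),
      bn = {
        nm <- sprintf("bn%d", lay$id)
        rr <- bn_forward(A, p[[sprintf("bn%d_gamma", lay$id)]],
                         p[[sprintf("bn%d_beta", lay$id)]], st[[nm]],
                         training, stats_env, nm)
        st[[nm]] <- rr$state
        rr
      },
      fcbn = {
        nm <- sprintf("fcbn%d", lay$id)
        rr <- bn_forward(A, p[[sprintf("fcbn%d_gamma", lay$id)]],
                         p[[sprintf("fcbn%d_beta", lay$id)]], st[[nm]],
                         training, stats_env, nm)
        st[[nm]] <- rr$state
        rr
      },
      relu = list(out = relu_forward(A), cache = A),
      pool = maxpool_forward(A),
      flatten = flatten_forward(A),
      fc = fc_forward(A, p[[sprintf("fc%d_W", lay$id)]],
                      p[[sprintf("fc%d_b", lay$id)]]))
    if (keep_cache) {
      caches[[li]] <- r$cache
      outs[[li]] <- r$out
    }
    A <- r$out
  }
  list(logits = A, state = st, caches = caches, outs = outs)
}

# Backward pass from dLoss/dLogits.  Returns gradients named like params.
# If `stop_at_layer` is given, stops after computing the gradient flowing
# INTO that layer's output and returns it as `d_stop`.
model_backward <- function(model, fwd, dlogits, stop_at_layer = NULL) {
  grads <- list()
  dA <- dlogits
  for (li in rev(seq_along(model$layers))) {
    if (!is.null(stop_at_layer) && li == stop_at_layer)
      return(list(grads = grads, d_stop = dA))
    lay <- model$layers[[li]]
    cache <- fwd$caches[[li]]
    dA <- switch(lay$type,
      conv = {
        r <- conv_backward(dA, cache)
        grads[[sprintf("conv%d_W", lay$id)]] <- r$dW
        grads[[sprintf("conv%d_b", lay$id)]] <- r$db
        r$dA
      },
      bn = {
        r <- bn_backward(dA, cache)
        grads[[sprintf("bn%d_gamma", lay$id)]] <- r$dgamma
        grads[[sprintf("bn%d_beta", lay$id)]] <- r$dbeta
        r$dA
      },
      fcbn = {
        r <- bn_backward(dA, cache)
        grads[[sprintf("fcbn%d_gamma", lay$id)]] <- r$dgamma
        grads[[sprintf("fcbn%d_beta", lay$id)]] <- r$dbeta
        r$dA
      },
      relu = relu_backward(dA, cache),
      pool = maxpool_backward(dA, cache),
      flatten = flatten_backward(dA, cache),
      fc = {
        r <- fc_backward(dA, cache)
        grads[[sprintf("fc%d_W", lay$id)]] <- r$dW
        grads[[sprintf("fc%d_b", lay$id)]] <- r$db
        r$dA
      })
  }
  list(grads = grads, d_stop = NULL)
}

# Recompute BatchNorm running statistics exactly, by pooling batch
# statistics over forward passes on the full training set with the current
# parameters.  With only a handful of optimizer steps per epoch the
# momentum-tracked running stats lag far behind the weights, which corrupts
# inference-mode predictions; an explicit recalibration pass after each
# epoch removes that mismatch.
recalibrate_bn <- function(model, X, chunk = 128L) {
  stats <- new.env(parent = emptyenv())
  n <- dim(X)[4]
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    if (length(idx) < 2L) next
    model_forward(model, X[, , , idx, drop = FALSE], training = TRUE,
                  stats_env = stats)
  }
  for (nm in ls(stats)) {
    acc <- stats[[nm]]
    mu <- acc$sum / acc$n
    v <- pmax(acc$sumsq / acc$n - mu^2, 0)
    model$state[[nm]]$running_mean <- mu
    model$state[[nm]]$running_var <- if (acc$n > 1) v * acc$n / (acc$n - 1)
    else v
  }
  model
}

# Stack a list of side_inputs into an (H, W, 1, N) array plus labels.
side_inputs_to_array <- function(inputs) {
  if (!length(inputs)) stopf("empty input set")
  d <- dim(inputs[[1]]$pixels)
  X <- array(0, c(d[1], d[2], 1L, length(inputs)))
  for (i in seq_along(inputs)) {
    if (!identical(dim(inputs[[i]]$pixels), d))
      stopf("side inputs have inconsistent dimensions")
    X[, , 1L, i] <- inputs[[i]]$pixels
  }
  list(X = X, y = vapply(inputs, `[[`, 0L, "label"))
}

bce_loss <- function(prob, y, w_pos = 1) {
  prob <- clamp(prob, 1e-12, 1 - 1e-12)
  w <- ifelse(y == 1, w_pos, 1)
  -sum(w * (y * log(prob) + (1 - y) * log(1 - prob))) / sum(w)
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam, fully seeded (weights were
#' drawn at [build_model()]; data order comes from `config$seed`).  After
#' every epoch the BatchNorm running statistics are recalibrated exactly
#' over the training set (momentum tracking lags badly when an epoch holds
#' only a few optimizer steps), the validation loss is evaluated in
#' inference mode, and the parameters with the best validation loss are
#' retained.
#'
#' @param model an untrained (or trained) `cnn3_model`.
#' @param train_set,val_set lists of `side_input` objects; the training set
#'   must contain both classes.
#' @param config a [train_config()].
#' @return The trained `cnn3_model` with a `history` data.frame (epoch,
#'   train_loss, val_loss).
#' @export
train_model <- function(model, train_set, val_set, config = train_config()) {
  tr <- side_inputs_to_array(train_set)
  va <- side_inputs_to_array(val_set)
  if (length(unique(tr$y)) < 2L)
    stopf("training set must contain both classes")
  n <- length(tr$y)
  bs <- min(config$batch_size, n)
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, state = model$state)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        if (length(idx) < 2L) next  # drop singleton tail batch
        Xb <- tr$X[, , , idx, drop = FALSE]
        yb <- tr$y[idx]
        fwd <- model_forward(model, Xb, training = TRUE, keep_cache = TRUE)
        model$state <- fwd$state
        prob <- stats::plogis(as.numeric(fwd$logits))
        loss <- bce_loss(prob, yb, config$pos_weight)
        if (!is.finite(loss))
          stopf("non-finite training loss at epoch %d (lr too high?)", ep)
        w <- ifelse(yb == 1, config$pos_weight, 1)
        dlogits <- matrix(w * (prob - yb) / sum(w), 1L)
        bwd <- model_backward(model, fwd, dlogits)
        stepped <- adam_step(model$params, bwd$grads, opt,
                             config$learning_rate, config$beta1,
                             config$beta2, config$epsilon)
        model$params <- stepped$params
        opt <- stepped$opt
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      model <- recalibrate_bn(model, tr$X)
      vp <- predict_prob(model, va$X)
      vloss <- bce_loss(vp, va$y, config$pos_weight)
      if (!is.finite(vloss)) stopf("non-finite validation loss at epoch %d", ep)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                      val_loss = vloss))
      if (vloss < best$loss)
        best <- list(loss = vloss, params = model$params,
                      state = model$state)
    }
  })
  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Predict malignancy probabilities for side inputs
#'
#' @param model a trained `cnn3_model`.
#' @param inputs a list of `side_input`s or a prepacked (H, W, 1, N) array.
#' @param chunk evaluation batch size.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, inputs, chunk = 128L) {
  X <- if (is.array(inputs) && length(dim(inputs)) == 4L) inputs
  else side_inputs_to_array(inputs)$X
  d <- dim(X)
  if (d[1] != model$input_h || d[2] != model$input_w)
    stopf("input is %dx%d but the model expects %dx%d",
          d[1], d[2], model$input_h, model$input_w)
  n <- d[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- model_forward(model, X[, , , idx, drop = FALSE], training = FALSE)
    out[idx] <- stats::plogis(as.numeric(fwd$logits))
  }
  out
}

#' Study-level prediction: malignant if either side is suspicious
#'
#' @param model a trained `cnn3_model`.
#' @param left,right the study's two `side_input`s.
#' @return `max(p_left, p_right)`.
#' @export
predict_study <- function(model, left, right) {
  p <- predict_prob(model, list(left, right))
  max(p)
}
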