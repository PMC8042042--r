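# Closed-form conv arithmetic oracle.
conv_stage <- function(n, k = 6, s = 2, p = 2) floor((n + 2 * p - k) / s) + 1

test_that("model_shapes matches the closed-form conv arithmetic", {
  cfg <- model_config()
  for (hw in list(c(96, 96), c(77, 76), c(64, 64), c(130, 101))) {
    sh <- model_shapes(cfg, hw[1], hw[2])
    h <- hw[1]; w <- hw[2]
    for (i in 1:3) {
      h <- conv_stage(h); w <- conv_stage(w)
      expect_equal(sh$h[sh$stage == sprintf("conv%d", i)], h)
      expect_equal(sh$w[sh$stage == sprintf("conv%d", i)], w)
      h <- h %/% 2; w <- w %/% 2
      expect_equal(sh$h[sh$stage == sprintf("pool%d", i)], h)
      expect_equal(sh$w[sh$stage == sprintf("pool%d", i)], w)
    }
  }
  expect_error(model_shapes(model_config(), 16, 16), "too small")
})

test_that("parameter count equals the hand-computed layer ledger", {
  cfg <- model_config()                        # conv 16/32/64, fc 256/64/1
  m <- build_model(cfg, 77, 76, seed = 1)
  flat <- with(tail(model_shapes(cfg, 77, 76), 1), h * w * channels)
  expected <-
    (16 * 36 * 1 + 16) + (32 * 36 * 16 + 32) + (64 * 36 * 32 + 64) + # convs
    2 * (16 + 32 + 64) +                                             # conv BN
    (256 * flat + 256) + (64 * 256 + 64) + (1 * 64 + 1) +            # fcs
    2 * (256 + 64)                                                   # fc BN
  expect_equal(n_parameters(m), expected)
})

test_that("a fresh model produces finite probabilities in [0, 1]", {
  m <- build_model(model_config(), 64, 64, seed = 3)
  X <- array(0, c(64, 64, 1, 2))
  p <- predict_prob(m, X)
  expect_length(p, 2)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  expect_error(predict_prob(m, array(0, c(32, 64, 1, 1))), "expects")
})

test_that("compiled conv/pool kernels agree with the R reference", {
  set.seed(42)
  for (rep in 1:3) {
    A <- array(rnorm(20 * 18 * 3 * 2), c(20, 18, 3, 2))
    W <- matrix(rnorm(4 * 6 * 6 * 3), 4)
    b <- rnorm(4)
    ref <- crstress:::conv_forward_ref(A, W, b, 6, 2, 2)
    got <- crstress:::conv_forward(A, W, b, 6, 2, 2)$out
    expect_equal(got, ref, tolerance = 1e-12)
    P <- crstress:::maxpool_forward(ref)$out
    expect_equal(P, crstress:::maxpool_forward_ref(ref), tolerance = 1e-12)
  }
})

test_that("conv backward matches finite differences", {
  set.seed(7)
  A <- array(rnorm(12 * 10 * 2 * 2), c(12, 10, 2, 2))
  W <- matrix(rnorm(3 * 6 * 6 * 2), 3)
  b <- rnorm(3)
  R <- array(rnorm(length(crstress:::conv_forward(A, W, b, 6, 2, 2)$out)),
             dim(crstress:::conv_forward(A, W, b, 6, 2, 2)$out))
  loss <- function(Wx, Ax, bx)
    sum(crstress:::conv_forward(Ax, Wx, bx, 6, 2, 2)$out * R)
  fw <- crstress:::conv_forward(A, W, b, 6, 2, 2)
  bw <- crstress:::conv_backward(R, fw$cache)
  eps <- 1e-6
  for (idx in c(1, 17, 59)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    expect_equal(bw$dW[idx], (loss(Wp, A, b) - loss(Wm, A, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (idx in c(2, 101, 230)) {
    Ap <- A; Ap[idx] <- Ap[idx] + eps
    Am <- A; Am[idx] <- Am[idx] - eps
    expect_equal(bw$dA[idx], (loss(W, Ap, b) - loss(W, Am, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("batchnorm backward matches finite differences", {
  set.seed(8)
  X <- array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  state <- list(running_mean = numeric(3), running_var = rep(1, 3))
  R <- array(rnorm(length(X)), dim(X))
  loss <- function(Xx) {
    f <- crstress:::bn_forward(Xx, gamma, beta, state, training = TRUE)
    sum(f$out * R)
  }
  f <- crstress:::bn_forward(X, gamma, beta, state, training = TRUE)
  bw <- crstress:::bn_backward(R, f$cache)
  eps <- 1e-5
  for (idx in c(3, 200, 511)) {
    Xp <- X; Xp[idx] <- Xp[idx] + eps
    Xm <- X; Xm[idx] <- Xm[idx] - eps
    expect_equal(bw$dA[idx], (loss(Xp) - loss(Xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training reduces loss on linearly separable inputs", {
  inputs <- separable_inputs(60)
  tm <- train_model(build_model(model_config(), 64, 64, seed = 5),
                    inputs[1:48], inputs[49:60],
                    train_config(learning_rate = 1e-3, epochs = 5,
                                 batch_size = 16, seed = 5))
  expect_lt(tail(tm$history$train_loss, 1), tm$history$train_loss[1])
  expect_true(tm$trained)
  p <- predict_prob(tm, inputs[49:60])
  y <- vapply(inputs[49:60], `[[`, 0L, "label")
  expect_gte(auroc(p, y), 0.9)                 # trivially separable task
})

test_that("training is deterministic for a fixed seed", {
  inputs <- separable_inputs(30)
  run <- function() {
    tm <- train_model(build_model(model_config(), 64, 64, seed = 6),
                      inputs[1:24], inputs[25:30],
                      train_config(learning_rate = 1e-3, epochs = 3,
                                   batch_size = 8, seed = 6))
    tail(tm$history$val_loss, 1)
  }
  expect_identical(run(), run())
})

test_that("training rejects degenerate inputs", {
  inputs <- separable_inputs(20)
  ones <- Filter(function(x) x$label == 1L, inputs)
  expect_error(
    train_model(build_model(model_config(), 64, 64, seed = 1),
                ones, inputs[1:4], train_config(epochs = 1)),
    "both classes")
})

test_that("permuted labels give chance-level validation AUROC", {
  labels <- crstress:::with_seed(123, sample(rep(0:1, each = 100)))
  inputs <- noise_inputs(labels)
  tm <- train_model(build_model(model_config(), 64, 64, seed = 9),
                    inputs[1:160], inputs[161:200],
                    train_config(learning_rate = 1e-3, epochs = 3,
                                 batch_size = 32, seed = 9))
  p <- predict_prob(tm, inputs[161:200])
  y <- labels[161:200]
  a <- auroc(p, y)
  expect_gte(a, 0.35)
  expect_lte(a, 0.65)
})

test_that("predict_study takes the maximum over sides", {
  inputs <- separable_inputs(10)
  tm <- train_model(build_model(model_config(), 64, 64, seed = 2),
                    inputs[1:8], inputs[9:10],
                    train_config(epochs = 1, batch_size = 4, seed = 2))
  p <- predict_prob(tm, inputs[1:2])
  expect_equal(predict_study(tm, inputs[[1]], inputs[[2]]), max(p))
})
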