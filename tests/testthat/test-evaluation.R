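test_that("auroc handles the canonical cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)  # all tied
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
  expect_error(auroc(1:3, c(1, 0)), "length")
})

test_that("auroc equals exhaustive concordant-pair counting", {
  pair_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  for (seed in 1:6) {
    set.seed(seed)
    s <- round(runif(12), 1)                   # rounding forces ties
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auroc(s, y), pair_oracle(s, y))
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(11)
  s <- runif(30); y <- rbinom(30, 1, 0.4); y[1:2] <- c(0, 1)
  base <- auroc(s, y)
  expect_equal(auroc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y), base)
  expect_equal(auroc(100 * s + 3, y), base)
  expect_equal(auroc(s^3, y), base)
})

test_that("auprc handles the canonical cases", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # constant scores: AP equals prevalence
  expect_equal(auprc(rep(0.5, 10), c(rep(1, 2), rep(0, 8))), 0.2)
  expect_error(auprc(1:3, c(0, 0, 0)), "no positive")
})

test_that("auprc matches a hand-stepped precision-recall walk", {
  step_oracle <- function(s, y) {
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; y <- y[ord]
    ap <- 0; prev_rec <- 0; P <- sum(y)
    for (thr in unique(s)) {
      sel <- s >= thr
      rec <- sum(y[sel]) / P
      prec <- sum(y[sel]) / sum(sel)
      ap <- ap + (rec - prev_rec) * prec
      prev_rec <- rec
    }
    ap
  }
  for (seed in 1:6) {
    set.seed(seed)
    s <- round(runif(12), 1)
    y <- rbinom(12, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(auprc(s, y), step_oracle(s, y))
  }
})

test_that("auroc/auprc agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- runif(40); y <- rbinom(40, 1, 0.3); y[1:2] <- c(0, 1)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  expect_equal(auroc(s, y), ref, tolerance = 1e-12)
})

test_that("make_folds partitions subjects with the 7:1:2 layout", {
  ids <- sprintf("S%03d", 1:100)
  split <- make_folds(ids, k = 5, ratio = c(7, 1, 2), seed = 4)
  expect_equal(split$k, 5L)
  tests <- unlist(lapply(split$folds, `[[`, "test"))
  expect_setequal(tests, ids)                  # test sets partition subjects
  expect_equal(anyDuplicated(tests), 0L)
  for (f in split$folds) {
    expect_equal(sort(c(f$train, f$val, f$test)), sort(ids))
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_equal(length(f$test), 20)
    expect_equal(length(f$train), 70)          # 80 * 7/8
    expect_equal(length(f$val), 10)
  }
  expect_error(make_folds(ids[1:5], k = 5), "too few")
})

test_that("fold-metric aggregation matches hand arithmetic", {
  pf <- data.frame(fold = 1:5, test_cr = 1,
                   auroc = c(0.86, 0.87, 0.88, 0.86, 0.88),
                   auprc = c(0.70, 0.72, 0.74, 0.71, 0.73))
  cell <- crstress:::new_eval_cell(1, 1, pf, diagonal = TRUE)
  expect_equal(cell$auroc_mean, 0.87)
  expect_equal(cell$auroc_sd, sd(c(0.86, 0.87, 0.88, 0.86, 0.88)))
  half <- 1.96 * cell$auroc_sd / sqrt(5)
  expect_equal(cell$auroc_ci_low, 0.87 - half)
  expect_equal(cell$auroc_ci_high, 0.87 + half)
  expect_true(cell$auroc_ci_low <= cell$auroc_mean &&
                cell$auroc_mean <= cell$auroc_ci_high)

  # degenerate: identical folds collapse the CI onto the mean
  pf0 <- data.frame(fold = 1:5, test_cr = 1, auroc = rep(0.9, 5),
                    auprc = rep(0.5, 5))
  cell0 <- crstress:::new_eval_cell(1, 1, pf0)
  expect_equal(cell0$auroc_sd, 0)
  expect_equal(cell0$auroc_ci_low, cell0$auroc_mean)
  expect_equal(cell0$auroc_ci_high, cell0$auroc_mean)
})

test_that("augment_with_crs unions materialized CRs multiplicatively", {
  co <- generate_cohort(31, 10, c(0.3, 0.3, 0.4), 64, 80)
  ds1 <- make_side_dataset(co$studies, 1, factor = 1)
  datasets <- list("1" = ds1)
  expect_identical(augment_with_crs(datasets, 1), ds1$inputs)  # identity
  datasets[["2"]] <- ds1                        # stand-in second CR
  both <- augment_with_crs(datasets, c(1, 2))
  expect_length(both, 2 * length(ds1$inputs))
  sub <- augment_with_crs(datasets, c(1, 2), subjects = c("S00001", "S00002"))
  expect_length(sub, 2 * 2 * 2)
  expect_error(augment_with_crs(datasets, numeric(0)), "empty")
  expect_error(augment_with_crs(datasets, 99), "no materialized")
})

test_that("roc/pr curve points are consistent with the areas", {
  set.seed(33)
  s <- runif(25); y <- rbinom(25, 1, 0.4); y[1:2] <- c(0, 1)
  rp <- roc_points(s, y)
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(tail(rp$fpr, 1), 1); expect_equal(tail(rp$tpr, 1), 1)
  trap <- sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2)
  expect_equal(trap, auroc(s, y), tolerance = 1e-12)
  pp <- pr_points(s, y)
  ap <- sum(diff(c(0, pp$recall)) * pp$precision)
  expect_equal(ap, auprc(s, y), tolerance = 1e-12)
})

test_that("cross-validation wiring keeps subjects apart and is deterministic", {
  co <- generate_cohort(41, 24, c(0.35, 0.25, 0.40), 64, 80, 0.9)
  datasets <- list("1" = make_side_dataset(co$studies, 1, factor = 1))
  split <- make_folds(vapply(co$studies, `[[`, "", "subject_id"),
                      k = 3, seed = 1)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 11)
  mcfg <- model_config(conv_channels = c(4L, 8L, 8L),
                       fc_sizes = c(16L, 8L, 1L))
  cells <- crossval(datasets, 1, 1, mcfg, cfg, split)
  expect_length(cells, 1)
  cell <- cells[[1]]
  expect_true(cell$diagonal)
  expect_equal(nrow(cell$per_fold), 3)
  expect_true(all(is.finite(cell$per_fold$auroc)))
  preds <- attr(cells, "predictions")
  # predictions are study-level: one row per test subject per fold
  expect_equal(nrow(preds), 24)
  expect_equal(anyDuplicated(preds$subject_id), 0L)
  # determinism
  cells2 <- crossval(datasets, 1, 1, mcfg, cfg, split)
  expect_identical(cells[[1]]$per_fold, cells2[[1]]$per_fold)
})
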