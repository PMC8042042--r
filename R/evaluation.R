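# ROC/PR metrics with fold-level confidence intervals, subject-level
# k-fold cross-validation, the train-CR x test-CR matrix, and mixed-CR
# augmentation.

#' Area under the ROC curve
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties counted half (the rank/Mann-Whitney formulation,
#' identical to trapezoidal ROC integration).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision style) integration: at each distinct score
#' threshold, precision is accumulated against the recall increment.  No
#' precision envelope is applied; tied scores are processed as one block.
#' Uninformative constant scores yield the prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L) stopf("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # block ends: last index of each run of tied scores
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]
  fp <- ends - tp
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Subject-level cross-validation folds with train/validation/test roles
#'
#' The k folds partition the subjects into test sets; within each fold the
#' remaining subjects are split train:validation by the first two
#' components of `ratio` (default 7:1, giving the overall 7:1:2 layout for
#' k = 5).  Both breasts of a subject always share a partition because the
#' split is at subject level.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param k number of folds (default 5).
#' @param ratio (train, validation, test) proportions; test is implied by
#'   1/k and the first two set the train:validation split of the rest.
#' @param seed integer seed for the subject shuffle.
#' @return A `fold_split` object: list of k folds, each with `train`,
#'   `val`, `test` id vectors.
#' @export
make_folds <- function(subject_ids, k = 5L, ratio = c(7, 1, 2), seed = 0L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < 2L * k) stopf("too few subjects for %d folds", k)
  if (length(ratio) != 3L || any(ratio <= 0)) stopf("`ratio` must be 3 positive numbers")
  shuffled <- with_seed(seed, sample(subject_ids))
  fold_of <- rep_len(seq_len(k), length(shuffled))
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[fold_of == f]
    rest <- shuffled[fold_of != f]
    n_tr <- round(length(rest) * ratio[1] / (ratio[1] + ratio[2]))
    list(train = rest[seq_len(n_tr)],
         val = rest[-seq_len(n_tr)],
         test = test)
  })
  structure(list(k = as.integer(k), ratio = ratio, seed = as.integer(seed),
                 folds = folds),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split k=%d, ratio %s, %d subjects>\n", x$k,
              paste(x$ratio, collapse = ":"),
              length(unlist(lapply(x$folds[[1]], identity)))))
  invisible(x)
}

# A side_dataset packs every side input of a cohort materialized at one CR.
new_side_dataset <- function(inputs, cr) {
  structure(list(inputs = inputs,
                 subject = vapply(inputs, `[[`, "", "subject_id"),
                 label = vapply(inputs, `[[`, 0L, "label"),
                 cr = cr),
            class = "side_dataset")
}

#' Materialize a cohort of studies as side inputs at one compression ratio
#'
#' Compresses every view to `cr` (identity at CR 1), then runs the
#' preprocessing pipeline.
#'
#' @param studies list of [study_record()]s.
#' @param cr target compression ratio.
#' @param factor resize factor.
#' @param codec_config a [rate_control_config()].
#' @return A `side_dataset` (inputs, subject, label, cr).
#' @export
make_side_dataset <- function(studies, cr, factor = 0.3,
                              codec_config = rate_control_config()) {
  compressed <- compress_studies(studies, cr, codec_config)
  inputs <- list()
  for (i in seq_along(compressed)) {
    pp <- preprocess_study(compressed[[i]], factor = factor, source_cr = cr)
    inputs[[length(inputs) + 1L]] <- pp$left
    inputs[[length(inputs) + 1L]] <- pp$right
    compressed[i] <- list(NULL)   # release the decoded views as we go
  }
  ds <- new_side_dataset(inputs, cr)
  attr(ds, "achieved_cr") <- attr(compressed, "achieved_cr") %||% cr
  attr(ds, "psnr_db") <- attr(compressed, "psnr_db") %||% 100
  ds
}

#' Materialize a cohort at several compression ratios
#'
#' Runs [make_side_dataset()] for each CR and returns the datasets keyed
#' by `format(cr)` — the layout [crossval()] and [build_cr_matrix()]
#' expect.
#'
#' @inheritParams make_side_dataset
#' @param crs compression ratios to materialize.
#' @return Named list of `side_dataset`s.
#' @export
materialize_datasets <- function(studies, crs, factor = 0.3,
                                 codec_config = rate_control_config()) {
  out <- list()
  for (cr in crs)
    out[[format(cr)]] <- make_side_dataset(studies, cr, factor, codec_config)
  out
}

dataset_for <- function(datasets, cr) {
  ds <- datasets[[format(cr)]]
  if (is.null(ds)) stopf("no materialized dataset for CR %s", format(cr))
  ds
}

subset_inputs <- function(dataset, subjects) {
  dataset$inputs[dataset$subject %in% subjects]
}

# Study-level scores on one fold's test subjects: max over the two sides.
study_scores <- function(model, dataset, subjects) {
  inputs <- subset_inputs(dataset, subjects)
  probs <- predict_prob(model, inputs)
  ids <- vapply(inputs, `[[`, "", "subject_id")
  labs <- vapply(inputs, `[[`, 0L, "label")
  agg <- tapply(probs, ids, max)
  lab <- tapply(labs, ids, max)
  list(scores = as.numeric(agg), labels = as.integer(lab),
       subject = names(agg))
}

summarize_fold_metrics <- function(vals) {
  k <- length(vals)
  m <- mean(vals); s <- if (k > 1) stats::sd(vals) else 0
  half <- 1.96 * s / sqrt(k)
  c(mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

new_eval_cell <- function(train_cr, test_cr, per_fold, diagonal = FALSE) {
  a <- summarize_fold_metrics(per_fold$auroc)
  p <- summarize_fold_metrics(per_fold$auprc)
  structure(list(train_cr = train_cr, test_cr = test_cr,
                 per_fold = per_fold, diagonal = diagonal,
                 auroc_mean = a[["mean"]], auroc_sd = a[["sd"]],
                 auroc_ci_low = a[["ci_low"]], auroc_ci_high = a[["ci_high"]],
                 auprc_mean = p[["mean"]], auprc_sd = p[["sd"]],
                 auprc_ci_low = p[["ci_low"]], auprc_ci_high = p[["ci_high"]]),
            class = "eval_cell")
}

#' @export
print.eval_cell <- function(x, ...) {
  cat(sprintf(
    "<eval_cell train CR %.6g / test CR %.6g: AUROC %.3f (%.3f, %.3f), AUPRC %.3f (%.3f, %.3f)>\n",
    x$train_cr, x$test_cr, x$auroc_mean, x$auroc_ci_low, x$auroc_ci_high,
    x$auprc_mean, x$auprc_ci_low, x$auprc_ci_high))
  invisible(x)
}

#' @export
as.data.frame.eval_cell <- function(x, ...) {
  data.frame(train_cr = x$train_cr, test_cr = x$test_cr,
             diagonal = x$diagonal,
             auroc_mean = x$auroc_mean, auroc_sd = x$auroc_sd,
             auroc_ci_low = x$auroc_ci_low, auroc_ci_high = x$auroc_ci_high,
             auprc_mean = x$auprc_mean, auprc_sd = x$auprc_sd,
             auprc_ci_low = x$auprc_ci_low, auprc_ci_high = x$auprc_ci_high)
}

cells_to_table <- function(cells) {
  do.call(rbind, lapply(cells, as.data.frame))
}

#' Cross-validated evaluation of models trained at one (or a mix of) CRs
#'
#' Per fold, a fresh model is trained on the fold's training subjects
#' materialized at `train_crs` (a single CR, or several for
#' compression-based augmentation), validated at the first CR of
#' `train_crs`, and evaluated on the fold's test subjects at every CR in
#' `test_crs` with the study-level max-over-sides rule.  Fold metrics are
#' aggregated as mean, sd, and 95% CI = mean +/- 1.96 sd / sqrt(k).  A fold
#' whose test set is single-class is skipped with a warning (k reduced).
#'
#' @param datasets named list of `side_dataset`s keyed by `format(cr)`,
#'   from [materialize_datasets()], covering all train and test CRs.
#' @param train_crs CR(s) the training set is drawn at.
#' @param test_crs CRs to evaluate on.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; fold f trains with seed
#'   `train_cfg$seed + 1000 * f`.
#' @param split a [make_folds()] split.
#' @param keep_models return the per-fold trained models (memory-heavy).
#' @return List of `eval_cell`s, one per test CR; if `keep_models`, the
#'   models are attached as `attr(, "models")`.
#' @export
crossval <- function(datasets, train_crs, test_crs, model_cfg = model_config(),
                     train_cfg = train_config(), split, keep_models = FALSE) {
  stopifnot(inherits(split, "fold_split"))
  d1 <- dim(dataset_for(datasets, train_crs[1])$inputs[[1]]$pixels)
  models <- list()
  fold_rows <- list()
  pred_rows <- list()
  for (f in seq_len(split$k)) {
    fold <- split$folds[[f]]
    train_inputs <- list()
    for (cr in train_crs)
      train_inputs <- c(train_inputs,
                        subset_inputs(dataset_for(datasets, cr), fold$train))
    val_inputs <- subset_inputs(dataset_for(datasets, train_crs[1]), fold$val)
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + 1000L * f
    model <- build_model(model_cfg, d1[1], d1[2], seed = cfg_f$seed)
    model <- train_model(model, train_inputs, val_inputs, cfg_f)
    if (keep_models) models[[f]] <- model
    for (cr in test_crs) {
      sc <- study_scores(model, dataset_for(datasets, cr), fold$test)
      if (length(unique(sc$labels)) < 2L) {
        warning(sprintf("fold %d has a single-class test set; skipped", f))
        next
      }
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = f, test_cr = cr, auroc = auroc(sc$scores, sc$labels),
        auprc = auprc(sc$scores, sc$labels))
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        fold = f, test_cr = cr, subject_id = sc$subject,
        score = sc$scores, label = sc$labels)
    }
  }
  per <- do.call(rbind, fold_rows)
  train_tag <- if (length(train_crs) == 1L) train_crs else min(train_crs)
  cells <- lapply(test_crs, function(cr) {
    new_eval_cell(train_tag, cr, per[per$test_cr == cr, , drop = FALSE],
                  diagonal = length(train_crs) == 1L &&
                    isTRUE(all.equal(train_crs[1], cr)))
  })
  attr(cells, "train_crs") <- train_crs
  attr(cells, "predictions") <- do.call(rbind, pred_rows)
  if (keep_models) attr(cells, "models") <- models
  cells
}

#' ROC curve points from pooled predictions
#'
#' @inheritParams auroc
#' @return data.frame (threshold, fpr, tpr) over the distinct score
#'   thresholds, from (1, 1) down to (0, 0).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]; fp <- ends - tp
  data.frame(threshold = c(Inf, s[ends]),
             fpr = c(0, fp / sum(y == 0L)),
             tpr = c(0, tp / sum(y == 1L)))
}

#' Precision-recall curve points from pooled predictions
#'
#' @inheritParams auroc
#' @return data.frame (threshold, recall, precision) over the distinct
#'   score thresholds.
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]; fp <- ends - tp
  data.frame(threshold = s[ends], recall = tp / sum(y == 1L),
             precision = tp / (tp + fp))
}

#' Expand a training set with compressed copies of every study
#'
#' Compression-based data augmentation: the training set becomes the union
#' over `cr_list` of each study's side inputs materialized at that CR.
#' Validation and test sets are untouched by design.
#'
#' @param datasets named list of `side_dataset`s keyed by `format(cr)`.
#' @param cr_list CRs to pool (non-empty; all must be materialized).
#' @param subjects optional subject filter.
#' @return A list of `side_input`s of size
#'   `(number of sides) * length(cr_list)`.
#' @export
augment_with_crs <- function(datasets, cr_list, subjects = NULL) {
  if (!length(cr_list)) stopf("`cr_list` must not be empty")
  out <- list()
  for (cr in cr_list) {
    ds <- dataset_for(datasets, cr)
    out <- c(out, if (is.null(subjects)) ds$inputs
             else subset_inputs(ds, subjects))
  }
  out
}

#' Full train-CR x test-CR evaluation matrix
#'
#' Trains one model per (train CR, fold) and evaluates it at every test CR,
#' filling the full ordered-pair matrix (diagonal cells are the
#' single-CR experiment and are flagged).
#'
#' @inheritParams crossval
#' @param cr_grid ordered CR grid; every pair is evaluated once.
#' @return A `cr_matrix`: list with `cr_grid`, `cells` (list) and `table`
#'   (tidy data.frame).
#' @export
build_cr_matrix <- function(datasets, cr_grid, model_cfg = model_config(),
                            train_cfg = train_config(), split) {
  cells <- list()
  for (tcr in cr_grid) {
    row_cells <- crossval(datasets, tcr, cr_grid, model_cfg, train_cfg, split)
    cells <- c(cells, row_cells)
  }
  structure(list(cr_grid = cr_grid, cells = cells,
                 table = cells_to_table(cells)),
            class = "cr_matrix")
}

#' @export
print.cr_matrix <- function(x, ...) {
  cat(sprintf("<cr_matrix over CRs {%s}: %d cells>\n",
              paste(format(x$cr_grid), collapse = ", "), length(x$cells)))
  m <- matrix(x$table$auroc_mean, nrow = length(x$cr_grid), byrow = TRUE,
              dimnames = list(train = format(x$cr_grid),
                              test = format(x$cr_grid)))
  print(round(m, 3))
  invisible(x)
}
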