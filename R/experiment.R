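# End-to-end orchestration of the two experiments: (1) single-CR
# train/test performance across the CR grid, and (2) the cross-CR matrix
# plus compression-based data augmentation.

#' The full clinical-scale CR grid
#'
#' The eleven compression-ratio conditions of the clinical experiment:
#' uncompressed (CR 1), the radiological-society recommendations 15/20/25,
#' and the extreme ratios 50, 100, 500, 1K, 5K, 10K and 11K.
#'
#' @return Numeric vector of length 11.
#' @export
paper_cr_grid <- function() {
  c(1, 15, 20, 25, 50, 100, 500, 1000, 5000, 10000, 11000)
}

#' Desk-scale CR grid for a given image size
#'
#' Small synthetic images cannot reach the clinical extremes (the
#' codestream size floors at the codec overhead), so the desk grid keeps
#' the low-CR conditions and substitutes the two largest reachable values:
#' roughly 40% and 80% of the saturation CR measured on a textured probe
#' image of the requested size.
#'
#' @param width,height view dimensions the grid must be reachable for.
#' @param probe_seed seed for the probe study.
#' @return Sorted numeric grid starting at 1; the extreme pair is recorded
#'   in `attr(, "extremes")`.
#' @export
desk_cr_grid <- function(width = 256L, height = 320L, probe_seed = 99L) {
  probe <- generate_study(probe_seed, "normal", width = width,
                          height = height)$views$LCC
  sat <- max_reachable_cr(probe)
  ext <- signif(c(0.4, 0.8) * sat, 2)
  grid <- sort(unique(c(1, 15, 50, 100, ext)))
  attr(grid, "extremes") <- ext
  attr(grid, "saturation_cr") <- sat
  grid
}

#' Assemble an experiment configuration
#'
#' Bundles every constant the two experiments need.  `cr_grid = NULL`
#' resolves to [desk_cr_grid()] for the configured image size at run time;
#' `paper_cr_grid()` gives the clinical eleven-condition grid.
#'
#' @param cr_grid CR conditions (sorted, unique, all >= 1) or `NULL`.
#' @param n_subjects cohort size for the synthetic generator.
#' @param width,height,separability,class_weights generator settings, see
#'   [generate_cohort()].
#' @param k_folds,split_ratio cross-validation layout, see [make_folds()].
#' @param resize_factor preprocessing resize factor.
#' @param seed master seed: cohort, folds and per-fold training seeds all
#'   derive from it.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param codec a [rate_control_config()].
#' @param aug_prefixes list of CR subsets for the augmentation experiment;
#'   `NULL` means the nested prefixes of the grid.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cr_grid = NULL, n_subjects = 400L,
                              width = 256L, height = 320L,
                              separability = 0.8,
                              class_weights = default_class_weights(),
                              k_folds = 5L, split_ratio = c(7, 1, 2),
                              resize_factor = 0.3, seed = 0L,
                              model = model_config(),
                              train = train_config(),
                              codec = rate_control_config(),
                              aug_prefixes = NULL) {
  if (!is.null(cr_grid)) {
    if (is.unsorted(cr_grid, strictly = TRUE) || any(cr_grid < 1))
      stopf("`cr_grid` must be strictly increasing with all values >= 1")
  }
  if (resize_factor <= 0 || resize_factor > 1)
    stopf("`resize_factor` must lie in (0, 1]")
  structure(list(cr_grid = cr_grid, n_subjects = as.integer(n_subjects),
                 width = as.integer(width), height = as.integer(height),
                 separability = separability, class_weights = class_weights,
                 k_folds = as.integer(k_folds), split_ratio = split_ratio,
                 resize_factor = resize_factor, seed = as.integer(seed),
                 model = model, train = train, codec = codec,
                 aug_prefixes = aug_prefixes),
            class = "experiment_config")
}

resolve_grid <- function(config) {
  config$cr_grid %||% desk_cr_grid(config$width, config$height,
                                   probe_seed = config$seed + 99L)
}

# Shared setup: cohort, folds, and materialized datasets for `crs`.
experiment_setup <- function(config, crs) {
  cohort <- generate_cohort(config$seed + 1L, config$n_subjects,
                            config$class_weights, config$width,
                            config$height, config$separability)
  split <- make_folds(vapply(cohort$studies, `[[`, "", "subject_id"),
                      k = config$k_folds, ratio = config$split_ratio,
                      seed = config$seed + 2L)
  datasets <- materialize_datasets(cohort$studies, crs,
                                   config$resize_factor, config$codec)
  list(cohort = cohort, split = split, datasets = datasets)
}

write_provenance <- function(config, grid, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(
    package_version = as.character(utils::packageVersion("crstress")),
    resolved_cr_grid = as.numeric(grid),
    seed = config$seed,
    n_subjects = config$n_subjects,
    width = config$width, height = config$height,
    separability = config$separability,
    class_weights = as.numeric(config$class_weights),
    k_folds = config$k_folds, split_ratio = config$split_ratio,
    resize_factor = config$resize_factor,
    model = unclass(config$model), train = unclass(config$train),
    codec = unclass(config$codec))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Experiment 1: single-CR train/test performance across the grid
#'
#' For each CR in the grid: compress the cohort, preprocess, run k-fold
#' cross-validation training and testing at that CR, and collect the
#' AUROC/AUPRC cell.  Optionally writes tidy CSVs (aggregate metrics,
#' per-fold metrics, pooled ROC/PR curve points) and a provenance file.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @param keep_models keep the per-fold trained models of every CR (for
#'   saliency follow-up; memory-heavy).
#' @return List with `table` (one row per CR), `cells`, `split`,
#'   `datasets`, `cohort`, and `models` when requested.
#' @export
run_experiment_1 <- function(config = experiment_config(), out_dir = NULL,
                             keep_models = FALSE) {
  grid <- resolve_grid(config)
  setup <- experiment_setup(config, grid)
  cells <- list(); models <- list(); preds <- list()
  for (cr in grid) {
    cc <- crossval(setup$datasets, cr, cr, config$model, config$train,
                   setup$split, keep_models = keep_models)
    cells[[format(cr)]] <- cc[[1]]
    if (keep_models) models[[format(cr)]] <- attr(cc, "models")
    preds[[format(cr)]] <- attr(cc, "predictions")
  }
  tab <- cells_to_table(cells)
  if (!is.null(out_dir)) {
    write_provenance(config, grid, out_dir)
    utils::write.csv(tab, file.path(out_dir, "experiment1_metrics.csv"),
                     row.names = FALSE)
    perfold <- do.call(rbind, lapply(cells, function(cl) {
      pf <- cl$per_fold
      pf$train_cr <- cl$train_cr
      pf
    }))
    utils::write.csv(perfold,
                     file.path(out_dir, "experiment1_fold_metrics.csv"),
                     row.names = FALSE)
    curves <- list()
    for (cr in names(preds)) {
      p <- preds[[cr]]
      if (is.null(p)) next
      rp <- roc_points(p$score, p$label); rp$kind <- "roc"; rp$cr <- cr
      pp <- pr_points(p$score, p$label); pp$kind <- "pr"; pp$cr <- cr
      names(rp)[2:3] <- c("x", "y"); names(pp)[2:3] <- c("x", "y")
      curves[[length(curves) + 1L]] <- rbind(rp, pp)
    }
    if (length(curves))
      utils::write.csv(do.call(rbind, curves),
                       file.path(out_dir, "experiment1_curves.csv"),
                       row.names = FALSE)
  }
  out <- list(table = tab, cells = cells, split = setup$split,
              datasets = setup$datasets, cohort = setup$cohort,
              cr_grid = grid)
  if (keep_models) out$models <- models
  out
}

#' Experiment 2: cross-CR matrix and compression-based augmentation
#'
#' Builds the full train-CR x test-CR matrix, then trains augmentation
#' models on nested CR mixtures (CR 1 alone, CR 1 + next, ..., the whole
#' grid) and evaluates each on every single CR.
#'
#' @inheritParams run_experiment_1
#' @return List with `matrix` (a `cr_matrix`), `augmentation` (tidy
#'   data.frame: aug_max_cr, test_cr, metrics), `split`, `datasets`,
#'   `cohort`.
#' @export
run_experiment_2 <- function(config = experiment_config(), out_dir = NULL) {
  grid <- resolve_grid(config)
  setup <- experiment_setup(config, grid)
  mat <- build_cr_matrix(setup$datasets, grid, config$model, config$train,
                         setup$split)
  prefixes <- config$aug_prefixes %||%
    lapply(seq_along(grid), function(m) grid[seq_len(m)])
  aug_rows <- list()
  for (pre in prefixes) {
    cc <- crossval(setup$datasets, pre, grid, config$model, config$train,
                   setup$split)
    tab <- cells_to_table(cc)
    tab$aug_max_cr <- max(pre)
    tab$aug_n_crs <- length(pre)
    aug_rows[[length(aug_rows) + 1L]] <- tab
  }
  aug <- do.call(rbind, aug_rows)
  if (!is.null(out_dir)) {
    write_provenance(config, grid, out_dir)
    utils::write.csv(mat$table, file.path(out_dir, "experiment2_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(aug, file.path(out_dir, "experiment2_augmentation.csv"),
                     row.names = FALSE)
  }
  list(matrix = mat, augmentation = aug, split = setup$split,
       datasets = setup$datasets, cohort = setup$cohort, cr_grid = grid)
}
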