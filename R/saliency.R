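# Grad-CAM saliency maps for trained models, and a quantitative
# lesion-encapsulation score.

#' Grad-CAM saliency map for one side input
#'
#' Channel weights are the spatial mean of the gradient of the predicted
#' probability with respect to the chosen conv block's (post-ReLU)
#' activations; the map is the ReLU of the weighted activation sum,
#' bilinearly upsampled to the input size and normalized to a maximum of 1
#' (unless identically zero).
#'
#' @param model a trained `cnn3_model`.
#' @param input a `side_input` preprocessed like the training data.
#' @param layer_index which conv block to attribute (1-3; default the
#'   last).
#' @return A `saliency_result`: `heatmap` (matrix in `[0,1]` congruent to
#'   the input), `predicted_prob`, and — when the input carries a non-empty
#'   lesion mask — `encapsulation` and `hit` at the default 0.8 quantile.
#' @export
grad_cam <- function(model, input, layer_index = 3L) {
  if (!inherits(model, "cnn3_model") || !model$trained)
    stopf("`model` must be a trained cnn3_model")
  if (!layer_index %in% 1:3) stopf("`layer_index` must be 1, 2 or 3")
  layer_index <- as.integer(layer_index)
  relu_li <- which(vapply(model$layers, function(l)
    l$type == "relu" && isTRUE(l$block == layer_index), TRUE))
  X <- array(input$pixels, c(dim(input$pixels), 1L, 1L))
  fwd <- model_forward(model, X, training = FALSE, keep_cache = TRUE)
  prob <- stats::plogis(as.numeric(fwd$logits))
  # d prob / d logit = p (1 - p); backprop that to the target activations
  dlogits <- matrix(prob * (1 - prob), 1L, 1L)
  bwd <- model_backward(model, fwd, dlogits, stop_at_layer = relu_li)
  acts <- fwd$outs[[relu_li]]            # (h, w, C, 1)
  grads <- bwd$d_stop
  C <- dim(acts)[3]
  w <- vapply(seq_len(C), function(c) mean(grads[, , c, 1]), 1)
  cam <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (c in seq_len(C)) cam <- cam + w[c] * acts[, , c, 1]
  cam <- pmax(cam, 0)
  heat <- resize_bilinear(cam, nrow(input$pixels), ncol(input$pixels))
  heat <- pmax(heat, 0)
  if (max(heat) > 0) heat <- heat / max(heat)
  enc <- NA_real_; hit <- NA
  if (!is.null(input$mask) && any(input$mask)) {
    es <- encapsulation_score(heat, input$mask)
    enc <- es$encapsulation; hit <- es$hit
  }
  structure(list(heatmap = heat, predicted_prob = prob,
                 encapsulation = enc, hit = hit,
                 layer_index = as.integer(layer_index)),
            class = "saliency_result")
}

#' @export
print.saliency_result <- function(x, ...) {
  cat(sprintf("<saliency_result %dx%d, prob %.3f, encapsulation %s>\n",
              nrow(x$heatmap), ncol(x$heatmap), x$predicted_prob,
              if (is.na(x$encapsulation)) "n/a"
              else sprintf("%.3f", x$encapsulation)))
  invisible(x)
}

#' Fraction of the lesion covered by the salient region
#'
#' The heatmap is binarized at its own `quantile` (pixels strictly above
#' the threshold are salient); encapsulation is
#' `|salient AND mask| / |mask|` and `hit` records any overlap at all.
#'
#' @param heatmap matrix in `[0, 1]`.
#' @param mask non-empty logical matrix (or [lesion_mask()]) congruent to
#'   the heatmap.
#' @param quantile binarization quantile in (0, 1); default 0.8, i.e. the
#'   top fifth of heatmap values counts as salient.
#' @return List with `encapsulation` in `[0, 1]` and logical `hit`.
#' @export
encapsulation_score <- function(heatmap, mask, quantile = 0.8) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  if (quantile <= 0 || quantile >= 1) stopf("`quantile` must lie in (0, 1)")
  if (!identical(dim(heatmap), dim(mask)))
    stopf("heatmap and mask dimensions differ")
  mask <- mask > 0
  if (!any(mask)) stopf("mask is empty")
  thr <- stats::quantile(heatmap, quantile, names = FALSE)
  salient <- heatmap > thr
  enc <- sum(salient & mask) / sum(mask)
  list(encapsulation = enc, hit = enc > 0)
}

#' Median lesion encapsulation over correctly classified malignant studies
#'
#' For every malignant study correctly flagged by the model (study-level
#' probability above `prob_threshold`), computes the Grad-CAM
#' encapsulation on its most suspicious side and returns the cohort
#' median.  This turns the visual "does the saliency map cover the
#' radiologist's annotation" reading into a number.
#'
#' @param model a trained `cnn3_model`.
#' @param dataset a `side_dataset` (from [make_side_dataset()]) carrying
#'   masks.
#' @param subjects subject ids to score (e.g. a fold's test set).
#' @param prob_threshold classification cut-off (default 0.5).
#' @param quantile binarization quantile passed to [encapsulation_score()].
#' @param layer_index conv block for [grad_cam()].
#' @return List with `median_encapsulation`, `n_scored`, and the per-study
#'   data.frame `details`.
#' @export
saliency_encapsulation <- function(model, dataset, subjects,
                                   prob_threshold = 0.5, quantile = 0.8,
                                   layer_index = 3L) {
  rows <- list()
  for (sid in unique(subjects)) {
    inputs <- subset_inputs(dataset, sid)
    if (!length(inputs) || inputs[[1]]$label != 1L) next
    masked <- Filter(function(x) !is.null(x$mask) && any(x$mask), inputs)
    if (!length(masked)) next
    probs <- predict_prob(model, inputs)
    if (max(probs) <= prob_threshold) next  # missed malignancy: no map scored
    pm <- predict_prob(model, masked)
    best <- masked[[which.max(pm)]]
    sr <- grad_cam(model, best, layer_index)
    es <- encapsulation_score(sr$heatmap, best$mask, quantile)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid, side = best$side, prob = max(probs),
      encapsulation = es$encapsulation, hit = es$hit)
  }
  details <- if (length(rows)) do.call(rbind, rows)
  else data.frame(subject_id = character(), side = character(),
                  prob = numeric(), encapsulation = numeric(),
                  hit = logical())
  list(median_encapsulation = if (nrow(details))
    stats::median(details$encapsulation)
       else NA_real_,
       n_scored = nrow(details), details = details)
}
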