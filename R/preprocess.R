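# View preprocessing: resize -> crop -> paired-view concatenation, turning
# a four-view study into two side-level network inputs.
#
# Coordinate convention: row 1 = top, column 1 = left; crops are stated as
# kept extents.  Resize rounds target dimensions half-up; crops discard
# floor(W/2) / floor(H/5) pixels.

#' Resize a view by a scale factor
#'
#' Bilinear interpolation to `round(factor * dim)` per axis
#' (round-half-up).  The paired lesion mask, if resized alongside with
#' [preprocess_study()], uses the same transform followed by a 0.5
#' threshold.
#'
#' @param view a [view_image()].
#' @param factor scale in (0, 1]; the screening pipeline default is 0.3.
#' @return The resized [view_image()].
#' @export
resize_view <- function(view, factor) {
  if (!inherits(view, "view_image")) stopf("`view` must be a view_image")
  if (factor <= 0 || factor > 1) stopf("`factor` must lie in (0, 1]")
  h2 <- round_half_up(factor * nrow(view$pixels))
  w2 <- round_half_up(factor * ncol(view$pixels))
  if (h2 < 8 || w2 < 8)
    stopf("resize factor %.3g yields %dx%d, below the 8-pixel minimum",
          factor, h2, w2)
  px <- resize_bilinear(view$pixels, h2, w2)
  view_image(matrix(as.integer(clamp(round(px), 0, 65535)), h2, w2),
             view$view)
}

resize_bilinear <- function(m, h2, w2) {
  if (identical(c(h2, w2), dim(m))) return(m + 0)
  EBImage::resize(m + 0, w = h2, h = w2)  # EBImage's w/h follow dim order
}

resize_mask <- function(mask, h2, w2) {
  resize_bilinear(mask * 1, h2, w2) >= 0.5
}

# Kept extents for each view tag: the chest-wall half of the columns (left
# half for L views, right half for R views), and the diagnostically
# relevant rows (MLO views lose the top fifth, CC views the bottom fifth).
crop_extents <- function(tag, h, w) {
  keep_w <- floor(w / 2)
  cols <- if (startsWith(tag, "L")) seq_len(keep_w)
  else seq.int(w - keep_w + 1L, w)
  drop_h <- floor(h / 5)
  rows <- if (endsWith(tag, "MLO")) seq.int(drop_h + 1L, h)
  else seq_len(h - drop_h)
  list(rows = rows, cols = cols)
}

#' Crop a view to its informative region
#'
#' LMLO/LCC keep the left half of the columns and RMLO/RCC the right half
#' (the chest-wall side); MLO views drop the top fifth of the rows and CC
#' views the bottom fifth.
#'
#' @param view a [view_image()].
#' @return The cropped [view_image()].
#' @export
crop_view <- function(view) {
  if (!inherits(view, "view_image")) stopf("`view` must be a view_image")
  ext <- crop_extents(view$view, nrow(view$pixels), ncol(view$pixels))
  view_image(view$pixels[ext$rows, ext$cols, drop = FALSE], view$view)
}

new_side_input <- function(pixels, side, label, source_cr = 1, mask = NULL,
                           subject_id = NA_character_) {
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stopf("side-input pixels must be finite and in [0, 1]")
  if (!is.null(mask) && !identical(dim(mask), dim(pixels)))
    stopf("mask must be congruent to the side-input pixels")
  structure(list(pixels = pixels, side = side, label = as.integer(label),
                 source_cr = source_cr, mask = mask,
                 subject_id = subject_id),
            class = "side_input")
}

#' @export
print.side_input <- function(x, ...) {
  cat(sprintf("<side_input %s %s side, %dx%d, label %d, source CR %.6g>\n",
              x$subject_id, x$side, nrow(x$pixels), ncol(x$pixels),
              x$label, x$source_cr))
  invisible(x)
}

#' Concatenate the two views of one breast side into a network input
#'
#' The CC view is placed leftmost and the MLO view beside it along the
#' x-axis; if heights differ the shorter is zero-padded at the bottom.
#' Intensities are rescaled to `[0, 1]` by division by 65535.  Optional
#' lesion masks receive the identical transform and are unioned.
#'
#' @param cc,mlo resized and cropped [view_image()]s of the same
#'   laterality.
#' @param cc_mask,mlo_mask optional logical matrices congruent to the
#'   respective views.
#' @param label study label for this input: 0 = normal/benign,
#'   1 = malignant.
#' @param source_cr compression ratio the views were materialized at.
#' @param subject_id carried through for split hygiene.
#' @return A `side_input` object.
#' @export
concat_side <- function(cc, mlo, cc_mask = NULL, mlo_mask = NULL, label = 0L,
                        source_cr = 1, subject_id = NA_character_) {
  if (!inherits(cc, "view_image") || !inherits(mlo, "view_image"))
    stopf("`cc` and `mlo` must be view_images")
  if (!endsWith(cc$view, "CC") || !endsWith(mlo$view, "MLO"))
    stopf("expected a CC view and an MLO view, got %s and %s",
          cc$view, mlo$view)
  if (cc$laterality != mlo$laterality)
    stopf("laterality mismatch: %s vs %s", cc$view, mlo$view)
  h <- max(nrow(cc$pixels), nrow(mlo$pixels))
  pad <- function(m) {
    if (nrow(m) == h) return(m)
    rbind(m, matrix(0, h - nrow(m), ncol(m)))
  }
  pixels <- cbind(pad(cc$pixels + 0), pad(mlo$pixels + 0)) / 65535
  mask <- NULL
  if (!is.null(cc_mask) || !is.null(mlo_mask)) {
    cc_mask <- cc_mask %||% matrix(FALSE, nrow(cc$pixels), ncol(cc$pixels))
    mlo_mask <- mlo_mask %||% matrix(FALSE, nrow(mlo$pixels), ncol(mlo$pixels))
    mask <- cbind(pad(cc_mask * 1), pad(mlo_mask * 1)) > 0
  }
  new_side_input(pixels, cc$laterality, label, source_cr, mask, subject_id)
}

#' Preprocess a study into its two side-level inputs
#'
#' Runs resize -> crop -> concatenate for each side.  Masks follow the
#' identical geometric transform.  The side label is 1 iff the study label
#' is malignant (the study-level rule then takes the maximum over sides at
#' prediction time).
#'
#' @param study a [study_record()].
#' @param factor resize factor (default 0.3).
#' @param source_cr CR annotation carried into the side inputs.
#' @return List with elements `left` and `right`, each a `side_input`.
#' @export
preprocess_study <- function(study, factor = 0.3, source_cr = 1) {
  if (!inherits(study, "study_record")) stopf("`study` must be a study_record")
  label <- as.integer(study_is_malignant(study))
  one_view <- function(tag) {
    v <- resize_view(study$views[[tag]], factor)
    m <- study$masks[[tag]]
    mk <- if (m$present)
      resize_mask(m$mask, nrow(v$pixels), ncol(v$pixels))
    else matrix(FALSE, nrow(v$pixels), ncol(v$pixels))
    ext <- crop_extents(tag, nrow(v$pixels), ncol(v$pixels))
    list(view = crop_view(v), mask = mk[ext$rows, ext$cols, drop = FALSE])
  }
  pv <- lapply(setNames(VIEW_TAGS, VIEW_TAGS), one_view)
  list(
    left = concat_side(pv$LCC$view, pv$LMLO$view, pv$LCC$mask, pv$LMLO$mask,
                       label, source_cr, study$subject_id),
    right = concat_side(pv$RCC$view, pv$RMLO$view, pv$RCC$mask, pv$RMLO$mask,
                        label, source_cr, study$subject_id))
}
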