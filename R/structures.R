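# Core value types.  Pixel matrices follow the image convention
# [row = y from top, column = x from left]; intensities are unsigned 16-bit
# values (0..65535) held in integer matrices.

VIEW_TAGS <- c("LCC", "LMLO", "RCC", "RMLO")
STUDY_LABELS <- c("normal", "benign", "malignant")

#' Construct a single mammographic view
#'
#' A view image couples a 16-bit intensity matrix with its standard
#' screening-view tag (craniocaudal or mediolateral-oblique, left or right).
#'
#' @param pixels integer or numeric matrix (height x width) of intensities
#'   in `[0, 65535]`.
#' @param view one of `"LCC"`, `"LMLO"`, `"RCC"`, `"RMLO"`.
#' @return A `view_image` object with fields `pixels`, `view`, `laterality`.
#' @export
view_image <- function(pixels, view) {
  view <- match.arg(view, VIEW_TAGS)
  if (!is.matrix(pixels)) stopf("`pixels` must be a matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stopf("view dimensions must be at least 16x16, got %dx%d",
          nrow(pixels), ncol(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 65535)
    stopf("intensities must lie in [0, 65535] with no missing values")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, view = view,
         laterality = if (startsWith(view, "L")) "left" else "right"),
    class = "view_image")
}

#' @export
print.view_image <- function(x, ...) {
  cat(sprintf("<view_image %s (%s) %dx%d px, range [%d, %d]>\n",
              x$view, x$laterality, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

view_height <- function(v) nrow(v$pixels)
view_width <- function(v) ncol(v$pixels)

#' Construct a lesion mask paired with a view
#'
#' @param mask logical or 0/1 matrix congruent to the paired view's pixels.
#' @param present logical; `FALSE` forces an all-zero mask (benign blobs and
#'   normal tissue carry no annotation).
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(mask, present = any(mask > 0)) {
  if (!is.matrix(mask)) stopf("`mask` must be a matrix")
  mask <- mask > 0
  if (!present && any(mask)) stopf("present = FALSE requires an all-zero mask")
  if (present && !any(mask)) stopf("present = TRUE requires a non-empty mask")
  structure(list(mask = mask, present = present), class = "lesion_mask")
}

#' Construct a four-view study record
#'
#' The unit of classification: one subject's four screening views, their
#' lesion masks, the study label and bookkeeping metadata.  BI-RADS is tied
#' to the label (normal = 1, benign = 2-3, malignant = 4-5) and malignant
#' studies must carry at least one annotated mask.
#'
#' @param subject_id opaque subject identifier.
#' @param views named list of four [view_image()]s (names LCC, LMLO, RCC,
#'   RMLO).
#' @param masks named list of four [lesion_mask()]s congruent to the views.
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param exam_date a `Date`.
#' @param birads integer 1-5 consistent with `label`.
#' @return A `study_record` object.
#' @export
study_record <- function(subject_id, views, masks, label, exam_date, birads) {
  label <- match.arg(label, STUDY_LABELS)
  if (!setequal(names(views), VIEW_TAGS))
    stopf("`views` must be named %s", paste(VIEW_TAGS, collapse = ", "))
  if (!setequal(names(masks), VIEW_TAGS))
    stopf("`masks` must be named %s", paste(VIEW_TAGS, collapse = ", "))
  views <- views[VIEW_TAGS]
  masks <- masks[VIEW_TAGS]
  for (tag in VIEW_TAGS) {
    if (views[[tag]]$view != tag) stopf("view under name %s is tagged %s",
                                        tag, views[[tag]]$view)
    if (!identical(dim(masks[[tag]]$mask), dim(views[[tag]]$pixels)))
      stopf("mask for %s is not congruent to its view", tag)
  }
  birads <- as.integer(birads)
  ok <- switch(label,
               normal = identical(birads, 1L),
               benign = birads %in% c(2L, 3L),
               malignant = birads %in% c(4L, 5L))
  if (!ok) stopf("birads %d inconsistent with label '%s'", birads, label)
  if (label == "malignant" && !any(vapply(masks, `[[`, TRUE, "present")))
    stopf("malignant study requires at least one present lesion mask")
  structure(
    list(subject_id = as.character(subject_id), views = views, masks = masks,
         label = label, exam_date = as.Date(exam_date), birads = birads),
    class = "study_record")
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record %s: %s (BI-RADS %d), exam %s, views %dx%d>\n",
              x$subject_id, x$label, x$birads, format(x$exam_date),
              view_height(x$views$LCC), view_width(x$views$LCC)))
  invisible(x)
}

study_is_malignant <- function(study) study$label == "malignant"
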