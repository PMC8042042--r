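# Synthetic mammogram-like studies with ground-truth lesion masks, plus the
# cohort-selection filter applied to a subject manifest.

#' Reference screening-cohort class counts
#'
#' Class composition of the clinical screening cohort that the synthetic
#' generator's default class weights emulate: 5672 normal, 1686 benign and
#' 1753 malignant studies, i.e. a roughly 4:1 non-malignant:malignant ratio.
#'
#' @return Named integer vector with elements `normal`, `benign`,
#'   `malignant`.
#' @export
reference_class_counts <- function() {
  c(normal = 5672L, benign = 1686L, malignant = 1753L)
}

#' Default class weights for the synthetic cohort generator
#'
#' @return Named numeric vector of proportions summing to 1, derived from
#'   [reference_class_counts()].
#' @export
default_class_weights <- function() {
  n <- reference_class_counts()
  n / sum(n)
}

# Band-limited Gaussian texture: white noise low-pass filtered with a
# Gaussian kernel and rescaled to unit standard deviation.  The smoothing
# gives the codec realistic spatial correlation to exploit.
band_limited_noise <- function(h, w, sigma) {
  x <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) x <- EBImage::gblur(x, sigma = sigma)
  x / stats::sd(x)
}

# Half-elliptical "breast" support with its flat side on the chest-wall
# edge: the left image edge for left-laterality views, the right edge for
# right-laterality views (so the standard half-image crop keeps the tissue).
tissue_support <- function(h, w, laterality) {
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  cx <- if (laterality == "left") 0.5 else w + 0.5
  cy <- (h + 1) / 2
  a <- 0.52 * w
  b <- 0.44 * h
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Isotropic Gaussian-profile blob of peak `amp` centred at (y0, x0).
gaussian_blob <- function(h, w, y0, x0, sigma, amp) {
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  amp * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))
}

# Intensity model constants (16-bit scale).  Benign and malignant studies
# both carry a broad, low-contrast Gaussian mass drawn from the same
# amplitude and size distribution (log-normal jitter included), so gross
# density is NOT a class cue.  Malignancy is marked by fine-grained
# multiplicative microtexture confined to the mass: a distributed,
# high-frequency, zero-mean feature whose energy is spread over many small
# wavelet coefficients.  Moderate JPEG 2000 compression preserves it;
# extreme rate budgets quantize every one of those coefficients away,
# erasing exactly the diagnostic evidence while the smooth mass (which is
# what the codec keeps) stays class-uninformative.
.SYN <- list(
  dark_base = 2500, dark_sd = 200,
  tissue_base = 22000, texture_sd = 2500, texture_sigma = 2.5,
  mass_span = 12000,          # mass peak = separability * span / ratio^2
  mass_sigma_ratio = 2.2,     # mass sigma relative to the base lesion sigma
  microtex_span = 7000,       # microtexture sd at the mass centre
  microtex_sigma = 1.0,       # microtexture correlation length (pixels)
  amp_jitter_sdlog = 0.35)

# Draw a lesion centre inside the tissue, within the region every crop
# keeps: x within [0.10, 0.38] of the width from the chest-wall edge,
# y within [0.32, 0.68] of the height.
draw_lesion_centre <- function(h, w, laterality) {
  xr <- runif(1, 0.10, 0.38) * w
  x0 <- if (laterality == "left") xr else w - xr
  y0 <- runif(1, 0.32, 0.68) * h
  c(y0 = y0, x0 = x0)
}

# All-zero masks dominate a cohort (every view of every non-malignant
# study); share one immutable object per geometry instead of allocating
# h*w logicals each time.
.mask_cache <- new.env(parent = emptyenv())

empty_lesion_mask <- function(h, w) {
  key <- paste0(h, "x", w)
  hit <- .mask_cache[[key]]
  if (is.null(hit)) {
    hit <- lesion_mask(matrix(FALSE, h, w), present = FALSE)
    .mask_cache[[key]] <- hit
  }
  hit
}

render_view <- function(tag, h, w, lesions) {
  lat <- if (startsWith(tag, "L")) "left" else "right"
  tis <- tissue_support(h, w, lat)
  px <- .SYN$dark_base + .SYN$dark_sd * band_limited_noise(h, w, 1)
  px[tis] <- .SYN$tissue_base +
    .SYN$texture_sd * band_limited_noise(h, w, .SYN$texture_sigma)[tis]
  mask <- matrix(FALSE, h, w)
  for (les in lesions) {
    if (les$side != lat) next
    y0 <- les$y0 + rnorm(1, 0, 0.015 * h)
    x0 <- les$x0 + rnorm(1, 0, 0.015 * w)
    g <- gaussian_blob(h, w, y0, x0, les$sigma, les$amp)
    px <- px + g
    if (les$microtex_amp > 0) {
      # fine-grained stochastic structure, weighted by the mass profile so
      # it lives inside the lesion
      px <- px + (g / les$amp) * les$microtex_amp *
        band_limited_noise(h, w, .SYN$microtex_sigma)
    }
    if (les$annotated) mask <- mask | (g > les$amp / 2)
  }
  px <- matrix(as.integer(clamp(round(px), 0, 65535)), h, w)
  list(view = view_image(px, tag),
       mask = if (any(mask)) lesion_mask(mask, present = TRUE)
       else empty_lesion_mask(h, w))
}

#' Generate one synthetic four-view study
#'
#' Each view holds a half-elliptical tissue region (flat side on the
#' chest-wall edge) filled with band-limited noise texture over a dark
#' field.  Benign studies add a broad, low-contrast Gaussian-profile mass
#' with no annotation; malignant studies add a mass drawn from the same
#' distribution whose interior carries fine-grained stochastic
#' microtexture, with the ground-truth mask set where the mass profile
#' exceeds half its peak; normal studies add nothing.  Because benign and
#' malignant masses are interchangeable in their smooth component, the
#' class signal lives entirely in the fine-scale texture — the part of the
#' image lossy compression discards first.
#'
#' @param rng_seed integer seed; the study is a pure function of the seed
#'   and arguments.
#' @param label `"normal"`, `"benign"` or `"malignant"`.
#' @param width,height view dimensions in pixels (both >= 64).
#' @param separability lesion contrast relative to the background texture,
#'   in (0, 1]; the malignant peak amplitude is `separability * 36000`
#'   intensity units.
#' @return A [study_record()].
#' @export
#' @examples
#' s <- generate_study(1, "malignant", width = 128, height = 160)
#' s$masks$LCC$present || s$masks$RCC$present
generate_study <- function(rng_seed, label = c("normal", "benign", "malignant"),
                           width = 256L, height = 320L, separability = 0.8) {
  label <- match.arg(label)
  if (width < 64L || height < 64L)
    stopf("views must be at least 64x64 to place a lesion; got %dx%d",
          height, width)
  if (separability <= 0 || separability > 1)
    stopf("`separability` must lie in (0, 1]")
  with_seed(rng_seed, {
    h <- as.integer(height); w <- as.integer(width)
    sig <- max(3, 0.035 * min(h, w))
    rr <- .SYN$mass_sigma_ratio
    add_mass <- function(lesions, side, malignant = FALSE) {
      ctr <- draw_lesion_centre(h, w, side)
      jit <- exp(rnorm(1, 0, .SYN$amp_jitter_sdlog))
      jit_t <- exp(rnorm(1, 0, .SYN$amp_jitter_sdlog))
      lesions[[length(lesions) + 1L]] <- list(
        side = side, y0 = ctr[["y0"]], x0 = ctr[["x0"]], sigma = rr * sig,
        amp = separability * .SYN$mass_span * jit / rr^2,
        microtex_amp = if (malignant)
          separability * .SYN$microtex_span * jit_t else 0,
        annotated = malignant)
      lesions
    }
    lesions <- list()
    if (label == "malignant") {
      sides <- switch(sample(c("left", "right", "both"), 1,
                             prob = c(0.505, 0.489, 0.006)),
                      left = "left", right = "right", both = c("left", "right"))
      for (s in sides)
        lesions <- add_mass(lesions, s, malignant = TRUE)
    } else if (label == "benign") {
      s <- sample(c("left", "right", "both"), 1, prob = c(0.361, 0.311, 0.328))
      for (sd_ in if (s == "both") c("left", "right") else s)
        lesions <- add_mass(lesions, sd_)
    }
    vm <- lapply(setNames(VIEW_TAGS, VIEW_TAGS), render_view,
                 h = h, w = w, lesions = lesions)
    birads <- switch(label, normal = 1L,
                     benign = sample(2:3, 1),
                     malignant = sample(4:5, 1))
    exam_date <- as.Date("2013-01-01") + sample.int(2191L, 1L) - 1L
    study_record(subject_id = sprintf("SYN%010d", as.integer(rng_seed)),
                 views = lapply(vm, `[[`, "view"),
                 masks = lapply(vm, `[[`, "mask"),
                 label = label, exam_date = exam_date, birads = birads)
  })
}

#' Generate a synthetic cohort and its subject manifest
#'
#' Labels are a seeded multinomial draw from `class_weights`; each subject
#' contributes one study/exam.  The default weights emulate the ~4:1
#' non-malignant:malignant composition of [reference_class_counts()].
#'
#' @param rng_seed integer seed for the whole cohort.
#' @param n_subjects number of subjects (>= 10).
#' @param class_weights proportions for (normal, benign, malignant); must be
#'   non-negative and sum to 1 within 1e-9.
#' @inheritParams generate_study
#' @return List with `studies` (list of [study_record()]) and `manifest`
#'   (data.frame: subject_id, exam_date, birads, label, had_surgery).
#' @export
generate_cohort <- function(rng_seed, n_subjects,
                            class_weights = default_class_weights(),
                            width = 256L, height = 320L, separability = 0.8) {
  if (n_subjects < 10L) stopf("`n_subjects` must be at least 10")
  if (length(class_weights) != 3L || any(class_weights < 0))
    stopf("`class_weights` must be three non-negative proportions")
  if (abs(sum(class_weights) - 1) > 1e-9)
    stopf("`class_weights` must sum to 1 (got %.12f)", sum(class_weights))
  draws <- with_seed(rng_seed, list(
    labels = sample(STUDY_LABELS, n_subjects, replace = TRUE,
                    prob = class_weights),
    seeds = sample.int(.Machine$integer.max - 1L, n_subjects)))
  studies <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s <- generate_study(draws$seeds[i], draws$labels[i],
                        width = width, height = height,
                        separability = separability)
    s$subject_id <- sprintf("S%05d", i)
    studies[[i]] <- s
  }
  manifest <- data.frame(
    subject_id = vapply(studies, `[[`, "", "subject_id"),
    exam_date = as.Date(vapply(studies, function(s) format(s$exam_date), "")),
    birads = vapply(studies, `[[`, 1L, "birads"),
    label = vapply(studies, `[[`, "", "label"),
    had_surgery = vapply(studies, study_is_malignant, TRUE),
    stringsAsFactors = FALSE)
  list(studies = studies, manifest = manifest)
}

#' Select qualifying subjects from an exam manifest
#'
#' Applies the screening-cohort selection rule: a non-malignant subject
#' qualifies when its two most recent exams are at least 365 days apart and
#' carry the same BI-RADS score, in which case only the most recent exam is
#' kept; a malignant subject qualifies when it underwent surgery, keeping
#' its latest (preoperative) exam.  Each subject contributes at most one
#' exam; non-qualifying subjects are dropped and listed in the `"dropped"`
#' attribute.
#'
#' @param manifest data.frame with columns subject_id, exam_date, birads,
#'   label, had_surgery.
#' @return data.frame (subject_id, exam_date) of selected exams, ordered by
#'   subject_id, with dropped subject ids in `attr(, "dropped")`.
#' @export
cohort_filter <- function(manifest) {
  need <- c("subject_id", "exam_date", "birads", "label", "had_surgery")
  if (!all(need %in% names(manifest)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  manifest$exam_date <- tryCatch(as.Date(manifest$exam_date),
                                 error = function(e) as.Date(NA))
  if (anyNA(manifest$exam_date)) stopf("manifest contains invalid exam dates")
  if (anyDuplicated(manifest[c("subject_id", "exam_date")]))
    stopf("(subject_id, exam_date) pairs must be unique")
  sel <- list(); dropped <- character()
  for (sid in sort(unique(manifest$subject_id))) {
    rows <- manifest[manifest$subject_id == sid, , drop = FALSE]
    rows <- rows[order(rows$exam_date, decreasing = TRUE), , drop = FALSE]
    keep <- if (any(rows$label == "malignant")) {
      any(rows$had_surgery)
    } else {
      nrow(rows) >= 2L &&
        as.numeric(rows$exam_date[1] - rows$exam_date[2]) >= 365 &&
        rows$birads[1] == rows$birads[2]
    }
    if (keep) {
      sel[[length(sel) + 1L]] <- data.frame(
        subject_id = sid, exam_date = rows$exam_date[1],
        stringsAsFactors = FALSE)
    } else dropped <- c(dropped, sid)
  }
  out <- if (length(sel)) do.call(rbind, sel)
  else data.frame(subject_id = character(), exam_date = as.Date(character()))
  attr(out, "dropped") <- dropped
  out
}

#' Write a synthetic cohort to disk
#'
#' Views are written as 16-bit single-channel TIFF, masks as 8-bit PNG
#' (0/255), and the manifest as CSV with ISO-8601 dates plus per-view file
#' paths.
#'
#' @param cohort a list as returned by [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame including path columns.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (tag in VIEW_TAGS) {
    man[[paste0("path_", tag)]] <- NA_character_
    man[[paste0("maskpath_", tag)]] <- NA_character_
  }
  for (i in seq_along(cohort$studies)) {
    s <- cohort$studies[[i]]
    for (tag in VIEW_TAGS) {
      vp <- file.path(dir, sprintf("%s_%s.tif", s$subject_id, tag))
      tiff::writeTIFF(s$views[[tag]]$pixels / 65535, vp, bits.per.sample = 16L)
      man[[paste0("path_", tag)]][i] <- vp
      m <- s$masks[[tag]]
      if (m$present) {
        mp <- file.path(dir, sprintf("%s_%s_mask.png", s$subject_id, tag))
        png::writePNG(m$mask * 1, mp)
        man[[paste0("maskpath_", tag)]][i] <- mp
      }
    }
  }
  man$exam_date <- format(man$exam_date)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the image files.
#' @return A list with `studies` and `manifest`, as [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  studies <- lapply(seq_len(nrow(man)), function(i) {
    views <- list(); masks <- list()
    for (tag in VIEW_TAGS) {
      px <- tiff::readTIFF(man[[paste0("path_", tag)]][i])
      views[[tag]] <- view_image(matrix(as.integer(round(px * 65535)),
                                        nrow(px), ncol(px)), tag)
      mp <- man[[paste0("maskpath_", tag)]][i]
      masks[[tag]] <- if (is.na(mp) || !nzchar(mp)) {
        lesion_mask(matrix(FALSE, nrow(px), ncol(px)), present = FALSE)
      } else {
        m <- png::readPNG(mp)
        lesion_mask(m > 0.5)
      }
    }
    study_record(man$subject_id[i], views, masks, man$label[i],
                 man$exam_date[i], man$birads[i])
  })
  man$exam_date <- as.Date(man$exam_date)
  list(studies = studies, manifest = man)
}
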