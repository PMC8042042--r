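# JPEG 2000 compression to a target compression ratio (CR) with rate
# control, plus CR and PSNR accounting.  Encoding/decoding is delegated to
# the OpenJPEG codec (through Pillow, driven as a batch subprocess); the
# rate-control loop, CR bookkeeping and PSNR live here.

.codec_env <- new.env(parent = emptyenv())

j2k_python <- function() {
  if (!is.null(.codec_env$python)) return(.codec_env$python)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (!nzchar(path)) next
    ok <- suppressWarnings(system2(
      path, c("-c", shQuote("from PIL import features; import tifffile; assert features.check('jpg_2000')")),
      stdout = FALSE, stderr = FALSE))
    if (identical(ok, 0L)) {
      .codec_env$python <- path
      return(path)
    }
  }
  stopf("no python with JPEG 2000-enabled Pillow and tifffile found on PATH")
}

j2k_script <- function() {
  p <- system.file("python", "j2k_tool.py", package = "crstress")
  if (!nzchar(p)) stopf("j2k_tool.py not found; is the package installed?")
  p
}

# Run a batch of encode/decode jobs in one subprocess call.
j2k_run <- function(jobs) {
  jobfile <- tempfile("j2kjobs", fileext = ".json")
  outfile <- tempfile("j2kres", fileext = ".json")
  on.exit(unlink(c(jobfile, outfile)))
  jsonlite::write_json(list(jobs = jobs), jobfile,
                       auto_unbox = TRUE, digits = NA)
  status <- system2(j2k_python(), c(j2k_script(), jobfile, outfile),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(outfile))
    stopf("JPEG 2000 helper failed (exit status %s)", status)
  res <- jsonlite::read_json(outfile)
  errs <- Filter(function(r) !is.null(r$error), res)
  if (length(errs))
    stopf("JPEG 2000 codec error: %s", errs[[1]]$error)
  res
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "view_image")) image <- image$pixels
  if (!is.matrix(image)) stopf("`image` must be a matrix or view_image")
  if (length(image) == 0L) stopf("empty image")
  if (anyNA(image) || min(image) < 0 || max(image) > 65535)
    stopf("pixel values must lie in [0, 65535]")
  image
}

write_tiff16 <- function(pixels, path) {
  tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L)
  path
}

read_tiff16 <- function(path) {
  px <- tiff::readTIFF(path)
  matrix(as.integer(round(px * 65535)), nrow(px), ncol(px))
}

#' Peak signal-to-noise ratio of a reconstruction
#'
#' `10 * log10(MAX^2 / MSE)` in decibels with `MAX = 2^bit_depth - 1` and
#' MSE the mean squared pixel difference.  A perfect reconstruction has
#' infinite PSNR; by convention it is reported as the label 100, and values
#' are clamped to `[0, 100]`.
#'
#' @param source,reconstruction congruent 2-D intensity matrices.
#' @param bit_depth 8 or 16 (default 16), matching the data.
#' @return PSNR in dB, in `[0, 100]`.
#' @export
#' @examples
#' compute_psnr(matrix(100, 2, 2), matrix(c(110, 110, 90, 90), 2, 2))
compute_psnr <- function(source, reconstruction, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 16L)) stopf("`bit_depth` must be 8 or 16")
  source <- as_pixel_matrix(source)
  reconstruction <- as_pixel_matrix(reconstruction)
  if (!identical(dim(source), dim(reconstruction)))
    stopf("source and reconstruction dimensions differ (%s vs %s)",
          paste(dim(source), collapse = "x"),
          paste(dim(reconstruction), collapse = "x"))
  if (length(source) == 0L) stopf("empty image")
  mse <- mean((as.numeric(source) - as.numeric(reconstruction))^2)
  if (mse == 0) return(100)
  maxi <- 2^bit_depth - 1
  clamp(10 * log10(maxi^2 / mse), 0, 100)
}

#' Compression ratio from byte counts
#'
#' `CR = original size / compressed size`; e.g. a 30 MB image compressed to
#' 3 MB has a CR of 10.  The original size convention in this package is
#' the raw pixel-buffer size (width x height x 2 for 16-bit), which is
#' container-independent.
#'
#' @param original_bytes,compressed_bytes positive byte counts.
#' @return The ratio as a real number.
#' @export
compute_cr <- function(original_bytes, compressed_bytes) {
  if (any(original_bytes <= 0)) stopf("`original_bytes` must be positive")
  if (any(compressed_bytes <= 0)) stopf("`compressed_bytes` must be positive")
  original_bytes / compressed_bytes
}

#' Rate-control settings for JPEG 2000 encoding
#'
#' @param tolerance relative tolerance on the achieved CR, in (0, 0.5].
#' @param max_iterations maximum encoder calls per image.
#' @param bit_depth 8 or 16.
#' @return A `rate_control_config` list.
#' @export
rate_control_config <- function(tolerance = 0.10, max_iterations = 20L,
                                bit_depth = 16L) {
  if (tolerance <= 0 || tolerance > 0.5)
    stopf("`tolerance` must lie in (0, 0.5]")
  if (!bit_depth %in% c(8L, 16L)) stopf("`bit_depth` must be 8 or 16")
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 bit_depth = as.integer(bit_depth)),
            class = "rate_control_config")
}

raw_buffer_bytes <- function(pixels, bit_depth = 16L) {
  as.numeric(nrow(pixels)) * ncol(pixels) * (bit_depth / 8)
}

new_compression_result <- function(codestream, target_cr, achieved_cr,
                                   psnr_db, original_bytes, compressed_bytes,
                                   decoded) {
  structure(list(codestream = codestream, target_cr = target_cr,
                 achieved_cr = achieved_cr, psnr_db = psnr_db,
                 original_bytes = original_bytes,
                 compressed_bytes = compressed_bytes, decoded = decoded),
            class = "compression_result")
}

#' @export
print.compression_result <- function(x, ...) {
  cat(sprintf(
    "<compression_result target CR %.6g, achieved %.6g (%d -> %d bytes), PSNR %.2f dB>\n",
    x$target_cr, x$achieved_cr, as.integer(x$original_bytes),
    as.integer(x$compressed_bytes), x$psnr_db))
  invisible(x)
}

# Encode a list of pixel matrices at per-image requested rates in one
# subprocess call.  Returns byte sizes and codestream paths.
j2k_encode_files <- function(srcs, dsts, rates, lossless = FALSE) {
  jobs <- lapply(seq_along(srcs), function(i) {
    list(id = i, op = "encode", src = srcs[i], dst = dsts[i],
         rate = rates[i], lossless = lossless)
  })
  res <- j2k_run(jobs)
  vapply(res[order(vapply(res, `[[`, 1L, "id"))], function(r)
    as.numeric(r$bytes), 1)
}

j2k_decode_files <- function(srcs, dsts) {
  jobs <- lapply(seq_along(srcs), function(i)
    list(id = i, op = "decode", src = srcs[i], dst = dsts[i]))
  invisible(j2k_run(jobs))
}

#' Encode an image losslessly to a JPEG 2000 codestream
#'
#' @param image matrix or [view_image()].
#' @return Raw vector holding the codestream.
#' @export
j2k_encode_lossless <- function(image) {
  px <- as_pixel_matrix(image)
  work <- tempfile("j2k")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  src <- write_tiff16(px, file.path(work, "in.tif"))
  dst <- file.path(work, "out.j2k")
  j2k_encode_files(src, dst, rates = 0, lossless = TRUE)
  readBin(dst, "raw", file.size(dst))
}

#' Decode a JPEG 2000 codestream
#'
#' @param codestream raw vector or path to a `.j2k`/`.jp2` file.
#' @return Integer matrix of 16-bit intensities with the original
#'   dimensions.
#' @export
j2k_decode <- function(codestream) {
  work <- tempfile("j2k")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  src <- if (is.raw(codestream)) {
    p <- file.path(work, "in.j2k")
    writeBin(codestream, p)
    p
  } else codestream
  dst <- file.path(work, "out.tif")
  j2k_decode_files(src, dst)
  read_tiff16(dst)
}

#' Largest compression ratio reachable for an image
#'
#' Asks the encoder for an extreme rate and reports the CR actually
#' achieved; the codestream size floors at the codec's header/coarsest-band
#' overhead, which bounds the reachable CR for a given image size.
#'
#' @param image matrix or [view_image()].
#' @return The saturation CR (raw buffer bytes / minimal codestream bytes).
#' @export
max_reachable_cr <- function(image) {
  px <- as_pixel_matrix(image)
  work <- tempfile("j2k")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  src <- write_tiff16(px, file.path(work, "in.tif"))
  dst <- file.path(work, "out.j2k")
  bytes <- j2k_encode_files(src, dst, rates = 1e6)
  raw_buffer_bytes(px) / bytes
}

# Rate control for a batch of images sharing one target CR.  The requested
# encoder rate is bisected (geometrically) per image until the achieved CR
# lands within tolerance; images converge independently but each iteration
# costs one subprocess call for all still-pending images.
compress_batch <- function(images, target_cr,
                           config = rate_control_config(),
                           on_unreachable = c("error", "best")) {
  on_unreachable <- match.arg(on_unreachable)
  if (target_cr < 1) stopf("`target_cr` must be >= 1")
  pix <- lapply(images, as_pixel_matrix)
  n <- length(pix)
  orig <- vapply(pix, raw_buffer_bytes, 1, bit_depth = config$bit_depth)

  if (target_cr == 1) {
    return(lapply(seq_len(n), function(i)
      new_compression_result(NULL, 1, 1, 100, orig[i], orig[i], pix[[i]])))
  }

  work <- tempfile("j2kbatch")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE))
  srcs <- vapply(seq_len(n), function(i)
    write_tiff16(pix[[i]], file.path(work, sprintf("s%05d.tif", i))), "")
  dsts <- file.path(work, sprintf("c%05d.j2k", seq_len(n)))

  tol <- config$tolerance
  rate <- rep(target_cr, n)      # requested rate tracks CR closely
  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n)
  bytes <- rep(NA_real_, n); achieved <- rep(NA_real_, n)
  best_rate <- rep(NA_real_, n); best_gap <- rep(Inf, n)
  done <- rep(FALSE, n); saturated_at <- rep(NA_real_, n)

  for (iter in seq_len(config$max_iterations)) {
    pend <- which(!done)
    if (!length(pend)) break
    got <- j2k_encode_files(srcs[pend], dsts[pend], rate[pend])
    last_bytes <- bytes
    bytes[pend] <- got
    achieved[pend] <- orig[pend] / bytes[pend]
    for (i in pend) {
      gap <- abs(achieved[i] - target_cr)
      if (gap < best_gap[i]) { best_gap[i] <- gap; best_rate[i] <- rate[i] }
      if (gap <= tol * target_cr) { done[i] <- TRUE; next }
      if (achieved[i] < target_cr) {
        # need smaller codestream; detect the size floor (saturation)
        if (!is.na(last_bytes[i]) && bytes[i] >= last_bytes[i] &&
            is.na(hi[i])) {
          saturated_at[i] <- achieved[i]
          done[i] <- TRUE
          next
        }
        lo[i] <- rate[i]
        rate[i] <- if (is.na(hi[i])) rate[i] * 2 else sqrt(rate[i] * hi[i])
      } else {
        hi[i] <- rate[i]
        rate[i] <- if (is.na(lo[i])) max(1, rate[i] / 2)
        else sqrt(rate[i] * lo[i])
      }
    }
  }

  # final encode at the best rate for images whose last trial was not best
  redo <- which(!vapply(seq_len(n), function(i)
    isTRUE(all.equal(rate[i], best_rate[i])) || done[i], TRUE))
  if (length(redo)) {
    got <- j2k_encode_files(srcs[redo], dsts[redo], best_rate[redo])
    bytes[redo] <- got
    achieved[redo] <- orig[redo] / bytes[redo]
  }

  bad <- which(abs(achieved - target_cr) > tol * target_cr)
  if (length(bad) && on_unreachable == "error")
    stopf(paste0("target CR %.6g unreachable for image %d ",
                 "(best achieved CR %.6g); the image is too small to ",
                 "compress that far"),
          target_cr, bad[1], achieved[bad[1]])

  dec <- file.path(work, sprintf("d%05d.tif", seq_len(n)))
  j2k_decode_files(dsts, dec)
  lapply(seq_len(n), function(i) {
    decoded <- read_tiff16(dec[i])
    new_compression_result(
      codestream = readBin(dsts[i], "raw", file.size(dsts[i])),
      target_cr = target_cr, achieved_cr = achieved[i],
      psnr_db = compute_psnr(pix[[i]], decoded, config$bit_depth),
      original_bytes = orig[i], compressed_bytes = bytes[i],
      decoded = decoded)
  })
}

#' Compress an image to a target compression ratio
#'
#' Performs lossy JPEG 2000 encoding, bisecting the encoder's requested
#' rate until the achieved CR (raw pixel-buffer bytes over codestream
#' bytes) is within `config$tolerance` of `target_cr`.  `target_cr = 1`
#' returns the original pixels unmodified with a PSNR label of 100.
#'
#' @param image matrix or [view_image()] of 16-bit intensities.
#' @param target_cr target compression ratio (>= 1).
#' @param config a [rate_control_config()].
#' @return A `compression_result` with fields `codestream`, `target_cr`,
#'   `achieved_cr`, `psnr_db`, `original_bytes`, `compressed_bytes` and the
#'   `decoded` pixel matrix.
#' @export
compress_to_target_cr <- function(image, target_cr,
                                  config = rate_control_config()) {
  compress_batch(list(image), target_cr, config)[[1]]
}

# Replace every view of every study with its decoded compressed version at
# one CR (masks keep the original ground truth).  Views are batched across
# studies so rate control shares subprocess calls.
compress_studies <- function(studies, cr, config = rate_control_config(),
                             chunk_studies = 100L) {
  if (cr == 1) return(studies)
  acr <- c(); psnr <- c()
  for (lo in seq(1L, length(studies), by = chunk_studies)) {
    hi <- min(lo + chunk_studies - 1L, length(studies))
    views <- list(); where <- list()
    for (si in lo:hi) for (tag in VIEW_TAGS) {
      views[[length(views) + 1L]] <- studies[[si]]$views[[tag]]$pixels
      where[[length(where) + 1L]] <- list(si, tag)
    }
    res <- compress_batch(views, cr, config)
    for (k in seq_along(res)) {
      studies[[where[[k]][[1]]]]$views[[where[[k]][[2]]]]$pixels <-
        res[[k]]$decoded
    }
    acr <- c(acr, vapply(res, `[[`, 1, "achieved_cr"))
    psnr <- c(psnr, vapply(res, `[[`, 1, "psnr_db"))
    rm(res, views)
  }
  attr(studies, "achieved_cr") <- mean(acr)
  attr(studies, "psnr_db") <- mean(psnr)
  studies
}
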