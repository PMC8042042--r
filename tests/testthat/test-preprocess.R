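# Closed-form dimension oracles used throughout this file.
rhu <- function(x) floor(x + 0.5)
resize_dims <- function(h, w, f) c(rhu(f * h), rhu(f * w))
crop_dims <- function(h, w) c(h - floor(h / 5), floor(w / 2))

test_that("resize_view follows the round-half-up dimension rule", {
  v <- view_image(matrix(1000L, 1000, 1000), "LCC")
  expect_equal(dim(resize_view(v, 0.3)$pixels), c(300, 300))

  v2 <- view_image(matrix(1000L, 333, 217), "RMLO")
  expect_equal(dim(resize_view(v2, 0.3)$pixels), c(100, 65))

  v3 <- view_image(matrix(1000L, 70, 90), "LMLO")
  expect_identical(dim(resize_view(v3, 1.0)$pixels), c(70L, 90L))

  expect_error(resize_view(v, 0), "factor")
  expect_error(resize_view(view_image(matrix(1L, 20, 20), "LCC"), 0.1),
               "8-pixel")
})

test_that("resize preserves the intensity range and overall brightness", {
  px <- tiny_study(5, "malignant")$views$LCC$pixels
  out <- resize_view(view_image(px, "LCC"), 0.5)$pixels
  expect_true(min(out) >= 0 && max(out) <= 65535)
  expect_lt(abs(mean(out) - mean(px)) / mean(px), 0.05)
})

test_that("crop_view keeps the chest-wall half and the informative rows", {
  m <- matrix(as.integer(seq_len(300 * 300) %% 65536L), 300, 300)
  lcc <- crop_view(view_image(m, "LCC"))
  expect_equal(dim(lcc$pixels), c(240, 150))
  expect_identical(lcc$pixels, view_image(m, "LCC")$pixels[1:240, 1:150])

  rmlo <- crop_view(view_image(m, "RMLO"))
  expect_equal(dim(rmlo$pixels), c(240, 150))
  expect_identical(rmlo$pixels, view_image(m, "RMLO")$pixels[61:300, 151:300])

  m2 <- matrix(1L, 301, 301)
  expect_equal(dim(crop_view(view_image(m2, "LMLO"))$pixels), c(241, 150))
})

test_that("concat_side concatenates CC then MLO with padding and scaling", {
  cc <- view_image(matrix(65535L, 240, 150), "LCC")
  mlo <- view_image(matrix(0L, 240, 150), "LMLO")
  si <- concat_side(cc, mlo, label = 0L)
  expect_equal(dim(si$pixels), c(240, 300))
  expect_equal(si$pixels[1, 1], 1)             # CC leftmost, rescaled
  expect_equal(si$pixels[1, 300], 0)
  expect_equal(si$side, "left")

  # height mismatch: shorter is zero-padded at the bottom
  short <- view_image(matrix(65535L, 200, 150), "LMLO")
  si2 <- concat_side(cc, short)
  expect_equal(dim(si2$pixels), c(240, 300))
  expect_equal(si2$pixels[240, 200], 0)

  expect_error(concat_side(cc, view_image(matrix(0L, 240, 150), "RMLO")),
               "laterality")
  expect_error(concat_side(mlo, mlo), "CC view")

  z <- matrix(FALSE, 240, 150)
  si3 <- concat_side(cc, mlo, cc_mask = z, mlo_mask = z)
  expect_true(all(!si3$mask))
})

test_that("preprocess_study applies resize -> crop -> concat per side", {
  s <- generate_study(9, "malignant", 256, 320, 0.8)
  pp <- preprocess_study(s, 0.3)
  rd <- resize_dims(320, 256, 0.3)             # 96 x 77
  cd <- crop_dims(rd[1], rd[2])                # 77 x 38
  expect_equal(dim(pp$left$pixels), c(cd[1], 2 * cd[2]))
  expect_equal(dim(pp$right$pixels), c(cd[1], 2 * cd[2]))
  expect_equal(pp$left$label, 1L)
  expect_equal(pp$right$label, 1L)
  expect_true(all(pp$left$pixels >= 0 & pp$left$pixels <= 1))

  ben <- preprocess_study(generate_study(2, "benign", 256, 320), 0.3)
  expect_equal(ben$left$label, 0L)
  expect_equal(ben$right$label, 0L)
})

test_that("output dimensions match the closed form across a size sweep", {
  for (hw in list(c(64, 64), c(100, 81), c(257, 193), c(512, 340))) {
    h <- hw[1]; w <- hw[2]
    v <- view_image(matrix(1L, h, w), "LCC")
    f <- 0.5
    rd <- resize_dims(h, w, f)
    r <- resize_view(v, f)
    expect_equal(dim(r$pixels), rd)
    cd <- crop_dims(rd[1], rd[2])
    expect_equal(dim(crop_view(r)$pixels), cd)
  }
})

test_that("side-input masks descend from the original lesion masks", {
  s <- generate_study(13, "malignant", 256, 320, 0.8)
  pp <- preprocess_study(s, 0.3)
  present_sides <- c(left = s$masks$LCC$present || s$masks$LMLO$present,
                     right = s$masks$RCC$present || s$masks$RMLO$present)
  for (side in c("left", "right")) {
    si <- pp[[side]]
    if (!present_sides[[side]]) {
      expect_true(all(!si$mask))
      next
    }
    expect_gt(sum(si$mask), 0)
    # mask pixels must sit on bright (lesion) image regions, not background
    expect_gt(mean(si$pixels[si$mask]), mean(si$pixels[!si$mask]))
  }
})

test_that("preprocessing is deterministic", {
  s <- generate_study(14, "benign", 128, 160)
  a <- preprocess_study(s, 0.3)
  b <- preprocess_study(s, 0.3)
  expect_identical(a$left$pixels, b$left$pixels)
  expect_identical(a$right$pixels, b$right$pixels)
})
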