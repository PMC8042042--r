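test_that("reference cohort composition and default weights are consistent", {
  counts <- reference_class_counts()
  w <- default_class_weights()
  expect_equal(sum(w), 1)
  expect_equal(w, counts / sum(counts))
  expect_true(abs(sum(counts[c("normal", "benign")]) / counts["malignant"] -
                    4.2) < 0.3)  # roughly 4:1 non-malignant:malignant
})

test_that("generate_study honours the label contracts", {
  s_norm <- generate_study(1, "normal", 256, 320, 0.8)
  expect_false(any(vapply(s_norm$masks, `[[`, TRUE, "present")))
  expect_equal(s_norm$birads, 1L)

  s_ben <- generate_study(2, "benign", 256, 320, 0.8)
  expect_false(any(vapply(s_ben$masks, `[[`, TRUE, "present")))
  expect_true(s_ben$birads %in% 2:3)

  s_mal <- generate_study(3, "malignant", 256, 320, 0.8)
  expect_true(any(vapply(s_mal$masks, `[[`, TRUE, "present")))
  expect_true(s_mal$birads %in% 4:5)

  expect_error(generate_study(1, "weird", 256, 320), "arg")
  expect_error(generate_study(1, "normal", 32, 32), "64")
})

test_that("generation is a pure function of the seed", {
  a <- generate_study(1, "malignant", 128, 160, 0.8)
  b <- generate_study(1, "malignant", 128, 160, 0.8)
  for (tag in names(a$views))
    expect_identical(a$views[[tag]]$pixels, b$views[[tag]]$pixels)
  c <- generate_study(2, "malignant", 128, 160, 0.8)
  expect_false(identical(a$views$LCC$pixels, c$views$LCC$pixels))
})

test_that("lesion interior is brighter than surrounding tissue", {
  for (seed in c(7, 17, 27)) {
    s <- generate_study(seed, "malignant", 256, 320, 0.8)
    present <- names(which(vapply(s$masks, `[[`, TRUE, "present")))
    expect_gt(length(present), 0)
    for (tag in present) {
      px <- s$views[[tag]]$pixels
      mk <- s$masks[[tag]]$mask
      tissue <- px > 10000 & !mk
      expect_gt(mean(px[mk]), mean(px[tissue]))
    }
  }
  # holds down to modest separability
  s <- generate_study(7, "malignant", 256, 320, 0.25)
  tag <- names(which(vapply(s$masks, `[[`, TRUE, "present")))[1]
  px <- s$views[[tag]]$pixels
  mk <- s$masks[[tag]]$mask
  expect_gt(mean(px[mk]), mean(px[px > 10000 & !mk]))
})

test_that("tissue sits against the chest-wall edge the crop keeps", {
  s <- generate_study(4, "normal", width = 128, height = 160)
  lcc <- s$views$LCC$pixels                    # 160 x 128 (h x w)
  rcc <- s$views$RCC$pixels
  # left-laterality tissue occupies the left columns, right the right
  expect_gt(mean(lcc[, 1:32]), mean(lcc[, 97:128]))
  expect_gt(mean(rcc[, 97:128]), mean(rcc[, 1:32]))
})

test_that("generate_cohort conserves counts and respects weights", {
  co <- generate_cohort(3, 100, c(0.62, 0.18, 0.20), 64, 80)
  expect_length(co$studies, 100)
  expect_equal(nrow(co$manifest), 100)
  expect_setequal(unique(co$manifest$label),
                  intersect(c("normal", "benign", "malignant"),
                            co$manifest$label))

  all_mal <- generate_cohort(3, 50, c(0, 0, 1), 64, 80)
  expect_true(all(all_mal$manifest$label == "malignant"))
  expect_true(all(all_mal$manifest$had_surgery))

  # malignant fraction within 3 binomial sd of its expectation
  co5 <- generate_cohort(5, 500, c(0.62, 0.18, 0.20), 64, 80)
  frac <- mean(co5$manifest$label == "malignant")
  expect_lt(abs(frac - 0.20), 3 * sqrt(0.2 * 0.8 / 500))

  expect_error(generate_cohort(1, 100, c(0.5, 0.6, -0.1)), "non-negative")
  expect_error(generate_cohort(1, 100, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(generate_cohort(1, 5), "at least 10")
})

test_that("cohorts are seed-deterministic and seed-sensitive", {
  a <- generate_cohort(11, 12, width = 64, height = 80)
  b <- generate_cohort(11, 12, width = 64, height = 80)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$studies[[5]]$views$LMLO$pixels,
                   b$studies[[5]]$views$LMLO$pixels)
  c <- generate_cohort(12, 12, width = 64, height = 80)
  expect_false(identical(a$manifest$label, c$manifest$label))
})

test_that("cohort_filter reproduces the hand-enumerated selection", {
  man <- toy_manifest()
  sel <- cohort_filter(man)
  # by hand: A qualifies (>= 365 days, equal BI-RADS) -> latest exam;
  # B fails the interval, C fails equal BI-RADS, D has one exam,
  # E is malignant with surgery -> latest exam, F malignant without surgery
  expect_equal(sel$subject_id, c("A", "E"))
  expect_equal(sel$exam_date, as.Date(c("2015-03-01", "2016-05-01")))
  expect_setequal(attr(sel, "dropped"), c("B", "C", "D", "F"))
})

test_that("cohort_filter is stable on a manifest of selected subjects", {
  man <- toy_manifest()
  sel <- cohort_filter(man)
  kept <- man[man$subject_id %in% sel$subject_id, , drop = FALSE]
  sel2 <- cohort_filter(kept)
  expect_equal(sel2$subject_id, sel$subject_id)
  expect_equal(sel2$exam_date, sel$exam_date)
})

test_that("cohort_filter validates its input", {
  man <- toy_manifest()
  man$exam_date <- as.character(man$exam_date)
  man$exam_date[1] <- "not-a-date"
  expect_error(cohort_filter(man), "invalid exam dates")
  dup <- toy_manifest()[c(1, 1, 2), ]
  expect_error(cohort_filter(dup), "unique")
})

test_that("a cohort round-trips through the on-disk layout", {
  co <- generate_cohort(8, 10, c(0.3, 0.3, 0.4), 64, 80)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back$studies, 10)
  for (i in c(1, 7)) {
    expect_identical(back$studies[[i]]$views$LCC$pixels,
                     co$studies[[i]]$views$LCC$pixels)
    expect_identical(back$studies[[i]]$masks$RMLO$mask,
                     co$studies[[i]]$masks$RMLO$mask)
    expect_equal(back$studies[[i]]$label, co$studies[[i]]$label)
  }
})
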