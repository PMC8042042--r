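# Shared fixture builders.  Everything is generated in code at test time.

# Smallest study size the generator and the three-stage network accept.
tiny_study <- function(seed = 1, label = "normal", separability = 0.8) {
  generate_study(seed, label, width = 64L, height = 80L,
                 separability = separability)
}

# A textured 16-bit image for codec tests (tissue-like band-limited noise).
textured_image <- function(seed = 1, h = 320L, w = 256L) {
  generate_study(seed, "normal", width = w, height = h)$views$LCC$pixels
}

# Hand-written manifest covering the cohort-filter rule branches.
toy_manifest <- function() {
  data.frame(
    subject_id = c("A", "A", "B", "B", "C", "C", "D", "E", "F"),
    exam_date = as.Date(c("2014-01-01", "2015-03-01",   # A: 14 months, same BI-RADS
                          "2014-01-01", "2014-07-01",   # B: 6 months apart
                          "2014-01-01", "2015-06-01",   # C: >1y but BI-RADS differs
                          "2015-01-01",                 # D: single exam
                          "2016-05-01",                 # E: malignant, surgery
                          "2016-06-01")),               # F: malignant, no surgery
    birads = c(1L, 1L, 2L, 2L, 1L, 2L, 3L, 5L, 4L),
    label = c("normal", "normal", "benign", "benign", "normal", "benign",
              "benign", "malignant", "malignant"),
    had_surgery = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Linearly separable side inputs for optimization sanity checks: class 1
# carries a bright block, class 0 does not.  Dimensions admit the three
# conv+pool stages.
separable_inputs <- function(n = 60, h = 64L, w = 64L, seed = 99) {
  crstress:::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lab <- as.integer(i %% 2L == 0L)
      px <- matrix(runif(h * w, 0, 0.2), h, w)
      if (lab == 1L) px[20:34, 20:34] <- px[20:34, 20:34] + 0.6
      crstress:::new_side_input(pmin(px, 1), side = "left", label = lab,
                                subject_id = sprintf("T%03d", i))
    })
  })
}

# Random-noise side inputs with the given labels.
noise_inputs <- function(labels, h = 64L, w = 64L, seed = 7) {
  crstress:::with_seed(seed, {
    lapply(seq_along(labels), function(i) {
      crstress:::new_side_input(matrix(runif(h * w), h, w), side = "left",
                                label = labels[i],
                                subject_id = sprintf("N%03d", i))
    })
  })
}
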