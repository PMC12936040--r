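test_that("background-only channels decode to absent", {
  ch <- array(-10, c(32, 32, 3))
  expect_null(extract_endpoints(ch, "buccal_dehiscence", 0.25))
})

test_that("single-pixel components are rejected as degenerate", {
  ch <- array(-10, c(32, 32, 3))
  ch[16, 16, 1] <- 10
  ch[, , 2] <- 0; ch[, , 3] <- -1
  expect_null(extract_endpoints(ch, "buccal_dehiscence", 0.25))
})

test_that("largest connected component wins over smaller blobs", {
  ann <- slice_annotation(
    "P", "T", 0, 0.25,
    list(landmark_pair("buccal_dehiscence", c(10, 5), c(10, 25))))
  st <- target_as_logits(build_target_stack(ann, c(48, 32)))
  ch <- st[, , 1:3]
  ch[40:41, 28, 1] <- 10   # distractor blob, 2 px
  det <- extract_endpoints(ch, "buccal_dehiscence", 0.25)
  expect_lt(sqrt(sum((det$p2 - c(10, 5))^2)), 1)   # CEJ (coronal)
  expect_lt(sqrt(sum((det$p1 - c(10, 25))^2)), 1)  # ARC (apical)
})

test_that("measure_length applies the pixel pitch linearly", {
  det <- list(p1 = c(0, 0), p2 = c(3, 4))
  expect_equal(measure_length(det, 0.25), 1.25)
  expect_equal(measure_length(det, 0.5), 2.5)
})

test_that("slice classification applies strict thresholds per class", {
  mk <- function(class, len) {
    structure(list(class = class, p1 = c(0, 0), p2 = c(len, 0),
                   length_mm = len, score = 0.9), class = "detection")
  }
  r <- classify_slice(list(mk("buccal_dehiscence", 2.5)))
  expect_true(r$label[r$class == "buccal_dehiscence"])

  for (len in c(1.9, 2.0)) {
    r <- classify_slice(list(mk("lingual_dehiscence", len)))
    expect_false(r$label[r$class == "lingual_dehiscence"], label = len)
  }
  r <- classify_slice(list(mk("buccal_fenestration", 2.2)))
  expect_false(r$label[r$class == "buccal_fenestration"])
  r <- classify_slice(list(mk("buccal_fenestration", 2.3)))
  expect_true(r$label[r$class == "buccal_fenestration"])

  none <- classify_slice(list())
  expect_true(all(!none$label))
  expect_true(all(none$score == 0))
})

test_that("tooth consensus is the AND rule with min score", {
  mk_slice <- function(len, score) {
    det <- structure(list(class = "buccal_dehiscence", p1 = c(0, 0),
                          p2 = c(len, 0), length_mm = len, score = score),
                     class = "detection")
    classify_slice(list(det))
  }
  pos <- diagnose_tooth(list(mk_slice(3, 0.9), mk_slice(3.1, 0.7),
                             mk_slice(2.9, 0.8)))
  row <- pos[pos$class == "buccal_dehiscence", ]
  expect_true(row$tooth_label)
  expect_equal(row$tooth_score, 0.7)

  neg <- diagnose_tooth(list(mk_slice(3, 0.9), mk_slice(3.1, 0.7),
                             mk_slice(1.5, 0.8)))
  expect_false(neg$tooth_label[neg$class == "buccal_dehiscence"])

  expect_error(diagnose_tooth(list(mk_slice(3, 1), mk_slice(3, 1))),
               "exactly 3")
})

test_that("tooth label is monotone in slice labels", {
  combos <- expand.grid(s1 = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                        s3 = c(TRUE, FALSE))
  mk_slice <- function(pos) {
    len <- if (pos) 3 else 1
    det <- structure(list(class = "buccal_dehiscence", p1 = c(0, 0),
                          p2 = c(len, 0), length_mm = len, score = 0.5),
                     class = "detection")
    classify_slice(list(det))
  }
  for (i in seq_len(nrow(combos))) {
    labs <- as.logical(combos[i, ])
    d <- diagnose_tooth(lapply(labs, mk_slice))
    expect_equal(d$tooth_label[d$class == "buccal_dehiscence"], all(labs))
    # flipping any positive slice to negative never turns the tooth positive
    for (j in which(labs)) {
      labs2 <- labs; labs2[j] <- FALSE
      d2 <- diagnose_tooth(lapply(labs2, mk_slice))
      expect_false(d2$tooth_label[d2$class == "buccal_dehiscence"] &&
                     !d$tooth_label[d$class == "buccal_dehiscence"])
    }
  }
})

test_that("heatmap-mode decoding recovers separated endpoints", {
  ann <- slice_annotation(
    "P", "T", 0, 0.25,
    list(landmark_pair("lingual_fenestration", c(12, 10), c(12, 40))))
  st <- build_target_stack(ann, c(64, 32), mode = "heatmap",
                           heatmap = heatmap_spec(2))
  det <- extract_endpoints(st[, , 10:12], "lingual_fenestration", 0.25,
                           mode = "heatmap", sigma_px = 2)
  expect_false(is.null(det))
  expect_lt(sqrt(sum((det$p1 - c(12, 10))^2)), 1.5)  # CB coronal
  expect_lt(sqrt(sum((det$p2 - c(12, 40))^2)), 1.5)  # AB apical
  expect_true(det$score > 0 && det$score <= 1)
})
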