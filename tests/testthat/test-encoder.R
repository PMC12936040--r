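test_that("Gaussian heatmap follows the analytic form without clipping", {
  h <- encode_heatmap(list(c(10, 10)), c(32, 32), heatmap_spec(2))
  expect_equal(h[11, 11], 1.0)
  expect_equal(h[15, 14], exp(-25 / 8), tolerance = 1e-12)
  expect_equal(h[15, 14], 0.04394, tolerance = 1e-4)

  two <- encode_heatmap(list(c(10, 10), c(10, 10)), c(32, 32),
                        heatmap_spec(2))
  expect_equal(max(two), 2.0)

  expect_true(all(h >= 0))
  expect_equal(sum(encode_heatmap(list(), c(8, 8), heatmap_spec(1))), 0)
  expect_error(heatmap_spec(0), "positive")
})

test_that("heatmap global maximum sits on a landmark when peaks are separated", {
  set.seed(2)
  for (i in 1:20) {
    sigma <- runif(1, 1, 3)
    repeat {
      p1 <- runif(2, 5, 58); p2 <- runif(2, 5, 58)
      if (sqrt(sum((p1 - p2)^2)) >= 4 * sigma) break
    }
    h <- encode_heatmap(list(p1, p2), c(64, 64), heatmap_spec(sigma))
    peak <- which(h == max(h), arr.ind = TRUE)[1, ]
    xy <- c(peak[2] - 1, peak[1] - 1)
    d <- min(sqrt(sum((xy - p1)^2)), sqrt(sum((xy - p2)^2)))
    expect_lt(d, 1)
  }
})

test_that("segment masks have the expected area and extent", {
  pair <- landmark_pair("buccal_dehiscence", c(5, 10), c(25, 10))
  m <- encode_mask(pair, c(32, 40), width_px = 3)
  expect_gte(sum(m), 60 - 6)
  expect_lte(sum(m), 60 + 6)
  cols <- range(which(colSums(m) > 0)) - 1
  expect_lte(abs(cols[1] - 5), 1)
  expect_lte(abs(cols[2] - 25), 1)
  expect_error(encode_mask(landmark_pair("buccal_dehiscence", c(0, 0),
                                         c(5, 5)), c(10, 10), 0), "width")
})

test_that("direction fields are unit-norm and follow apex-to-crown", {
  # vertical pair: for dehiscence the larger-y endpoint is apical, so the
  # field points upward (negative y)
  pair <- landmark_pair("buccal_dehiscence", c(0, 10), c(0, 0))
  m <- encode_mask(pair, c(16, 8))
  d <- encode_direction(pair, m)
  expect_equal(unique(d$dy[m > 0]), -1)
  expect_equal(unique(d$dx[m > 0]), 0)

  # 3-4-5 fenestration: AB (p2) -> CB (p1)
  pair2 <- landmark_pair("buccal_fenestration", c(3, 0), c(0, 4))
  m2 <- encode_mask(pair2, c(12, 12))
  d2 <- encode_direction(pair2, m2)
  expect_equal(unique(d2$dx[m2 > 0]), 0.6)
  expect_equal(unique(d2$dy[m2 > 0]), -0.8)

  norms <- sqrt(d2$dx^2 + d2$dy^2)
  expect_equal(sum(norms), sum(m2), tolerance = 1e-6)
  expect_true(all(norms[m2 == 0] == 0))
})

test_that("target stacks respect the channel-group layout", {
  ann <- slice_annotation(
    "P", "T", 0, 0.25,
    list(landmark_pair("buccal_fenestration", c(10, 20), c(10, 40))))
  st <- build_target_stack(ann, c(64, 48))
  expect_equal(dim(st), c(64, 48, 12))
  expect_true(all(st[, , c(1:6, 10:12)] == 0))
  expect_gt(sum(st[, , 7]), 0)

  empty <- build_target_stack(slice_annotation("P", "T", 0, 0.25), c(64, 48))
  expect_true(all(empty == 0))
})

test_that("heatmap-mode stacks place two local maxima at the endpoints", {
  ann <- slice_annotation(
    "P", "T", 0, 0.25,
    list(landmark_pair("lingual_dehiscence", c(20, 10), c(20, 40))))
  st <- build_target_stack(ann, c(64, 48), mode = "heatmap",
                           heatmap = heatmap_spec(2))
  h <- st[, , 4]
  # oracle: exhaustive local-maximum scan over 3x3 neighborhoods
  peaks <- list()
  for (r in 2:63) for (cc in 2:47) {
    if (h[r, cc] > 0.5 && h[r, cc] == max(h[(r - 1):(r + 1),
                                            (cc - 1):(cc + 1)])) {
      peaks[[length(peaks) + 1L]] <- c(cc - 1, r - 1)
    }
  }
  expect_equal(length(peaks), 2)
  ds <- sapply(peaks, function(p) min(sqrt(sum((p - c(20, 10))^2)),
                                      sqrt(sum((p - c(20, 40))^2))))
  expect_true(all(ds < 1))
})

test_that("encode then decode recovers endpoints on noiseless targets", {
  set.seed(7)
  spec <- clean_spec()
  for (i in 1:6) {
    sl <- random_annotated_slice(spec, seed = 1000 + i)
    ann <- sl$annotation
    st <- target_as_logits(build_target_stack(ann, dim(sl$image$pixels)))
    dets <- decode_stack(st, ann$pixel_pitch_mm)
    for (d in ann$defects) {
      det <- dets[[d$class]]
      expect_false(is.null(det), label = d$class)
      expect_lt(sqrt(sum((det$p1 - d$p1)^2)), 1)
      expect_lt(sqrt(sum((det$p2 - d$p2)^2)), 1)
      expect_lt(abs(det$length_mm -
                      px_to_mm(pair_length_px(d), ann$pixel_pitch_mm)),
                ann$pixel_pitch_mm * sqrt(2))
    }
  }
})
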