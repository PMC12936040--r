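# Evaluation-report assembly checked against hand-built detection tables,
# independent of the network.

.mk_det_tbl <- function(rows) {
  dc <- defect_classes()
  purrr::map_dfr(rows, function(r) {
    thr <- dc$threshold_mm[dc$class == r$class]
    tibble::tibble(
      patient_id = r$pid, tooth_id = r$tid, slice_index = r$k,
      pixel_pitch_mm = 0.25, class = r$class,
      detected = !is.null(r$len) && !is.na(r$len),
      x1 = r$x %||% NA_real_, y1 = r$y %||% NA_real_,
      x2 = (r$x %||% NA_real_) + (r$len %||% 0) / 0.25,
      y2 = r$y %||% NA_real_,
      length_mm = r$len %||% NA_real_,
      score = r$score %||% 0,
      label = isTRUE((r$len %||% 0) > thr))
  })
}

.mk_truth_tbl <- function(rows) {
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      patient_id = r$pid, tooth_id = r$tid, slice_index = r$k,
      pixel_pitch_mm = 0.25, class = r$class %||% NA_character_,
      x1 = r$x %||% NA_real_, y1 = r$y %||% NA_real_,
      x2 = (r$x %||% NA_real_) + (r$len %||% 0) / 0.25,
      y2 = r$y %||% NA_real_,
      length_mm = r$len %||% NA_real_)
  })
}

test_that("a perfect detector scores perfectly at both granularities", {
  rows <- list()
  for (t in c("T1", "T2")) {
    for (k in 0:2) {
      len <- if (t == "T1") 3.0 else 1.0   # T1 positive, T2 sub-threshold
      rows[[length(rows) + 1L]] <- list(pid = "P1", tid = t, k = k,
                                        class = "buccal_dehiscence",
                                        x = 10, y = 10 + k, len = len,
                                        score = if (t == "T1") 0.9 else 0.4)
    }
  }
  det <- .mk_det_tbl(rows)
  truth <- .mk_truth_tbl(rows)
  rep <- evaluate_detections(det, truth, tolerance_mm = 2)
  expect_equal(rep$keypoints$recognition_rate, 1)
  bd <- rep$image[rep$image$class == "buccal_dehiscence", ]
  expect_equal(bd$accuracy, 1)
  expect_equal(bd$recall, 1)
  expect_equal(bd$AUC, 1)
  tl <- rep$tooth[rep$tooth$class == "buccal_dehiscence", ]
  expect_equal(tl$accuracy, 1)
  expect_equal(rep$lengths$MAE[rep$lengths$class == "buccal_dehiscence"], 0)
  expect_equal(rep$agreement$bias, 0)
})

test_that("missed detections lower recall and recognition but not specificity", {
  rows_truth <- list(
    list(pid = "P1", tid = "T1", k = 0, class = "buccal_fenestration",
         x = 10, y = 10, len = 3.0),
    list(pid = "P1", tid = "T1", k = 1, class = "buccal_fenestration",
         x = 10, y = 10, len = 3.0),
    list(pid = "P1", tid = "T1", k = 2, class = "buccal_fenestration",
         x = 10, y = 10, len = 3.0),
    list(pid = "P1", tid = "T2", k = 0), list(pid = "P1", tid = "T2", k = 1),
    list(pid = "P1", tid = "T2", k = 2))
  truth <- .mk_truth_tbl(rows_truth)
  det <- .mk_det_tbl(list(
    list(pid = "P1", tid = "T1", k = 0, class = "buccal_fenestration",
         x = 10, y = 10, len = 3.0, score = 0.9)))
  rep <- evaluate_detections(det, truth, tolerance_mm = 2)
  expect_equal(rep$keypoints$recognition_rate, 1 / 3)
  bf <- rep$image[rep$image$class == "buccal_fenestration", ]
  expect_equal(bf$recall, 1 / 3)
  expect_equal(bf$specificity, 1)
  # tooth-level consensus fails with two missing slices
  tl <- rep$tooth[rep$tooth$class == "buccal_fenestration", ]
  expect_equal(tl$recall, 0)
})

test_that("tooth-level consensus in reports follows the AND rule", {
  rows_truth <- list()
  for (k in 0:2) {
    rows_truth[[k + 1]] <- list(pid = "P1", tid = "T1", k = k,
                                class = "lingual_dehiscence", x = 5, y = 5,
                                len = 4)
  }
  truth <- .mk_truth_tbl(rows_truth)
  # predicted positive on only 2 of 3 slices
  det <- .mk_det_tbl(list(
    list(pid = "P1", tid = "T1", k = 0, class = "lingual_dehiscence",
         x = 5, y = 5, len = 4, score = .8),
    list(pid = "P1", tid = "T1", k = 1, class = "lingual_dehiscence",
         x = 5, y = 5, len = 4, score = .8),
    list(pid = "P1", tid = "T1", k = 2, class = "lingual_dehiscence",
         x = 5, y = 5, len = 1, score = .2)))
  rep <- evaluate_detections(det, truth, tolerance_mm = 2)
  ld_img <- rep$image[rep$image$class == "lingual_dehiscence", ]
  expect_equal(ld_img$TP, 2L); expect_equal(ld_img$FN, 1L)
  ld_tooth <- rep$tooth_labels[rep$tooth_labels$class == "lingual_dehiscence", ]
  expect_true(ld_tooth$true_label)
  expect_false(ld_tooth$pred_label)
  expect_equal(ld_tooth$score, 0.2)
})

test_that("report writing emits the JSON and CSV artifacts", {
  rows <- list()
  for (t in c("T1", "T2")) for (k in 0:2) {
    rows[[length(rows) + 1L]] <- list(pid = "P1", tid = t, k = k,
                                      class = "buccal_dehiscence",
                                      x = 10, y = 10,
                                      len = if (t == "T1") 3 else 1,
                                      score = if (t == "T1") .9 else .1)
  }
  rep <- evaluate_detections(.mk_det_tbl(rows), .mk_truth_tbl(rows), 2)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "image_detection.csv")))
  expect_true(file.exists(file.path(dir, "keypoint_rates.csv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$keypoints$recognition_rate, 1)
  # layout: metrics as rows, classes as columns
  tab <- readr::read_csv(file.path(dir, "image_detection.csv"),
                         show_col_types = FALSE)
  expect_true("metric" %in% names(tab))
  expect_true("buccal_dehiscence" %in% names(tab))
})

test_that("glance and tidy summarize a report", {
  rows <- list()
  for (t in c("T1", "T2")) for (k in 0:2) {
    rows[[length(rows) + 1L]] <- list(pid = "P1", tid = t, k = k,
                                      class = "lingual_fenestration",
                                      x = 4, y = 6,
                                      len = if (t == "T1") 3.5 else 1.2,
                                      score = if (t == "T1") .8 else .2)
  }
  rep <- evaluate_detections(.mk_det_tbl(rows), .mk_truth_tbl(rows), 2)
  g <- glance(rep)
  expect_equal(g$recognition_rate, 1)
  td <- tidy(rep)
  expect_true(all(c("class", "metric", "value", "granularity") %in%
                    names(td)))
})
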