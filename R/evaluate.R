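#' Predict detections for a list of slices
#'
#' Standardizes the raw slices, runs the network in batches and decodes each
#' 12-channel prediction into per-class endpoint detections.
#'
#' @param model A `swin_unetr`.
#' @param images List of intensity matrices (raw 0..255 render scale).
#' @param pixel_pitch_mm Millimetres per pixel.
#' @param mode Decoding mode matching the supervision mode.
#' @param mask_threshold Sigmoid threshold of the mask decoder.
#' @param sigma_px Heatmap sigma (heatmap mode).
#' @param batch_size Slices per forward pass.
#' @return List (one per slice) of [decode_stack()] results.
#' @export
predict_slices <- function(model, images, pixel_pitch_mm,
                           mode = c("mask_direction", "heatmap"),
                           mask_threshold = 0.5, sigma_px = 2,
                           batch_size = 8L,
                           boundary_level = mask_threshold) {
  mode <- match.arg(mode)
  out <- vector("list", length(images))
  idx <- split(seq_along(images), ceiling(seq_along(images) / batch_size))
  for (ix in idx) {
    H <- nrow(images[[ix[1]]]); W <- ncol(images[[ix[1]]])
    arr <- array(0, c(H, W, length(ix)))
    for (j in seq_along(ix)) arr[, , j] <- standardize(images[[ix[j]]])
    pred <- ad_no_grad(net_forward(model, arr))
    for (j in seq_along(ix)) {
      out[[ix[j]]] <- decode_stack(pred[, , , j], pixel_pitch_mm, mode,
                                   mask_threshold, sigma_px, boundary_level)
    }
  }
  out
}

.add_slice_id <- function(tbl) {
  dplyr::mutate(tbl, slice_id = paste(.data$tooth_id, .data$slice_index,
                                      sep = "#"))
}

# long keypoint table (one row per endpoint) from a detection/annotation table
.keypoint_table <- function(tbl) {
  dc <- defect_classes()
  rows <- dplyr::filter(tbl, !is.na(.data$class))
  if (!nrow(rows)) {
    return(tibble::tibble(slice_id = character(), class = character(),
                          role = character(), x = numeric(), y = numeric(),
                          pixel_pitch_mm = numeric()))
  }
  rows <- dplyr::left_join(rows, dc[, c("class", "role_p1", "role_p2")],
                           by = "class")
  dplyr::bind_rows(
    dplyr::transmute(rows, slice_id = .data$slice_id, class = .data$class,
                     role = .data$role_p1, x = .data$x1, y = .data$y1,
                     pixel_pitch_mm = .data$pixel_pitch_mm),
    dplyr::transmute(rows, slice_id = .data$slice_id, class = .data$class,
                     role = .data$role_p2, x = .data$x2, y = .data$y2,
                     pixel_pitch_mm = .data$pixel_pitch_mm))
}

# per-slice-per-class truth/prediction label grid
.label_grid <- function(det, truth) {
  dc <- defect_classes()
  slices <- dplyr::distinct(truth, .data$tooth_id, .data$slice_index,
                            .data$slice_id)
  grid <- tidyr::crossing(slices, class = dc$class)
  grid <- dplyr::left_join(grid, dc[, c("class", "threshold_mm")],
                           by = "class")
  tl <- dplyr::filter(truth, !is.na(.data$class))
  tl <- dplyr::transmute(tl, slice_id = .data$slice_id, class = .data$class,
                         true_length = .data$length_mm)
  grid <- dplyr::left_join(grid, tl, by = c("slice_id", "class"))
  pd <- dplyr::transmute(det, slice_id = .data$slice_id, class = .data$class,
                         pred_length = .data$length_mm,
                         score = .data$score, pred_label = .data$label)
  grid <- dplyr::left_join(grid, pd, by = c("slice_id", "class"))
  dplyr::mutate(grid,
                true_label = !is.na(.data$true_length) &
                  .data$true_length > .data$threshold_mm,
                pred_label = dplyr::coalesce(.data$pred_label, FALSE),
                score = dplyr::coalesce(.data$score, 0))
}

.class_confusion <- function(grid, truth_col, pred_col) {
  dplyr::summarise(
    dplyr::group_by(grid, .data$class),
    TP = sum(.data[[truth_col]] & .data[[pred_col]]),
    TN = sum(!.data[[truth_col]] & !.data[[pred_col]]),
    FP = sum(!.data[[truth_col]] & .data[[pred_col]]),
    FN = sum(.data[[truth_col]] & !.data[[pred_col]]),
    .groups = "drop")
}

.classification_by_class <- function(grid, truth_col = "true_label",
                                     pred_col = "pred_label",
                                     score_col = "score") {
  conf <- .class_confusion(grid, truth_col, pred_col)
  stats <- purrr::map_dfr(seq_len(nrow(conf)), function(i) {
    s <- classification_stats(confusion_counts(conf$TP[i], conf$TN[i],
                                               conf$FP[i], conf$FN[i]))
    dplyr::mutate(s, class = conf$class[i], .before = 1)
  })
  aucs <- purrr::map_dfr(unique(grid$class), function(cl) {
    g <- grid[grid$class == cl, ]
    auc <- NA_real_
    curve <- NULL
    if (length(unique(g[[truth_col]])) == 2L) {
      r <- roc_auc(g[[score_col]], g[[truth_col]])
      auc <- r$auc
      curve <- dplyr::mutate(r$curve, class = cl)
    }
    tibble::tibble(class = cl, AUC = auc, curve = list(curve))
  })
  stats <- dplyr::left_join(stats, aucs[, c("class", "AUC")], by = "class")
  list(stats = stats,
       roc = dplyr::bind_rows(purrr::compact(aucs$curve)))
}

#' Evaluate detections against ground-truth annotations
#'
#' The full evaluation protocol: keypoint recognition rate and Euclidean
#' distance statistics (with a tolerance sweep), length accuracy
#' (MAE/RMSE/MRE/PCC), Bland-Altman agreement, and per-class
#' accuracy/recall/precision/specificity/F1/AUC at both the individual-image
#' and the tooth (three-slice consensus) level.
#'
#' @param detections Tibble from [detection_table()].
#' @param truth Tibble from [annotation_table()] covering the same slices.
#' @param tolerance_mm Keypoint match tolerance (default 2 mm).
#' @return An `evaluation_report` object (a list of tibbles).
#' @export
evaluate_detections <- function(detections, truth, tolerance_mm = 2) {
  det <- .add_slice_id(detections)
  tru <- .add_slice_id(truth)

  kp_pred <- .keypoint_table(dplyr::filter(det, .data$detected))
  kp_true <- .keypoint_table(tru)
  overall <- match_keypoints(kp_pred, kp_true, tolerance_mm)
  rate_by_class <- purrr::map_dfr(unique(kp_true$class), function(cl) {
    m <- match_keypoints(kp_pred[kp_pred$class == cl, ],
                         kp_true[kp_true$class == cl, ], tolerance_mm)
    tibble::tibble(class = cl, recognition_rate = m$rate,
                   n_truth = m$n_truth, n_recognized = m$n_recognized)
  })
  if (nrow(overall$distances)) {
    kp_stats <- dplyr::group_by(overall$distances, .data$class, .data$role)
    kp_stats <- dplyr::reframe(kp_stats, keypoint_stats(.data$dist_mm))
  } else {
    kp_stats <- tibble::tibble(class = character(), role = character(),
                               AED = numeric(), SD = numeric(),
                               Q1 = numeric(), median = numeric(),
                               Q3 = numeric(), n = integer())
  }
  sweep <- purrr::map_dfr(seq(0.25, 4, by = 0.25), function(tol) {
    m <- match_keypoints(kp_pred, kp_true, tol)
    tibble::tibble(tolerance_mm = tol, recognition_rate = m$rate)
  })

  # length pairs: truth defect present and a detection of the same class
  td <- dplyr::filter(tru, !is.na(.data$class))
  pairs <- dplyr::inner_join(
    dplyr::transmute(td, slice_id = .data$slice_id, class = .data$class,
                     true_mm = .data$length_mm),
    dplyr::transmute(dplyr::filter(det, .data$detected),
                     slice_id = .data$slice_id, class = .data$class,
                     pred_mm = .data$length_mm),
    by = c("slice_id", "class"))
  empty_lengths <- tibble::tibble(class = character(), MAE = numeric(),
                                  RMSE = numeric(), MRE = numeric(),
                                  PCC = numeric(), n = integer())
  lengths <- purrr::map_dfr(unique(pairs$class), function(cl) {
    p <- pairs[pairs$class == cl, ]
    if (nrow(p) < 2L) return(tibble::tibble(class = cl, MAE = NA_real_,
                                            RMSE = NA_real_, MRE = NA_real_,
                                            PCC = NA_real_, n = nrow(p)))
    dplyr::mutate(length_stats(p$pred_mm, p$true_mm), class = cl,
                  .before = 1)
  })
  if (!nrow(lengths)) lengths <- empty_lengths
  agreement <- purrr::map_dfr(unique(pairs$class), function(cl) {
    p <- pairs[pairs$class == cl, ]
    if (nrow(p) < 2L) return(NULL)
    dplyr::mutate(bland_altman(p$pred_mm, p$true_mm), class = cl,
                  .before = 1)
  })

  grid <- .label_grid(det, tru)
  image_cls <- .classification_by_class(grid)

  tooth <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(grid,
                                  tooth_id = sub("#.*$", "", .data$slice_id)),
                    .data$tooth_id, .data$class),
    true_label = all(.data$true_label), pred_label = all(.data$pred_label),
    score = min(.data$score), .groups = "drop")
  tooth_cls <- .classification_by_class(tooth)

  structure(list(
    tolerance_mm = tolerance_mm,
    keypoints = list(recognition_rate = overall$rate,
                     by_class = rate_by_class, stats = kp_stats,
                     tolerance_sweep = sweep,
                     distances = overall$distances),
    lengths = lengths, agreement = agreement, length_pairs = pairs,
    image = image_cls$stats, image_roc = image_cls$roc,
    tooth = tooth_cls$stats, tooth_roc = tooth_cls$roc,
    tooth_labels = tooth,
    n_slices = dplyr::n_distinct(tru$slice_id)),
    class = "evaluation_report")
}

#' Evaluate a fitted model on one subset of a dataset
#'
#' @param fit A `fenestra_fit` from [train_model()].
#' @param dataset The dataset the fit's split refers to.
#' @param subset `"test"` (default), `"val"` or `"train"`.
#' @param tolerance_mm Keypoint tolerance.
#' @param mask_threshold Decoder threshold.
#' @return List with `report` (an `evaluation_report`), `detections` and
#'   `truth` tables.
#' @export
evaluate_model <- function(fit, dataset, subset = "test", tolerance_mm = 2,
                           mask_threshold = 0.5) {
  recs <- .dataset_slices(dataset, fit$split, subset)
  if (!length(recs)) stop("no slices in subset ", subset, call. = FALSE)
  images <- lapply(recs, `[[`, "image")
  pw <- rep(fit$config$pos_weight %||% 1, length.out = 4L)
  dets <- predict_slices(fit$model, images, recs[[1]]$pixel_pitch_mm,
                         mode = fit$config$landmark_mode,
                         mask_threshold = mask_threshold,
                         sigma_px = fit$config$sigma_px,
                         boundary_level = pmax(mask_threshold,
                                               pw / (1 + pw)))
  meta <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(patient_id = r$patient_id, tooth_id = r$tooth_id,
                   slice_index = r$slice_index,
                   pixel_pitch_mm = r$pixel_pitch_mm)
  })
  det_tbl <- detection_table(dets, meta)
  truth <- annotation_table(lapply(recs, `[[`, "annotation"))
  list(report = evaluate_detections(det_tbl, truth, tolerance_mm),
       detections = det_tbl, truth = truth)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d slices, tolerance %.2g mm\n",
              x$n_slices, x$tolerance_mm))
  cat(sprintf("  keypoint recognition rate: %.3f\n",
              x$keypoints$recognition_rate))
  if (nrow(x$lengths)) {
    cat(sprintf("  length PCC: %s\n",
                paste(sprintf("%s %.3f", x$lengths$class, x$lengths$PCC),
                      collapse = ", ")))
  }
  cat(sprintf("  image-level accuracy: %s\n",
              paste(sprintf("%s %.3f", x$image$class, x$image$accuracy),
                    collapse = ", ")))
  invisible(x)
}

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  num <- function(tbl, granularity) {
    tidyr::pivot_longer(tbl, cols = dplyr::where(is.numeric),
                        names_to = "metric", values_to = "value") |>
      dplyr::mutate(granularity = granularity)
  }
  dplyr::bind_rows(
    num(x$lengths, "image"),
    num(x$image, "image"),
    num(x$tooth, "tooth"),
    num(x$keypoints$by_class, "image"))
}

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    recognition_rate = x$keypoints$recognition_rate,
    mean_pcc = mean(x$lengths$PCC, na.rm = TRUE),
    mean_image_accuracy = mean(x$image$accuracy, na.rm = TRUE),
    mean_tooth_accuracy = mean(x$tooth$accuracy, na.rm = TRUE),
    n_slices = x$n_slices)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` plus CSV tables (metrics as rows, defect classes as
#' columns, mirroring the clinical reporting layout) and ROC point files.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- function(tbl, drop = c("TP", "TN", "FP", "FN", "n")) {
    if (!nrow(tbl) || !"class" %in% names(tbl)) {
      return(tibble::tibble(metric = character()))
    }
    tbl <- tbl[, setdiff(names(tbl), drop)]
    long <- tidyr::pivot_longer(tbl, -"class", names_to = "metric")
    tidyr::pivot_wider(long, names_from = "class", values_from = "value")
  }
  readr::write_csv(wide(report$lengths), file.path(dir, "length_accuracy.csv"))
  readr::write_csv(wide(report$image), file.path(dir, "image_detection.csv"))
  readr::write_csv(wide(report$tooth), file.path(dir, "tooth_detection.csv"))
  if (nrow(report$agreement)) {
    readr::write_csv(wide(report$agreement),
                     file.path(dir, "bland_altman.csv"))
  }
  readr::write_csv(report$keypoints$stats, file.path(dir, "keypoint_stats.csv"))
  readr::write_csv(report$keypoints$by_class,
                   file.path(dir, "keypoint_rates.csv"))
  readr::write_csv(report$keypoints$tolerance_sweep,
                   file.path(dir, "tolerance_sweep.csv"))
  if (nrow(report$image_roc)) {
    readr::write_csv(report$image_roc, file.path(dir, "roc_image.csv"))
  }
  if (nrow(report$tooth_roc)) {
    readr::write_csv(report$tooth_roc, file.path(dir, "roc_tooth.csv"))
  }
  json <- list(
    tolerance_mm = report$tolerance_mm, n_slices = report$n_slices,
    keypoints = list(recognition_rate = report$keypoints$recognition_rate,
                     by_class = report$keypoints$by_class,
                     stats = report$keypoints$stats),
    lengths = report$lengths, agreement = report$agreement,
    image = report$image, tooth = report$tooth)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(dir)
}
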