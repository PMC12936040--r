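#' Match predicted keypoints to ground truth
#'
#' A truth keypoint is "recognized" when a predicted keypoint with the same
#' slice, class and endpoint role lies within `tolerance_mm` of it. The
#' recognition rate is the recognized fraction of all truth keypoints;
#' Euclidean distances are collected over recognized points only (the rate
#' is reported alongside, so unmatched points are visible, not silently
#' averaged in).
#'
#' @param predicted,truth Tibbles with columns `slice_id`, `class`, `role`,
#'   `x`, `y` (pixels) and `pixel_pitch_mm`.
#' @param tolerance_mm Match tolerance in millimetres (> 0; default 2).
#' @return List with `rate`, `n_truth`, `n_recognized` and `distances`
#'   (a tibble of recognized pairs with their distance in mm).
#' @export
match_keypoints <- function(predicted, truth, tolerance_mm = 2) {
  if (tolerance_mm <= 0) stop("tolerance_mm must be positive", call. = FALSE)
  if (!nrow(truth)) stop("truth keypoint set is empty", call. = FALSE)
  joined <- dplyr::left_join(
    truth, predicted, by = c("slice_id", "class", "role"),
    suffix = c("", "_pred"), relationship = "many-to-many")
  joined <- dplyr::mutate(
    joined,
    dist_mm = sqrt((.data$x - .data$x_pred)^2 + (.data$y - .data$y_pred)^2) *
      .data$pixel_pitch_mm)
  # keep the closest prediction per truth point
  joined <- dplyr::slice_min(
    dplyr::group_by(joined, .data$slice_id, .data$class, .data$role),
    .data$dist_mm, n = 1, with_ties = FALSE, na_rm = FALSE)
  joined <- dplyr::ungroup(joined)
  rec <- dplyr::filter(joined, !is.na(.data$dist_mm),
                       .data$dist_mm <= tolerance_mm)
  list(rate = nrow(rec) / nrow(truth), n_truth = nrow(truth),
       n_recognized = nrow(rec),
       distances = dplyr::select(rec, "slice_id", "class", "role", "dist_mm"))
}

#' Summary statistics of keypoint localization errors
#'
#' @param distances Numeric vector of Euclidean distances (mm), nonempty.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A tibble with `AED` (mean), `SD`, `Q1`, `median`, `Q3` (linear
#'   interpolation quantiles) and `n`.
#' @export
keypoint_stats <- function(distances, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!length(distances)) stop("no distances supplied", call. = FALSE)
  n <- length(distances)
  if (n == 1L) {
    message("keypoint_stats(): single sample; SD reported as 0 (population)")
    s <- 0
  } else if (sd_type == "sample") {
    s <- stats::sd(distances)
  } else {
    s <- sqrt(mean((distances - mean(distances))^2))
  }
  q <- stats::quantile(distances, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(AED = mean(distances), SD = s, Q1 = q[1], median = q[2],
                 Q3 = q[3], n = n)
}

#' Length measurement accuracy
#'
#' Mean absolute error, root mean squared error, mean relative error
#' (against the ground-truth denominator) and Pearson correlation between
#' predicted and true defect lengths.
#'
#' @param predicted_mm,true_mm Paired numeric vectors; `true_mm` must be
#'   positive for the relative error.
#' @return A tibble with `MAE`, `RMSE`, `MRE`, `PCC` and `n`. `PCC` is `NA`
#'   (flagged with a warning) when fewer than 2 pairs are available.
#' @export
length_stats <- function(predicted_mm, true_mm) {
  stopifnot(length(predicted_mm) == length(true_mm))
  if (any(true_mm <= 0)) stop("true lengths must be positive", call. = FALSE)
  err <- predicted_mm - true_mm
  pcc <- if (length(true_mm) < 2L) {
    warning("PCC undefined for fewer than 2 pairs", call. = FALSE)
    NA_real_
  } else {
    stats::cor(predicted_mm, true_mm)
  }
  tibble::tibble(MAE = mean(abs(err)), RMSE = sqrt(mean(err^2)),
                 MRE = mean(abs(err) / true_mm), PCC = pcc,
                 n = length(err))
}

#' Bland-Altman agreement between predicted and true measurements
#'
#' Bias is the mean predicted-minus-true difference; the 95% limits of
#' agreement are `bias +/- 1.96 * SD(differences)`.
#'
#' @param predicted,true Paired numeric vectors, `n >= 2`.
#' @return A tibble with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(predicted, true) {
  stopifnot(length(predicted) == length(true))
  if (length(predicted) < 2L) {
    stop("Bland-Altman analysis requires n >= 2", call. = FALSE)
  }
  d <- predicted - true
  s <- stats::sd(d)
  tibble::tibble(bias = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, sd_diff = s,
                 n = length(d))
}

#' Confusion counts
#' @param TP,TN,FP,FN Nonnegative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Classification statistics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)` and F1
#' `2*precision*recall/(precision+recall)`. A ratio with zero denominator is
#' reported as `NA`, not 0.
#'
#' @param counts A [confusion_counts()] object, or TP when giving the four
#'   counts positionally.
#' @param TN,FP,FN Remaining counts when not using a `confusion_counts`.
#' @return A tibble with `accuracy`, `recall`, `precision`, `specificity`,
#'   `F1` and the four counts.
#' @export
classification_stats <- function(counts, TN = NULL, FP = NULL, FN = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts, TN, FP, FN)
  }
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- ratio(TP, TP + FN)
  precision <- ratio(TP, TP + FP)
  f1 <- if (is.na(recall) || is.na(precision) || (precision + recall) == 0) {
    if (!is.na(recall) && !is.na(precision)) 0 else NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(accuracy = ratio(TP + TN, total), recall = recall,
                 precision = precision, specificity = ratio(TN, TN + FP),
                 F1 = f1, TP = TP, TN = TN, FP = FP, FN = FN)
}

#' ROC curve and AUC
#'
#' Trapezoidal area under the ROC curve over all score thresholds, equal to
#' the probability that a random positive outscores a random negative with
#' ties counted one half.
#'
#' @param scores Numeric confidence scores (higher = more positive).
#' @param labels Logical (or 0/1) true labels; both classes must be present.
#' @return List with `auc` and `curve`, a tibble of `threshold`, `fpr`,
#'   `tpr` points.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stop("roc_auc() requires both label classes", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  curve <- tibble::tibble(threshold = r$thresholds,
                          fpr = 1 - r$specificities,
                          tpr = r$sensitivities)
  curve <- dplyr::arrange(curve, .data$fpr, .data$tpr)
  list(auc = as.numeric(r$auc), curve = curve)
}

#' Cohen's kappa between two label vectors
#'
#' Generic chance-corrected agreement utility for two categorical vectors of
#' equal length.
#'
#' @param a,b Vectors of labels.
#' @return Kappa coefficient.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- union(unique(a), unique(b))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
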