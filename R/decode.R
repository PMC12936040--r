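.sigmoid <- function(x) 1 / (1 + exp(-x))

# Largest 8-connected component of a binary matrix; size ties broken by the
# first component in scan order. Returns a logical matrix, or NULL when the
# input is empty.
.largest_component <- function(bin) {
  if (!any(bin)) return(NULL)
  lab <- label_components(bin)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  lab == best
}

# Greedy non-maximum suppression peak picking on a heatmap.
.heatmap_peaks <- function(h, radius, floor_frac = 0.2) {
  floor_val <- floor_frac * max(1, max(h))
  cand <- which(h > floor_val)
  if (!length(cand)) return(NULL)
  cand <- cand[order(h[cand], decreasing = TRUE)]
  H <- nrow(h)
  xy <- cbind((cand - 1) %/% H, (cand - 1) %% H)  # 0-based (x, y)
  keep <- integer(0)
  for (i in seq_along(cand)) {
    if (length(keep) == 2L) break
    ok <- TRUE
    for (j in keep) {
      if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= radius) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  if (length(keep) < 2L) return(NULL)
  list(p = xy[keep, , drop = FALSE], value = h[cand[keep]])
}

#' Extract an endpoint detection from one channel group
#'
#' Mask mode: pixels with `sigmoid(mask logit) > mask_threshold` form the
#' candidate region; the largest connected component is kept, the direction
#' field is averaged over it to a unit vector, member pixels are projected
#' onto that vector, and the minimum/maximum-projection pixels become the
#' apical and coronal endpoints. The confidence score is the maximum sigmoid
#' probability. Heatmap mode: the endpoints are the two highest local maxima
#' separated by more than the non-maximum-suppression radius (`2 * sigma`),
#' with score the normalized peak height. Absence (empty region, single-pixel
#' component, or fewer than two peaks) is a valid outcome and returns `NULL`.
#'
#' @param group_channels `height x width x 3` array: mask/heatmap channel
#'   then the two direction channels.
#' @param class Defect class of the group.
#' @param pixel_pitch_mm Millimetres per pixel, used for the reported length.
#' @param mode `"mask_direction"` or `"heatmap"`.
#' @param mask_threshold Probability threshold applied after the sigmoid
#'   (default 0.5, strict inequality).
#' @param sigma_px Heatmap spread, setting the suppression radius in heatmap
#'   mode.
#' @param boundary_level Probability level at which the endpoints are read
#'   off along the component axis. Defaults to `mask_threshold`. When the
#'   mask was trained with a positive-class weight `w`, the decision
#'   boundary of the weighted cross-entropy sits where the true posterior is
#'   `1 / (1 + w)`, so the unbiased measurement boundary is the level
#'   `w / (1 + w)`; detection presence still uses `mask_threshold`.
#' @return A `detection` (list with `class`, `p1`, `p2`, `length_mm`,
#'   `score`) or `NULL` if no defect is detected.
#' @export
extract_endpoints <- function(group_channels, class, pixel_pitch_mm,
                              mode = c("mask_direction", "heatmap"),
                              mask_threshold = 0.5, sigma_px = 2,
                              boundary_level = mask_threshold) {
  mode <- match.arg(mode)
  row <- .class_row(class)
  H <- dim(group_channels)[1]
  m <- group_channels[, , 1]

  if (mode == "mask_direction") {
    prob <- .sigmoid(m)
    comp <- .largest_component(prob > mask_threshold)
    if (is.null(comp)) return(NULL)
    idx <- which(comp)
    if (length(idx) < 2L) return(NULL)  # single pixel: degenerate, p1 == p2
    x <- (idx - 1) %/% H; y <- (idx - 1) %% H   # 0-based pixel coords
    d <- c(mean(group_channels[, , 2][idx]), mean(group_channels[, , 3][idx]))
    nd <- sqrt(sum(d^2))
    if (nd < 1e-8) d <- c(0, -1) else d <- d / nd   # fallback: crown-up
    t <- x * d[1] + y * d[2]
    # sub-pixel endpoints: the extreme member pixels at or above the
    # measurement boundary level are projected onto the axis through their
    # centroid and extended outward to the sub-pixel point where the
    # probability crosses the level (interpolated to the outward
    # neighbour). On a binary target this lands half a pixel out, undoing
    # the inward bias of pixel centres; on a smooth prediction it reads the
    # calibrated contour.
    level <- max(boundary_level, mask_threshold)
    probs <- prob[idx]
    sel <- probs > level
    if (sum(sel) < 2L) { sel <- rep(TRUE, length(idx)); level <- mask_threshold }
    ctr <- c(mean(x[sel]), mean(y[sel]))
    tc <- sum(ctr * d)
    W <- dim(group_channels)[2]
    crossing <- function(which_ext, sign) {
      px <- c(x[which_ext], y[which_ext])
      p_in <- prob[px[2] + 1, px[1] + 1]
      nb <- round(px + sign * d)
      if (any(nb < 0) || nb[1] > W - 1 || nb[2] > H - 1) return(0.5)
      p_out <- prob[nb[2] + 1, nb[1] + 1]
      if (p_out >= level) return(1)
      min(1, max(0, (p_in - level) / (p_in - p_out)))
    }
    ts <- t[sel]
    sel_idx <- which(sel)
    lo <- sel_idx[which.min(ts)]; hi <- sel_idx[which.max(ts)]
    apical <- ctr + d * (min(ts) - crossing(lo, -1) - tc)
    coronal <- ctr + d * (max(ts) + crossing(hi, +1) - tc)
    score <- max(probs)
  } else {
    pk <- .heatmap_peaks(m, radius = 2 * sigma_px)
    if (is.null(pk)) return(NULL)
    idx <- which(m > 0.1 * max(m))
    d <- c(mean(group_channels[, , 2][idx]), mean(group_channels[, , 3][idx]))
    nd <- sqrt(sum(d^2))
    if (nd < 1e-8) d <- c(0, -1) else d <- d / nd
    t1 <- sum(pk$p[1, ] * d); t2 <- sum(pk$p[2, ] * d)
    if (t1 <= t2) { apical <- pk$p[1, ]; coronal <- pk$p[2, ] }
    else { apical <- pk$p[2, ]; coronal <- pk$p[1, ] }
    score <- min(1, max(pk$value))
  }

  if (all(apical == coronal)) return(NULL)  # degenerate single-pixel hit
  # map apical/coronal extremes onto the class's stored endpoint roles:
  # dehiscence p1 = ARC (apical), p2 = CEJ; fenestration p1 = CB (coronal),
  # p2 = AB (apical)
  if (row$type == "dehiscence") { p1 <- apical; p2 <- coronal }
  else { p1 <- coronal; p2 <- apical }
  det <- list(class = class, p1 = as.numeric(p1), p2 = as.numeric(p2),
              length_mm = px_to_mm(sqrt(sum((p1 - p2)^2)), pixel_pitch_mm),
              score = as.numeric(score))
  class(det) <- "detection"
  det
}

#' Measure a detection's length in millimetres
#'
#' Euclidean distance between the predicted endpoints times the pixel pitch.
#'
#' @param detection A detection from [extract_endpoints()].
#' @param pixel_pitch_mm Millimetres per pixel.
#' @return Length in millimetres.
#' @export
measure_length <- function(detection, pixel_pitch_mm) {
  px_to_mm(sqrt(sum((detection$p1 - detection$p2)^2)), pixel_pitch_mm)
}

#' Decode a full 12-channel map into per-class detections
#'
#' @param stack `height x width x 12` array of predictions (mask channels as
#'   logits) or noiseless targets.
#' @param pixel_pitch_mm Millimetres per pixel.
#' @inheritParams extract_endpoints
#' @return Named list (one entry per defect class) of detections or `NULL`s.
#' @export
decode_stack <- function(stack, pixel_pitch_mm,
                         mode = c("mask_direction", "heatmap"),
                         mask_threshold = 0.5, sigma_px = 2,
                         boundary_level = mask_threshold) {
  mode <- match.arg(mode)
  dc <- defect_classes()
  boundary_level <- rep(boundary_level, length.out = nrow(dc))
  out <- vector("list", nrow(dc))
  names(out) <- dc$class
  for (i in seq_len(nrow(dc))) {
    ch <- c(dc$mask_channel[i], dc$dir_channel_x[i], dc$dir_channel_y[i])
    out[i] <- list(extract_endpoints(stack[, , ch, drop = FALSE],
                                     dc$class[i], pixel_pitch_mm, mode,
                                     mask_threshold, sigma_px,
                                     boundary_level[i]))
  }
  out
}

#' Classify one slice from its detections
#'
#' Applies the strict diagnostic thresholds: a dehiscence is positive when
#' its measured length exceeds 2 mm, a fenestration when it exceeds 2.2 mm.
#' An absent detection is negative with score 0; a detection's score passes
#' through as the slice's continuous confidence.
#'
#' @param detections Named list as returned by [decode_stack()] (entries may
#'   be `NULL`), or a list of detections.
#' @return A tibble with one row per defect class: `class`, `detected`,
#'   `length_mm`, `label`, `score`.
#' @export
classify_slice <- function(detections) {
  dc <- defect_classes()
  purrr::map_dfr(seq_len(nrow(dc)), function(i) {
    cls <- dc$class[i]
    det <- NULL
    if (!is.null(names(detections)) && cls %in% names(detections)) {
      det <- detections[[cls]]
    } else {
      for (d in detections) if (!is.null(d) && d$class == cls) det <- d
    }
    if (is.null(det)) {
      tibble::tibble(class = cls, detected = FALSE, length_mm = NA_real_,
                     label = FALSE, score = 0)
    } else {
      tibble::tibble(class = cls, detected = TRUE, length_mm = det$length_mm,
                     label = det$length_mm > dc$threshold_mm[i],
                     score = det$score)
    }
  })
}

#' Tooth-level consensus diagnosis
#'
#' A tooth is positive for a class only when all three consecutive slices
#' are positive for it; the tooth-level confidence is the minimum of the
#' three slice scores (mirroring the AND rule).
#'
#' @param slice_results List of exactly 3 tibbles from [classify_slice()],
#'   ordered mesial to distal.
#' @return A tibble with one row per class: `class`, `label_s0`, `label_s1`,
#'   `label_s2`, `tooth_label`, `tooth_score`.
#' @export
diagnose_tooth <- function(slice_results) {
  if (length(slice_results) != 3L) {
    stop("diagnose_tooth() requires exactly 3 slice results", call. = FALSE)
  }
  dc <- defect_classes()
  purrr::map_dfr(dc$class, function(cls) {
    rows <- lapply(slice_results, function(r) r[r$class == cls, ])
    labs <- vapply(rows, function(r) r$label, logical(1))
    scores <- vapply(rows, function(r) r$score, numeric(1))
    tibble::tibble(class = cls, label_s0 = labs[1], label_s1 = labs[2],
                   label_s2 = labs[3], tooth_label = all(labs),
                   tooth_score = min(scores))
  })
}

#' Tabulate detections for a set of slices
#'
#' @param detections_by_slice Named list: one [decode_stack()] result per
#'   slice.
#' @param meta Tibble with one row per slice (`patient_id`, `tooth_id`,
#'   `slice_index`, `pixel_pitch_mm`) aligned with `detections_by_slice`.
#' @return A tibble with one row per slice x class: endpoints, `length_mm`,
#'   `score`, `detected`, `label`.
#' @export
detection_table <- function(detections_by_slice, meta) {
  stopifnot(nrow(meta) == length(detections_by_slice))
  dc <- defect_classes()
  purrr::map_dfr(seq_along(detections_by_slice), function(i) {
    dets <- detections_by_slice[[i]]
    purrr::map_dfr(seq_len(nrow(dc)), function(j) {
      cls <- dc$class[j]
      det <- dets[[cls]]
      base <- meta[i, c("patient_id", "tooth_id", "slice_index",
                        "pixel_pitch_mm")]
      if (is.null(det)) {
        dplyr::mutate(base, class = cls, detected = FALSE, x1 = NA_real_,
                      y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
                      length_mm = NA_real_, score = 0,
                      label = FALSE)
      } else {
        dplyr::mutate(base, class = cls, detected = TRUE,
                      x1 = det$p1[1], y1 = det$p1[2],
                      x2 = det$p2[1], y2 = det$p2[2],
                      length_mm = det$length_mm, score = det$score,
                      label = det$length_mm > dc$threshold_mm[j])
      }
    })
  })
}
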