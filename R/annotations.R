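#' Defect class table
#'
#' The four alveolar bone defect classes handled by the package, with their
#' endpoint-role pairs, channel-group layout and diagnostic thresholds.
#'
#' Dehiscence defects are measured between the alveolar ridge crest (ARC) and
#' the cementoenamel junction (CEJ); fenestration defects between the coronal
#' border (CB) and apical border (AB) of the bone window. Each class owns one
#' group of three consecutive channels in the 12-channel supervision stack:
#' the first channel of the group is the segmentation mask (or heatmap), the
#' remaining two the (dx, dy) direction field.
#'
#' A dehiscence is diagnosed positive when its ARC-CEJ distance exceeds
#' 2 mm; a fenestration when its CB-AB gap is greater than 2.2 mm. Both
#' inequalities are strict.
#'
#' @return A tibble with one row per defect class: `class`, `type`
#'   (dehiscence/fenestration), `side` (buccal = labial/buccal, lingual =
#'   lingual/palatal), `group` (1-4), `mask_channel`, `dir_channel_x`,
#'   `dir_channel_y`, `role_p1`, `role_p2`, and `threshold_mm`.
#' @examples
#' defect_classes()
#' @export
defect_classes <- function() {
  tibble::tibble(
    class = c("buccal_dehiscence", "lingual_dehiscence",
              "buccal_fenestration", "lingual_fenestration"),
    type = c("dehiscence", "dehiscence", "fenestration", "fenestration"),
    side = c("buccal", "lingual", "buccal", "lingual"),
    group = 1:4,
    mask_channel = c(1L, 4L, 7L, 10L),
    dir_channel_x = c(2L, 5L, 8L, 11L),
    dir_channel_y = c(3L, 6L, 9L, 12L),
    role_p1 = c("ARC", "ARC", "CB", "CB"),
    role_p2 = c("CEJ", "CEJ", "AB", "AB"),
    threshold_mm = c(2.0, 2.0, 2.2, 2.2)
  )
}

.class_names <- function() defect_classes()$class

.class_row <- function(class) {
  dc <- defect_classes()
  i <- match(class, dc$class)
  if (is.na(i)) {
    stop("unknown defect class: ", class, call. = FALSE)
  }
  dc[i, ]
}

#' Convert a pixel distance to millimetres
#'
#' @param distance_px Distance in pixels (nonnegative).
#' @param pixel_pitch_mm Physical size of one pixel in millimetres
#'   (nonnegative; sagittal CBCT exports here use 0.25 mm).
#' @return `distance_px * pixel_pitch_mm`, in millimetres.
#' @examples
#' px_to_mm(5, 0.25) # 1.25
#' @export
px_to_mm <- function(distance_px, pixel_pitch_mm) {
  if (any(distance_px < 0) || any(pixel_pitch_mm < 0)) {
    stop("px_to_mm() requires nonnegative inputs", call. = FALSE)
  }
  distance_px * pixel_pitch_mm
}

#' Construct a landmark endpoint pair
#'
#' Coordinates are 0-based pixel positions with `x` the column and `y` the
#' row, origin at the top-left pixel centre. `p1` carries the first-named
#' role of the class (ARC for dehiscence, CB for fenestration) and `p2` the
#' second (CEJ, AB).
#'
#' @param class Defect class name (see [defect_classes()]).
#' @param p1,p2 Numeric `(x, y)` coordinates; must differ.
#' @return A `landmark_pair` object.
#' @export
landmark_pair <- function(class, p1, p2) {
  .class_row(class) # validates
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L || !all(is.finite(c(p1, p2)))) {
    stop("landmark endpoints must be finite (x, y) pairs", call. = FALSE)
  }
  if (any(c(p1, p2) < 0)) {
    stop("landmark coordinates must be nonnegative", call. = FALSE)
  }
  if (all(p1 == p2)) {
    stop("degenerate landmark pair: p1 == p2", call. = FALSE)
  }
  structure(list(class = class, p1 = p1, p2 = p2), class = "landmark_pair")
}

#' Pixel separation of a landmark pair
#' @param pair A [landmark_pair()].
#' @return Euclidean distance between the endpoints, in pixels.
#' @export
pair_length_px <- function(pair) {
  sqrt(sum((pair$p1 - pair$p2)^2))
}

#' Construct a per-slice annotation
#'
#' One annotated sagittal slice: identifiers, pixel pitch, and zero to four
#' landmark pairs (at most one per defect class). A slice with no defects is
#' a valid, negative slice.
#'
#' @param patient_id,tooth_id Character identifiers.
#' @param slice_index Integer in 0..2 (position within the mesial-to-distal
#'   three-slice series).
#' @param pixel_pitch_mm Millimetres per pixel.
#' @param defects List of [landmark_pair()] objects.
#' @return A `slice_annotation` object.
#' @export
slice_annotation <- function(patient_id, tooth_id, slice_index,
                             pixel_pitch_mm = 0.25, defects = list()) {
  slice_index <- as.integer(slice_index)
  if (!slice_index %in% 0:2) {
    stop("slice_index must be 0, 1 or 2", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop("pixel_pitch_mm must be positive", call. = FALSE)
  }
  if (!all(vapply(defects, inherits, logical(1), "landmark_pair"))) {
    stop("defects must be a list of landmark_pair objects", call. = FALSE)
  }
  cls <- vapply(defects, `[[`, character(1), "class")
  if (anyDuplicated(cls)) {
    stop("at most one landmark pair per defect class per slice", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         tooth_id = as.character(tooth_id),
         slice_index = slice_index,
         pixel_pitch_mm = pixel_pitch_mm,
         defects = defects),
    class = "slice_annotation"
  )
}

#' @export
print.slice_annotation <- function(x, ...) {
  cat(sprintf("<slice_annotation> %s/%s slice %d (%.3g mm/px), %d defect(s)\n",
              x$patient_id, x$tooth_id, x$slice_index, x$pixel_pitch_mm,
              length(x$defects)))
  for (d in x$defects) {
    cat(sprintf("  %s: (%.1f, %.1f) -- (%.1f, %.1f)  %.2f mm\n", d$class,
                d$p1[1], d$p1[2], d$p2[1], d$p2[2],
                px_to_mm(pair_length_px(d), x$pixel_pitch_mm)))
  }
  invisible(x)
}

.annotation_to_record <- function(ann) {
  list(
    patient_id = ann$patient_id,
    tooth_id = ann$tooth_id,
    slice_index = ann$slice_index,
    pixel_pitch_mm = ann$pixel_pitch_mm,
    defects = lapply(ann$defects, function(d) {
      list(class = d$class, p1 = d$p1, p2 = d$p2)
    })
  )
}

.record_to_annotation <- function(rec, where) {
  known <- c("patient_id", "tooth_id", "slice_index", "pixel_pitch_mm",
             "defects")
  extra <- setdiff(names(rec), known)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown annotation field(s): %s", where,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  need <- setdiff(c("patient_id", "tooth_id", "slice_index", "pixel_pitch_mm"),
                  names(rec))
  if (length(need)) {
    stop(sprintf("%s: missing required field(s): %s", where,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  defects <- lapply(rec$defects, function(d) {
    if (is.null(d$class) || is.null(d$p1) || is.null(d$p2)) {
      stop(sprintf("%s: defect record missing class/p1/p2", where),
           call. = FALSE)
    }
    landmark_pair(d$class, unlist(d$p1), unlist(d$p2))
  })
  tryCatch(
    slice_annotation(rec$patient_id, rec$tooth_id, rec$slice_index,
                     rec$pixel_pitch_mm, defects),
    error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e)),
                             call. = FALSE)
  )
}

#' Read and write slice annotations as JSON
#'
#' The on-disk format is a JSON array of records
#' `{patient_id, tooth_id, slice_index, pixel_pitch_mm,
#'   defects: [{class, p1: [x, y], p2: [x, y]}]}`.
#' Writing then reading is the identity on all fields; unknown keys in a
#' record are ignored with a warning, and malformed records raise an error
#' naming the offending record.
#'
#' @param anns List of [slice_annotation()] objects.
#' @param path File path.
#' @return `read_annotations()` returns a list of `slice_annotation`;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(anns, path) {
  stopifnot(all(vapply(anns, inherits, logical(1), "slice_annotation")))
  recs <- lapply(anns, .annotation_to_record)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(seq_along(recs), function(i) {
    .record_to_annotation(recs[[i]], sprintf("record %d", i))
  })
}

#' Tabulate annotations
#'
#' Flattens a list of slice annotations into a tibble with one row per
#' slice-by-defect; slices without defects keep one row with `class = NA` so
#' every slice stays represented.
#'
#' @param anns List of [slice_annotation()] objects.
#' @return A tibble with columns `patient_id`, `tooth_id`, `slice_index`,
#'   `pixel_pitch_mm`, `class`, `x1`, `y1`, `x2`, `y2`, `length_mm`.
#' @export
annotation_table <- function(anns) {
  rows <- purrr::map_dfr(anns, function(a) {
    base <- tibble::tibble(
      patient_id = a$patient_id, tooth_id = a$tooth_id,
      slice_index = a$slice_index, pixel_pitch_mm = a$pixel_pitch_mm
    )
    if (!length(a$defects)) {
      return(dplyr::mutate(base, class = NA_character_, x1 = NA_real_,
                           y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
                           length_mm = NA_real_))
    }
    purrr::map_dfr(a$defects, function(d) {
      dplyr::mutate(base, class = d$class, x1 = d$p1[1], y1 = d$p1[2],
                    x2 = d$p2[1], y2 = d$p2[2],
                    length_mm = px_to_mm(pair_length_px(d), a$pixel_pitch_mm))
    })
  })
  rows
}
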