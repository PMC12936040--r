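#' Phantom specification
#'
#' Parameters of the synthetic sagittal-slice phantom. The phantom renders a
#' schematic labio-lingual cross-section of a single-rooted tooth: enamel
#' crown, tapered root, periodontal-ligament line, trabecular bone with a
#' bright cortical rim along the root surface, and (per sampled class) a
#' washed-out bone-gap region whose two ground-truth endpoints are recorded
#' in the annotation. Appearance is schematic rather than photorealistic:
#' the downstream model consumes intensity contrast at the root-bone rim,
#' which schematic rendering provides.
#'
#' The anatomy is laid out in fractions of the image so that smaller render
#' sizes show the same field of view at a coarser pixel pitch; `pixel_pitch_mm`
#' defaults to `0.25 * 320 / image_height_px`, i.e. the native 0.25 mm pitch
#' of a 320-pixel-tall export.
#'
#' @param image_height_px,image_width_px Render size in pixels
#'   (default 320 x 224).
#' @param pixel_pitch_mm Millimetres per pixel.
#' @param class_prevalence Named probability per defect class that a tooth is
#'   tooth-level positive for that class.
#' @param length_range_mm Interval from which true endpoint separations are
#'   drawn (lower bound must be positive).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the 8-bit
#'   intensity range.
#' @param blur_sigma_px Gaussian smoothing applied to the clean render
#'   (0 disables).
#' @param sub_threshold_prob For teeth not sampled positive: probability of
#'   carrying an annotated sub-threshold defect (annotation precedes
#'   threshold application, so such defects are annotated yet
#'   diagnosis-negative).
#' @param mixed_prob For teeth not sampled positive: probability of a
#'   "2 slices positive, 1 negative" configuration, which exercises the
#'   three-slice consensus rule and is tooth-level negative.
#' @param margin_mm Sampled tooth-positive lengths stay at least this far
#'   above the diagnostic threshold (and slice-to-slice jitter never crosses
#'   it), so the intended tooth label always matches the label derived from
#'   the stored lengths.
#' @param seed Default seed used by [generate_dataset()].
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_height_px = 320L, image_width_px = 224L,
                         pixel_pitch_mm = 0.25 * 320 / image_height_px,
                         class_prevalence = c(
                           buccal_dehiscence = 0.35,
                           lingual_dehiscence = 0.30,
                           buccal_fenestration = 0.25,
                           lingual_fenestration = 0.20),
                         length_range_mm = c(0.5, 6.0),
                         noise_sd = 0.03, blur_sigma_px = 0.7,
                         sub_threshold_prob = 0.25, mixed_prob = 0.10,
                         margin_mm = 0.25, seed = 1L) {
  if (image_height_px <= 0 || image_width_px <= 0) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  cls <- .class_names()
  if (is.null(names(class_prevalence))) names(class_prevalence) <- cls
  if (!setequal(names(class_prevalence), cls)) {
    stop("class_prevalence must be named with the four defect classes",
         call. = FALSE)
  }
  class_prevalence <- class_prevalence[cls]
  if (any(class_prevalence < 0 | class_prevalence > 1)) {
    stop("class prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (length(length_range_mm) != 2L || length_range_mm[1] <= 0 ||
      diff(length_range_mm) < 0) {
    stop("length_range_mm must be an increasing interval with positive lower bound",
         call. = FALSE)
  }
  spec <- structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         pixel_pitch_mm = pixel_pitch_mm,
         class_prevalence = class_prevalence,
         length_range_mm = length_range_mm,
         noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
         sub_threshold_prob = sub_threshold_prob, mixed_prob = mixed_prob,
         margin_mm = margin_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  geo <- .phantom_geometry(spec)
  max_len_px <- length_range_mm[2] / pixel_pitch_mm
  if (max_len_px > 0.85 * (geo$y_apex - geo$y_cej)) {
    stop("sizing error: length_range_mm does not fit the rendered root extent",
         call. = FALSE)
  }
  spec
}

# Fixed anatomy layout in pixels (fractions of the frame). y grows downward;
# crown is up, so the apical side of the image is the bottom.
.phantom_geometry <- function(spec) {
  H <- spec$image_height_px; W <- spec$image_width_px
  list(
    cx = 0.5 * (W - 1),
    y_top = 0.08 * H, y_cej = 0.24 * H, y_apex = 0.82 * H,
    hw_cej = 0.16 * W, hw_apex = 0.035 * W, crown_hw = 0.21 * W,
    crest_offset_mm = 0.3,   # physiologic ARC-CEJ distance on healthy sides
    pdl_mm = 0.30,           # dark periodontal ligament line width
    cortical_mm = 1.0,       # bright rim thickness along the root surface
    washout_mm = 2.2         # lateral extent of the rendered bone gap
  )
}

# x-coordinate of the root surface at row y on side s (-1 buccal/left,
# +1 lingual/right); linear taper so distances along the surface are exact.
.surface_x <- function(geo, y, s) {
  t <- (y - geo$y_cej) / (geo$y_apex - geo$y_cej)
  geo$cx + s * (geo$hw_cej + (geo$hw_apex - geo$hw_cej) * t)
}

# Secant factor of the surface line: Euclidean distance along the surface per
# unit of y.
.surface_sec <- function(geo) {
  slope <- (geo$hw_apex - geo$hw_cej) / (geo$y_apex - geo$y_cej)
  sqrt(1 + slope^2)
}

# Sample per-tooth defect plan: for each class, a stratum ("pos", "sub",
# "none") per slice plus a nominal length. Uses the current RNG stream.
.sample_tooth_plan <- function(spec) {
  dc <- defect_classes()
  lr <- spec$length_range_mm
  plan <- list()
  for (i in seq_len(nrow(dc))) {
    cls <- dc$class[i]; thr <- dc$threshold_mm[i]
    pos_lo <- thr + spec$margin_mm
    u <- stats::runif(1)
    if (u < spec$class_prevalence[[cls]]) {
      strata <- rep("pos", 3)
      nominal <- stats::runif(1, pos_lo, lr[2])
    } else {
      v <- stats::runif(1)
      if (v < spec$sub_threshold_prob) {
        strata <- rep("sub", 3)
        nominal <- stats::runif(1, lr[1], min(thr - spec$margin_mm, lr[2]))
      } else if (v < spec$sub_threshold_prob + spec$mixed_prob) {
        strata <- rep("pos", 3)
        strata[sample.int(3, 1)] <- "sub"
        nominal <- stats::runif(1, pos_lo, lr[2])
      } else {
        strata <- rep("none", 3)
        nominal <- NA_real_
      }
    }
    plan[[cls]] <- list(strata = strata, nominal = nominal,
                        intended = all(strata == "pos"))
  }
  plan
}

# Per-slice length for a stratum, jittered around the nominal but clamped so
# the stratum's label never flips.
.slice_length <- function(spec, thr, stratum, nominal) {
  lr <- spec$length_range_mm
  if (stratum == "none") return(NA_real_)
  jit <- stats::runif(1, -0.12, 0.12)
  if (stratum == "pos") {
    lo <- thr + spec$margin_mm
    nom <- if (is.na(nominal) || nominal < lo) stats::runif(1, lo, lr[2]) else nominal
    min(max(nom + jit, lo), lr[2])
  } else {
    hi <- min(thr - spec$margin_mm, lr[2])
    nom <- if (is.na(nominal) || nominal > hi) stats::runif(1, lr[1], hi) else nominal
    min(max(nom + jit, lr[1]), hi)
  }
}

# Render one slice. defects: named list class -> list(p1, p2, y1, y2, side)
# in pixel coordinates (0-based). Returns intensity matrix (H x W, 0..255).
.render_slice <- function(spec, geo, defects, dx, dy) {
  H <- spec$image_height_px; W <- spec$image_width_px
  xg <- matrix(rep(0:(W - 1), each = H), H, W) - dx
  yg <- matrix(rep(0:(H - 1), W), H, W) - dy
  q <- function(mm) mm / spec$pixel_pitch_mm

  img <- matrix(48, H, W)  # soft-tissue background

  in_root_zone <- yg >= geo$y_cej & yg <= geo$y_apex
  t <- pmin(pmax((yg - geo$y_cej) / (geo$y_apex - geo$y_cej), 0), 1)
  hw <- geo$hw_cej + (geo$hw_apex - geo$hw_cej) * t
  lat <- abs(xg - geo$cx) - hw           # signed lateral distance from surface
  side_sign <- ifelse(xg < geo$cx, -1, 1)

  # trabecular bone below the physiologic crest, outside root + PDL
  crest_y <- geo$y_cej + q(geo$crest_offset_mm)
  bone <- yg >= crest_y & !(in_root_zone & lat < q(geo$pdl_mm)) &
    yg <= 0.98 * H
  img[bone] <- 130
  cortical <- bone & in_root_zone & lat >= q(geo$pdl_mm) &
    lat < q(geo$pdl_mm + geo$cortical_mm)
  img[cortical] <- 205
  # below the apex, close the socket with cortical bone
  apex_cap <- yg > geo$y_apex & yg < geo$y_apex + q(geo$cortical_mm + geo$pdl_mm) &
    abs(xg - geo$cx) < geo$hw_apex + q(geo$pdl_mm + geo$cortical_mm)
  img[apex_cap & bone] <- 205

  # defect washouts: remove bone lateral to the root surface
  for (d in defects) {
    reg <- in_root_zone & side_sign == d$side &
      lat >= q(geo$pdl_mm) & lat < q(geo$washout_mm) &
      yg >= d$y1 & yg <= d$y2
    img[reg] <- 48
  }

  # root dentine and PDL line
  root <- in_root_zone & lat < 0
  img[root] <- 175
  pdl <- in_root_zone & lat >= 0 & lat < q(geo$pdl_mm)
  img[pdl] <- 60

  # crown: ellipse above the CEJ
  ecy <- (geo$y_top + geo$y_cej) / 2
  crown <- ((xg - geo$cx) / geo$crown_hw)^2 +
    ((yg - ecy) / ((geo$y_cej - geo$y_top) / 2))^2 <= 1
  img[crown] <- 235
  img
}

# Place endpoints for one defect of class `cls` with slice length len_mm.
# min_y_fen: lowest allowed coronal border for a fenestration on this side
# (keeps it clear of a coexisting dehiscence). Returns
# list(p1, p2, y1, y2, side).
.place_defect <- function(spec, geo, cls, len_mm, fen_center_frac, dx, dy,
                          min_y_fen = -Inf) {
  row <- .class_row(cls)
  s <- if (row$side == "buccal") -1 else 1
  sec <- .surface_sec(geo)
  len_px <- len_mm / spec$pixel_pitch_mm
  dy_span <- len_px / sec
  if (row$type == "dehiscence") {
    y1 <- geo$y_cej                      # CEJ
    y2 <- geo$y_cej + dy_span            # ARC (receded crest, apical)
    p_cej <- c(.surface_x(geo, y1, s) + dx, y1 + dy)
    p_arc <- c(.surface_x(geo, y2, s) + dx, y2 + dy)
    # p1 = ARC, p2 = CEJ (class convention); washout spans CEJ..ARC
    list(p1 = p_arc, p2 = p_cej, y1 = y1, y2 = y2, side = s)
  } else {
    lo <- max(geo$y_cej + (2.5 / spec$pixel_pitch_mm), min_y_fen)
    hi <- max(geo$y_apex - (1.0 / spec$pixel_pitch_mm) - dy_span, lo)
    yc <- lo + fen_center_frac * max(hi - lo, 0)
    y1 <- yc; y2 <- yc + dy_span
    p_cb <- c(.surface_x(geo, y1, s) + dx, y1 + dy)   # coronal border
    p_ab <- c(.surface_x(geo, y2, s) + dx, y2 + dy)   # apical border
    list(p1 = p_cb, p2 = p_ab, y1 = y1, y2 = y2, side = s)
  }
}

#' Generate one annotated three-slice tooth series
#'
#' Renders three consecutive sagittal slices of one phantom tooth with small
#' geometric jitter between slices, samples defects per class according to
#' the spec's prevalences, and records the ground-truth endpoint pair of
#' every rendered defect in the slice annotations. Tooth-level-positive
#' defects keep a consistent positive status on all three slices;
#' sub-threshold defects are rendered and annotated but diagnosis-negative.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id,tooth_id Identifiers stored in the annotations.
#' @param seed Optional integer; when given, seeds the RNG so the call is
#'   reproducible bit-for-bit.
#' @param force_defects Optional named numeric vector `class -> length_mm`
#'   overriding sampling: exactly these defects are rendered at exactly these
#'   separations on all three slices (no length jitter).
#' @return A `tooth_series`: list with `patient_id`, `tooth_id`, `intended`
#'   (named logical tooth-level label per class) and `slices`, a list of 3
#'   `list(image = slice_image, annotation = slice_annotation)` ordered
#'   mesial to distal.
#' @export
generate_tooth_series <- function(spec, patient_id = "P001",
                                  tooth_id = "T01", seed = NULL,
                                  force_defects = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  geo <- .phantom_geometry(spec)
  dc <- defect_classes()

  if (is.null(force_defects)) {
    plan <- .sample_tooth_plan(spec)
  } else {
    if (is.null(names(force_defects)) ||
        !all(names(force_defects) %in% dc$class)) {
      stop("force_defects must be named with defect classes", call. = FALSE)
    }
    plan <- list()
    for (cls in dc$class) {
      if (cls %in% names(force_defects)) {
        thr <- .class_row(cls)$threshold_mm
        plan[[cls]] <- list(strata = rep("forced", 3),
                            nominal = force_defects[[cls]],
                            intended = force_defects[[cls]] > thr)
      } else {
        plan[[cls]] <- list(strata = rep("none", 3), nominal = NA_real_,
                            intended = FALSE)
      }
    }
  }
  # one fenestration placement per class per tooth, shared across slices
  fen_frac <- stats::runif(nrow(dc))
  names(fen_frac) <- dc$class

  slices <- vector("list", 3)
  for (k in 1:3) {
    dx <- stats::runif(1, -0.8, 0.8)
    dy <- stats::runif(1, -0.8, 0.8)
    defects <- list()
    pairs <- list()
    deh_extent <- c(buccal = -Inf, lingual = -Inf)
    # dehiscences first so same-side fenestrations can be placed clear of them
    ord <- order(dc$type != "dehiscence")
    for (i in ord) {
      cls <- dc$class[i]; p <- plan[[cls]]
      stratum <- p$strata[k]
      if (stratum == "none") next
      len <- if (stratum == "forced") p$nominal else
        .slice_length(spec, dc$threshold_mm[i], stratum, p$nominal)
      min_y_fen <- deh_extent[[dc$side[i]]] + 1.5 / spec$pixel_pitch_mm
      d <- .place_defect(spec, geo, cls, len, fen_frac[[cls]], dx, dy,
                         min_y_fen)
      if (dc$type[i] == "dehiscence") {
        deh_extent[[dc$side[i]]] <- max(deh_extent[[dc$side[i]]], d$y2)
      }
      defects[[length(defects) + 1L]] <- d
      pairs[[length(pairs) + 1L]] <- landmark_pair(cls, d$p1, d$p2)
    }
    img <- .render_slice(spec, geo, defects, dx, dy)
    if (spec$blur_sigma_px > 0) {
      img <- gauss_blur(img, spec$blur_sigma_px)
    }
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd * 255)
    }
    img <- matrix(round(pmin(pmax(img, 0), 255)),
                  spec$image_height_px, spec$image_width_px)
    ann <- slice_annotation(patient_id, tooth_id, k - 1L,
                            spec$pixel_pitch_mm, pairs)
    slices[[k]] <- list(
      image = structure(list(pixels = img,
                             pixel_pitch_mm = spec$pixel_pitch_mm),
                        class = "slice_image"),
      annotation = ann)
  }
  structure(
    list(patient_id = as.character(patient_id),
         tooth_id = as.character(tooth_id),
         intended = vapply(plan, `[[`, logical(1), "intended"),
         slices = slices),
    class = "tooth_series")
}

#' Generate a phantom dataset
#'
#' @param n_patients Number of patients (>= 1).
#' @param teeth_per_patient Teeth rendered per patient (>= 1).
#' @param spec A [phantom_spec()].
#' @param seed Master seed (defaults to the spec's).
#' @return A `phantom_dataset`: list with `series` (list of
#'   [generate_tooth_series()] results) and `manifest`, a tibble with one row
#'   per tooth (`patient_id`, `tooth_id`, `n_slices`, and the intended
#'   tooth-level label per class).
#' @export
generate_dataset <- function(n_patients, teeth_per_patient, spec,
                             seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_patients < 1 || teeth_per_patient < 1) {
    stop("n_patients and teeth_per_patient must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  series <- vector("list", n_patients * teeth_per_patient)
  idx <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (t in seq_len(teeth_per_patient)) {
      idx <- idx + 1L
      series[[idx]] <- generate_tooth_series(
        spec, patient_id = pid, tooth_id = sprintf("%s_T%02d", pid, t))
    }
  }
  manifest <- purrr::map_dfr(series, function(s) {
    dplyr::bind_cols(
      tibble::tibble(patient_id = s$patient_id, tooth_id = s$tooth_id,
                     n_slices = length(s$slices)),
      tibble::as_tibble(as.list(stats::setNames(
        s$intended, paste0("intended_", names(s$intended)))))
    )
  })
  structure(list(series = series, manifest = manifest, spec = spec),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d teeth, %d patients, %dx%d px @ %.3g mm/px\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              x$spec$image_height_px, x$spec$image_width_px,
              x$spec$pixel_pitch_mm))
  invisible(x)
}

#' All slice annotations of a dataset
#' @param dataset A `phantom_dataset`.
#' @return List of [slice_annotation()] in series order.
#' @export
dataset_annotations <- function(dataset) {
  unlist(lapply(dataset$series, function(s) {
    lapply(s$slices, `[[`, "annotation")
  }), recursive = FALSE)
}

#' Write a phantom dataset to disk
#'
#' Images go to `dir/images/<tooth_id>_s<k>.png` (8-bit grayscale PNG),
#' annotations to `dir/annotations.json` and the manifest to
#' `dir/manifest.csv`.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (s in dataset$series) {
    for (k in seq_along(s$slices)) {
      png::writePNG(s$slices[[k]]$image$pixels / 255,
                    file.path(dir, "images",
                              sprintf("%s_s%d.png", s$tooth_id, k - 1L)))
    }
  }
  write_annotations(dataset_annotations(dataset),
                    file.path(dir, "annotations.json"))
  readr::write_csv(dataset$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}
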