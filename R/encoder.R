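#' Heatmap specification
#'
#' Spread of the Gaussian landmark heatmap. Each annotated landmark
#' contributes `exp(-((x - xi)^2 + (y - yi)^2) / (2 sigma^2))` to the map and
#' contributions are summed literally, without clipping, so coincident
#' landmarks stack.
#'
#' @param sigma_px Gaussian spread in pixels (> 0). Default 2 px, a spread
#'   comparable to the rendered rim thickness at native pitch.
#' @return A `heatmap_spec` object.
#' @export
heatmap_spec <- function(sigma_px = 2) {
  if (!is.numeric(sigma_px) || sigma_px <= 0) {
    stop("sigma_px must be positive", call. = FALSE)
  }
  structure(list(sigma_px = sigma_px), class = "heatmap_spec")
}

#' Encode landmarks as a Gaussian-sum heatmap
#'
#' `h(x, y) = sum_i exp(-((x - x_i)^2 + (y - y_i)^2) / (2 sigma^2))` over the
#' `k` landmarks, evaluated at every pixel centre.
#'
#' @param landmarks List (possibly empty) of numeric `(x, y)` pixel
#'   coordinates (0-based).
#' @param shape `c(height, width)` of the map.
#' @param spec A [heatmap_spec()].
#' @return A `height x width` matrix (row = y, column = x).
#' @examples
#' h <- encode_heatmap(list(c(10, 10)), c(32, 32), heatmap_spec(2))
#' h[11, 11] # 1 at the landmark
#' @export
encode_heatmap <- function(landmarks, shape, spec = heatmap_spec()) {
  stopifnot(inherits(spec, "heatmap_spec"))
  H <- shape[1]; W <- shape[2]
  h <- matrix(0, H, W)
  if (!length(landmarks)) return(h)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  s2 <- 2 * spec$sigma_px^2
  for (lm in landmarks) {
    h <- h + exp(-(outer((ys - lm[2])^2, (xs - lm[1])^2, `+`)) / s2)
  }
  h
}

#' Rasterize a landmark pair as a binary segment mask
#'
#' Marks every pixel whose centre lies within `width_px / 2` of the segment
#' `p1 -> p2` *and* whose projection onto the segment falls inside it (flat
#' end caps), so the extreme mask pixels along the segment direction stay
#' within one pixel of the true endpoints.
#'
#' @param pair A [landmark_pair()].
#' @param shape `c(height, width)`.
#' @param width_px Mask width in pixels (>= 1; default 3).
#' @return Binary `height x width` matrix.
#' @export
encode_mask <- function(pair, shape, width_px = 3) {
  stopifnot(inherits(pair, "landmark_pair"))
  if (width_px < 1) stop("width_px must be >= 1", call. = FALSE)
  v <- pair$p2 - pair$p1
  L <- sqrt(sum(v^2))
  if (L == 0) stop("degenerate segment: p1 == p2", call. = FALSE)
  u <- v / L
  H <- shape[1]; W <- shape[2]
  # the mask lives inside the segment's bounding box padded by the width;
  # rasterize only there
  pad <- width_px / 2 + 1
  xr <- c(max(0, floor(min(pair$p1[1], pair$p2[1]) - pad)),
          min(W - 1, ceiling(max(pair$p1[1], pair$p2[1]) + pad)))
  yr <- c(max(0, floor(min(pair$p1[2], pair$p2[2]) - pad)),
          min(H - 1, ceiling(max(pair$p1[2], pair$p2[2]) + pad)))
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  nh <- length(ys); nw <- length(xs)
  xg <- matrix(rep(xs, each = nh), nh, nw) - pair$p1[1]
  yg <- matrix(rep(ys, nw), nh, nw) - pair$p1[2]
  t <- xg * u[1] + yg * u[2]
  perp <- abs(-xg * u[2] + yg * u[1])
  mm <- (t >= -1e-9) & (t <= L + 1e-9) & (perp <= width_px / 2)
  m <- matrix(0, H, W)
  m[ys + 1, xs + 1] <- mm + 0
  if (!any(m > 0)) {
    # segment shorter than a pixel: mark the pixels nearest each endpoint
    for (p in list(pair$p1, pair$p2)) {
      m[pmin(pmax(round(p[2]), 0), H - 1) + 1,
        pmin(pmax(round(p[1]), 0), W - 1) + 1] <- 1
    }
  }
  m
}

# Unit direction vector of a pair, pointing from the apical-role endpoint
# toward the coronal-role endpoint (root apex -> crown). Fenestrations use
# their stored AB role; dehiscences use the endpoint nearer the apical
# (bottom) side of the image, since images are oriented crown-up.
.pair_direction <- function(pair) {
  row <- .class_row(pair$class)
  if (row$type == "fenestration") {
    apical <- pair$p2; coronal <- pair$p1   # p1 = CB, p2 = AB
  } else if (pair$p1[2] >= pair$p2[2]) {
    apical <- pair$p1; coronal <- pair$p2   # larger y is apical (crown-up)
  } else {
    apical <- pair$p2; coronal <- pair$p1
  }
  d <- coronal - apical
  d / sqrt(sum(d^2))
}

#' Encode the per-pixel direction field of a defect
#'
#' At every mask pixel the field holds the unit vector pointing from the
#' defect's apical endpoint toward its coronal endpoint (root apex to crown);
#' zero outside the mask.
#'
#' @param pair A [landmark_pair()].
#' @param mask Binary matrix as from [encode_mask()].
#' @return List of two matrices, `dx` and `dy`.
#' @export
encode_direction <- function(pair, mask) {
  stopifnot(inherits(pair, "landmark_pair"))
  if (!any(mask > 0)) stop("mask is empty", call. = FALSE)
  d <- .pair_direction(pair)
  list(dx = d[1] * mask, dy = d[2] * mask)
}

#' Build the 12-channel supervision stack for one slice
#'
#' Four channel groups, one per defect class in [defect_classes()] order;
#' within a group, channel 1 is the binary segment mask (or, in heatmap
#' mode, the Gaussian-sum heatmap of the two endpoints) and channels 2-3 the
#' `(dx, dy)` direction field. Groups whose class is absent from the
#' annotation are all-zero.
#'
#' @param annotation A [slice_annotation()].
#' @param shape `c(height, width)` of the slice.
#' @param mode `"mask_direction"` (default) or `"heatmap"`.
#' @param mask_width_px Target mask width in pixels.
#' @param heatmap Optional [heatmap_spec()] (heatmap mode).
#' @return `height x width x 12` array with attributes `mode` and
#'   `pixel_pitch_mm`.
#' @export
build_target_stack <- function(annotation, shape,
                               mode = c("mask_direction", "heatmap"),
                               mask_width_px = 3, heatmap = heatmap_spec()) {
  stopifnot(inherits(annotation, "slice_annotation"))
  mode <- match.arg(mode)
  H <- shape[1]; W <- shape[2]
  stack <- array(0, dim = c(H, W, 12))
  for (d in annotation$defects) {
    row <- .class_row(d$class)
    if (any(c(d$p1, d$p2) < 0) || any(c(d$p1[1], d$p2[1]) > W - 1) ||
        any(c(d$p1[2], d$p2[2]) > H - 1)) {
      stop("landmark pair outside image bounds for class ", d$class,
           call. = FALSE)
    }
    mask <- encode_mask(d, shape, mask_width_px)
    if (mode == "mask_direction") {
      stack[, , row$mask_channel] <- mask
    } else {
      stack[, , row$mask_channel] <-
        encode_heatmap(list(d$p1, d$p2), shape, heatmap)
    }
    dir <- encode_direction(d, mask)
    stack[, , row$dir_channel_x] <- dir$dx
    stack[, , row$dir_channel_y] <- dir$dy
  }
  attr(stack, "mode") <- mode
  attr(stack, "pixel_pitch_mm") <- annotation$pixel_pitch_mm
  stack
}
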