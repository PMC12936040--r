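#' Patient-level train/validation/test split
#'
#' Patients are shuffled and assigned whole to subsets in the given ratios
#' (default 7:2:1), so no patient contributes slices to two subsets. Subset
#' sizes are the rounded proportional shares (largest-remainder method) and
#' always sum to the number of patients.
#'
#' @param patient_ids Character vector (duplicates allowed; the unique set
#'   is split).
#' @param ratios Numeric length-3 proportions for train/val/test.
#' @param seed RNG seed making the assignment reproducible.
#' @return A `split_spec`: tibble with `patient_id` and `subset`
#'   (train/val/test), with `ratios` and `seed` attributes.
#' @export
split_patients <- function(patient_ids, ratios = c(7, 2, 1), seed = 1L) {
  ids <- unique(as.character(patient_ids))
  n <- length(ids)
  nonzero <- sum(ratios > 0)
  if (n < nonzero) {
    stop("fewer patients than nonzero subsets", call. = FALSE)
  }
  share <- n * ratios / sum(ratios)
  sizes <- floor(share)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(share - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  set.seed(seed)
  ids <- sample(ids)
  subset <- rep(c("train", "val", "test"), times = sizes)
  out <- tibble::tibble(patient_id = ids, subset = subset)
  out <- dplyr::arrange(out, .data$patient_id)
  attr(out, "ratios") <- ratios
  attr(out, "seed") <- seed
  class(out) <- c("split_spec", class(out))
  out
}

#' Augmentation specification
#'
#' Ranges of the random training-time transforms: scaling, rotation,
#' translation, Gaussian blurring and additive noise. Every range must
#' contain the identity so augmentation can leave a sample unchanged.
#'
#' @param scale_range Multiplicative scale range (contains 1).
#' @param rotation_range_deg Rotation range in degrees (contains 0).
#' @param translation_range_frac Translation range as a fraction of each
#'   image extent (contains 0).
#' @param blur_sigma_range_px Gaussian blur sigma range (lower bound 0).
#' @param noise_sd_range Additive noise SD range, fraction of intensity
#'   range (lower bound 0).
#' @return An `augment_spec` object.
#' @export
augment_spec <- function(scale_range = c(0.9, 1.1),
                         rotation_range_deg = c(-10, 10),
                         translation_range_frac = c(-0.05, 0.05),
                         blur_sigma_range_px = c(0, 1.5),
                         noise_sd_range = c(0, 0.05)) {
  contains <- function(r, v) r[1] <= v && v <= r[2]
  if (!contains(scale_range, 1) || !contains(rotation_range_deg, 0) ||
      !contains(translation_range_frac, 0) ||
      !contains(blur_sigma_range_px, 0) || !contains(noise_sd_range, 0)) {
    stop("augmentation ranges must contain the identity transform",
         call. = FALSE)
  }
  structure(list(scale_range = scale_range,
                 rotation_range_deg = rotation_range_deg,
                 translation_range_frac = translation_range_frac,
                 blur_sigma_range_px = blur_sigma_range_px,
                 noise_sd_range = noise_sd_range),
            class = "augment_spec")
}

#' Randomly augment an image/annotation pair
#'
#' A random similarity transform (scale, rotation about the image centre,
#' translation) is applied identically to the pixels (bilinear resampling)
#' and to the landmark coordinates, followed by photometric Gaussian blur
#' and additive noise which leave the geometry untouched. Landmark pairs
#' pushed outside the image are dropped from the transformed annotation; the
#' number dropped is attached as attribute `n_dropped` and logged.
#'
#' @param image Numeric matrix of intensities (0..255).
#' @param annotation A [slice_annotation()].
#' @param spec An [augment_spec()].
#' @param seed Optional seed for reproducibility.
#' @param params Optional explicit transform parameters (list with any of
#'   `scale`, `rotation_deg`, `tx_frac`, `ty_frac`, `blur`, `noise`),
#'   applied deterministically instead of sampling from `spec`; useful for
#'   reproducing a specific transform.
#' @return List with `image`, `annotation` and the applied `params`.
#' @export
augment <- function(image, annotation, spec = augment_spec(), seed = NULL,
                    params = NULL) {
  stopifnot(inherits(spec, "augment_spec"))
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(image); W <- ncol(image)
  if (is.null(params)) params <- list()
  sc <- params$scale %||%
    stats::runif(1, spec$scale_range[1], spec$scale_range[2])
  th <- (params$rotation_deg %||%
           stats::runif(1, spec$rotation_range_deg[1],
                        spec$rotation_range_deg[2])) * pi / 180
  tx <- (params$tx_frac %||%
           stats::runif(1, spec$translation_range_frac[1],
                        spec$translation_range_frac[2])) * W
  ty <- (params$ty_frac %||%
           stats::runif(1, spec$translation_range_frac[1],
                        spec$translation_range_frac[2])) * H
  blur <- params$blur %||%
    stats::runif(1, spec$blur_sigma_range_px[1], spec$blur_sigma_range_px[2])
  noise <- params$noise %||%
    stats::runif(1, spec$noise_sd_range[1], spec$noise_sd_range[2])

  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  R <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_vec <- c(cx + tx, cy + ty) - R %*% c(cx, cy)
  fwd <- function(p) as.numeric(R %*% p + t_vec)
  # inverse map for pixel resampling
  Ri <- solve(R)
  ti <- -Ri %*% t_vec
  m <- c(Ri[1, 1], Ri[1, 2], ti[1], Ri[2, 1], Ri[2, 2], ti[2])
  out_img <- warp_affine(image, m, H, W, background = stats::median(image))

  kept <- list(); dropped <- 0L
  for (d in annotation$defects) {
    p1 <- fwd(d$p1); p2 <- fwd(d$p2)
    inb <- function(p) p[1] >= 0 && p[1] <= W - 1 && p[2] >= 0 && p[2] <= H - 1
    if (inb(p1) && inb(p2)) {
      kept[[length(kept) + 1L]] <- landmark_pair(d$class, p1, p2)
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L) {
    message(sprintf("augment(): dropped %d out-of-bounds landmark pair(s)",
                    dropped))
  }
  if (blur > 0.05) out_img <- gauss_blur(out_img, blur)
  if (noise > 0) {
    out_img <- out_img + stats::rnorm(length(out_img), sd = noise * 255)
  }
  out_img <- pmin(pmax(out_img, 0), 255)
  ann2 <- slice_annotation(annotation$patient_id, annotation$tooth_id,
                           annotation$slice_index, annotation$pixel_pitch_mm,
                           kept)
  attr(ann2, "n_dropped") <- dropped
  list(image = out_img, annotation = ann2,
       params = list(scale = sc, rotation_rad = th, tx = tx, ty = ty,
                     blur = blur, noise = noise))
}

#' Per-image z-score standardization
#'
#' @param image Numeric matrix.
#' @return Matrix with mean 0 and SD 1; a constant image maps to all zeros
#'   with a warning.
#' @export
standardize <- function(image) {
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    warning("constant image standardized to zeros", call. = FALSE)
    return(image * 0)
  }
  (image - mean(image)) / s
}

# ---- composite loss -----------------------------------------------------

# target stack array (H x W x 12) -> token matrix in network row order
.stack_tokens <- function(stack) {
  d <- dim(stack)
  matrix(aperm(stack, c(2, 1, 3)), d[1] * d[2], d[3])
}

# loss on token matrices; pred is an ad node (N x 12), target a matrix
.loss_node <- function(pred, target, mode = "mask_direction",
                       mask_weight = 1, direction_weight = 1,
                       pos_weight = 1) {
  ad_stack_loss(pred, target, mode, mask_weight, direction_weight,
                pos_weight)
}

#' Composite supervision loss on a 12-channel prediction
#'
#' In `mask_direction` mode each group's mask channel is scored with mean
#' binary cross-entropy on logits and its two direction channels with mean
#' squared error; in `heatmap` mode the first channel uses MSE as well. The
#' per-group terms are summed unweighted by default; weights and a positive
#' -class weight for the BCE are exposed.
#'
#' @param pred `H x W x 12` array (mask channels as logits) or
#'   `H x W x 12 x B`.
#' @param target Matching target stack array (see [build_target_stack()]).
#' @param mode `"mask_direction"` or `"heatmap"`.
#' @param mask_weight,direction_weight Term weights.
#' @param pos_weight Weight of positive pixels inside the BCE.
#' @return Scalar loss value.
#' @export
loss_stack <- function(pred, target, mode = c("mask_direction", "heatmap"),
                       mask_weight = 1, direction_weight = 1,
                       pos_weight = 1) {
  mode <- match.arg(mode)
  if (!identical(dim(pred), dim(target))) {
    stop("prediction and target shapes differ", call. = FALSE)
  }
  if (length(dim(pred)) == 4L) {
    pt <- do.call(rbind, lapply(seq_len(dim(pred)[4]),
                                function(b) .stack_tokens(pred[, , , b])))
    tt <- do.call(rbind, lapply(seq_len(dim(target)[4]),
                                function(b) .stack_tokens(target[, , , b])))
  } else {
    pt <- .stack_tokens(pred); tt <- .stack_tokens(target)
  }
  .loss_node(ad_const(pt), tt, mode, mask_weight, direction_weight,
             pos_weight)$value
}

#' Training configuration
#'
#' Defaults follow the training protocol: AdamW with initial learning rate
#' 1e-4 annealed to `lr_min` on a cosine schedule over `epochs` epochs
#' (default 200).
#'
#' @param epochs Training epochs (>= 1).
#' @param initial_lr Initial learning rate (> 0).
#' @param lr_min Final learning rate of the cosine schedule.
#' @param batch_size Slices per optimization step.
#' @param seed Master seed for splitting, shuffling, augmentation and
#'   initialization.
#' @param landmark_mode `"mask_direction"` or `"heatmap"` supervision.
#' @param weight_decay AdamW decoupled weight decay (not applied to norms
#'   and biases).
#' @param pos_weight BCE positive-class weight compensating the sparsity of
#'   defect-mask pixels (about 0.5% of the image). Moderate values keep the
#'   decoded mask extent close to the true segment; large values dilate it.
#' @param mask_width_px Target mask width.
#' @param sigma_px Heatmap sigma (heatmap mode).
#' @param mask_weight,direction_weight Loss term weights.
#' @param augment Logical, apply random augmentation to training slices.
#' @param augment_spec An [augment_spec()].
#' @param val_every Compute the validation loss every this many epochs
#'   (checkpointing still tracks the best validated epoch).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 200L, initial_lr = 1e-4, lr_min = 1e-6,
                         batch_size = 8L, seed = 42L,
                         landmark_mode = c("mask_direction", "heatmap"),
                         weight_decay = 0.01, pos_weight = 5,
                         mask_width_px = 3, sigma_px = 2, mask_weight = 1,
                         direction_weight = 1, augment = TRUE,
                         augment_spec = fenestra::augment_spec(),
                         val_every = 1L) {
  landmark_mode <- match.arg(landmark_mode)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (initial_lr <= 0) stop("initial_lr must be positive", call. = FALSE)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_min = lr_min, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), landmark_mode = landmark_mode,
                 weight_decay = weight_decay, pos_weight = pos_weight,
                 mask_width_px = mask_width_px, sigma_px = sigma_px,
                 mask_weight = mask_weight,
                 direction_weight = direction_weight,
                 augment = augment, augment_spec = augment_spec,
                 val_every = as.integer(val_every)),
            class = "train_config")
}

#' Cosine-annealed learning rate at a given epoch
#' @param epoch Epoch index (1-based).
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, config) {
  e <- config$epochs
  frac <- if (e == 1L) 0 else (epoch - 1) / (e - 1)
  config$lr_min + (config$initial_lr - config$lr_min) *
    (1 + cos(pi * frac)) / 2
}

# flatten a dataset into per-slice records for a subset of patients
.dataset_slices <- function(dataset, split = NULL, subset = NULL) {
  recs <- list()
  for (s in dataset$series) {
    if (!is.null(split)) {
      sub <- split$subset[match(s$patient_id, split$patient_id)]
      if (!is.null(subset) && !identical(sub, subset)) next
    }
    for (k in seq_along(s$slices)) {
      sl <- s$slices[[k]]
      recs[[length(recs) + 1L]] <- list(
        patient_id = s$patient_id, tooth_id = s$tooth_id,
        slice_index = k - 1L, image = sl$image$pixels,
        annotation = sl$annotation,
        pixel_pitch_mm = sl$image$pixel_pitch_mm)
    }
  }
  recs
}

.encode_batch <- function(recs, mode, mask_width_px, sigma_px) {
  H <- nrow(recs[[1]]$image); W <- ncol(recs[[1]]$image)
  imgs <- array(0, c(H, W, length(recs)))
  tts <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    imgs[, , i] <- standardize(recs[[i]]$image)
    st <- build_target_stack(recs[[i]]$annotation, c(H, W), mode,
                             mask_width_px, heatmap_spec(sigma_px))
    tts[[i]] <- .stack_tokens(st)
  }
  list(images = imgs, targets = do.call(rbind, tts))
}

#' Train the detector
#'
#' Patient-level 7:2:1 split, per-epoch shuffled minibatches, optional
#' random augmentation, AdamW with cosine-annealed learning rate, and
#' checkpointing of the weights with the lowest validation loss.
#'
#' @param dataset A `phantom_dataset` (or any list with the same structure).
#' @param net A [net_config()] or an already-initialized `swin_unetr`.
#' @param config A [train_config()].
#' @param split Optional precomputed [split_patients()] assignment; computed
#'   from the dataset's patients with ratios 7:2:1 otherwise.
#' @param verbose Print per-epoch progress.
#' @return A `fenestra_fit`: the best-validation model plus `history`
#'   (tibble of epoch, lr, train/val loss), the split, and both configs.
#' @export
train_model <- function(dataset, net = net_config_tiny(),
                        config = train_config(), split = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(config, "train_config"))
  set.seed(config$seed)
  if (is.null(split)) {
    split <- split_patients(unique(dataset$manifest$patient_id),
                            c(7, 2, 1), seed = config$seed)
  }
  model <- if (inherits(net, "swin_unetr")) net else
    init_model(net, seed = config$seed)

  train_recs <- .dataset_slices(dataset, split, "train")
  val_recs <- .dataset_slices(dataset, split, "val")
  if (!length(train_recs)) stop("empty training split", call. = FALSE)
  mode <- config$landmark_mode
  st <- adamw_state(model$params, weight_decay = config$weight_decay)
  no_decay <- names(model$params)[grepl("(_b$|ln_g$|ln_b$|bias_table|\\.b$)",
                                        names(model$params))]

  val_batches <- NULL
  if (length(val_recs)) {
    vb <- split(seq_along(val_recs),
                ceiling(seq_along(val_recs) / config$batch_size))
    val_batches <- lapply(vb, function(ix) {
      .encode_batch(val_recs[ix], mode, config$mask_width_px,
                    config$sigma_px)
    })
  }

  history <- vector("list", config$epochs)
  best_val <- Inf; best_values <- NULL; best_epoch <- NA_integer_
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(epoch, config)
    ord <- sample(seq_along(train_recs))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bi in batches) {
      recs <- train_recs[bi]
      if (config$augment) {
        recs <- lapply(recs, function(r) {
          a <- suppressMessages(augment(r$image, r$annotation,
                                        config$augment_spec))
          r$image <- a$image; r$annotation <- a$annotation; r
        })
      }
      eb <- .encode_batch(recs, mode, config$mask_width_px, config$sigma_px)
      fw <- .forward_node(model, eb$images)
      loss <- .loss_node(fw$logits, eb$targets, mode, config$mask_weight,
                         config$direction_weight, config$pos_weight)
      ad_backward(loss)
      adamw_step(model$params, st, lr, no_decay)
      tl <- tl + loss$value * length(bi)
    }
    tl <- tl / length(train_recs)

    vl <- NA_real_
    val_every <- config$val_every %||% 1L
    if (!is.null(val_batches) &&
        (epoch %% val_every == 0L || epoch == config$epochs)) {
      vtot <- 0; vn <- 0
      for (eb in val_batches) {
        fw <- ad_no_grad(.forward_node(model, eb$images))
        l <- .loss_node(ad_const(fw$logits$value), eb$targets, mode,
                        config$mask_weight, config$direction_weight,
                        config$pos_weight)
        nb <- dim(eb$images)[3]
        vtot <- vtot + l$value * nb; vn <- vn + nb
      }
      vl <- vtot / vn
      if (vl < best_val) {
        best_val <- vl
        best_epoch <- epoch
        best_values <- lapply(model$params, function(p) p$value)
      }
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                       train_loss = tl, val_loss = vl)
    if (verbose) {
      message(sprintf("epoch %3d/%d  lr %.2e  train %.4f  val %s", epoch,
                      config$epochs, lr, tl,
                      if (is.na(vl)) "-" else sprintf("%.4f", vl)))
    }
  }
  if (!is.null(best_values)) {
    for (nm in names(best_values)) model$params[[nm]]$value <- best_values[[nm]]
  } else {
    best_epoch <- config$epochs
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 split = split, config = config,
                 net_config = model$config, best_epoch = best_epoch),
            class = "fenestra_fit")
}

# evaluate expressions with gradient tracking disabled
ad_no_grad <- function(expr) {
  old <- .ad_state$no_grad %||% FALSE
  .ad_state$no_grad <- TRUE
  on.exit(.ad_state$no_grad <- old)
  force(expr)
}

#' @export
print.fenestra_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<fenestra_fit> %d epochs, best val loss %.4f (epoch %d)\n",
              nrow(h), min(h$val_loss, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy fenestra_fit
#' @export
tidy.fenestra_fit <- function(x, ...) x$history

#' @method glance fenestra_fit
#' @export
glance.fenestra_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h), best_epoch = x$best_epoch,
    best_val_loss = if (all(is.na(h$val_loss))) NA_real_ else
      min(h$val_loss, na.rm = TRUE),
    final_train_loss = h$train_loss[nrow(h)],
    n_params = net_num_params(x$model))
}
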