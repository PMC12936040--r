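# Shared fixtures: small phantom specs and noiseless target helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

fast_spec <- function(h = 96L, w = 64L, ...) {
  phantom_spec(image_height_px = h, image_width_px = w, ...)
}

clean_spec <- function(h = 320L, w = 224L, ...) {
  phantom_spec(image_height_px = h, image_width_px = w, noise_sd = 0,
               blur_sigma_px = 0, ...)
}

# target stack with mask channels mapped to confident logits, so decoding a
# noiseless encoding exercises the same path as decoding a prediction
target_as_logits <- function(stack) {
  for (g in c(1, 4, 7, 10)) stack[, , g] <- (stack[, , g] * 2 - 1) * 10
  stack
}

# random annotated slice (guaranteed at least one defect) for round trips
random_annotated_slice <- function(spec, seed) {
  ts <- generate_tooth_series(spec, seed = seed)
  for (sl in ts$slices) {
    if (length(sl$annotation$defects)) return(sl)
  }
  cls <- sample(defect_classes()$class, 1)
  len <- stats::runif(1, 1, 5.5)
  ts <- generate_tooth_series(spec, seed = seed,
                              force_defects = stats::setNames(len, cls))
  ts$slices[[1]]
}

tiny_train_config <- function(...) {
  train_config(batch_size = 8L, initial_lr = 3e-4, seed = 1L, ...)
}
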