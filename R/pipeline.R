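#' Pipeline configuration
#'
#' One object driving the whole reproducible pipeline: phantom generation,
#' patient-level splitting, training, prediction, decoding and evaluation.
#' All randomness flows from `seed`, expanded deterministically per stage.
#'
#' @param out_dir Output directory for artifacts.
#' @param dataset_dir Optional directory with an existing dataset written by
#'   [write_dataset()]; when `NULL`, `phantom` must be given and the dataset
#'   is generated.
#' @param phantom A [phantom_spec()] (or `NULL` when `dataset_dir` is set).
#' @param n_patients,teeth_per_patient Phantom dataset size.
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @param tolerance_mm Keypoint match tolerance for evaluation.
#' @param mask_threshold Decoder probability threshold.
#' @param seed Master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, dataset_dir = NULL,
                            phantom = phantom_spec(), n_patients = 30L,
                            teeth_per_patient = 3L,
                            net = net_config_tiny(),
                            train = train_config(epochs = 20L),
                            tolerance_mm = 2, mask_threshold = 0.5,
                            seed = 7L) {
  if (missing(out_dir) || is.null(out_dir)) {
    stop("pipeline config requires an output directory", call. = FALSE)
  }
  if (is.null(dataset_dir) && is.null(phantom)) {
    stop("pipeline config needs a dataset path or a phantom spec",
         call. = FALSE)
  }
  if (tolerance_mm <= 0) stop("tolerance_mm must be positive", call. = FALSE)
  structure(list(out_dir = out_dir, dataset_dir = dataset_dir,
                 phantom = phantom, n_patients = as.integer(n_patients),
                 teeth_per_patient = as.integer(teeth_per_patient),
                 net = net, train = train, tolerance_mm = tolerance_mm,
                 mask_threshold = mask_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `images/`, `annotations.json` and
#'   `manifest.csv`.
#' @return A `phantom_dataset`-shaped object.
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  anns <- read_annotations(file.path(dir, "annotations.json"))
  key <- vapply(anns, function(a) paste(a$tooth_id, a$slice_index),
                character(1))
  series <- lapply(seq_len(nrow(manifest)), function(i) {
    tid <- manifest$tooth_id[i]
    slices <- lapply(0:2, function(k) {
      ann <- anns[[match(paste(tid, k), key)]]
      img <- png::readPNG(file.path(dir, "images",
                                    sprintf("%s_s%d.png", tid, k)))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      list(image = structure(list(pixels = round(img * 255),
                                  pixel_pitch_mm = ann$pixel_pitch_mm),
                             class = "slice_image"),
           annotation = ann)
    })
    intended <- as.logical(unlist(manifest[i, grep("^intended_",
                                                   names(manifest))]))
    names(intended) <- sub("^intended_", "",
                           grep("^intended_", names(manifest), value = TRUE))
    structure(list(patient_id = manifest$patient_id[i], tooth_id = tid,
                   intended = intended, slices = slices),
              class = "tooth_series")
  })
  structure(list(series = series, manifest = manifest, spec = NULL),
            class = "phantom_dataset")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Generate (or load) the phantom dataset, split patients 7:2:1, train the
#' network, predict and decode the held-out test slices, evaluate, and write
#' all artifacts (report JSON/CSV, detections, history, checkpoint, figures,
#' and a run manifest with seeds, config hash and library versions) under
#' `config$out_dir`. Reruns with the same config and seed reproduce the
#' report byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print progress.
#' @return List with `report`, `fit`, `dataset`, `detections` and `out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stale_flag <- file.path(config$out_dir, "STALE")
  file.create(stale_flag)

  dataset <- .stage("phantom", {
    if (!is.null(config$dataset_dir)) read_dataset(config$dataset_dir)
    else generate_dataset(config$n_patients, config$teeth_per_patient,
                          config$phantom, seed = config$seed)
  })

  split <- .stage("split", {
    split_patients(unique(dataset$manifest$patient_id), c(7, 2, 1),
                   seed = config$seed + 1L)
  })

  tcfg <- config$train
  tcfg$seed <- config$seed + 2L
  fit <- .stage("train", {
    train_model(dataset, config$net, tcfg, split = split, verbose = verbose)
  })

  ev <- .stage("evaluate", {
    evaluate_model(fit, dataset, "test", config$tolerance_mm,
                   config$mask_threshold)
  })

  .stage("report", {
    out <- config$out_dir
    write_report(ev$report, out)
    readr::write_csv(ev$detections, file.path(out, "detections.csv"))
    readr::write_csv(fit$history, file.path(out, "history.csv"))
    save_model(fit$model, file.path(out, "model.rds"))
    fig <- file.path(out, "figures")
    dir.create(fig, showWarnings = FALSE)
    if (nrow(ev$report$image_roc)) {
      grDevices::png(file.path(fig, "roc_image.png"), 800, 600)
      print(autoplot(ev$report, "roc"))
      grDevices::dev.off()
    }
    if (nrow(ev$report$agreement)) {
      grDevices::png(file.path(fig, "bland_altman.png"), 800, 600)
      print(autoplot(ev$report, "bland_altman"))
      grDevices::dev.off()
    }
    # overlay of the first test tooth's middle slice
    recs <- .dataset_slices(dataset, fit$split, "test")
    if (length(recs)) {
      r <- recs[[1]]
      dets <- predict_slices(fit$model, list(r$image), r$pixel_pitch_mm,
                             fit$config$landmark_mode,
                             config$mask_threshold)[[1]]
      grDevices::png(file.path(fig, "overlay_example.png"), 600, 800)
      print(plot_slice(r$image, r$annotation, dets))
      grDevices::dev.off()
    }
    manifest <- list(
      seed = config$seed,
      stage_seeds = list(phantom = config$seed, split = config$seed + 1L,
                         train = config$seed + 2L),
      config_hash = rlang::hash(list(
        phantom = if (!is.null(config$phantom)) unclass(config$phantom),
        n_patients = config$n_patients,
        teeth_per_patient = config$teeth_per_patient,
        net = unclass(config$net), train = unclass(rapply(
          list(config$train), unclass, how = "replace")[[1]]),
        tolerance_mm = config$tolerance_mm,
        mask_threshold = config$mask_threshold)),
      r_version = R.version.string,
      package_versions = {
        pkgs <- c("fenestra", "pROC", "jsonlite", "ggplot2",
                  "dplyr", "Rcpp")
        stats::setNames(lapply(pkgs, function(p)
          as.character(utils::packageVersion(p))), pkgs)
      })
    yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))
  })

  unlink(stale_flag)
  if (verbose) message("pipeline complete: ", config$out_dir)
  list(report = ev$report, fit = fit, dataset = dataset,
       detections = ev$detections, out_dir = config$out_dir)
}

#' Run the bundled scaled phantom study
#'
#' Generates a phantom dataset, trains the tiny network on the patient-level
#' 7:2:1 split and evaluates the held-out test patients. This is the
#' package's self-contained demonstration study: every number it reports is
#' computed end to end at run time. The default problem size (the render
#' size, cohort size, epochs and learning rate) is chosen to complete on a
#' single CPU in minutes; see the methods vignette for the rationale.
#'
#' @param seed Master seed for generation, splitting and training.
#' @param n_patients,teeth_per_patient Cohort size.
#' @param image_height_px,image_width_px Render size (the pixel pitch scales
#'   so the field of view stays fixed).
#' @param epochs,initial_lr,batch_size,pos_weight Training settings.
#' @param net Network architecture (defaults to a 0.54M-parameter preset).
#' @param verbose Print per-epoch progress.
#' @return List with `dataset`, `fit`, `evaluation` (see
#'   [evaluate_model()]), `report` and `summary`, a one-row tibble of the
#'   headline quantities (keypoint recognition rate, pooled length PCC,
#'   per-class accuracies).
#' @export
run_scaled_study <- function(seed = 7L, n_patients = 50L,
                             teeth_per_patient = 3L,
                             image_height_px = 96L, image_width_px = 64L,
                             epochs = 30L, initial_lr = 1e-3,
                             batch_size = 14L, pos_weight = 4,
                             net = net_config(patch_size = 2L,
                                              embed_dim = 16L,
                                              depths = c(2L, 2L, 2L, 2L),
                                              heads = c(2L, 2L, 4L, 4L),
                                              window_size = 4L,
                                              mlp_ratio = 2),
                             verbose = TRUE) {
  spec <- phantom_spec(image_height_px, image_width_px, seed = seed)
  dataset <- generate_dataset(n_patients, teeth_per_patient, spec,
                              seed = seed)
  split <- split_patients(unique(dataset$manifest$patient_id), c(7, 2, 1),
                          seed = seed + 1L)
  cfg <- train_config(epochs = epochs, initial_lr = initial_lr,
                      batch_size = batch_size, seed = seed + 2L,
                      pos_weight = pos_weight, val_every = 2L)
  fit <- train_model(dataset, net, cfg, split = split,
                     verbose = verbose)
  ev <- evaluate_model(fit, dataset, "test")
  rep <- ev$report
  pooled_pcc <- if (nrow(rep$length_pairs) >= 2) {
    stats::cor(rep$length_pairs$pred_mm, rep$length_pairs$true_mm)
  } else NA_real_
  acc <- stats::setNames(rep$image$accuracy,
                         paste0("image_accuracy_", rep$image$class))
  summary <- dplyr::bind_cols(
    tibble::tibble(recognition_rate = rep$keypoints$recognition_rate,
                   length_pcc = pooled_pcc,
                   n_test_slices = rep$n_slices),
    tibble::as_tibble(as.list(acc)))
  list(dataset = dataset, fit = fit, evaluation = ev, report = rep,
       summary = summary)
}
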