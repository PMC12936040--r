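test_that("patient split matches the rounded 7:2:1 shares", {
  s20 <- split_patients(sprintf("P%02d", 1:20), c(7, 2, 1), seed = 1)
  expect_equal(as.integer(table(s20$subset)[c("train", "val", "test")]),
               c(14L, 4L, 2L))
  s10 <- split_patients(sprintf("P%02d", 1:10), c(7, 2, 1), seed = 1)
  expect_equal(as.integer(table(s10$subset)[c("train", "val", "test")]),
               c(7L, 2L, 1L))

  again <- split_patients(sprintf("P%02d", 1:20), c(7, 2, 1), seed = 1)
  expect_identical(as.data.frame(s20), as.data.frame(again))

  expect_error(split_patients(c("a", "b"), c(7, 2, 1)), "fewer patients")
})

test_that("the split is patient-disjoint across many seeds", {
  ids <- sprintf("P%03d", 1:23)
  for (seed in 1:300) {
    s <- split_patients(ids, c(7, 2, 1), seed = seed)
    expect_equal(nrow(s), 23)
    expect_false(anyDuplicated(s$patient_id) > 0)
  }
})

test_that("identity augmentation leaves image and landmarks unchanged", {
  spec_id <- augment_spec(scale_range = c(1, 1),
                          rotation_range_deg = c(0, 0),
                          translation_range_frac = c(0, 0),
                          blur_sigma_range_px = c(0, 0),
                          noise_sd_range = c(0, 0))
  img <- matrix(runif(48 * 32, 0, 255), 48, 32)
  ann <- slice_annotation("P", "T", 0, 0.25,
                          list(landmark_pair("buccal_dehiscence", c(10, 12),
                                             c(14, 30))))
  out <- augment(img, ann, spec_id, seed = 1)
  expect_equal(out$image, img, tolerance = 1e-9)
  expect_equal(out$annotation$defects[[1]]$p1, c(10, 12))
  expect_equal(out$annotation$defects[[1]]$p2, c(14, 30))
})

test_that("rotation moves landmarks by the same affine map as pixels", {
  H <- 41; W <- 41
  img <- matrix(0, H, W)
  img[1, 11] <- 255          # point (x=10, y=0)
  ann <- slice_annotation("P", "T", 0, 0.25,
                          list(landmark_pair("buccal_dehiscence", c(10, 0),
                                             c(20, 20))))
  out <- augment(img, ann, params = list(scale = 1, rotation_deg = 90,
                                         tx_frac = 0, ty_frac = 0,
                                         blur = 0, noise = 0))
  # independent affine oracle: rotate (10,0) by 90 deg about the centre
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expected <- as.numeric(R %*% (c(10, 0) - c(cx, cy))) + c(cx, cy)
  got <- out$annotation$defects[[1]]$p1
  expect_lt(sqrt(sum((got - expected)^2)), 1e-6)
  # and the bright pixel landed where the landmark says (within 0.5 px)
  hit <- which(out$image == max(out$image), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((c(hit[2] - 1, hit[1] - 1) - got)^2)), 0.5 + 1e-9)
})

test_that("photometric-only augmentation keeps landmarks bit-identical", {
  img <- matrix(runif(48 * 32, 0, 255), 48, 32)
  ann <- slice_annotation("P", "T", 0, 0.25,
                          list(landmark_pair("lingual_fenestration",
                                             c(9, 7), c(11, 29))))
  out <- augment(img, ann, seed = 3,
                 params = list(scale = 1, rotation_deg = 0, tx_frac = 0,
                               ty_frac = 0, blur = 1.2, noise = 0.04))
  expect_identical(out$annotation$defects[[1]]$p1, c(9, 7))
  expect_identical(out$annotation$defects[[1]]$p2, c(11, 29))
  expect_gt(mean(abs(out$image - img)), 0)
})

test_that("augmentation drops out-of-bounds pairs with a logged count", {
  img <- matrix(0, 32, 32)
  ann <- slice_annotation("P", "T", 0, 0.25,
                          list(landmark_pair("buccal_dehiscence", c(28, 28),
                                             c(30, 30))))
  expect_message(
    out <- augment(img, ann, params = list(scale = 1, rotation_deg = 0,
                                           tx_frac = 0.4, ty_frac = 0.4,
                                           blur = 0, noise = 0)),
    "dropped")
  expect_length(out$annotation$defects, 0)
  expect_equal(attr(out$annotation, "n_dropped"), 1L)
})

test_that("augment_spec rejects ranges excluding the identity", {
  expect_error(augment_spec(scale_range = c(1.05, 1.2)), "identity")
})

test_that("standardization yields mean 0 / SD 1 and affine invariance", {
  img <- matrix(runif(100, 10, 200), 10, 10)
  s <- standardize(img)
  expect_lt(abs(mean(s)), 1e-6)
  expect_lt(abs(sd(s) - 1), 1e-6)
  expect_equal(standardize(3.7 * img + 11), s, tolerance = 1e-9)
  expect_warning(z <- standardize(matrix(5, 4, 4)), "constant")
  expect_true(all(z == 0))
})

test_that("the composite loss matches its closed forms", {
  ann <- slice_annotation("P", "T", 0, 0.25,
                          list(landmark_pair("buccal_dehiscence", c(5, 5),
                                             c(5, 25))))
  tgt <- build_target_stack(ann, c(32, 16))

  # perfect fit: masks at confident logits, directions exact
  pred <- tgt
  for (g in c(1, 4, 7, 10)) pred[, , g] <- (tgt[, , g] * 2 - 1) * 20
  expect_lt(loss_stack(pred, tgt), 1e-6)

  # all-zero logits vs all-zero targets: ln 2 per pixel per mask channel
  zero_t <- build_target_stack(slice_annotation("P", "T", 0, 0.25),
                               c(32, 16))
  expect_equal(loss_stack(zero_t * 0, zero_t), 4 * log(2), tolerance = 1e-9)

  # constant direction offset c on every pixel: per-group MSE is |c|^2 / 2
  # (mean over the two direction channels)
  cvec <- c(0.3, -0.4)
  pred2 <- zero_t * 0
  pred2[, , 2] <- cvec[1]; pred2[, , 3] <- cvec[2]
  pred2[, , c(1, 4, 7, 10)] <- -40   # silence the BCE terms
  expect_equal(loss_stack(pred2, zero_t), sum(cvec^2) / 2, tolerance = 1e-6)

  expect_error(loss_stack(pred[, , 1:6], tgt), "shapes differ")
})

test_that("cosine schedule starts at the initial rate and decays", {
  cfg <- train_config(epochs = 50L, initial_lr = 1e-3, lr_min = 1e-5)
  lrs <- vapply(1:50, cosine_lr, numeric(1), config = cfg)
  expect_equal(lrs[1], 1e-3)
  expect_equal(lrs[50], 1e-5)
  expect_lt(lrs[50], lrs[1])
  expect_true(all(diff(lrs) < 0))
})

test_that("training on a small overfit set drives the loss down", {
  spec <- fast_spec(48L, 32L)
  ds <- generate_dataset(7, 1, spec, seed = 4)
  net <- net_config(patch_size = 2L, embed_dim = 8L,
                    depths = c(1L, 1L, 1L, 1L), heads = c(2L, 2L, 2L, 2L),
                    window_size = 3L, mlp_ratio = 2)
  cfg <- train_config(epochs = 6L, initial_lr = 1e-3, batch_size = 7L,
                      seed = 9L, augment = FALSE, pos_weight = 10)
  fit <- train_model(ds, net, cfg, verbose = FALSE)
  h <- fit$history
  expect_equal(nrow(h), 6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  # memorization sanity: first epochs decrease monotonically
  expect_true(all(diff(h$train_loss[1:5]) < 0))
  expect_lt(h$lr[6], h$lr[1])
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$epochs, 6)
})

test_that("one-epoch training yields a one-row history", {
  spec <- fast_spec(48L, 32L)
  ds <- generate_dataset(4, 1, spec, seed = 2)
  net <- net_config(patch_size = 2L, embed_dim = 4L,
                    depths = c(1L, 1L, 1L, 1L), heads = c(1L, 1L, 1L, 1L),
                    window_size = 3L, mlp_ratio = 2)
  fit <- train_model(ds, net, train_config(epochs = 1L, batch_size = 4L,
                                           seed = 3L, augment = FALSE),
                     verbose = FALSE)
  expect_equal(nrow(fit$history), 1)
})
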