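test_that("full-extent windowed attention equals global self-attention", {
  set.seed(31)
  H <- 16; W <- 16; C <- 8; nh <- 2
  feat <- array(rnorm(H * W * C), c(H, W, C))
  qkv_w <- matrix(rnorm(C * 3 * C, sd = 0.2), C, 3 * C)
  qkv_b <- rnorm(3 * C, sd = 0.1)
  proj_w <- matrix(rnorm(C * C, sd = 0.2), C, C)
  proj_b <- rnorm(C, sd = 0.1)
  out <- window_attention(feat, qkv_w, qkv_b, proj_w, proj_b, nh,
                          window_size = 16L)

  # brute-force global attention with the same weights
  X <- matrix(aperm(feat, c(2, 1, 3)), H * W, C)
  qkv <- sweep(X %*% qkv_w, 2, qkv_b, "+")
  dh <- C / nh
  O <- matrix(0, H * W, C)
  for (h in 1:nh) {
    ix <- ((h - 1) * dh + 1):(h * dh)
    q <- qkv[, ix]; k <- qkv[, C + ix]; v <- qkv[, 2 * C + ix]
    A <- q %*% t(k) / sqrt(dh)
    A <- exp(A - apply(A, 1, max)); A <- A / rowSums(A)
    O[, ix] <- A %*% v
  }
  O <- sweep(O %*% proj_w, 2, proj_b, "+")
  oracle <- aperm(array(O, c(W, H, C)), c(2, 1, 3))
  expect_lt(max(abs(out - oracle)), 1e-5)
})

test_that("zero features stay finite and unshifted windows do not leak", {
  C <- 4; nh <- 1
  qkv_w <- matrix(rnorm(C * 3 * C, sd = 0.3), C, 3 * C)
  qkv_b <- rnorm(3 * C, sd = 0.1)
  proj_w <- diag(C); proj_b <- numeric(C)

  z <- window_attention(array(0, c(8, 8, C)), qkv_w, qkv_b, proj_w, proj_b,
                        nh, window_size = 4L)
  expect_true(all(is.finite(z)))

  # permuting whole windows permutes outputs identically (window size 4 on
  # an 8x8 map -> four windows)
  set.seed(5)
  feat <- array(rnorm(8 * 8 * C), c(8, 8, C))
  out <- window_attention(feat, qkv_w, qkv_b, proj_w, proj_b, nh, 4L)
  perm <- feat
  perm[1:4, 1:4, ] <- feat[5:8, 5:8, ]   # swap two windows
  perm[5:8, 5:8, ] <- feat[1:4, 1:4, ]
  out_p <- window_attention(perm, qkv_w, qkv_b, proj_w, proj_b, nh, 4L)
  expect_equal(out_p[1:4, 1:4, ], out[5:8, 5:8, ], tolerance = 1e-10)
  expect_equal(out_p[5:8, 5:8, ], out[1:4, 1:4, ], tolerance = 1e-10)
  expect_equal(out_p[1:4, 5:8, ], out[1:4, 5:8, ], tolerance = 1e-10)

  expect_error(window_attention(feat, qkv_w, qkv_b, proj_w, proj_b, nh,
                                window_size = 9L), "window larger")
})

test_that("shifted windows mix information across window boundaries", {
  set.seed(6)
  C <- 4
  qkv_w <- matrix(rnorm(C * 3 * C, sd = 0.3), C, 3 * C)
  qkv_b <- numeric(3 * C)
  proj_w <- diag(C); proj_b <- numeric(C)
  feat <- array(rnorm(8 * 8 * C), c(8, 8, C))
  out_u <- window_attention(feat, qkv_w, qkv_b, proj_w, proj_b, 1L, 4L,
                            shift = FALSE)
  out_s <- window_attention(feat, qkv_w, qkv_b, proj_w, proj_b, 1L, 4L,
                            shift = TRUE)
  expect_true(all(is.finite(out_s)))
  expect_gt(max(abs(out_s - out_u)), 1e-6)
})

test_that("patch merging halves resolution and doubles channels", {
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  expect_equal(dim(patch_merge(x)), c(4, 4, 10))
  # odd extent is zero-padded before merging
  x2 <- array(rnorm(7 * 8 * 5), c(7, 8, 5))
  expect_equal(dim(patch_merge(x2)), c(4, 4, 10))
})

test_that("the network maps images to 12-channel maps at input resolution", {
  model <- init_model(net_config_tiny(), seed = 4)
  img <- matrix(rnorm(64 * 64), 64, 64)
  out <- net_forward(model, img)
  expect_equal(dim(out), c(64, 64, 12, 1))
  expect_true(all(is.finite(out)))

  out2 <- net_forward(model, img)
  expect_identical(out, out2)   # inference determinism

  expect_error(net_forward(model, matrix(0, 10, 10)), "divisible")
})

test_that("stage resolutions follow the patch/merge schedule", {
  model <- init_model(net_config_tiny(), seed = 4)
  img <- array(rnorm(64 * 48 * 2), c(64, 48, 2))
  fw <- fenestra:::.forward_node(model, img)
  expect_equal(dim(fw$logits$value), c(64 * 48 * 2, 12))
  # 64x48, patch 2 then three merges: 32x24 -> 16x12 -> 8x6 -> 4x3
  pe <- fenestra:::.patch_idx(64, 48, 1, 2)
  expect_equal(c(pe$H, pe$W), c(32, 24))
  m1 <- fenestra:::.merge_idx(32, 24, 1)
  m2 <- fenestra:::.merge_idx(m1$H, m1$W, 1)
  m3 <- fenestra:::.merge_idx(m2$H, m2$W, 1)
  expect_equal(c(m3$H, m3$W), c(4, 3))
})

test_that("gradient reaches every parameter on a synthetic batch", {
  model <- init_model(net_config_tiny(), seed = 8)
  img <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  tgt <- matrix(0, 32 * 32 * 2, 12)
  tgt[sample(nrow(tgt), 60), 1] <- 1
  fw <- fenestra:::.forward_node(model, img)
  loss <- fenestra:::.loss_node(fw$logits, tgt, "mask_direction",
                                pos_weight = 5)
  fenestra:::ad_backward(loss)
  dead <- names(model$params)[vapply(model$params,
                                     function(p) is.null(p$grad) ||
                                       all(p$grad == 0), logical(1))]
  expect_length(dead, 0)
})

test_that("the tiny preset stays under 1M parameters and trains fast", {
  model <- init_model(net_config_tiny(), seed = 1)
  expect_lt(net_num_params(model), 1e6)
  img <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  tgt <- matrix(0, 64 * 64 * 4, 12)
  run <- function() {
    fw <- fenestra:::.forward_node(model, img)
    loss <- fenestra:::.loss_node(fw$logits, tgt, "mask_direction")
    fenestra:::ad_backward(loss)
    fenestra:::ad_zero_grads(model$params)
  }
  run()  # warm the geometry caches
  t0 <- Sys.time()
  run()
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
})

test_that("checkpoints round-trip weights and configs survive YAML", {
  model <- init_model(net_config_tiny(), seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(net_forward(back, img), net_forward(model, img))

  ypath <- withr::local_tempfile(fileext = ".yaml")
  net_config_yaml(model$config, ypath)
  cfg <- net_config_yaml(path = ypath)
  expect_equal(cfg, model$config)
})
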