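# 2D Swin-UNETR: hierarchical shifted-window transformer encoder with patch
# merging, plus a skip-connected convolutional decoder emitting the
# 12-channel prediction map. Built on the package's autodiff engine.
#
# Token layout: a feature map of size H x W with batch B is a matrix of
# B*H*W rows (batch outermost, then row y, with column x fastest) by C
# channels. All spatial reshuffles (window partition, patch merging, conv
# neighborhoods, pixel shuffle) are precomputed gather index vectors cached
# per input geometry.

#' Network configuration
#'
#' Architecture hyperparameters of the 2D Swin-UNETR. The encoder has four
#' stages of shifted-window transformer blocks with patch merging between
#' stages; the decoder upsamples with transposed convolutions (implemented
#' as linear pixel-shuffle) and concatenates encoder skips; the head emits
#' 12 channels (4 defect-class groups x mask + direction x/y).
#'
#' @param patch_size Patch embedding size (input downsampling factor of
#'   stage 1).
#' @param embed_dim Channels after patch embedding; doubles per stage.
#' @param depths Integer vector of 4 block counts per stage; within a stage
#'   blocks alternate unshifted / shifted windows.
#' @param heads Attention heads per stage; must divide the stage width.
#' @param window_size Attention window side in tokens.
#' @param mlp_ratio Width multiplier of the transformer MLPs.
#' @param stem_dim Channels of the full-resolution convolutional stem used
#'   as the finest decoder skip.
#' @param out_channels Output channels (12).
#' @return A `net_config` object.
#' @export
net_config <- function(patch_size = 2L, embed_dim = 24L,
                       depths = c(2L, 2L, 2L, 2L),
                       heads = c(3L, 6L, 12L, 24L), window_size = 7L,
                       mlp_ratio = 4, stem_dim = max(4L, embed_dim %/% 2L),
                       out_channels = 12L) {
  if (length(depths) != 4L || length(heads) != 4L) {
    stop("depths and heads must have 4 entries (4 encoder stages)",
         call. = FALSE)
  }
  if (window_size < 1L) stop("window_size must be >= 1", call. = FALSE)
  if (out_channels != 12L) stop("out_channels must be 12", call. = FALSE)
  dims <- embed_dim * 2^(0:3)
  if (any(dims %% heads != 0)) {
    stop("stage widths must be divisible by their head counts", call. = FALSE)
  }
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths), heads = as.integer(heads),
                 window_size = as.integer(window_size),
                 mlp_ratio = mlp_ratio, stem_dim = as.integer(stem_dim),
                 out_channels = 12L),
            class = "net_config")
}

#' Tiny preset for tests and CPU demos (about 0.3M parameters)
#' @return A `net_config`.
#' @export
net_config_tiny <- function() {
  net_config(patch_size = 2L, embed_dim = 12L, depths = c(2L, 2L, 1L, 1L),
             heads = c(2L, 2L, 4L, 4L), window_size = 4L, mlp_ratio = 2,
             stem_dim = 6L)
}

.rnorm_mat <- function(n, p, sd = 0.02) matrix(stats::rnorm(n * p, sd = sd), n, p)

#' Initialize a Swin-UNETR model
#'
#' Linear and attention weights are drawn N(0, 0.02); convolutional weights
#' use He initialization; layer-norm scales start at 1 and all biases and
#' relative-position-bias tables at 0.
#'
#' @param config A [net_config()].
#' @param seed RNG seed for the initialization.
#' @return A `swin_unetr` model object (parameters plus config).
#' @export
init_model <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  C <- config$embed_dim
  p <- config$patch_size
  w <- config$window_size
  nbias <- (2L * w - 1L)^2
  prm <- list()
  add <- function(name, value) prm[[name]] <<- ad_param(value)

  add("embed.w", .rnorm_mat(p * p, C))
  add("embed.b", numeric(C))
  add("embed.ln_g", rep(1, C)); add("embed.ln_b", numeric(C))

  for (s in 1:4) {
    Cs <- C * 2^(s - 1)
    nh <- config$heads[s]
    for (d in seq_len(config$depths[s])) {
      nm <- sprintf("s%d.b%d.", s, d)
      add(paste0(nm, "ln1_g"), rep(1, Cs)); add(paste0(nm, "ln1_b"), numeric(Cs))
      add(paste0(nm, "qkv_w"), .rnorm_mat(Cs, 3 * Cs))
      add(paste0(nm, "qkv_b"), numeric(3 * Cs))
      add(paste0(nm, "bias_table"), matrix(0, nbias, nh))
      add(paste0(nm, "proj_w"), .rnorm_mat(Cs, Cs))
      add(paste0(nm, "proj_b"), numeric(Cs))
      add(paste0(nm, "ln2_g"), rep(1, Cs)); add(paste0(nm, "ln2_b"), numeric(Cs))
      hid <- round(config$mlp_ratio * Cs)
      add(paste0(nm, "mlp1_w"), .rnorm_mat(Cs, hid))
      add(paste0(nm, "mlp1_b"), numeric(hid))
      add(paste0(nm, "mlp2_w"), .rnorm_mat(hid, Cs))
      add(paste0(nm, "mlp2_b"), numeric(Cs))
    }
    if (s < 4) {
      nm <- sprintf("merge%d.", s)
      add(paste0(nm, "ln_g"), rep(1, 4 * Cs)); add(paste0(nm, "ln_b"), numeric(4 * Cs))
      add(paste0(nm, "w"), .rnorm_mat(4 * Cs, 2 * Cs))
    }
  }

  he <- function(fan_in, nout) .rnorm_mat(fan_in, nout, sd = sqrt(2 / fan_in))
  for (l in 3:1) {
    Cl <- C * 2^(l - 1)
    nm <- sprintf("dec%d.", l)
    add(paste0(nm, "up_w"), he(2 * Cl, 4 * Cl))   # (2Cl -> 4*Cl) pixel shuffle
    add(paste0(nm, "up_b"), numeric(4 * Cl))
    add(paste0(nm, "conv_w"), he(9 * 2 * Cl, Cl))
    add(paste0(nm, "conv_b"), numeric(Cl))
  }
  # head: 12 logit channels per 2x2 output block, emitted at the stage-1
  # resolution and pixel-shuffled back to full resolution (the final
  # transposed convolution of the decoder)
  head_b <- numeric(4 * 12)
  for (ch in c(1L, 4L, 7L, 10L)) {
    head_b[((ch - 1L) * 4L + 1L):(ch * 4L)] <- -3  # prior-matched: defect
  }                                                # pixels are rare
  add("head.w", .rnorm_mat(C, 4 * 12)); add("head.b", head_b)

  structure(list(config = config, params = prm,
                 cache = new.env(parent = emptyenv())),
            class = "swin_unetr")
}

#' Number of trainable parameters
#' @param model A `swin_unetr`.
#' @return Integer parameter count.
#' @export
net_num_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' @export
print.swin_unetr <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<swin_unetr> embed %d, depths [%s], heads [%s], ",
                     "window %d, %s parameters\n"),
              cfg$embed_dim, paste(cfg$depths, collapse = ","),
              paste(cfg$heads, collapse = ","), cfg$window_size,
              format(net_num_params(x), big.mark = ",")))
  invisible(x)
}

# ---- geometry index caches ---------------------------------------------

.cache_get <- function(cache, key, builder) {
  if (is.null(cache[[key]])) cache[[key]] <- builder()
  cache[[key]]
}

# token order helper: rows (b outer, y, x fastest)
.tok_from_array_idx <- function(H, W, B) {
  b <- rep(seq_len(B), each = H * W)
  y <- rep(rep(0:(H - 1), each = W), times = B)
  x <- rep(0:(W - 1), times = H * B)
  (b - 1L) * H * W + x * H + y + 1L
}

.tokens_from_images <- function(images) {
  d <- dim(images)
  if (length(d) == 2L) { dim(images) <- c(d, 1L); d <- dim(images) }
  H <- d[1]; W <- d[2]; B <- d[3]
  matrix(images[.tok_from_array_idx(H, W, B)], ncol = 1L)
}

.array_from_tokens <- function(mat, H, W, B) {
  C <- ncol(mat)
  a <- array(mat, c(W, H, B, C))
  aperm(a, c(2, 1, 4, 3))   # H x W x C x B
}

# gather indices for one conv3x3 neighborhood (zero outside the map)
.conv3_idx <- function(H, W, B) {
  y <- rep(rep(0:(H - 1), each = W), times = B)
  x <- rep(0:(W - 1), times = H * B)
  boff <- rep((seq_len(B) - 1L) * H * W, each = H * W)
  lapply(list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, -1L), c(0L, 0L), c(0L, 1L),
              c(1L, -1L), c(1L, 0L), c(1L, 1L)), function(o) {
    yy <- y + o[1]; xx <- x + o[2]
    ok <- yy >= 0L & yy < H & xx >= 0L & xx < W
    ifelse(ok, boff + yy * W + xx + 1L, 0L)
  })
}

# patch-embedding gather (patch p, stride p)
.patch_idx <- function(H, W, B, p) {
  H1 <- H %/% p; W1 <- W %/% p
  y1 <- rep(rep(0:(H1 - 1), each = W1), times = B)
  x1 <- rep(0:(W1 - 1), times = H1 * B)
  boff <- rep((seq_len(B) - 1L) * H * W, each = H1 * W1)
  idx <- list()
  for (dy in 0:(p - 1)) for (dx in 0:(p - 1)) {
    idx[[length(idx) + 1L]] <- boff + (y1 * p + dy) * W + (x1 * p + dx) + 1L
  }
  list(idx = idx, H = H1, W = W1)
}

# 2x2 patch-merging gather (ceil halving, zero-padded)
.merge_idx <- function(H, W, B) {
  H2 <- (H + 1L) %/% 2L; W2 <- (W + 1L) %/% 2L
  y2 <- rep(rep(0:(H2 - 1), each = W2), times = B)
  x2 <- rep(0:(W2 - 1), times = H2 * B)
  boff <- rep((seq_len(B) - 1L) * H * W, each = H2 * W2)
  one <- function(dy, dx) {
    yy <- y2 * 2L + dy; xx <- x2 * 2L + dx
    ok <- yy < H & xx < W
    ifelse(ok, boff + yy * W + xx + 1L, 0L)
  }
  list(idx = list(one(0L, 0L), one(1L, 0L), one(0L, 1L), one(1L, 1L)),
       H = H2, W = W2)
}

# pixel-shuffle upsampling gather: fine row -> row of the (4*Nc x C) matrix
.up_idx <- function(Hc, Wc, B, Ht, Wt) {
  y <- rep(rep(0:(Ht - 1), each = Wt), times = B)
  x <- rep(0:(Wt - 1), times = Ht * B)
  boff <- rep((seq_len(B) - 1L) * Hc * Wc, each = Ht * Wt)
  list(coarse = boff + (y %/% 2L) * Wc + (x %/% 2L) + 1L,
       offset = (y %% 2L) * 2L + (x %% 2L) + 1L)
}

# window partition / reverse / mask / relative-position indices
.window_cache <- function(H, W, B, ws, shift, table_ws) {
  s <- if (shift) ws %/% 2L else 0L
  Hp <- ((H + ws - 1L) %/% ws) * ws
  Wp <- ((W + ws - 1L) %/% ws) * ws
  nwy <- Hp %/% ws; nwx <- Wp %/% ws
  nwin <- nwy * nwx
  wsq <- ws * ws

  win_y <- rep(0:(nwy - 1L), each = nwx)
  win_x <- rep(0:(nwx - 1L), times = nwy)
  ty <- rep(0:(ws - 1L), each = ws)
  tx <- rep(0:(ws - 1L), times = ws)
  # per (win, tok), tok fastest
  y_v <- rep(win_y * ws, each = wsq) + rep(ty, nwin)
  x_v <- rep(win_x * ws, each = wsq) + rep(tx, nwin)
  y_src <- (y_v + s) %% Hp
  x_src <- (x_v + s) %% Wp
  real <- y_src < H & x_src < W
  base <- ifelse(real, y_src * W + x_src + 1L, 0L)
  boff <- rep((seq_len(B) - 1L) * H * W, each = nwin * wsq)
  idx <- ifelse(rep(base, B) == 0L, 0L, rep(base, B) + boff)

  # inverse: original token -> its position in window order
  yo <- rep(rep(0:(H - 1), each = W), times = B)
  xo <- rep(0:(W - 1), times = H * B)
  yp <- (yo - s) %% Hp; xp <- (xo - s) %% Wp
  wpos <- (yp %/% ws) * nwx + (xp %/% ws)
  tpos <- (yp %% ws) * ws + (xp %% ws)
  inv <- rep((seq_len(B) - 1L) * nwin * wsq, each = H * W) +
    wpos * wsq + tpos + 1L

  # attention mask (needed when shifted or padded)
  mask <- NULL
  if (s > 0L || Hp != H || Wp != W) {
    band <- function(v, P) {
      if (s == 0L) rep(0L, length(v))
      else ifelse(v < P - ws, 0L, ifelse(v < P - s, 1L, 2L))
    }
    id <- ifelse(real, band(y_src, Hp) * 3L + band(x_src, Wp), -1L)
    mask <- array(0, c(wsq, wsq, nwin))
    for (wi in seq_len(nwin)) {
      ids <- id[((wi - 1L) * wsq + 1L):(wi * wsq)]
      mask[, , wi] <- ifelse(outer(ids, ids, `==`), 0, -1e9)
    }
  }

  di <- rep(ty, wsq) - rep(ty, each = wsq)   # query index fastest
  dj <- rep(tx, wsq) - rep(tx, each = wsq)
  relidx <- (di + table_ws - 1L) * (2L * table_ws - 1L) +
    (dj + table_ws - 1L) + 1L

  list(idx = idx, inv = inv, nwin = nwin, wsq = wsq, mask = mask,
       relidx = relidx, Hp = Hp, Wp = Wp)
}

# ---- forward building blocks -------------------------------------------

.attention <- function(x, H, W, B, C, nh, ws, shift, prm, cache, table_ws) {
  key <- sprintf("win_%d_%d_%d_%d_%d", H, W, B, ws, as.integer(shift))
  wc <- .cache_get(cache, key,
                   function() .window_cache(H, W, B, ws, shift, table_ws))
  dh <- C %/% nh
  wsq <- wc$wsq
  nW <- B * wc$nwin
  S <- nh * nW

  xw <- ad_gather_rows(x, wc$idx)
  qkv <- ad_linear(xw, prm$qkv_w, prm$qkv_b)
  qc <- ad_split_heads(qkv, wsq, nW, dh, nh, 0L)
  kc <- ad_split_heads(qkv, wsq, nW, dh, nh, C)
  vc <- ad_split_heads(qkv, wsq, nW, dh, nh, 2L * C)

  attn <- ad_scale(ad_bmm(qc, kc, tb = TRUE), 1 / sqrt(dh))  # (wsq, wsq, S)
  bias <- ad_reshape(ad_gather_rows(prm$bias_table, wc$relidx),
                     c(wsq, wsq, nh))
  attn <- ad_add_expand(attn, bias, rep(seq_len(nh), times = nW))
  if (!is.null(wc$mask)) {
    win_of_slice <- ((((seq_len(S) - 1L) %/% nh)) %% wc$nwin) + 1L
    attn <- ad_add_expand(attn, ad_const(wc$mask), win_of_slice)
  }
  attn <- ad_softmax_keys(attn)

  out <- ad_bmm(attn, vc)                              # (wsq, dh, S)
  out <- ad_merge_heads(out, wsq, nW, dh, nh, C)
  out <- ad_linear(out, prm$proj_w, prm$proj_b)
  ad_gather_rows(out, wc$inv)
}

.swin_block <- function(x, H, W, B, C, nh, ws, shift, prm, cache, table_ws) {
  # single-window maps gain nothing from shifting
  if (H <= ws && W <= ws) shift <- FALSE
  a <- ad_layernorm(x, prm$ln1_g, prm$ln1_b)
  a <- .attention(a, H, W, B, C, nh, min(ws, max(H, W)), shift, prm, cache,
                  table_ws)
  x <- ad_add(x, a)
  m <- ad_layernorm(x, prm$ln2_g, prm$ln2_b)
  m <- ad_gelu(ad_linear(m, prm$mlp1_w, prm$mlp1_b))
  m <- ad_linear(m, prm$mlp2_w, prm$mlp2_b)
  ad_add(x, m)
}

.block_params <- function(model, s, d) {
  pick <- function(suffix) model$params[[sprintf("s%d.b%d.%s", s, d, suffix)]]
  list(ln1_g = pick("ln1_g"), ln1_b = pick("ln1_b"), qkv_w = pick("qkv_w"),
       qkv_b = pick("qkv_b"), bias_table = pick("bias_table"),
       proj_w = pick("proj_w"), proj_b = pick("proj_b"),
       ln2_g = pick("ln2_g"), ln2_b = pick("ln2_b"),
       mlp1_w = pick("mlp1_w"), mlp1_b = pick("mlp1_b"),
       mlp2_w = pick("mlp2_w"), mlp2_b = pick("mlp2_b"))
}

.conv3 <- function(x, H, W, B, w, b, cache) {
  key <- sprintf("c3_%d_%d_%d", H, W, B)
  idx <- .cache_get(cache, key,
                    function() unlist(.conv3_idx(H, W, B), use.names = FALSE))
  ad_conv_linear(x, w, b, idx, 9L)
}

.upsample <- function(x, Hc, Wc, B, Ht, Wt, Cout, w, b, cache) {
  key <- sprintf("up_%d_%d_%d_%d_%d", Hc, Wc, B, Ht, Wt)
  ix <- .cache_get(cache, key, function() .up_idx(Hc, Wc, B, Ht, Wt))
  m <- ad_linear(x, w, b)                              # (Nc x 4*Cout)
  ad_pixel_shuffle(m, ix$coarse, ix$offset, Cout)
}

# Full forward pass; returns the logits node (B*H*W x 12) plus geometry.
.forward_node <- function(model, images) {
  cfg <- model$config
  prm <- model$params
  cache <- model$cache
  d <- dim(images)
  if (length(d) == 2L) dim(images) <- c(d, 1L)
  H <- dim(images)[1]; W <- dim(images)[2]; B <- dim(images)[3]
  p <- cfg$patch_size
  if (H %% (p * 8L) != 0L || W %% (p * 8L) != 0L) {
    stop(sprintf("input size %dx%d must be divisible by %d (patch x 3 merges)",
                 H, W, p * 8L), call. = FALSE)
  }
  tokens <- ad_const(.tokens_from_images(images))

  pe <- .cache_get(cache, sprintf("pe_%d_%d_%d", H, W, B),
                   function() .patch_idx(H, W, B, p))
  x <- ad_conv_linear(tokens, prm$`embed.w`, prm$`embed.b`,
                      unlist(pe$idx, use.names = FALSE), p * p)
  x <- ad_layernorm(x, prm$`embed.ln_g`, prm$`embed.ln_b`)

  Hs <- pe$H; Ws <- pe$W
  skips <- list(); res <- list()
  for (s in 1:4) {
    Cs <- cfg$embed_dim * 2^(s - 1)
    for (dth in seq_len(cfg$depths[s])) {
      x <- .swin_block(x, Hs, Ws, B, Cs, cfg$heads[s],
                       min(cfg$window_size, max(Hs, Ws)),
                       shift = (dth %% 2L == 0L),
                       .block_params(model, s, dth), cache,
                       table_ws = cfg$window_size)
    }
    skips[[s]] <- x; res[[s]] <- c(Hs, Ws)
    if (s < 4) {
      mi <- .cache_get(cache, sprintf("mg_%d_%d_%d", Hs, Ws, B),
                       function() .merge_idx(Hs, Ws, B))
      x <- ad_im2col(x, unlist(mi$idx, use.names = FALSE), 4L)
      nm <- sprintf("merge%d.", s)
      x <- ad_layernorm(x, prm[[paste0(nm, "ln_g")]], prm[[paste0(nm, "ln_b")]])
      x <- ad_matmul(x, prm[[paste0(nm, "w")]])
      Hs <- mi$H; Ws <- mi$W
    }
  }

  dcur <- skips[[4]]; Hc <- res[[4]][1]; Wc <- res[[4]][2]
  for (l in 3:1) {
    Cl <- cfg$embed_dim * 2^(l - 1)
    nm <- sprintf("dec%d.", l)
    Ht <- res[[l]][1]; Wt <- res[[l]][2]
    up <- .upsample(dcur, Hc, Wc, B, Ht, Wt, Cl,
                    prm[[paste0(nm, "up_w")]], prm[[paste0(nm, "up_b")]], cache)
    dcur <- ad_cbind(list(up, skips[[l]]))
    dcur <- ad_gelu(.conv3(dcur, Ht, Wt, B, prm[[paste0(nm, "conv_w")]],
                           prm[[paste0(nm, "conv_b")]], cache))
    Hc <- Ht; Wc <- Wt
  }
  half <- ad_linear(dcur, prm$`head.w`, prm$`head.b`)   # (N/4 x 48)
  ix <- .cache_get(cache, sprintf("up_%d_%d_%d_%d_%d", Hc, Wc, B, H, W),
                   function() .up_idx(Hc, Wc, B, H, W))
  logits <- ad_pixel_shuffle(half, ix$coarse, ix$offset, 12L)
  list(logits = logits, H = H, W = W, B = B)
}

#' Run the network on standardized images
#'
#' @param model A `swin_unetr` from [init_model()] or [train_model()].
#' @param images `H x W` matrix or `H x W x B` array of standardized
#'   intensities (see [standardize()]).
#' @return `H x W x 12 x B` array of predictions; mask channels are
#'   pre-activation logits.
#' @export
net_forward <- function(model, images) {
  fw <- .forward_node(model, images)
  .array_from_tokens(fw$logits$value, fw$H, fw$W, fw$B)
}

# ---- exposed primitives (window attention, patch merging) ---------------

#' Shifted-window multi-head self-attention on a feature map
#'
#' Standalone windowed attention (no residual, no layer norm), exposed so
#' the mechanism can be probed directly: with `window_size` covering the
#' whole feature map and no shift it reduces to global self-attention with
#' the same weights.
#'
#' @param features `H x W x C` array.
#' @param qkv_w,qkv_b,proj_w,proj_b Projection weights (`C x 3C`, `3C`,
#'   `C x C`, `C`).
#' @param n_heads Number of attention heads (divides `C`).
#' @param window_size Window side in tokens; padded cyclically if the map is
#'   not a multiple.
#' @param shift Shift windows by half a window with masked wrap-around.
#' @param bias_table Optional relative-position bias table
#'   (`(2*window_size-1)^2 x n_heads`); zeros when omitted.
#' @return `H x W x C` array.
#' @export
window_attention <- function(features, qkv_w, qkv_b, proj_w, proj_b,
                             n_heads, window_size, shift = FALSE,
                             bias_table = NULL) {
  d <- dim(features)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (window_size > max(H, W)) {
    stop("window larger than the (padded) feature map", call. = FALSE)
  }
  if (is.null(bias_table)) {
    bias_table <- matrix(0, (2 * window_size - 1)^2, n_heads)
  }
  tok <- matrix(aperm(features, c(2, 1, 3)), H * W, C)  # rows x fastest
  prm <- list(qkv_w = ad_const(qkv_w), qkv_b = ad_const(qkv_b),
              proj_w = ad_const(proj_w), proj_b = ad_const(proj_b),
              bias_table = ad_const(bias_table))
  out <- .attention(ad_const(tok), H, W, 1L, C, n_heads, window_size, shift,
                    prm, new.env(parent = emptyenv()), window_size)
  .array_from_tokens(out$value, H, W, 1L)[, , , 1]
}

#' Patch merging: halve resolution, double channels
#'
#' Concatenates each 2x2 token neighborhood (zero-padding odd extents),
#' layer-normalizes and linearly projects `4C -> 2C` channels.
#'
#' @param features `H x W x C` array.
#' @param w Optional `4C x 2C` projection (a fixed deterministic matrix when
#'   omitted).
#' @param ln_gamma,ln_beta Optional layer-norm parameters (length `4C`).
#' @return `ceil(H/2) x ceil(W/2) x 2C` array.
#' @export
patch_merge <- function(features, w = NULL, ln_gamma = NULL, ln_beta = NULL) {
  d <- dim(features)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (is.null(w)) w <- matrix(sin(seq_len(8 * C * C)), 4 * C, 2 * C) * 0.1
  if (is.null(ln_gamma)) ln_gamma <- rep(1, 4 * C)
  if (is.null(ln_beta)) ln_beta <- numeric(4 * C)
  tok <- ad_const(matrix(aperm(features, c(2, 1, 3)), H * W, C))
  mi <- .merge_idx(H, W, 1L)
  x <- ad_im2col(tok, unlist(mi$idx, use.names = FALSE), 4L)
  x <- ad_layernorm(x, ad_const(ln_gamma), ad_const(ln_beta))
  x <- ad_matmul(x, ad_const(w))
  .array_from_tokens(x$value, mi$H, mi$W, 1L)[, , , 1]
}

# ---- checkpointing ------------------------------------------------------

#' Save / load model weights
#'
#' The checkpoint is a single RDS file with the architecture config embedded
#' alongside the parameter values; [net_config_yaml()] round-trips the
#' config alone through YAML.
#'
#' @param model A `swin_unetr`.
#' @param path Destination file.
#' @return `load_model()` returns the restored `swin_unetr`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               values = lapply(model$params, function(p) p$value)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(net_config, obj$config[setdiff(names(obj$config), "out_channels")])
  model <- init_model(cfg, seed = 1L)
  stopifnot(setequal(names(model$params), names(obj$values)))
  for (nm in names(obj$values)) model$params[[nm]]$value <- obj$values[[nm]]
  model
}

#' Write or read a network config as YAML
#' @param config A `net_config` (to write) or `NULL` (to read).
#' @param path YAML file path.
#' @return The `net_config` read or written, invisibly for writes.
#' @export
net_config_yaml <- function(config = NULL, path) {
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), path)
    return(invisible(config))
  }
  obj <- yaml::read_yaml(path)
  do.call(net_config, obj[setdiff(names(obj), "out_channels")])
}
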