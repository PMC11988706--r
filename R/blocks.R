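# Building blocks: CBAM (channel + spatial attention), ASPP, residual block,
# attention gate and stem block. Each block exists in two forms: a tape-level
# forward used inside models (differentiable) and an exported pure operator on
# a single H x W x C feature map used for inspection and testing.

# Glorot/Xavier uniform initialization (the framework-default scheme of the
# reference implementation stack): limit sqrt(6 / (fan_in + fan_out)), with
# fans derived from the kernel shape. Keeps initial logits near zero through
# deep residual stacks, so the sigmoid head starts unsaturated.
glorot_init <- function(dims) {
  d <- as.integer(dims)
  if (length(d) == 2) { fi <- d[2]; fo <- d[1] }            # dense (out, in)
  else if (length(d) == 3) { fi <- d[1] * d[2]; fo <- d[1] * d[2] }  # depthwise
  else { fi <- d[1] * d[2] * d[3]; fo <- d[1] * d[2] * d[4] }
  lim <- sqrt(6 / (fi + fo))
  array(runif(prod(d), -lim, lim), d)
}

bn_init <- function(C, eps = 1e-3) {
  list(gamma = rep(1, C), beta = rep(0, C),
       mean = rep(0, C), var = rep(1, C), eps = eps)
}

#' Channel attention parameters
#'
#' Builds the squeeze-excite style bottleneck of the channel attention branch:
#' two fully connected layers mapping the pooled per-channel descriptor
#' through `max(1, C %/% reduction)` hidden units (LeakyReLU) back to `C`
#' gates (sigmoid).
#'
#' @param channels Number of input channels `C`.
#' @param reduction Reduction ratio `r` of the bottleneck (default 16).
#' @param seed Seed for the weight initialization (Glorot uniform).
#' @return List with weight matrices `W1` (`h x C`), `W2` (`C x h`) and bias
#'   vectors `b1`, `b2`.
#' @export
channel_attention_params <- function(channels, reduction = 16, seed = 0) {
  check_that(channels >= 1, "channels: must be >= 1")
  check_that(reduction >= 1, "reduction: must be >= 1")
  h <- max(1L, channels %/% reduction)
  with_seed(seed, list(
    W1 = glorot_init(c(h, channels)), b1 = rep(0, h),
    W2 = glorot_init(c(channels, h)), b2 = rep(0, channels)))
}

#' Spatial attention parameters
#'
#' Two 7x7 convolutions: `C -> max(1, C %/% divisor)` channels (LeakyReLU)
#' then down to a single-channel sigmoid attention map.
#'
#' @param channels Number of input channels `C`.
#' @param divisor Channel divisor of the intermediate map (default 16).
#' @param seed Seed for the weight initialization (Glorot uniform).
#' @return List with kernels `W1` (`7x7xCxCd`), `W2` (`7x7xCdx1`) and biases.
#' @export
spatial_attention_params <- function(channels, divisor = 16, seed = 0) {
  check_that(channels >= 1, "channels: must be >= 1")
  cd <- max(1L, channels %/% divisor)
  with_seed(seed, list(
    W1 = glorot_init(c(7, 7, channels, cd)), b1 = rep(0, cd),
    W2 = glorot_init(c(7, 7, cd, 1)), b2 = 0))
}

#' CBAM parameters
#'
#' Convenience constructor bundling [channel_attention_params()] and
#' [spatial_attention_params()] for one CBAM application.
#'
#' @inheritParams channel_attention_params
#' @inheritParams spatial_attention_params
#' @return List with elements `channel` and `spatial`.
#' @export
cbam_params <- function(channels, reduction = 16, divisor = 16, seed = 0) {
  list(channel = channel_attention_params(channels, reduction,
                                          derive_seed(seed, 1)),
       spatial = spatial_attention_params(channels, divisor,
                                          derive_seed(seed, 2)))
}

#' ASPP parameters
#'
#' One 3x3 convolution plus batch normalization per dilation rate and a 1x1
#' fusion convolution applied to the elementwise sum of the branches.
#'
#' @param channels Channels of the bridge feature map.
#' @param rates Dilation rates of the parallel branches (default 1, 6, 12, 18).
#' @param seed Seed for the weight initialization (Glorot uniform).
#' @param eps Batch-normalization epsilon.
#' @return Nested list with one `branch` per rate and the `fuse` convolution.
#' @export
aspp_params <- function(channels, rates = c(1, 6, 12, 18), seed = 0,
                        eps = 1e-3) {
  check_that(all(rates >= 1), "rates: dilation rates must be positive")
  with_seed(seed, {
    branches <- lapply(rates, function(r) list(
      w = glorot_init(c(3, 3, channels, channels)),
      b = rep(0, channels),
      bn = bn_init(channels, eps)))
    names(branches) <- paste0("rate", rates)
    list(rates = rates, branches = branches,
         fuse = list(w = glorot_init(c(1, 1, channels, channels)),
                     b = rep(0, channels)))
  })
}

#' Residual block parameters
#'
#' Main path: batch norm, 3x3 depthwise-separable convolution (carrying the
#' stride), LeakyReLU, then a second batch norm / separable convolution /
#' LeakyReLU. Shortcut: strided 1x1 convolution plus batch norm.
#'
#' @param in_channels,out_channels Input and output channel widths.
#' @param stride 1 (shape preserving) or 2 (halves height and width).
#' @param seed Seed for the weight initialization (Glorot uniform).
#' @param eps Batch-normalization epsilon.
#' @return Nested parameter list.
#' @export
residual_block_params <- function(in_channels, out_channels, stride = 1,
                                  seed = 0, eps = 1e-3) {
  check_that(stride %in% c(1, 2), "stride: must be 1 or 2")
  with_seed(seed, list(
    stride = stride,
    bn1 = bn_init(in_channels, eps),
    dw1 = glorot_init(c(3, 3, in_channels)),
    pw1 = glorot_init(c(1, 1, in_channels, out_channels)),
    pb1 = rep(0, out_channels),
    bn2 = bn_init(out_channels, eps),
    dw2 = glorot_init(c(3, 3, out_channels)),
    pw2 = glorot_init(c(1, 1, out_channels, out_channels)),
    pb2 = rep(0, out_channels),
    sc_w = glorot_init(c(1, 1, in_channels, out_channels)),
    sc_b = rep(0, out_channels),
    bn3 = bn_init(out_channels, eps)))
}

#' Attention gate parameters
#'
#' Additive attention gate: 1x1 projections of the (pooled) encoder skip and
#' of the decoder features to `inter` channels, LeakyReLU, then a 1x1
#' convolution and sigmoid producing a single-channel gate.
#'
#' @param skip_channels Channels of the encoder skip connection.
#' @param dec_channels Channels of the gating decoder features.
#' @param inter Intermediate channel count (default `max(1, skip %/% 2)`).
#' @param seed Seed for the weight initialization (Glorot uniform).
#' @return Nested parameter list.
#' @export
attention_gate_params <- function(skip_channels, dec_channels,
                                  inter = NULL, seed = 0) {
  ci <- if (is.null(inter)) max(1L, skip_channels %/% 2L) else inter
  with_seed(seed, list(
    we = glorot_init(c(1, 1, skip_channels, ci)), be = rep(0, ci),
    wd = glorot_init(c(1, 1, dec_channels, ci)), bd = rep(0, ci),
    psi = glorot_init(c(1, 1, ci, 1)), bpsi = 0))
}

#' Stem block parameters
#'
#' Two concurrent paths from the network input: (a) 3x3 convolution, batch
#' norm, LeakyReLU, 3x3 convolution; (b) 1x1 convolution, 2x2 max pooling and
#' nearest-neighbour upsampling back to full resolution. The paths are merged
#' by addition, normalized and activated; models apply a CBAM on the merge.
#'
#' @param width Output channel width (first encoder level).
#' @param in_channels Input channels (1 for grayscale radiographs).
#' @param seed Seed for the weight initialization (Glorot uniform).
#' @param eps Batch-normalization epsilon.
#' @return Nested parameter list.
#' @export
stem_block_params <- function(width, in_channels = 1, seed = 0, eps = 1e-3) {
  with_seed(seed, list(
    a1_w = glorot_init(c(3, 3, in_channels, width)),
    a1_b = rep(0, width),
    bn1 = bn_init(width, eps),
    a2_w = glorot_init(c(3, 3, width, width)), a2_b = rep(0, width),
    b_w = glorot_init(c(1, 1, in_channels, width)),
    b_b = rep(0, width),
    bn2 = bn_init(width, eps)))
}

# ---- tape-level forwards ----------------------------------------------------
# `lf` lifts a plain array into a tape leaf once per forward pass; model code
# passes pre-lifted nodes instead.

lift <- function(tp, p) {
  if (is.list(p)) lapply(p, function(q) lift(tp, q)) else tn_leaf(tp, p)
}

bn_state_env <- function(bn) {
  st <- new.env(parent = emptyenv())
  st$mean <- bn$mean
  st$var <- bn$var
  st
}

# nodes: list with W1,b1,W2,b2 (already leaves); x: (H,W,C,N) node
fw_channel_attention <- function(tp, x, nd, slope = 0.01) {
  z <- op_gap(tp, x)
  h <- op_dense(tp, z, nd$W1, nd$b1)
  h <- op_lrelu(tp, h, slope)
  s <- op_dense(tp, h, nd$W2, nd$b2)
  s <- op_sigmoid(tp, s)
  list(out = op_mul_channel(tp, x, s), gate = s, pooled = z)
}

fw_spatial_attention <- function(tp, x, nd, slope = 0.01) {
  v <- op_conv(tp, x, nd$W1, nd$b1)
  v <- op_lrelu(tp, v, slope)
  m <- op_conv(tp, v, nd$W2, nd$b2)
  op_sigmoid(tp, m)
}

fw_cbam <- function(tp, x, nd, slope = 0.01) {
  ca <- fw_channel_attention(tp, x, nd$channel, slope)
  m <- fw_spatial_attention(tp, ca$out, nd$spatial, slope)
  list(out = op_mul_spatial(tp, ca$out, m), channel_gate = ca$gate,
       spatial_map = m, channel_out = ca$out)
}

fw_aspp <- function(tp, x, nd, st, training) {
  xs <- lapply(seq_along(nd$branches), function(i) {
    br <- nd$branches[[i]]
    h <- op_conv(tp, x, br$w, br$b, dil = as.integer(rate_of(nd, i)))
    op_bn(tp, h, br$bn$gamma, br$bn$beta, st$branches[[i]]$bn, training,
          eps = bn_eps(nd$branches[[i]]))
  })
  s <- op_add_list(tp, xs)
  op_conv(tp, s, nd$fuse$w, nd$fuse$b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rates / eps live as plain values inside lifted lists: lift() wraps numeric
# vectors in leaves, so unwrap where needed.
rate_of <- function(nd, i) {
  r <- nd$rates
  if (inherits(r, "environment")) r$val[i] else r[i]
}

bn_eps <- function(br) {
  e <- br$bn$eps
  if (inherits(e, "environment")) e$val else e
}

fw_residual_block <- function(tp, x, nd, st, training, slope = 0.01) {
  stride <- if (inherits(nd$stride, "environment")) nd$stride$val else nd$stride
  e1 <- if (inherits(nd$bn1$eps, "environment")) nd$bn1$eps$val else nd$bn1$eps
  h <- op_bn(tp, x, nd$bn1$gamma, nd$bn1$beta, st$bn1, training, eps = e1)
  h <- op_dwconv(tp, h, nd$dw1, stride = as.integer(stride))
  h <- op_conv(tp, h, nd$pw1, nd$pb1)
  h <- op_lrelu(tp, h, slope)
  h <- op_bn(tp, h, nd$bn2$gamma, nd$bn2$beta, st$bn2, training, eps = e1)
  h <- op_dwconv(tp, h, nd$dw2)
  h <- op_conv(tp, h, nd$pw2, nd$pb2)
  h <- op_lrelu(tp, h, slope)
  sc <- op_conv(tp, x, nd$sc_w, nd$sc_b, stride = as.integer(stride))
  sc <- op_bn(tp, sc, nd$bn3$gamma, nd$bn3$beta, st$bn3, training, eps = e1)
  op_add(tp, h, sc)
}

fw_attention_gate <- function(tp, enc, dec, nd, slope = 0.01) {
  de <- dim(enc$val)
  dd <- dim(dec$val)
  if (de[1] == 2 * dd[1] && de[2] == 2 * dd[2]) {
    e <- op_avgpool2(tp, enc)
    up <- TRUE
  } else if (de[1] == dd[1] && de[2] == dd[2]) {
    e <- enc
    up <- FALSE
  } else {
    stop_shape("attention_gate: encoder map must be at the decoder's ",
               "resolution or exactly twice it")
  }
  e <- op_conv(tp, e, nd$we, nd$be)
  d <- op_conv(tp, dec, nd$wd, nd$bd)
  a <- op_lrelu(tp, op_add(tp, e, d), slope)
  g <- op_sigmoid(tp, op_conv(tp, a, nd$psi, nd$bpsi))
  if (up) g <- op_upbilin2(tp, g)
  list(out = op_mul_spatial(tp, enc, g), gate = g)
}

fw_stem <- function(tp, x, nd, st, training, slope = 0.01) {
  e1 <- if (inherits(nd$bn1$eps, "environment")) nd$bn1$eps$val else nd$bn1$eps
  a <- op_conv(tp, x, nd$a1_w, nd$a1_b)
  a <- op_bn(tp, a, nd$bn1$gamma, nd$bn1$beta, st$bn1, training, eps = e1)
  a <- op_lrelu(tp, a, slope)
  a <- op_conv(tp, a, nd$a2_w, nd$a2_b)
  b <- op_conv(tp, x, nd$b_w, nd$b_b)
  b <- op_maxpool2(tp, b)
  b <- op_upnear2(tp, b)
  m <- op_add(tp, a, b)
  m <- op_bn(tp, m, nd$bn2$gamma, nd$bn2$beta, st$bn2, training, eps = e1)
  list(out = op_lrelu(tp, m, slope), merge = m)
}

# ---- exported pure operators ------------------------------------------------

check_fmap <- function(x, name = "x") {
  d <- dim(x)
  if (is.null(d) || length(d) != 3)
    stop_shape(name, ": expected an H x W x C feature map")
  if (!all(is.finite(x))) stop_shape(name, ": entries must be finite")
  invisible(d)
}

fmap_in <- function(x) {
  d <- dim(x)
  dim(x) <- c(d, 1L)
  x
}

fmap_out <- function(node) {
  v <- node$val
  d <- dim(v)
  dim(v) <- d[1:3]
  v
}

#' Channel attention
#'
#' Gates a feature map channelwise: the per-channel spatial mean is squeezed
#' through a two-layer bottleneck (LeakyReLU, then sigmoid) and the resulting
#' per-channel weight in (0,1) rescales the map.
#'
#' @param U An `H x W x C` feature map.
#' @param params Parameters from [channel_attention_params()].
#' @param slope LeakyReLU negative slope (default 0.01).
#' @param details If `TRUE` return a list with the gated map (`output`), the
#'   gate vector (`gate`) and the pooled descriptor (`pooled`).
#' @return The gated map, same shape as `U` (or the detail list).
#' @export
channel_attention <- function(U, params, slope = 0.01, details = FALSE) {
  d <- check_fmap(U, "U")
  if (ncol(params$W1) != d[3])
    stop_shape("channel_attention: parameters expect ", ncol(params$W1),
               " channels, map has ", d[3])
  tp <- tape_new()
  nd <- lift(tp, params)
  res <- fw_channel_attention(tp, tn_leaf(tp, fmap_in(U)), nd, slope)
  if (details)
    list(output = fmap_out(res$out), gate = as.vector(res$gate$val),
         pooled = as.vector(res$pooled$val))
  else fmap_out(res$out)
}

#' Spatial attention map
#'
#' Computes the single-channel spatial attention map: a 7x7 convolution to an
#' intermediate map (LeakyReLU) followed by a 7x7 convolution to one channel
#' and a sigmoid, so every entry lies strictly in (0, 1).
#'
#' @param U An `H x W x C` feature map (typically the channel-gated map).
#' @param params Parameters from [spatial_attention_params()].
#' @param slope LeakyReLU negative slope.
#' @return The `H x W x 1` attention map.
#' @export
spatial_attention <- function(U, params, slope = 0.01) {
  d <- check_fmap(U, "U")
  if (dim(params$W1)[3] != d[3])
    stop_shape("spatial_attention: parameters expect ", dim(params$W1)[3],
               " channels, map has ", d[3])
  tp <- tape_new()
  nd <- lift(tp, params)
  m <- fw_spatial_attention(tp, tn_leaf(tp, fmap_in(U)), nd, slope)
  fmap_out(m)
}

#' Convolutional block attention (CBAM)
#'
#' Applies channel attention followed by spatial attention and returns the
#' doubly gated feature map. Both gates are sigmoid outputs in (0, 1), so the
#' output magnitude never exceeds the input magnitude elementwise.
#'
#' @param U An `H x W x C` feature map.
#' @param params Parameters from [cbam_params()] (elements `channel` and
#'   `spatial`).
#' @param slope LeakyReLU negative slope.
#' @param details If `TRUE` also return the channel gate, the channel-gated
#'   map and the spatial map.
#' @return The gated map, same shape as `U` (or the detail list).
#' @export
cbam <- function(U, params, slope = 0.01, details = FALSE) {
  check_fmap(U, "U")
  tp <- tape_new()
  nd <- lift(tp, params)
  res <- fw_cbam(tp, tn_leaf(tp, fmap_in(U)), nd, slope)
  if (details)
    list(output = fmap_out(res$out),
         channel_gate = as.vector(res$channel_gate$val),
         channel_output = fmap_out(res$channel_out),
         spatial_map = fmap_out(res$spatial_map))
  else fmap_out(res$out)
}

#' Atrous spatial pyramid pooling (ASPP)
#'
#' Parallel dilated 3x3 convolutions (each followed by batch normalization)
#' whose outputs are summed elementwise and fused by a 1x1 convolution. The
#' spatial shape is preserved by same-padding.
#'
#' @param X An `H x W x C` feature map.
#' @param params Parameters from [aspp_params()].
#' @param training If `TRUE` normalize with the statistics of `X` itself;
#'   otherwise use the running statistics stored in the parameters.
#' @return The fused map, same shape as `X`.
#' @export
aspp <- function(X, params, training = FALSE) {
  d <- check_fmap(X, "X")
  if (dim(params$branches[[1]]$w)[3] != d[3])
    stop_shape("aspp: parameters expect ", dim(params$branches[[1]]$w)[3],
               " channels, map has ", d[3])
  check_that(all(params$rates >= 1), "rates: dilation rates must be positive")
  tp <- tape_new()
  nd <- lift(tp, params)
  st <- list(branches = lapply(params$branches,
                               function(br) list(bn = bn_state_env(br$bn))))
  y <- fw_aspp(tp, tn_leaf(tp, fmap_in(X)), nd, st, training)
  fmap_out(y)
}

#' Residual block
#'
#' Pre-activation style residual block with depthwise-separable convolutions:
#' main path BN, separable 3x3 (strided), LeakyReLU, BN, separable 3x3,
#' LeakyReLU; shortcut 1x1 convolution (strided) plus BN; outputs are added.
#'
#' @param x An `H x W x C` feature map; `C` must equal the block's input width.
#' @param params Parameters from [residual_block_params()].
#' @param training Batch-statistics (`TRUE`) vs running-statistics mode.
#' @param slope LeakyReLU negative slope.
#' @return The block output: `H x W x out_channels`, spatial size halved when
#'   the block stride is 2.
#' @export
residual_block <- function(x, params, training = FALSE, slope = 0.01) {
  d <- check_fmap(x, "x")
  if (dim(params$dw1)[3] != d[3])
    stop_shape("residual_block: parameters expect ", dim(params$dw1)[3],
               " channels, map has ", d[3])
  if (params$stride == 2 && (d[1] %% 2 != 0 || d[2] %% 2 != 0))
    stop_shape("residual_block: stride 2 requires even height and width")
  tp <- tape_new()
  nd <- lift(tp, params)
  st <- list(bn1 = bn_state_env(params$bn1), bn2 = bn_state_env(params$bn2),
             bn3 = bn_state_env(params$bn3))
  y <- fw_residual_block(tp, tn_leaf(tp, fmap_in(x)), nd, st, training, slope)
  fmap_out(y)
}

#' Attention gate on a skip connection
#'
#' Modulates encoder features with decoder features: both are projected by
#' 1x1 convolutions to an intermediate width, added, passed through LeakyReLU
#' and a final 1x1 convolution with sigmoid, yielding a single-channel gate in
#' (0, 1) that multiplies the encoder map. When the encoder map is at twice
#' the decoder resolution it is average-pooled before the projection and the
#' gate is bilinearly upsampled back.
#'
#' @param enc Encoder feature map (`H x W x C_enc`).
#' @param dec Decoder feature map at the same or half the resolution.
#' @param params Parameters from [attention_gate_params()].
#' @param slope LeakyReLU negative slope.
#' @param details If `TRUE` also return the gate map.
#' @return The gated encoder map (or the detail list).
#' @export
attention_gate <- function(enc, dec, params, slope = 0.01, details = FALSE) {
  check_fmap(enc, "enc")
  check_fmap(dec, "dec")
  tp <- tape_new()
  nd <- lift(tp, params)
  res <- fw_attention_gate(tp, tn_leaf(tp, fmap_in(enc)),
                           tn_leaf(tp, fmap_in(dec)), nd, slope)
  if (details) list(output = fmap_out(res$out), gate = fmap_out(res$gate))
  else fmap_out(res$out)
}

#' Stem block
#'
#' First block of the proposed network: path (a) 3x3 convolution, BN,
#' LeakyReLU, 3x3 convolution; path (b) 1x1 convolution, 2x2 max pool,
#' nearest-neighbour upsample; merged by addition, then BN and LeakyReLU.
#' (Inside models the merge is followed by a CBAM application.)
#'
#' @param x The network input map (`H x W x in_channels`, even H and W).
#' @param params Parameters from [stem_block_params()].
#' @param training Batch-statistics (`TRUE`) vs running-statistics mode.
#' @param slope LeakyReLU negative slope.
#' @param details If `TRUE` also return the pre-activation merge.
#' @return The stem output (`H x W x width`), or the detail list.
#' @export
stem_block <- function(x, params, training = FALSE, slope = 0.01,
                       details = FALSE) {
  d <- check_fmap(x, "x")
  if (dim(params$a1_w)[3] != d[3])
    stop_shape("stem_block: parameters expect ", dim(params$a1_w)[3],
               " input channels, map has ", d[3])
  tp <- tape_new()
  nd <- lift(tp, params)
  st <- list(bn1 = bn_state_env(params$bn1), bn2 = bn_state_env(params$bn2))
  res <- fw_stem(tp, tn_leaf(tp, fmap_in(x)), nd, st, training, slope)
  if (details) list(output = fmap_out(res$out), merge = fmap_out(res$merge))
  else fmap_out(res$out)
}
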