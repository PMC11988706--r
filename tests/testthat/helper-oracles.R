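# Brute-force reference implementations used as independent oracles.
# These deliberately use scalar loops and the definitions written out
# longhand, never the package's vectorized/C++ paths.

clip01 <- function(x) pmin(pmax(x, 0), 1)
lrelu_ref <- function(x, slope = 0.01) ifelse(x >= 0, x, slope * x)
sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# sliding-window convolution with same padding, single H x W x Cin map
loop_conv2d <- function(x, w, b = NULL, stride = 1, dil = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  pad <- function(len, k) {
    out <- ceiling(len / stride)
    total <- max(0, (out - 1) * stride + (k - 1) * dil + 1 - len)
    c(out, total %/% 2)
  }
  ph <- pad(H, kh); pw <- pad(W, kw)
  y <- array(0, c(ph[1], pw[1], Cout))
  for (co in 1:Cout) for (ho in 1:ph[1]) for (wo in 1:pw[1]) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in 1:Cin) for (i in 1:kh) for (j in 1:kw) {
      hi <- (ho - 1) * stride - ph[2] + (i - 1) * dil + 1
      wi <- (wo - 1) * stride - pw[2] + (j - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci] * w[i, j, ci, co]
    }
    y[ho, wo, co] <- acc
  }
  y
}

loop_dwconv2d <- function(x, w, stride = 1) {
  C <- dim(x)[3]
  y <- NULL
  for (c in 1:C) {
    wc <- array(0, c(dim(w)[1], dim(w)[2], 1, 1))
    wc[, , 1, 1] <- w[, , c]
    xc <- x[, , c, drop = FALSE]
    yc <- loop_conv2d(xc, wc, stride = stride)
    y <- if (is.null(y)) yc else {
      out <- array(0, c(dim(yc)[1], dim(yc)[2], c))
      out[, , 1:(c - 1)] <- y
      out[, , c] <- yc[, , 1]
      out
    }
  }
  y
}

# Channel attention, written from the pooled-mean / two-FC definition
loop_channel_attention <- function(U, p, slope = 0.01) {
  H <- dim(U)[1]; W <- dim(U)[2]; C <- dim(U)[3]
  z <- numeric(C)
  for (c in 1:C) {
    s <- 0
    for (i in 1:H) for (j in 1:W) s <- s + U[i, j, c]
    z[c] <- s / (H * W)
  }
  h <- lrelu_ref(as.vector(p$W1 %*% z + p$b1), slope)
  s <- sigmoid_ref(as.vector(p$W2 %*% h + p$b2))
  out <- U
  for (c in 1:C) out[, , c] <- U[, , c] * s[c]
  list(z = z, gate = s, out = out)
}

loop_spatial_attention <- function(U, p, slope = 0.01) {
  v <- lrelu_ref(loop_conv2d(U, p$W1, p$b1), slope)
  sigmoid_ref(loop_conv2d(v, p$W2, p$b2))
}

# batch norm in running-statistics mode
ref_bn_eval <- function(x3, bn) {
  C <- dim(x3)[3]
  for (c in 1:C)
    x3[, , c] <- bn$gamma[c] * (x3[, , c] - bn$mean[c]) /
      sqrt(bn$var[c] + bn$eps) + bn$beta[c]
  x3
}

loop_aspp <- function(X, p) {
  acc <- NULL
  for (i in seq_along(p$rates)) {
    br <- p$branches[[i]]
    h <- loop_conv2d(X, br$w, br$b, dil = p$rates[i])
    h <- ref_bn_eval(h, br$bn)
    acc <- if (is.null(acc)) h else acc + h
  }
  loop_conv2d(acc, p$fuse$w, p$fuse$b)
}

loop_residual_block <- function(x, p, slope = 0.01) {
  pw_conv <- function(h, pw, pb) loop_conv2d(h, pw, pb)
  h <- ref_bn_eval(x, p$bn1)
  h <- loop_dwconv2d(h, p$dw1, stride = p$stride)
  h <- lrelu_ref(pw_conv(h, p$pw1, p$pb1), slope)
  h <- ref_bn_eval(h, p$bn2)
  h <- loop_dwconv2d(h, p$dw2)
  h <- lrelu_ref(pw_conv(h, p$pw2, p$pb2), slope)
  sc <- loop_conv2d(x, p$sc_w, p$sc_b, stride = p$stride)
  sc <- ref_bn_eval(sc, p$bn3)
  h + sc
}

loop_attention_gate_equal <- function(enc, dec, p, slope = 0.01) {
  e <- loop_conv2d(enc, p$we, p$be)
  d <- loop_conv2d(dec, p$wd, p$bd)
  a <- lrelu_ref(e + d, slope)
  g <- sigmoid_ref(loop_conv2d(a, p$psi, p$bpsi))
  out <- enc
  for (c in 1:dim(enc)[3]) out[, , c] <- enc[, , c] * g[, , 1]
  list(out = out, gate = g)
}

loop_maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, c(H / 2, W / 2, C))
  for (c in 1:C) for (i in 1:(H / 2)) for (j in 1:(W / 2))
    y[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  y
}

loop_upnear2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, c(2 * H, 2 * W, C))
  for (c in 1:C) for (i in 1:(2 * H)) for (j in 1:(2 * W))
    y[i, j, c] <- x[ceiling(i / 2), ceiling(j / 2), c]
  y
}

loop_stem <- function(x, p, slope = 0.01) {
  a <- loop_conv2d(x, p$a1_w, p$a1_b)
  a <- ref_bn_eval(a, p$bn1)
  a <- lrelu_ref(a, slope)
  a <- loop_conv2d(a, p$a2_w, p$a2_b)
  b <- loop_conv2d(x, p$b_w, p$b_b)
  b <- loop_upnear2(loop_maxpool2(b))
  m <- ref_bn_eval(a + b, p$bn2)
  list(out = lrelu_ref(m, slope), merge = m)
}

# bilinear resampling with half-pixel centres, scalar loops
loop_resize_bilinear <- function(x, oh, ow) {
  H <- nrow(x); W <- ncol(x)
  y <- matrix(0, oh, ow)
  for (r in 1:oh) for (c in 1:ow) {
    sr <- min(max((r - 0.5) * H / oh - 0.5, 0), H - 1)
    sc <- min(max((c - 0.5) * W / ow - 0.5, 0), W - 1)
    r0 <- floor(sr); c0 <- floor(sc)
    r1 <- min(r0 + 1, H - 1); c1 <- min(c0 + 1, W - 1)
    tr <- sr - r0; tc <- sc - c0
    y[r, c] <- (1 - tr) * (1 - tc) * x[r0 + 1, c0 + 1] +
      (1 - tr) * tc * x[r0 + 1, c1 + 1] +
      tr * (1 - tc) * x[r1 + 1, c0 + 1] + tr * tc * x[r1 + 1, c1 + 1]
  }
  y
}

# nearest-neighbour rotation of output coordinates back into the source,
# counter-clockwise positive, centre (H-1)/2, 0 fill
loop_rotate_nn <- function(x, theta_deg) {
  H <- nrow(x); W <- ncol(x)
  rc <- (H - 1) / 2; cc <- (W - 1) / 2
  cs <- cospi(theta_deg / 180); sn <- sinpi(theta_deg / 180)
  y <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    dr <- (r - 1) - rc; dc <- (c - 1) - cc
    sr <- round(rc + dr * cs + dc * sn)
    sc <- round(cc - dr * sn + dc * cs)
    if (sr >= 0 && sr < H && sc >= 0 && sc < W) y[r, c] <- x[sr + 1, sc + 1]
  }
  y
}

# fill every weight array of a nested parameter list with a constant
fill_params <- function(p, value = 0) {
  for (nm in names(p)) {
    el <- p[[nm]]
    if (is.list(el)) p[[nm]] <- fill_params(el, value)
    else if (!nm %in% c("stride", "rates", "eps", "mean", "var", "gamma"))
      p[[nm]] <- el * 0 + value
  }
  p
}

tiny_pair <- function(n = 32, seed = 1, noise = 0.05) {
  generate_phantom(phantom_config(image_size = n, noise_sigma = noise,
                                  seed = seed), 0)
}

# independent enumeration oracle: U from the rank-sum formula with average
# ranks, over every assignment of the pooled values
mw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n * (n + 1) / 2
  }
  U <- u_of(seq_len(n))
  dev <- abs(U - n * m / 2)
  combos <- utils::combn(n + m, n)
  hits <- sum(apply(combos, 2, function(ix) {
    abs(u_of(ix) - n * m / 2) >= dev - 1e-12
  }))
  list(U = U, p = hits / ncol(combos))
}

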