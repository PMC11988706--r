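# Block operators against brute-force loop oracles and analytic limits.

test_that("channel attention matches the pooled-descriptor definition", {
  set.seed(11)
  U <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  p <- channel_attention_params(2, reduction = 1, seed = 3)
  ref <- loop_channel_attention(U, p)
  got <- channel_attention(U, p, details = TRUE)
  expect_equal(got$pooled, ref$z, tolerance = 1e-10)
  expect_equal(got$gate, ref$gate, tolerance = 1e-10)
  expect_equal(got$output, ref$out, tolerance = 1e-10)

  # a constant channel pools to exactly its value
  U2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  U2[, , 2] <- 3.0
  d <- channel_attention(U2, channel_attention_params(3, 1, seed = 1),
                         details = TRUE)
  expect_identical(d$pooled[2], 3.0)
})

test_that("zero-weight channel attention halves the map (sigmoid(0) gate)", {
  U <- array(runif(5 * 4 * 3), c(5, 4, 3))
  p <- fill_params(channel_attention_params(3, 2), 0)
  d <- channel_attention(U, p, details = TRUE)
  expect_equal(d$gate, rep(0.5, 3))
  expect_equal(d$output, U * 0.5)
})

test_that("spatial attention matches sliding-window evaluation and stays in (0,1)", {
  set.seed(12)
  U <- array(rnorm(5 * 5 * 1), c(5, 5, 1))
  # 3x3 stand-in kernels exercise the same convolution path as the 7x7 ones
  p <- list(W1 = array(rnorm(3 * 3 * 1 * 2, 0, 0.5), c(3, 3, 1, 2)),
            b1 = c(0.1, -0.2),
            W2 = array(rnorm(3 * 3 * 2 * 1, 0, 0.5), c(3, 3, 2, 1)),
            b2 = 0.05)
  got <- spatial_attention(U, p)
  ref <- loop_spatial_attention(U, p)
  expect_equal(got, ref, tolerance = 1e-10)
  expect_true(min(got) > 0 && max(got) < 1)
  expect_equal(dim(got), c(5L, 5L, 1L))

  # zero kernels and input -> sigmoid(0) everywhere
  z <- spatial_attention(array(0, c(4, 4, 2)),
                         fill_params(spatial_attention_params(2, 1), 0))
  expect_equal(as.vector(z), rep(0.5, 16))
})

test_that("cbam composes the two gates and never amplifies", {
  set.seed(13)
  U <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  p <- cbam_params(4, reduction = 2, divisor = 2, seed = 7)
  got <- cbam(U, p, details = TRUE)
  ca <- loop_channel_attention(U, p$channel)
  ms <- loop_spatial_attention(ca$out, p$spatial)
  ref <- ca$out
  for (c in 1:4) ref[, , c] <- ca$out[, , c] * ms[, , 1]
  expect_equal(got$output, ref, tolerance = 1e-10)
  expect_true(all(abs(got$output) <= abs(U)))

  # zero-weight networks gate by 0.5 * 0.5
  p0 <- fill_params(p, 0)
  expect_equal(cbam(U, p0), 0.25 * U, tolerance = 1e-12)
})

test_that("aspp matches a loop oracle, including the dilated taps", {
  set.seed(14)
  X <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
  p <- aspp_params(2, rates = c(1, 6, 12, 18), seed = 9)
  # randomize the running stats so the normalization is non-trivial
  for (i in 1:4) {
    p$branches[[i]]$bn$mean <- rnorm(2, 0, 0.1)
    p$branches[[i]]$bn$var <- runif(2, 0.5, 1.5)
  }
  expect_equal(aspp(X, p), loop_aspp(X, p), tolerance = 1e-10)
})

test_that("aspp rate-1 branch equals a standard 3x3 convolution", {
  set.seed(15)
  X <- array(rnorm(6 * 6 * 1), c(6, 6, 1))
  p <- aspp_params(1, seed = 2, eps = 0)   # identity BN: mean 0, var 1, eps 0
  # isolate the rate-1 branch: zero every other branch and make the 1x1
  # fusion the identity
  for (i in 2:4) {
    p$branches[[i]]$w[] <- 0
    p$branches[[i]]$b[] <- 0
  }
  p$fuse$w[] <- 1
  p$fuse$b[] <- 0
  got <- aspp(X, p)
  ref <- loop_conv2d(X, p$branches[[1]]$w, p$branches[[1]]$b, dil = 1)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("aspp with zero input, zero biases, identity BN is zero", {
  p <- aspp_params(2, seed = 3, eps = 0)
  y <- aspp(array(0, c(8, 8, 2)), p)
  expect_equal(as.vector(y), rep(0, 128))
})

test_that("aspp fusion is invariant to branch order", {
  set.seed(16)
  X <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  p <- aspp_params(2, seed = 5)
  perm <- c(3, 1, 4, 2)
  p2 <- p
  p2$rates <- p$rates[perm]
  p2$branches <- p$branches[perm]
  names(p2$branches) <- names(p$branches)
  expect_equal(aspp(X, p), aspp(X, p2), tolerance = 1e-12)
})

test_that("residual block matches a layerwise oracle and halves shape at stride 2", {
  set.seed(17)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  p <- residual_block_params(3, 5, stride = 1, seed = 21)
  expect_equal(residual_block(x, p), loop_residual_block(x, p),
               tolerance = 1e-10)

  p2 <- residual_block_params(3, 5, stride = 2, seed = 22)
  y2 <- residual_block(x, p2)
  expect_equal(dim(y2), c(3L, 3L, 5L))
  expect_equal(y2, loop_residual_block(x, p2), tolerance = 1e-10)

  # zero input: output determined solely by bias/BN offsets
  z <- array(0, c(4, 4, 3))
  expect_equal(residual_block(z, p), loop_residual_block(z, p),
               tolerance = 1e-12)
  expect_error(residual_block(array(0, c(5, 5, 3)), p2),
               class = "carunet_shape_error")
})

test_that("attention gate matches scalar evaluation and gates in (0,1)", {
  set.seed(18)
  enc <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  dec <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  p <- attention_gate_params(3, 2, inter = 2, seed = 31)
  got <- attention_gate(enc, dec, p, details = TRUE)
  ref <- loop_attention_gate_equal(enc, dec, p)
  expect_equal(got$output, ref$out, tolerance = 1e-10)
  expect_true(all(got$gate > 0 & got$gate < 1))

  # zero gate parameters -> sigmoid(0) = 0.5 everywhere
  p0 <- fill_params(p, 0)
  expect_equal(attention_gate(enc, dec, p0), 0.5 * enc, tolerance = 1e-12)

  # 2x encoder resolution is pooled, gated, and upsampled back
  enc2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  y <- attention_gate(enc2, dec, p, details = TRUE)
  expect_equal(dim(y$output), dim(enc2))
  expect_true(all(y$gate > 0 & y$gate < 1))
  expect_error(attention_gate(array(0, c(16, 16, 3)), dec, p),
               class = "carunet_shape_error")
})

test_that("stem block preserves shape and matches a path-by-path oracle", {
  set.seed(19)
  x <- array(rnorm(8 * 8 * 1), c(8, 8, 1))
  p <- stem_block_params(4, seed = 41)
  got <- stem_block(x, p, details = TRUE)
  ref <- loop_stem(x, p)
  expect_equal(dim(got$output), c(8L, 8L, 4L))
  expect_equal(got$output, ref$out, tolerance = 1e-10)
  expect_equal(got$merge, ref$merge, tolerance = 1e-10)

  # zero input with zero biases: the pre-CBAM merge vanishes
  p0 <- fill_params(p, 0)
  p0$bn1$gamma <- p$bn1$gamma
  p0$bn2$gamma <- p$bn2$gamma
  m0 <- stem_block(array(0, c(8, 8, 1)), p0, details = TRUE)
  expect_equal(as.vector(m0$merge), rep(0, 8 * 8 * 4))
})

test_that("block outputs stay finite on inputs spanning [-10, 10]", {
  set.seed(20)
  x <- array(runif(6 * 6 * 4, -10, 10), c(6, 6, 4))
  expect_true(all(is.finite(cbam(x, cbam_params(4, 2, 2, seed = 1)))))
  expect_true(all(is.finite(aspp(x, aspp_params(4, seed = 2)))))
  expect_true(all(is.finite(
    residual_block(x, residual_block_params(4, 6, seed = 3)))))
  expect_true(all(is.finite(
    stem_block(array(runif(8 * 8, -10, 10), c(8, 8, 1)),
               stem_block_params(3, seed = 4)))))
})

test_that("shape mismatches raise shape errors naming the expectation", {
  U <- array(0, c(4, 4, 3))
  expect_error(channel_attention(U, channel_attention_params(5)),
               class = "carunet_shape_error")
  expect_error(spatial_attention(U, spatial_attention_params(2)),
               class = "carunet_shape_error")
  expect_error(aspp(U, aspp_params(2)), class = "carunet_shape_error")
  expect_error(residual_block(U, residual_block_params(2, 4)),
               class = "carunet_shape_error")
})
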