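# Architecture assembly, analytic counting and width calibration.

test_that("closed-form layer counts match the published conventions", {
  expect_identical(carunet:::cnt_conv(3, 1, 8), 80)          # 3*3*1*8 + 8
  expect_identical(carunet:::cnt_sep(3, 8, 16), 72 + 128 + 16)
  # batch norm: 2C trainable + 2C running statistics
  p <- residual_block_params(4, 6)
  expect_length(p$bn2$gamma, 6)
  expect_length(p$bn2$mean, 6)
})

test_that("built models carry exactly the analytically counted arrays", {
  for (a in c("unet", "res_unet", "res_unet_attn", "proposed")) {
    cfg <- scale_model_config(model_config(a, input_size = 32), 0.2)
    model <- build_model(cfg, seed = 2)
    pa <- count_parameters(cfg)
    pb <- count_parameters(model)
    expect_identical(pa$total, pb$total)
    expect_identical(pa$trainable, pb$trainable)
  }
})

test_that("forward passes have sigmoid outputs and the input's spatial shape", {
  cfg <- scale_model_config(model_config("proposed", input_size = 32), 0.15)
  m <- build_model(cfg, seed = 4)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- model_forward(m, x)
  expect_identical(dim(y), c(32L, 32L, 1L, 1L))
  expect_true(all(y > 0 & y < 1))
  expect_error(model_forward(m, matrix(0, 16, 16)),
               class = "carunet_shape_error")
})

test_that("building is seeded: same seed, same weights, same outputs", {
  cfg <- scale_model_config(model_config("res_unet_attn", input_size = 32),
                            0.15)
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(model_forward(m1, x), model_forward(m2, x))
  m3 <- build_model(cfg, seed = 10)
  expect_false(identical(m1$params, m3$params))
})

test_that("ReLU and LeakyReLU variants have identical parameter counts", {
  iv <- model_config("proposed", activation = "relu")
  v <- model_config("proposed", activation = "leakyrelu")
  expect_identical(count_parameters(iv)$total, count_parameters(v)$total)
  expect_identical(iv$slope, 0)
  expect_identical(v$slope, 0.01)
})

test_that("doubling widths scales convolution-dominated counts ~4x", {
  base <- model_config("proposed")
  doubled <- model_config("proposed", widths = 2 * base$widths,
                          bottleneck = 2 * base$bottleneck)
  ratio <- count_parameters(doubled)$total / count_parameters(base)$total
  expect_lt(abs(ratio - 4) / 4, 0.05)
})

test_that("calibration returns a fixed point and reports infeasibility", {
  cfg <- model_config("res_unet")
  tot <- count_parameters(cfg)$total
  got <- calibrate_widths("res_unet", c(tot, tot))
  expect_identical(got$widths, cfg$widths)
  expect_identical(got$bottleneck, cfg$bottleneck)
  err <- tryCatch(calibrate_widths("unet", c(1, 2)), error = function(e) e)
  expect_s3_class(err, "carunet_config_error")
  expect_match(conditionMessage(err), "nearest achievable")
})

test_that("the proposed model is lighter than the attention-gated residual U-Net", {
  expect_lt(count_parameters(model_config("proposed"))$total,
            count_parameters(model_config("res_unet_attn"))$total)
})

test_that("checkpoints round-trip through disk", {
  cfg <- scale_model_config(model_config("res_unet", input_size = 32), 0.1)
  m <- build_model(cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$params, m2$params)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(model_forward(m, x), model_forward(m2, x))
})

test_that("model summaries partition the total count", {
  cfg <- scale_model_config(model_config("proposed", input_size = 32), 0.1)
  m <- build_model(cfg, seed = 1)
  s <- model_summary(m)
  expect_equal(sum(s$total), count_parameters(m)$total)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(model_config("vgg"), "arch", class = "carunet_config_error")
  expect_error(model_config("unet", widths = c(8, 8, 16, 32)),
               class = "carunet_config_error")
  expect_error(model_config("unet", input_size = 100),
               "input_size", class = "carunet_config_error")
})
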