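# Synthetic phantom generator: determinism, geometry and area contracts.

test_that("phantom generation is bit-identical for identical (seed, index)", {
  cfg <- phantom_config(image_size = 64, seed = 9)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$mask %in% c(0, 1)))
})

test_that("a degenerate area range pins the mask fraction", {
  cfg <- phantom_config(image_size = 128, lung_area_range = c(0.2, 0.2),
                        seed = 4)
  for (i in 0:4) {
    p <- generate_phantom(cfg, i)
    frac <- mean(p$mask)
    expect_lt(abs(frac - 0.2), 1 / 128)
  }
})

test_that("noiseless, stripeless phantoms take exactly two intensities", {
  cfg <- phantom_config(image_size = 64, noise_sigma = 0,
                        rib_stripes = FALSE, background_level = 0.25,
                        lung_level = 0.75, seed = 2)
  p <- generate_phantom(cfg, 1)
  expect_setequal(unique(as.vector(p$image)), c(0.25, 0.75))
  expect_identical((p$image == 0.75) * 1, p$mask)
})

test_that("masks are two disjoint 4-connected components with a column gap", {
  cfg <- phantom_config(image_size = 64, seed = 123)
  for (i in 0:9) {
    m <- generate_phantom(cfg, i)$mask
    lab <- carunet:::label_components(m)
    expect_identical(max(lab), 2L)
    # independent oracle: EBImage connected-component labelling
    lab2 <- EBImage::bwlabel(m)
    expect_equal(max(lab2), 2)
    # the two fields are separated by >= 2 all-background columns
    occupied <- which(colSums(m) > 0)
    gaps <- setdiff(seq(min(occupied), max(occupied)), occupied)
    expect_gte(length(gaps), 2)
  }
})

test_that("datasets index phantoms by counter and reproduce their fraction multiset", {
  cfg <- phantom_config(image_size = 48, seed = 77)
  expect_identical(generate_dataset(0, cfg), list())
  ds <- generate_dataset(5, cfg)
  expect_length(ds, 5)
  expect_identical(ds[[4]], generate_phantom(cfg, 3))

  big <- generate_dataset(100, phantom_config(image_size = 48, seed = 1))
  fr <- vapply(big, function(p) mean(p$mask), 0)
  expect_true(all(fr >= 0.15 - 0.01 & fr <= 0.35 + 0.01))
  fr2 <- vapply(generate_dataset(100, phantom_config(image_size = 48, seed = 1)),
                function(p) mean(p$mask), 0)
  expect_identical(sort(fr), sort(fr2))
})

test_that("invalid configurations name the offending field", {
  expect_error(phantom_config(image_size = 16), "image_size",
               class = "carunet_config_error")
  expect_error(phantom_config(lung_area_range = c(0.4, 0.2)),
               "lung_area_range", class = "carunet_config_error")
  expect_error(phantom_config(noise_sigma = -1), "noise_sigma",
               class = "carunet_config_error")
  expect_error(generate_dataset(-1), "n", class = "carunet_config_error")
  expect_error(generate_phantom(phantom_config(), -2), "index",
               class = "carunet_config_error")
})

test_that("png round trip preserves pairs to 8-bit precision", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, phantom_config(image_size = 32, seed = 6))
  write_image_pairs(ds, dir, split = c("train", "val", "test"))
  back <- read_image_pairs(dir)
  expect_length(back, 3)
  expect_identical(back[[1]]$mask, ds[[1]]$mask)
  expect_lt(max(abs(back[[2]]$image - ds[[2]]$image)), 1 / 255)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_setequal(man$split, c("train", "val", "test"))
})
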