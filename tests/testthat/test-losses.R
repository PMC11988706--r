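# Loss family identities and hand-computed values.

test_that("dice loss honors its closed form and limits", {
  G <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dice_loss(G, G), 0, tolerance = 1e-6)
  expect_identical(dice_loss(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  # P=[1,0], G=[1,1]: 1 - 2/3 in the eps -> 0 limit
  expect_equal(dice_loss(c(1, 0), c(1, 1), eps = 1e-12), 1 / 3,
               tolerance = 1e-9)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "carunet_shape_error")
})

test_that("bce loss matches scalar evaluations", {
  G <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(bce_loss(G, G), 1e-6)
  set.seed(1)
  Grand <- matrix(rbinom(20, 1, 0.4), 4, 5)
  expect_equal(bce_loss(matrix(0.5, 4, 5), Grand), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.25, 1), -log(0.25), tolerance = 1e-12)
})

test_that("focal loss reduces to bce at gamma 0 and matches hand values", {
  set.seed(2)
  P <- matrix(runif(24), 4, 6)
  G <- matrix(rbinom(24, 1, 0.5), 4, 6)
  expect_equal(focal_loss(P, G, focal_gamma = 0, focal_alpha = 1),
               bce_loss(P, G), tolerance = 1e-12)
  expect_equal(focal_loss(0.5, 1, focal_gamma = 2, focal_alpha = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_lt(focal_loss(G, G), 1e-6)
  expect_error(focal_loss(P, G, focal_gamma = -1),
               class = "carunet_config_error")
})

test_that("the compound loss is the weighted sum of its components", {
  set.seed(3)
  P <- matrix(runif(30), 5, 6)
  G <- matrix(rbinom(30, 1, 0.5), 5, 6)
  expect_identical(compound_loss(P, G, loss_config(1, 0, 0)), dice_loss(P, G))
  expect_equal(compound_loss(P, G, loss_config(1, 1, 1)),
               dice_loss(P, G) + bce_loss(P, G) + focal_loss(P, G),
               tolerance = 1e-12)
  expect_lt(compound_loss(G, G, loss_config(1, 1, 1)), 1e-5)
  expect_error(loss_config(0, 0, 0), class = "carunet_config_error")
})

test_that("losses are permutation invariant and monotone in foreground confidence", {
  set.seed(4)
  P <- runif(40)
  G <- rbinom(40, 1, 0.5)
  perm <- sample(40)
  expect_equal(dice_loss(P, G), dice_loss(P[perm], G[perm]))
  expect_equal(bce_loss(P, G), bce_loss(P[perm], G[perm]))
  expect_equal(focal_loss(P, G), focal_loss(P[perm], G[perm]))
  # raising P on a foreground pixel never increases dice or bce loss
  fg <- which(G == 1)[1]
  for (delta in c(0.05, 0.2)) {
    P2 <- P
    P2[fg] <- min(1, P[fg] + delta)
    expect_lte(dice_loss(P2, G), dice_loss(P, G))
    expect_lte(bce_loss(P2, G), bce_loss(P, G))
  }
})

test_that("named loss combinations map to the right weights", {
  cfg <- loss_config_by_name("bce+dice+focal")
  expect_identical(c(cfg$alpha, cfg$beta, cfg$gamma), c(1, 1, 1))
  cfg2 <- loss_config_by_name("focal")
  expect_identical(c(cfg2$alpha, cfg2$beta, cfg2$gamma), c(0, 0, 1))
  expect_error(loss_config_by_name("tversky"), class = "carunet_config_error")
})

test_that("dice loss and hard dice metric sum to one on binary inputs", {
  set.seed(5)
  P <- matrix(rbinom(36, 1, 0.5), 6, 6)
  G <- matrix(rbinom(36, 1, 0.5), 6, 6)
  m <- segmentation_metrics(P, G)
  expect_equal(dice_loss(P, G, eps = 0) + m[["dice"]], 1, tolerance = 1e-9)
})
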