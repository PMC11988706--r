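# Confusion-matrix metrics and report aggregation.

test_that("metrics match a hand confusion count (TP=1 FP=1 FN=0 TN=2)", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)   # column-major: [[1,1],[0,0]]
  gt <- matrix(c(1, 0, 0, 0), 2, 2)
  m <- segmentation_metrics(pred, gt)
  expect_equal(m[["accuracy"]], 0.75)
  expect_equal(m[["dice"]], 2 / 3)
  expect_equal(m[["iou"]], 1 / 2)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["precision"]], 1 / 2)
  expect_equal(m[["specificity"]], 2 / 3)
})

test_that("a perfect prediction scores 1 on all six metrics", {
  G <- matrix(rbinom(25, 1, 0.4), 5, 5)
  expect_equal(unname(segmentation_metrics(G, G)), rep(1, 6))
})

test_that("iou and dice obey iou = dice / (2 - dice) per image", {
  set.seed(6)
  for (i in 1:10) {
    P <- matrix(runif(64), 8, 8)
    G <- matrix(rbinom(64, 1, 0.3), 8, 8)
    m <- segmentation_metrics(P, G)
    expect_equal(m[["iou"]], m[["dice"]] / (2 - m[["dice"]]),
                 tolerance = 1e-12)
    expect_lte(m[["iou"]], m[["dice"]])
  }
})

test_that("metrics are invariant under joint permutation", {
  set.seed(7)
  P <- runif(50)
  G <- rbinom(50, 1, 0.5)
  perm <- sample(50)
  expect_equal(segmentation_metrics(P, G),
               segmentation_metrics(P[perm], G[perm]))
})

test_that("reports aggregate per-image means and optionally pooled counts", {
  set.seed(8)
  preds <- lapply(1:4, function(i) matrix(runif(16), 4, 4))
  masks <- lapply(1:4, function(i) matrix(rbinom(16, 1, 0.5), 4, 4))
  rep <- metric_report(preds, masks, pooled = TRUE)
  expect_identical(rep$aggregation, "image_mean")
  expect_equal(rep$mean[["dice"]], mean(rep$per_image$dice))
  expect_length(rep$pooled, 6)

  dir <- withr::local_tempdir()
  df <- write_metric_report(rep, file.path(dir, "m.csv"),
                            file.path(dir, "m.json"))
  expect_true(file.exists(file.path(dir, "m.csv")))
  expect_true(file.exists(file.path(dir, "m.json")))
  expect_identical(colnames(df),
                   c("accuracy", "dice", "iou", "recall", "precision",
                     "specificity"))
  expect_equal(df["mean", "dice"], round(100 * rep$mean[["dice"]], 2))
})

test_that("degenerate empty-mask cases follow the agreement convention", {
  empty <- matrix(0, 3, 3)
  m <- segmentation_metrics(empty, empty)
  expect_equal(unname(m), rep(1, 6))
  m2 <- segmentation_metrics(matrix(1, 3, 3), empty)
  expect_equal(m2[["recall"]], 0)       # nothing to find but plenty found
  expect_equal(m2[["specificity"]], 0)
})
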