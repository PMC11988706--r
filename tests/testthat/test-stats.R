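# Mann-Whitney U statistic and p-values.

test_that("separated samples give U = 0 and exact p = 0.1", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")
})

test_that("identical samples are maximally non-significant", {
  r <- mann_whitney_u(c(2, 5, 5, 9), c(2, 5, 5, 9))
  expect_equal(r$U, 8)              # nm/2 with ties counted as halves
  expect_equal(r$p, 1)
})

test_that("swapping the samples maps U to nm - U with the same p", {
  set.seed(9)
  a <- rnorm(4); b <- rnorm(5)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r1$U + r2$U, 20)
  expect_equal(r1$p, r2$p)
})

test_that("exact p matches independent enumeration for all n+m <= 8", {
  set.seed(10)
  for (n in 1:4) for (m in n:(8 - n)) {
    a <- sample(1:5, n, replace = TRUE)      # ties likely
    b <- sample(1:5, m, replace = TRUE)
    got <- mann_whitney_u(a, b)
    ref <- mw_oracle(a, b)
    if (abs(got$U - ref$U) > 1e-12) fail("U mismatch")
    if (abs(got$p - ref$p) > 1e-12) fail("p mismatch")
  }
  succeed()
})

test_that("tie-free exact p agrees with the classical distribution", {
  set.seed(11)
  a <- rnorm(4); b <- rnorm(4)
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("the normal approximation tracks the exact tail for n = m = 20", {
  set.seed(12)
  a <- rnorm(20); b <- rnorm(20, 0.3)
  got <- mann_whitney_u(a, b)          # nm = 400 -> normal approximation
  expect_identical(got$method, "normal")
  # exact (tie-free) reference from the wilcoxon distribution
  lo <- min(got$U, 400 - got$U)
  p_exact <- 2 * stats::pwilcox(lo, 20, 20)
  expect_lt(abs(got$p - p_exact), 0.02)
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney_u(numeric(), 1:3),
               class = "carunet_config_error")
})
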