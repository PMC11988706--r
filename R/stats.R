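# Nonparametric comparison of per-image score samples.

#' Mann-Whitney U test
#'
#' Computes the U statistic of sample `a` versus sample `b` (number of pairs
#' with `a_i > b_j`, plus half the tied pairs) and a two-sided p-value. When
#' `n*m <= 64` the p-value is exact, by enumeration of all assignments of the
#' pooled values to the two groups (ties handled exactly); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b Non-empty numeric score vectors.
#' @return List with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  check_that(length(a) > 0 && length(b) > 0,
             "a/b: both samples must be non-empty")
  check_that(all(is.finite(a)) && all(is.finite(b)),
             "a/b: scores must be finite")
  n <- length(a); m <- length(b)
  ustat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), 0))
  }
  U <- ustat(a, b)
  if (n * m <= 64) {
    pooled <- c(a, b)
    combos <- utils::combn(n + m, n)
    dev <- abs(U - n * m / 2)
    hits <- 0L
    for (j in seq_len(ncol(combos))) {
      ia <- combos[, j]
      u <- ustat(pooled[ia], pooled[-ia])
      if (abs(u - n * m / 2) >= dev - 1e-12) hits <- hits + 1L
    }
    list(U = U, p = hits / ncol(combos), method = "exact")
  } else {
    ties <- table(c(a, b))
    tiecorr <- sum(ties^3 - ties)
    sigma2 <- n * m / 12 * ((n + m + 1) - tiecorr / ((n + m) * (n + m - 1)))
    mu <- n * m / 2
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(U = U, p = min(1, 2 * pnorm(-z)), method = "normal")
  }
}
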