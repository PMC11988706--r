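#' @useDynLib carunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif pnorm sd
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Classed conditions: configuration errors (bad user input, CLI exit 2) vs
# runtime errors (CLI exit 1).
stop_config <- function(...) {
  stop(structure(class = c("carunet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_shape <- function(...) {
  stop(structure(class = c("carunet_shape_error", "carunet_config_error",
                           "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(ok, ...) if (!isTRUE(ok)) stop_config(...)

#' Derive a child seed from a base seed and counters
#'
#' Folds a base seed with one or more non-negative integer counters into a new
#' seed below 2^31, so that every stochastic stage of a run owns an
#' independent, reproducible stream. The derivation is a fixed integer hash:
#' the result depends only on its inputs, never on R's RNG state.
#'
#' @param seed Non-negative integer base seed.
#' @param ... Non-negative integer counters (e.g. an image index, a fold
#'   index, a grid-cell index).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  check_that(is.numeric(seed) && length(seed) == 1 && seed >= 0,
             "seed: must be a single non-negative integer")
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (x in c(...)) {
    # 16-bit split keeps every product below 2^53 so the arithmetic is exact
    h <- (h * 48271) %% m
    h <- (h + as.numeric(x) %% m) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 4-D array helpers; tensors are (H, W, C, N)
as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_shape("expected an array, got a vector")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  else if (length(d) != 4) stop_shape("expected a 2-4 dimensional array")
  x
}

t4_dim <- function(x) dim(x)

# broadcast a length-C vector over (H, W, C, N)
bc_channel_vec <- function(v, H, W) rep(v, each = H * W)

# broadcast a (C, N) matrix over (H, W, C, N)
bc_channel_mat <- function(s, H, W) rep(as.vector(s), each = H * W)

# broadcast a (H, W, 1, N) map over channels
bc_spatial <- function(m, C) {
  d <- dim(m)
  mm <- matrix(m, d[1] * d[2], d[4])
  as.vector(mm[rep.int(seq_len(d[1] * d[2]), C), , drop = FALSE])
}

# sum over H, W -> (C, N)
reduce_hw <- function(v, H, W, C, N) {
  matrix(colSums(matrix(v, H * W, C * N)), C, N)
}

# sum over H, W, N -> length C
reduce_hwn <- function(v, H, W, C, N) {
  rowSums(reduce_hw(v, H, W, C, N))
}

# sum over channels -> (H, W, 1, N)
reduce_channels <- function(v, H, W, C, N) {
  arr <- array(v, c(H * W, C, N))
  out <- colSums(aperm(arr, c(2, 1, 3)))
  dim(out) <- c(H, W, 1L, N)
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
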