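# Deterministic generator of lung-like phantom image/mask pairs: two bright,
# vertically elongated, slightly inward-rotated elliptical fields on a darker
# noisy background. The phantoms emulate the bimodal structure a lung-field
# segmenter must learn without claiming anatomical realism, so the whole
# pipeline is testable without any radiograph download.

#' Phantom generator configuration
#'
#' @param image_size Pixels per side of the square image (>= 32).
#' @param lung_area_range Closed interval of the total lung-mask fraction of
#'   the image area.
#' @param noise_sigma Standard deviation of additive Gaussian noise on the
#'   `[0, 1]` intensity scale.
#' @param background_level,lung_level Mean intensities of background and lung
#'   fields, both in `[0, 1]`.
#' @param rib_stripes If `TRUE`, low-amplitude horizontal sinusoidal bands are
#'   added to the image (rib-shadow caricature).
#' @param seed Non-negative integer; together with the pair index it fully
#'   determines each phantom.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 256, lung_area_range = c(0.15, 0.35),
                           noise_sigma = 0.05, background_level = 0.2,
                           lung_level = 0.8, rib_stripes = FALSE, seed = 0) {
  check_that(is.numeric(image_size) && length(image_size) == 1 &&
               image_size >= 32,
             "image_size: must be a single value >= 32")
  check_that(length(lung_area_range) == 2 &&
               lung_area_range[1] <= lung_area_range[2] &&
               lung_area_range[1] >= 0 && lung_area_range[2] <= 1,
             "lung_area_range: must be an interval inside [0, 1]")
  check_that(is.numeric(noise_sigma) && noise_sigma >= 0,
             "noise_sigma: must be >= 0")
  check_that(background_level >= 0 && background_level <= 1,
             "background_level: must be in [0, 1]")
  check_that(lung_level >= 0 && lung_level <= 1,
             "lung_level: must be in [0, 1]")
  check_that(is.logical(rib_stripes) && length(rib_stripes) == 1,
             "rib_stripes: must be TRUE or FALSE")
  check_that(is.numeric(seed) && length(seed) == 1 && seed >= 0,
             "seed: must be a single non-negative integer")
  structure(list(image_size = as.integer(image_size),
                 lung_area_range = as.numeric(lung_area_range),
                 noise_sigma = noise_sigma,
                 background_level = background_level,
                 lung_level = lung_level,
                 rib_stripes = rib_stripes,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# rasterize a rotated ellipse: centre (rc, cc) in pixels, semi-axes (ar, ac)
# along the rotated (row, col) directions, rotation phi in radians
ellipse_mask <- function(n, rc, cc, ar, ac, phi) {
  r <- matrix(seq_len(n) - 1, n, n) - rc
  c <- matrix(seq_len(n) - 1, n, n, byrow = TRUE) - cc
  u <- r * cos(phi) + c * sin(phi)
  v <- -r * sin(phi) + c * cos(phi)
  (u / ar)^2 + (v / ac)^2 <= 1
}

#' Generate one phantom image/mask pair
#'
#' The mask is the union of two disjoint filled ellipses (left and right lung
#' fields), each a single 4-connected component, separated by at least two
#' background columns; the image is `background_level` outside the mask and
#' `lung_level` inside, plus optional stripes and Gaussian noise, clipped to
#' `[0, 1]`. The output is fully determined by `(config$seed, index)`.
#'
#' @param config A [phantom_config()].
#' @param index Non-negative pair index within the dataset.
#' @return An `image_pair`: list with `image` (matrix in `[0, 1]`), `mask`
#'   (0/1 matrix) and `id`.
#' @export
generate_phantom <- function(config, index = 0) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  check_that(is.numeric(index) && length(index) == 1 && index >= 0,
             "index: must be a single non-negative integer")
  n <- config$image_size
  with_seed(derive_seed(config$seed, 7, index), {
    f <- runif(1, config$lung_area_range[1], config$lung_area_range[2])
    area_px <- f / 2 * n * n                    # per ellipse
    rho <- runif(2, 1.7, 2.3)                   # vertical elongation
    phi <- runif(1, 3, 8) * pi / 180            # inward rotation
    ac <- sqrt(area_px / (pi * rho))            # column semi-axes
    ar <- rho * ac
    rc <- (0.52 + runif(2, -0.02, 0.02)) * (n - 1)
    ccl <- (0.28 + runif(1, -0.02, 0.02)) * (n - 1)
    ccr <- (0.72 + runif(1, -0.02, 0.02)) * (n - 1)
    # column half-extent of a rotated ellipse; shift centres apart until at
    # least 3 background columns separate the fields (shifting preserves area)
    ext <- sqrt((ar * sin(phi))^2 + (ac * cos(phi))^2)
    gap <- (ccr - ext[2]) - (ccl + ext[1])
    if (gap < 3) {
      push <- (3 - gap) / 2
      ccl <- ccl - push
      ccr <- ccr + push
    }
    left <- ellipse_mask(n, rc[1], ccl, ar[1], ac[1], +phi)
    right <- ellipse_mask(n, rc[2], ccr, ar[2], ac[2], -phi)
    mask <- (left | right) * 1
    img <- config$background_level +
      (config$lung_level - config$background_level) * mask
    if (config$rib_stripes) {
      rows <- matrix(seq_len(n) - 1, n, n)
      img <- img + 0.03 * sin(2 * pi * rows / (n / 9))
    }
    if (config$noise_sigma > 0)
      img <- img + matrix(rnorm(n * n, 0, config$noise_sigma), n, n)
    img <- clip01(img)
    list(image = img, mask = mask,
         id = sprintf("phantom_%05d", as.integer(index)))
  })
}

#' Generate a phantom dataset
#'
#' Element `i` equals `generate_phantom(config, i - 1)`: pairs are indexed by
#' a counter, so a dataset is reproducible elementwise and independent of the
#' order of generation.
#'
#' @param n Number of pairs (>= 0).
#' @param config A [phantom_config()].
#' @return A list of `image_pair`s.
#' @export
generate_dataset <- function(n, config = phantom_config()) {
  check_that(is.numeric(n) && length(n) == 1 && n >= 0,
             "n: must be a single non-negative integer")
  lapply(seq_len(n), function(i) generate_phantom(config, i - 1))
}

#' Write image/mask pairs to PNG directories
#'
#' Writes 8-bit grayscale PNGs: `images/<id>.png` (intensities) and
#' `masks/<id>.png` (masks as 0/255), plus an optional manifest CSV with
#' columns `basename` and `split`.
#'
#' @param pairs List of `image_pair`s.
#' @param dir Output directory (created if missing).
#' @param split Optional character vector of split labels (recycled names for
#'   the manifest); if `NULL` no manifest is written.
#' @return `dir`, invisibly.
#' @export
write_image_pairs <- function(pairs, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    png::writePNG(p$image, file.path(dir, "images", paste0(p$id, ".png")))
    png::writePNG(p$mask, file.path(dir, "masks", paste0(p$id, ".png")))
  }
  if (!is.null(split)) {
    manifest <- data.frame(basename = vapply(pairs, `[[`, "", "id"),
                           split = rep_len(split, length(pairs)))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read image/mask pairs from PNG directories
#'
#' Inverse of [write_image_pairs()]: reads `images/*.png` and the matching
#' `masks/*.png`, returning intensities in `[0, 1]` and strictly binary masks
#' (thresholded at 0.5).
#'
#' @param dir Directory containing `images/` and `masks/`.
#' @param ids Optional basenames to read (default: all images present).
#' @return A list of `image_pair`s.
#' @export
read_image_pairs <- function(dir, ids = NULL) {
  imdir <- file.path(dir, "images")
  mkdir <- file.path(dir, "masks")
  if (!dir.exists(imdir)) stop_config("no images/ directory under ", dir)
  if (is.null(ids))
    ids <- sub("\\.png$", "", sort(list.files(imdir, pattern = "\\.png$")))
  lapply(ids, function(id) {
    img <- png::readPNG(file.path(imdir, paste0(id, ".png")))
    if (length(dim(img)) == 3) img <- img[, , 1]
    mfile <- file.path(mkdir, paste0(id, ".png"))
    msk <- if (file.exists(mfile)) {
      m <- png::readPNG(mfile)
      if (length(dim(m)) == 3) m <- m[, , 1]
      (m >= 0.5) * 1
    } else NULL
    list(image = img, mask = msk, id = id)
  })
}

# 4-connected component count of a binary matrix (flood fill)
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  todo <- which(mask > 0 & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% n + 1L
      c <- (q - 1L) %/% n + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1 && d[1] <= n && d[2] >= 1 && d[2] <= m &&
            mask[d[1], d[2]] > 0 && lab[d[1], d[2]] == 0L) {
          lab[d[1], d[2]] <- cur
          queue <- c(queue, (d[2] - 1L) * n + d[1])
        }
      }
    }
  }
  lab
}
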