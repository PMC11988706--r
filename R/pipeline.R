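# Preprocessing, 8:1:1 splitting and joint image/mask augmentation.
#
# Conventions (shared with the C++ geometry kernels): coordinates are
# (row, col), 0-based; rotations are counter-clockwise for positive angles,
# about the image centre, with constant-0 fill outside the support; images
# are resampled bilinearly (half-pixel centres), masks by nearest neighbour
# and re-binarized at 0.5.

ROTATION_ANGLES <- c(-15, 15, -30, 30, -45, 45, -90, 90)

#' Preprocess a raw image
#'
#' Resizes an 8-bit grayscale image to `size x size` pixels by bilinear
#' interpolation and rescales intensities to `[0, 1]` by dividing by 255.
#'
#' @param raw_image Non-empty numeric matrix with values in `[0, 255]`.
#' @param size Output side length (default 256).
#' @return A `size x size` matrix with values in `[0, 1]`.
#' @export
preprocess <- function(raw_image, size = 256) {
  if (is.null(dim(raw_image)) || length(dim(raw_image)) != 2 ||
      any(dim(raw_image) == 0))
    stop_shape("raw_image: expected a non-empty 2-D array")
  check_that(min(raw_image) >= 0 && max(raw_image) <= 255,
             "raw_image: values must lie in [0, 255]")
  y <- raw_image
  if (!all(dim(y) == c(size, size)))
    y <- .resize_bilinear(y, as.integer(size), as.integer(size))
  clip01(y / 255)
}

#' 8:1:1 split counts
#'
#' Validation and test sizes are `N/10` rounded half-up; training takes the
#' remainder, so the three counts always sum to `N`. This reproduces the
#' published per-dataset distribution, e.g. 662 radiographs split as
#' (530, 66, 66) and 138 as (110, 14, 14).
#'
#' @param N Dataset size (>= 3).
#' @return List with `n_train`, `n_val`, `n_test`.
#' @export
split_counts <- function(N) {
  check_that(is.numeric(N) && length(N) == 1 && N >= 3,
             "N: dataset size must be >= 3")
  n_val <- as.integer(floor(N / 10 + 0.5))
  n_test <- n_val
  list(n_train = as.integer(N - n_val - n_test), n_val = n_val,
       n_test = n_test)
}

#' Assign ids to train/validation/test splits
#'
#' Applies a seeded permutation to `ids` and assigns the first `n_train` to
#' training, the next `n_val` to validation and the rest to testing. The
#' partition is disjoint and exhaustive and identical for identical seeds.
#'
#' @param ids Character vector of unique ids.
#' @param counts A [split_counts()] list summing to `length(ids)`.
#' @param seed Shuffle seed.
#' @return Data frame with columns `id` and `split`.
#' @export
assign_split <- function(ids, counts, seed = 0) {
  if (anyDuplicated(ids)) stop_config("ids: duplicate ids in split input")
  N <- length(ids)
  check_that(counts$n_train + counts$n_val + counts$n_test == N,
             "counts: must sum to length(ids)")
  perm <- with_seed(derive_seed(seed, 11), sample.int(N))
  split <- rep(c("train", "val", "test"),
               c(counts$n_train, counts$n_val, counts$n_test))
  out <- data.frame(id = ids[perm], split = split,
                    stringsAsFactors = FALSE)
  out[order(match(out$id, ids)), , drop = FALSE]
}

#' Transform specification
#'
#' @param kind One of `"rotate"`, `"hflip"`, `"vflip"`, `"hvflip"`,
#'   `"brightness"`, `"gaussian_blur"`.
#' @param angle Rotation angle in degrees; for augmentation plans restricted
#'   to -15, 15, -30, 30, -45, 45, -90, 90.
#' @param factor Brightness factor (> 0).
#' @param sigma Gaussian blur standard deviation in pixels (> 0).
#' @return A `carunet_transform` list.
#' @export
transform_spec <- function(kind, angle = NULL, factor = NULL, sigma = NULL) {
  kinds <- c("rotate", "hflip", "vflip", "hvflip", "brightness",
             "gaussian_blur")
  check_that(length(kind) == 1 && kind %in% kinds,
             "kind: must be one of ", paste(kinds, collapse = ", "))
  if (kind == "rotate") {
    check_that(!is.null(angle), "angle: required for rotate")
  }
  if (kind == "brightness" && !is.null(factor))
    check_that(factor > 0, "factor: brightness factor must be > 0")
  if (kind == "gaussian_blur" && !is.null(sigma))
    check_that(sigma > 0, "sigma: blur sigma must be > 0")
  structure(list(kind = kind, angle = angle, factor = factor, sigma = sigma),
            class = "carunet_transform")
}

default_transforms <- function() {
  c(lapply(ROTATION_ANGLES, function(a) transform_spec("rotate", angle = a)),
    list(transform_spec("hflip"), transform_spec("vflip"),
         transform_spec("hvflip"), transform_spec("brightness"),
         transform_spec("gaussian_blur")))
}

transform_tag <- function(t) {
  switch(t$kind,
         rotate = sprintf("rot%+d", as.integer(t$angle)),
         brightness = sprintf("bright%.3f", t$factor),
         gaussian_blur = sprintf("blur%.3f", t$sigma),
         t$kind)
}

#' Build an augmentation plan
#'
#' Distributes a fixed augmentation budget over the training sources: each
#' source is used `floor(budget/n)` or `ceiling(budget/n)` times (imbalance
#' at most 1; the sources receiving an extra use are a seeded sample), and
#' within one source the transform list is cycled in order before any
#' transform repeats. Brightness factors are drawn uniformly from
#' `[0.8, 1.2]` and blur sigmas from `[0.5, 1.5]`, seeded.
#'
#' @param source_ids Character vector of training source ids (non-empty when
#'   `budget > 0`).
#' @param budget Number of augmented images to plan (default 8000).
#' @param transforms List of [transform_spec()]s to cycle through (default:
#'   the eight rotations, the three flips, brightness and blur).
#' @param seed Plan seed.
#' @return A `carunet_augmentation_plan`: data frame with one row per
#'   assignment (`source_id`, `kind`, `angle`, `factor`, `sigma`, `tag`).
#' @export
build_augmentation_plan <- function(source_ids, budget = 8000,
                                    transforms = default_transforms(),
                                    seed = 0) {
  check_that(is.numeric(budget) && length(budget) == 1 && budget >= 0,
             "budget: must be >= 0")
  if (budget == 0)
    return(structure(data.frame(source_id = character(), kind = character(),
                                angle = numeric(), factor = numeric(),
                                sigma = numeric(), tag = character(),
                                stringsAsFactors = FALSE),
                     class = c("carunet_augmentation_plan", "data.frame")))
  check_that(length(source_ids) > 0, "source_ids: empty with positive budget")
  check_that(length(transforms) > 0, "transforms: must be non-empty")
  n <- length(source_ids)
  base <- budget %/% n
  extra <- budget %% n
  uses <- rep(base, n)
  if (extra > 0) {
    picked <- with_seed(derive_seed(seed, 13), sample.int(n, extra))
    uses[picked] <- uses[picked] + 1L
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (uses[i] == 0) next
    js <- (seq_len(uses[i]) - 1L) %% length(transforms) + 1L
    ts <- lapply(seq_along(js), function(k) {
      t <- transforms[[js[k]]]
      jseed <- derive_seed(seed, 17, i, k)
      if (t$kind == "brightness" && is.null(t$factor))
        t$factor <- with_seed(jseed, runif(1, 0.8, 1.2))
      if (t$kind == "gaussian_blur" && is.null(t$sigma))
        t$sigma <- with_seed(jseed, runif(1, 0.5, 1.5))
      if (t$kind == "rotate")
        check_that(t$angle %in% ROTATION_ANGLES,
                   "angle: plan rotations restricted to ",
                   paste(ROTATION_ANGLES, collapse = ", "))
      t
    })
    rows[[i]] <- data.frame(
      source_id = source_ids[i],
      kind = vapply(ts, `[[`, "", "kind"),
      angle = vapply(ts, function(t) t$angle %||% NA_real_, 0),
      factor = vapply(ts, function(t) t$factor %||% NA_real_, 0),
      sigma = vapply(ts, function(t) t$sigma %||% NA_real_, 0),
      tag = vapply(ts, transform_tag, ""),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("carunet_augmentation_plan", "data.frame"))
}

gaussian_blur_2d <- function(x, sigma) {
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  reflect <- function(idx, len) {
    idx <- ifelse(idx < 1, 2 - idx, idx)
    ifelse(idx > len, 2 * len - idx, idx)
  }
  tmp <- matrix(0, n, m)
  for (o in seq(-radius, radius))
    tmp <- tmp + k[o + radius + 1] * x[reflect(seq_len(n) + o, n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (o in seq(-radius, radius))
    out <- out + k[o + radius + 1] * tmp[, reflect(seq_len(m) + o, m), drop = FALSE]
  out
}

#' Apply a transform to an image/mask pair
#'
#' Geometric transforms (rotations, flips) are applied to image and mask with
#' identical geometry: the image is resampled bilinearly, the mask by nearest
#' neighbour and re-binarized at 0.5. Photometric transforms (brightness,
#' Gaussian blur) touch the image only. The image is re-clipped to `[0, 1]`.
#'
#' @param pair An `image_pair` (list with `image`, `mask`, `id`).
#' @param t A [transform_spec()].
#' @return The transformed `image_pair`, with the transform tag appended to
#'   the id as `<id>__<tag>`.
#' @export
apply_transform <- function(pair, t) {
  if (!inherits(t, "carunet_transform"))
    stop_config("t: expected a transform_spec()")
  img <- pair$image
  msk <- pair$mask
  if (t$kind == "rotate") {
    # sinpi/cospi give exact values at multiples of 90 degrees, so axis-
    # aligned rotations restore pixels exactly
    cs <- cospi(t$angle / 180)
    sn <- sinpi(t$angle / 180)
    img <- .warp_rotate(img, cs, sn, 1L)
    if (!is.null(msk)) msk <- (.warp_rotate(msk, cs, sn, 0L) >= 0.5) * 1
  } else if (t$kind == "hflip") {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(msk)) msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  } else if (t$kind == "vflip") {
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    if (!is.null(msk)) msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  } else if (t$kind == "hvflip") {
    img <- img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(msk))
      msk <- msk[rev(seq_len(nrow(msk))), rev(seq_len(ncol(msk))), drop = FALSE]
  } else if (t$kind == "brightness") {
    check_that(!is.null(t$factor) && t$factor > 0, "factor: must be > 0")
    img <- img * t$factor
  } else if (t$kind == "gaussian_blur") {
    check_that(!is.null(t$sigma) && t$sigma > 0, "sigma: must be > 0")
    img <- gaussian_blur_2d(img, t$sigma)
  } else stop_config("unknown transform kind: ", t$kind)
  list(image = clip01(img), mask = msk,
       id = paste0(pair$id, "__", transform_tag(t)))
}

#' Execute an augmentation plan
#'
#' @param pairs Named list or list of `image_pair`s covering every source id
#'   in the plan.
#' @param plan A [build_augmentation_plan()] result.
#' @return List of augmented `image_pair`s, one per plan row, in plan order.
#' @export
apply_augmentation_plan <- function(pairs, plan) {
  ids <- vapply(pairs, `[[`, "", "id")
  lapply(seq_len(nrow(plan)), function(i) {
    src <- match(plan$source_id[i], ids)
    if (is.na(src)) stop_config("plan references unknown source id: ",
                                plan$source_id[i])
    t <- transform_spec(plan$kind[i],
                        angle = if (!is.na(plan$angle[i])) plan$angle[i],
                        factor = if (!is.na(plan$factor[i])) plan$factor[i],
                        sigma = if (!is.na(plan$sigma[i])) plan$sigma[i])
    apply_transform(pairs[[src]], t)
  })
}
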