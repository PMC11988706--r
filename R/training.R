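# Seeded trainer, evaluation, k-fold cross-validation and the ablation /
# loss / optimizer grid runner.

#' Training configuration
#'
#' Defaults follow the published regimen: Adam, initial learning rate 0.001,
#' batch size 32, 50 epochs, learning-rate reduction by a factor of 0.1 on a
#' validation-loss plateau (patience 5 epochs), Dice loss, checkpointing the
#' epoch with the minimum validation loss.
#'
#' @param optimizer One of `"adam"`, `"rmsprop"`, `"sgd"` (SGD uses momentum
#'   0.9).
#' @param initial_lr Initial learning rate.
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of epochs.
#' @param lr_reduce_factor Multiplicative learning-rate reduction in (0, 1).
#' @param lr_patience Epochs without validation improvement before reducing.
#' @param loss A [loss_config()]; default Dice loss only.
#' @param seed Seed controlling initialization, data order and augmentation
#'   jitter.
#' @return A `carunet_train_config` list.
#' @export
train_config <- function(optimizer = "adam", initial_lr = 0.001,
                         batch_size = 32, epochs = 50,
                         lr_reduce_factor = 0.1, lr_patience = 5,
                         loss = loss_config(alpha = 1, beta = 0, gamma = 0),
                         seed = 0) {
  check_that(optimizer %in% c("adam", "rmsprop", "sgd"),
             "optimizer: must be adam, rmsprop or sgd")
  check_that(batch_size >= 1, "batch_size: must be >= 1")
  check_that(epochs >= 1, "epochs: must be >= 1")
  check_that(lr_reduce_factor > 0 && lr_reduce_factor < 1,
             "lr_reduce_factor: must lie in (0, 1)")
  check_that(lr_patience >= 1, "lr_patience: must be >= 1")
  check_that(initial_lr > 0, "initial_lr: must be positive")
  if (!inherits(loss, "carunet_loss_config"))
    stop_config("loss: expected a loss_config()")
  structure(list(optimizer = optimizer, initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_patience = as.integer(lr_patience),
                 loss = loss, seed = as.integer(seed)),
            class = "carunet_train_config")
}

pairs_to_batch <- function(pairs, input_size) {
  B <- length(pairs)
  x <- array(0, c(input_size, input_size, 1, B))
  g <- array(0, c(input_size, input_size, 1, B))
  for (i in seq_len(B)) {
    im <- pairs[[i]]$image
    mk <- pairs[[i]]$mask
    if (!all(dim(im) == c(input_size, input_size)))
      stop_shape("image '", pairs[[i]]$id, "' is ", nrow(im), "x", ncol(im),
                 ", model expects ", input_size, "x", input_size)
    x[, , 1, i] <- im
    g[, , 1, i] <- mk
  }
  list(x = x, g = g)
}

# ---- optimizers -------------------------------------------------------------

opt_new <- function(kind, lr) {
  o <- new.env(parent = emptyenv())
  o$kind <- kind
  o$lr <- lr
  o$t <- 0L
  o$state <- new.env(parent = emptyenv())
  o
}

opt_update <- function(o, key, w, g) {
  if (o$kind == "adam") {
    s <- o$state[[key]]
    if (is.null(s)) s <- list(m = 0 * w, v = 0 * w)
    s$m <- 0.9 * s$m + 0.1 * g
    s$v <- 0.999 * s$v + 0.001 * g^2
    o$state[[key]] <- s
    mh <- s$m / (1 - 0.9^o$t)
    vh <- s$v / (1 - 0.999^o$t)
    w - o$lr * mh / (sqrt(vh) + 1e-7)
  } else if (o$kind == "rmsprop") {
    v <- o$state[[key]]
    if (is.null(v)) v <- 0 * w
    v <- 0.9 * v + 0.1 * g^2
    o$state[[key]] <- v
    w - o$lr * g / (sqrt(v) + 1e-7)
  } else {                                   # sgd with momentum 0.9
    v <- o$state[[key]]
    if (is.null(v)) v <- 0 * w
    v <- 0.9 * v - o$lr * g
    o$state[[key]] <- v
    w + v
  }
}

collect_grad <- function(node) if (is.null(node$grad)) NULL else node$grad

# walk params and lifted nodes in parallel, apply one optimizer update per
# trainable array
opt_step <- function(o, params, nodes, path = character()) {
  o$t <- o$t + 1L
  step_rec <- function(p, nd, path) {
    for (nm in names(p)) {
      el <- p[[nm]]
      if (is.list(el)) {
        p[[nm]] <- step_rec(el, nd[[nm]], c(path, nm))
      } else if (!(nm %in% c(NONPARAM_NAMES, STAT_NAMES))) {
        g <- collect_grad(nd[[nm]])
        if (!is.null(g)) {
          key <- paste(c(path, nm), collapse = ".")
          dim(g) <- dim(el) %||% NULL
          p[[nm]] <- opt_update(o, key, el, g)
        }
      }
    }
    p
  }
  step_rec(params, nodes, path)
}

# ---- training ---------------------------------------------------------------

#' Train a model
#'
#' Runs `cfg$epochs` epochs of mini-batch gradient descent with the
#' configured optimizer and compound loss, recording train and validation
#' loss after every epoch. The learning rate is multiplied by
#' `cfg$lr_reduce_factor` whenever the validation loss has not improved for
#' `cfg$lr_patience` consecutive epochs. The returned checkpoint is the model
#' at the epoch with minimum validation loss. Runs are pure functions of
#' (model seed, data, configuration): data order and initialization all
#' derive from `cfg$seed`.
#'
#' @param model A built `carunet_model` (modified in place: its weights hold
#'   the final epoch).
#' @param train_set,val_set Non-empty lists of `image_pair`s matching the
#'   model input size.
#' @param cfg A [train_config()].
#' @param verbose If `TRUE` print one line per epoch to stderr.
#' @return List with `best` (checkpointed `carunet_model`), `history` (data
#'   frame: epoch, train_loss, val_loss, lr) and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        verbose = FALSE) {
  check_that(length(train_set) > 0, "train_set: must be non-empty")
  check_that(length(val_set) > 0, "val_set: must be non-empty")
  if (!inherits(cfg, "carunet_train_config"))
    stop_config("cfg: expected a train_config()")
  size <- model$config$input_size
  tb <- pairs_to_batch(train_set, size)
  vb <- pairs_to_batch(val_set, size)
  o <- opt_new(cfg$optimizer, cfg$initial_lr)
  n <- length(train_set)
  best_val <- Inf
  best_snap <- NULL
  best_epoch <- NA_integer_
  wait <- 0L
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    perm <- with_seed(derive_seed(cfg$seed, 23, ep), sample.int(n))
    starts <- seq(1, n, by = cfg$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
      xb <- tb$x[, , , idx, drop = FALSE]
      gb <- tb$g[, , , idx, drop = FALSE]
      ft <- model_forward_tape(model, xb, training = TRUE)
      gt <- tn_leaf(ft$tape, gb)
      lo <- fw_compound_loss(ft$tape, ft$out, gt, cfg$loss)
      if (!is.finite(lo$val))
        stop("training diverged: non-finite loss at epoch ", ep)
      tape_backward(ft$tape, lo)
      model$params <- writeback_states(model$params, ft$states)
      model$params <- opt_step(o, model$params, ft$nodes)
      losses[bi] <- lo$val
    }
    val_loss <- eval_loss(model, vb, cfg$loss)
    if (!is.finite(val_loss))
      stop("training diverged: non-finite validation loss at epoch ", ep)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                             val_loss = val_loss, lr = o$lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      ep, mean(losses), val_loss, o$lr))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_snap <- model_snapshot(model)
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$lr_patience) {
        o$lr <- o$lr * cfg$lr_reduce_factor
        wait <- 0L
      }
    }
  }
  list(best = model_restore(best_snap), history = do.call(rbind, hist),
       best_epoch = best_epoch)
}

# mean compound loss over a batch list, evaluation mode, chunked
eval_loss <- function(model, batch, loss_cfg, chunk = 8L) {
  B <- dim(batch$x)[4]
  tot <- 0
  for (s in seq(1, B, by = chunk)) {
    idx <- s:min(s + chunk - 1, B)
    p <- model_forward(model, batch$x[, , , idx, drop = FALSE],
                       training = FALSE)
    tot <- tot + compound_loss(p, batch$g[, , , idx, drop = FALSE],
                               loss_cfg) * length(idx)
  }
  tot / B
}

#' Evaluate a model on a test set
#'
#' Deterministic forward passes in evaluation mode (running batch-norm
#' statistics), binarization at `threshold`, per-image metrics plus their
#' mean. Invariant to the ordering of `test_set`.
#'
#' @param model A `carunet_model` (e.g. the checkpoint from [train_model()]).
#' @param test_set Non-empty list of `image_pair`s.
#' @param threshold Binarization threshold.
#' @param pooled Also report the image-pooled variant.
#' @return A [metric_report()] with an additional `dice` element (per-image
#'   Dice vector in test-set order).
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5, pooled = FALSE) {
  check_that(length(test_set) > 0, "test_set: must be non-empty")
  preds <- predict(model, lapply(test_set, `[[`, "image"))
  masks <- lapply(test_set, `[[`, "mask")
  rep <- metric_report(preds, masks, threshold, pooled)
  rep$dice <- rep$per_image$dice
  rep
}

#' k-fold cross-validation
#'
#' Partitions the dataset into `k` near-equal seeded folds; fold `i` is the
#' held-out test set while the remaining pairs are split 9:1 into training
#' and validation (checkpoint selection) sets. Summary rows report the mean
#' and sample standard deviation of each metric over folds.
#'
#' @param dataset List of `image_pair`s.
#' @param k Number of folds (2 <= k <= length(dataset)).
#' @param config A [model_config()] for the per-fold models.
#' @param cfg A [train_config()].
#' @return List with `folds` (per-fold list of `report` and `dice`),
#'   `summary` (data frame: metric, mean, sd) and `assignments`.
#' @export
kfold_cv <- function(dataset, k = 5, config = model_config(),
                     cfg = train_config()) {
  n <- length(dataset)
  check_that(k >= 2, "k: must be >= 2")
  if (k > n) stop_config("k: cannot exceed the dataset size (", n, ")")
  perm <- with_seed(derive_seed(cfg$seed, 31), sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(k), n)
  folds <- lapply(seq_len(k), function(i) {
    test_idx <- which(fold_of == i)
    rest <- setdiff(seq_len(n), test_idx)
    nv <- max(1L, as.integer(floor(length(rest) / 10 + 0.5)))
    vidx <- rest[with_seed(derive_seed(cfg$seed, 37, i),
                           sample.int(length(rest), nv))]
    tidx <- setdiff(rest, vidx)
    model <- build_model(config, seed = derive_seed(cfg$seed, 41, i))
    fit <- train_model(model, dataset[tidx], dataset[vidx], cfg)
    rep <- evaluate_model(fit$best, dataset[test_idx])
    list(fold = i, report = rep, dice = rep$dice)
  })
  means <- t(vapply(folds, function(f) f$report$mean, numeric(6)))
  summary <- data.frame(metric = colnames(means),
                        mean = colMeans(means),
                        sd = apply(means, 2, sd))
  list(folds = folds, summary = summary, assignments = fold_of)
}

VARIANTS <- c(unet = "unet", res_unet = "res_unet",
              res_unet_attn = "res_unet_attn",
              proposed_relu = "proposed", proposed = "proposed")

variant_config <- function(variant, input_size, width_scale = 1) {
  check_that(variant %in% names(VARIANTS),
             "variant: must be one of ", paste(names(VARIANTS), collapse = ", "))
  arch <- VARIANTS[[variant]]
  cfgm <- model_config(arch, input_size = input_size,
                       activation = if (variant == "proposed_relu") "relu"
                       else NULL)
  if (width_scale != 1) cfgm <- scale_model_config(cfgm, width_scale)
  cfgm
}

#' Run an ablation / loss / optimizer grid
#'
#' Trains and evaluates one model per (variant, loss, optimizer) grid cell,
#' from scratch, with the cell index folded into the seed. The dataset is
#' split 8:1:1 once (seeded) and shared by all cells. For every non-reference
#' variant the per-image Dice scores (at the first loss/optimizer of the
#' grid) are compared against the reference variant with the Mann-Whitney U
#' test.
#'
#' @param dataset List of `image_pair`s (all the same size).
#' @param variants Character vector drawn from `unet`, `res_unet`,
#'   `res_unet_attn`, `proposed_relu`, `proposed` (ablation items I-V).
#' @param losses Character vector of loss-combination names, see
#'   [loss_config_by_name()].
#' @param optimizers Character vector drawn from `adam`, `rmsprop`, `sgd`.
#' @param cfg A [train_config()] (its loss/optimizer fields are overridden
#'   per cell).
#' @param width_scale Width multiplier for the per-cell models (reduced-width
#'   models keep toy grids cheap).
#' @param reference Reference variant of the p-value comparison (default:
#'   the last element of `variants`).
#' @return List with `metrics` (one row per cell), `pvalues` (one row per
#'   non-reference variant) and `cells` (per-cell reports).
#' @export
run_ablation_grid <- function(dataset, variants = names(VARIANTS),
                              losses = "dice", optimizers = "adam",
                              cfg = train_config(), width_scale = 1,
                              reference = NULL) {
  check_that(length(dataset) >= 3, "dataset: need at least 3 pairs")
  for (v in variants) check_that(v %in% names(VARIANTS),
                                 "unknown variant name: ", v)
  for (o in optimizers) check_that(o %in% c("adam", "rmsprop", "sgd"),
                                   "unknown optimizer name: ", o)
  for (l in losses) loss_config_by_name(l)   # validates names
  if (is.null(reference)) reference <- variants[length(variants)]
  size <- nrow(dataset[[1]]$image)
  ids <- vapply(dataset, `[[`, "", "id")
  counts <- split_counts(length(dataset))
  if (counts$n_val == 0 || counts$n_test == 0)
    stop_config("dataset: too small for an 8:1:1 split")
  sp <- assign_split(ids, counts, seed = cfg$seed)
  tr <- dataset[sp$split == "train"]
  va <- dataset[sp$split == "val"]
  te <- dataset[sp$split == "test"]
  cells <- list()
  rows <- list()
  cell_idx <- 0L
  for (v in variants) for (l in losses) for (o in optimizers) {
    cell_idx <- cell_idx + 1L
    cseed <- derive_seed(cfg$seed, 43, cell_idx)
    ccfg <- cfg
    ccfg$loss <- loss_config_by_name(l)
    ccfg$optimizer <- o
    ccfg$seed <- cseed
    model <- build_model(variant_config(v, size, width_scale), seed = cseed)
    fit <- train_model(model, tr, va, ccfg)
    rep <- evaluate_model(fit$best, te)
    key <- paste(v, l, o, sep = "|")
    cells[[key]] <- rep
    rows[[key]] <- data.frame(variant = v, loss = l, optimizer = o,
                              t(rep$mean))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  ref_key <- paste(reference, losses[1], optimizers[1], sep = "|")
  others <- setdiff(variants, reference)
  pvalues <- do.call(rbind, lapply(others, function(v) {
    key <- paste(v, losses[1], optimizers[1], sep = "|")
    mw <- mann_whitney_u(cells[[key]]$dice, cells[[ref_key]]$dice)
    data.frame(variant = v, U = mw$U, p_dice = mw$p)
  }))
  list(metrics = metrics, pvalues = pvalues, cells = cells,
       split = sp, reference = reference)
}
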