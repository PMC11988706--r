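# Model assembly: the four ablation architectures, analytic parameter
# counting, and calibration of channel widths to fixed parameter budgets.
#
# All architectures share a 4-level encoder (each level halves the spatial
# size) and a bridge at 1/16 resolution:
#   unet          plain double-conv U-Net, max-pool encoder, 2x2 transposed-
#                 convolution decoder (classical baseline, ReLU)
#   res_unet      residual blocks everywhere, two-residual-block bridge,
#                 bilinear+conv decoder
#   res_unet_attn res_unet plus attention-gated skip connections
#   proposed      stem + CBAM after every residual block + ASPP bridge +
#                 attention-gated skips, LeakyReLU
# Encoder widths follow a x2 ladder from a base width; the bridge width is a
# free parameter used by the budget calibration.

ARCHS <- c("unet", "res_unet", "res_unet_attn", "proposed")

default_widths <- list(
  unet          = list(widths = c(21, 42, 84, 168), bottleneck = 328),
  res_unet      = list(widths = c(30, 60, 120, 240), bottleneck = 600),
  res_unet_attn = list(widths = c(27, 54, 108, 216), bottleneck = 688),
  proposed      = list(widths = c(15, 30, 60, 120), bottleneck = 248)
)

#' Model configuration
#'
#' Describes one of the four segmentation architectures. The default channel
#' widths are the calibrated ones: they reproduce the published parameter
#' budgets (3.27 M for the U-Net, 5.06 M for the residual U-Net, 5.86 M with
#' attention gates, 3.24 M / 12.37 MB for the proposed model) under the
#' 4-bytes-per-parameter size convention.
#'
#' @param arch One of `"unet"`, `"res_unet"`, `"res_unet_attn"`, `"proposed"`.
#' @param widths Encoder channel widths, levels 1-4 (strictly increasing).
#' @param bottleneck Bridge channel width (> last encoder width).
#' @param reduction CBAM channel-attention reduction ratio r.
#' @param spatial_divisor CBAM spatial-attention channel divisor.
#' @param gate_divisor Attention-gate intermediate width divisor (the gate
#'   projects a skip with C channels to `max(1, C %/% gate_divisor)`).
#' @param input_size Input image side length; must be divisible by 16.
#' @param in_channels Input channels (1 for grayscale radiographs).
#' @param activation `"leakyrelu"` (slope 0.01) or `"relu"`; the published
#'   ablation's variant IV is `proposed` with `"relu"`, variant V with
#'   `"leakyrelu"`. Defaults to `"relu"` for `unet`, `"leakyrelu"` otherwise.
#' @param slope Negative slope used when `activation = "leakyrelu"`.
#' @return A `carunet_model_config` list.
#' @export
model_config <- function(arch = "proposed", widths = NULL, bottleneck = NULL,
                         reduction = 16, spatial_divisor = 16,
                         gate_divisor = 2, input_size = 256, in_channels = 1,
                         activation = NULL, slope = 0.01) {
  check_that(length(arch) == 1 && arch %in% ARCHS,
             "arch: must be one of ", paste(ARCHS, collapse = ", "))
  if (is.null(widths)) widths <- default_widths[[arch]]$widths
  if (is.null(bottleneck)) {
    bottleneck <- if (identical(widths, default_widths[[arch]]$widths))
      default_widths[[arch]]$bottleneck else 2 * widths[4]
  }
  if (is.null(activation)) activation <- if (arch == "unet") "relu" else "leakyrelu"
  check_that(length(widths) == 4 && all(widths >= 1),
             "widths: need 4 positive encoder widths")
  check_that(all(diff(c(widths, bottleneck)) > 0),
             "widths: widths and bottleneck must be strictly increasing")
  check_that(input_size %% 16 == 0 && input_size >= 16,
             "input_size: must be a positive multiple of 16")
  check_that(activation %in% c("leakyrelu", "relu"),
             "activation: must be 'leakyrelu' or 'relu'")
  check_that(reduction >= 1 && spatial_divisor >= 1 && gate_divisor >= 1,
             "reduction/spatial_divisor/gate_divisor: must be >= 1")
  structure(list(arch = arch, widths = as.integer(widths),
                 bottleneck = as.integer(bottleneck),
                 reduction = as.integer(reduction),
                 spatial_divisor = as.integer(spatial_divisor),
                 gate_divisor = as.integer(gate_divisor),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 activation = activation,
                 slope = if (activation == "relu") 0 else slope),
            class = "carunet_model_config")
}

#' Scale the channel widths of a configuration
#'
#' Returns the same architecture with every width multiplied by `factor`
#' (floored, at least 1). Used for reduced-width test-bench models, e.g. the
#' quarter-width proposed network.
#'
#' @param config A [model_config()].
#' @param factor Positive scale factor.
#' @return A new `carunet_model_config`.
#' @export
scale_model_config <- function(config, factor = 0.25) {
  check_that(factor > 0, "factor: must be positive")
  w <- pmax(1L, as.integer(floor(config$widths * factor)))
  b <- max(w[4] + 1L, as.integer(floor(config$bottleneck * factor)))
  w <- as.integer(pmax(w, seq_len(4)))          # keep strictly increasing
  for (i in 2:4) if (w[i] <= w[i - 1]) w[i] <- w[i - 1] + 1L
  model_config(config$arch, widths = w, bottleneck = b,
               reduction = config$reduction,
               spatial_divisor = config$spatial_divisor,
               gate_divisor = config$gate_divisor,
               input_size = config$input_size,
               in_channels = config$in_channels,
               activation = config$activation)
}

# ---- analytic parameter counting -------------------------------------------
# Closed-form counts per layer type:
#   standard conv  kH*kW*Cin*Cout + Cout
#   separable conv kH*kW*Cin + Cin*Cout + Cout
#   batch norm     2C trainable + 2C non-trainable (running mean/variance)

cnt_conv <- function(k, cin, cout) k * k * cin * cout + cout
cnt_sep <- function(k, cin, cout) k * k * cin + cin * cout + cout
cnt_rb <- function(cin, cout) {
  c(tr = 2 * cin + cnt_sep(3, cin, cout) + 2 * cout + cnt_sep(3, cout, cout) +
      cnt_conv(1, cin, cout) + 2 * cout,
    nt = 2 * cin + 4 * cout)
}
cnt_cbam <- function(C, r, d) {
  h <- max(1L, C %/% r)
  cd <- max(1L, C %/% d)
  C * h + h + h * C + C + 49 * C * cd + cd + 49 * cd + 1
}
cnt_gate <- function(cs, cdch, gdiv) {
  ci <- max(1L, cs %/% gdiv)
  (cs * ci + ci) + (cdch * ci + ci) + (ci + 1)
}
cnt_aspp <- function(C) c(tr = 4 * (cnt_conv(3, C, C) + 2 * C) + cnt_conv(1, C, C),
                          nt = 8 * C)
cnt_stem <- function(w1, cin) c(tr = cnt_conv(3, cin, w1) +
                                  cnt_conv(3, w1, w1) + cnt_conv(1, cin, w1) +
                                  4 * w1,        # two BN layers, 2C each
                                nt = 4 * w1)

param_count_analytic <- function(config) {
  w <- config$widths
  w5 <- config$bottleneck
  cin0 <- config$in_channels
  tr <- 0; nt <- 0
  addp <- function(p) { tr <<- tr + p[["tr"]]; nt <<- nt + p[["nt"]] }
  addt <- function(p) tr <<- tr + p
  if (config$arch == "unet") {
    cin <- cin0
    for (i in 1:4) {
      addt(cnt_conv(3, cin, w[i]) + cnt_conv(3, w[i], w[i]))
      cin <- w[i]
    }
    addt(cnt_conv(3, w[4], w5) + cnt_conv(3, w5, w5))
    up_in <- w5
    for (j in 4:1) {
      addt(cnt_conv(2, up_in, w[j]))                    # 2x2 transposed conv
      addt(cnt_conv(3, 2 * w[j], w[j]) + cnt_conv(3, w[j], w[j]))
      up_in <- w[j]
    }
    addt(cnt_conv(1, w[1], 1))
  } else {
    prop <- config$arch == "proposed"
    gated <- config$arch %in% c("res_unet_attn", "proposed")
    cb <- function(C) if (prop)
      addt(cnt_cbam(C, config$reduction, config$spatial_divisor))
    if (prop) { addp(cnt_stem(w[1], cin0)); cb(w[1]) } else addp(cnt_rb(cin0, w[1]))
    cin <- w[1]
    for (i in c(w[2], w[3], w[4], w5)) { addp(cnt_rb(cin, i)); cb(i); cin <- i }
    if (prop) addp(cnt_aspp(w5)) else { addp(cnt_rb(w5, w5)); addp(cnt_rb(w5, w5)) }
    up_in <- w5
    for (j in 4:1) {
      if (gated) addt(cnt_gate(w[j], up_in, config$gate_divisor))
      addt(cnt_conv(3, up_in, w[j]))                    # bilinear up + 3x3 conv
      addp(cnt_rb(2 * w[j], w[j]))
      cb(w[j])
      up_in <- w[j]
    }
    addt(cnt_conv(1, w[1], 1))
  }
  list(total = tr + nt, trainable = tr, nontrainable = nt)
}

param_count_obj <- function(total, trainable) {
  total <- as.integer(total)
  trainable <- as.integer(trainable)
  structure(list(total = total, trainable = trainable,
                 nontrainable = total - trainable,
                 size_mb = total * 4 / 2^20),
            class = "carunet_param_count")
}

#' @export
print.carunet_param_count <- function(x, ...) {
  # millions and megabytes truncated to two decimals, the convention the
  # published size column follows
  tr2 <- function(v) sprintf("%.2f", floor(v * 100) / 100)
  cat(sprintf("Total parameters:     %d (%s M)\n", x$total,
              tr2(x$total / 1e6)))
  cat(sprintf("Trainable parameters: %d (%s M)\n", x$trainable,
              tr2(x$trainable / 1e6)))
  cat(sprintf("Non-trainable:        %d\n", x$nontrainable))
  cat(sprintf("Size (MB, 4 B/param): %s\n", tr2(x$size_mb)))
  invisible(x)
}

#' Count model parameters
#'
#' For a built model, counts parameters by traversing the actual weight
#' arrays; for a configuration, computes the same totals analytically from
#' closed-form per-layer sums. Trainable parameters are the weights, biases
#' and batch-norm scale/shift; the non-trainable parameters are exactly the
#' batch-norm running statistics. The reported size assumes 4 bytes per
#' parameter, in binary megabytes.
#'
#' @param x A `carunet_model` or a `carunet_model_config`.
#' @return A `carunet_param_count` with `total`, `trainable`, `nontrainable`
#'   and `size_mb`.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.carunet_model_config <- function(x) {
  p <- param_count_analytic(x)
  param_count_obj(p$total, p$trainable)
}

NONPARAM_NAMES <- c("stride", "rates", "eps")
STAT_NAMES <- c("mean", "var")

walk_params <- function(p, fun, path = character()) {
  for (nm in names(p)) {
    el <- p[[nm]]
    if (is.list(el)) walk_params(el, fun, c(path, nm))
    else fun(c(path, nm), el)
  }
}

#' @export
count_parameters.carunet_model <- function(x) {
  tr <- 0; nt <- 0
  walk_params(x$params, function(path, el) {
    nm <- path[length(path)]
    if (nm %in% NONPARAM_NAMES) return()
    if (nm %in% STAT_NAMES) nt <<- nt + length(el)
    else tr <<- tr + length(el)
  })
  param_count_obj(tr + nt, tr)
}

# ---- calibration ------------------------------------------------------------

#' Calibrate channel widths to a parameter budget
#'
#' Searches a configuration grid for the architecture whose analytic total
#' parameter count falls inside `window`, returning the first hit in
#' lexicographic order (base width, bridge width, reduction ratio, spatial
#' divisor). The grid: base width 8..40 with a x2 encoder ladder, bridge
#' width from `8*base + 8` to `32*base` in steps of 8 and, for the proposed
#' model, reduction and spatial divisor in {4, 8, 16}. The shipped default
#' configurations are the calibrated ones.
#'
#' @param arch Architecture name.
#' @param window Integer interval `c(lo, hi)` of admissible total counts.
#' @param base_range Candidate base widths.
#' @return The calibrated [model_config()].
#' @export
calibrate_widths <- function(arch, window, base_range = 8:40) {
  check_that(length(window) == 2 && window[1] <= window[2],
             "window: need a non-empty interval c(lo, hi)")
  rd_grid <- if (arch == "proposed") c(4L, 8L, 16L) else 16L
  nearest <- NULL; nearest_dist <- Inf
  for (b in base_range) for (w5 in seq(8L * b + 8L, 32L * b, by = 8L))
    for (r in rd_grid) for (d in rd_grid) {
      cfg <- model_config(arch, widths = b * c(1L, 2L, 4L, 8L),
                          bottleneck = w5, reduction = r, spatial_divisor = d)
      tot <- param_count_analytic(cfg)$total
      if (tot >= window[1] && tot <= window[2]) return(cfg)
      dd <- min(abs(tot - window))
      if (dd < nearest_dist) { nearest_dist <- dd; nearest <- tot }
    }
  stop_config("calibrate_widths: no configuration inside [", window[1], ", ",
              window[2], "]; nearest achievable total is ", nearest)
}

# ---- building ---------------------------------------------------------------

#' Build a segmentation model
#'
#' Instantiates the architecture described by `config` with seeded Glorot-uniform
#' weight initialization (biases zero, batch-norm scale 1 / shift 0, running
#' statistics mean 0 / variance 1). Models with the same seed have identical
#' initial weights and produce identical outputs.
#'
#' @param config A [model_config()].
#' @param seed Initialization seed.
#' @return A `carunet_model` environment with fields `config` and `params`.
#' @export
build_model <- function(config, seed = 0) {
  if (!inherits(config, "carunet_model_config"))
    stop_config("config: expected a carunet_model_config")
  w <- config$widths
  w5 <- config$bottleneck
  cin0 <- config$in_channels
  k <- 0L
  nseed <- function() { k <<- k + 1L; derive_seed(seed, k) }
  conv_par <- function(kk, cin, cout) with_seed(nseed(), list(
    w = glorot_init(c(kk, kk, cin, cout)), b = rep(0, cout)))
  p <- list()
  if (config$arch == "unet") {
    cin <- cin0
    for (i in 1:4) {
      p[[paste0("enc", i)]] <- list(c1 = conv_par(3, cin, w[i]),
                                    c2 = conv_par(3, w[i], w[i]))
      cin <- w[i]
    }
    p$neck <- list(c1 = conv_par(3, w[4], w5), c2 = conv_par(3, w5, w5))
    up_in <- w5
    for (j in 4:1) {
      p[[paste0("dec", j)]] <- list(up = conv_par(2, up_in, w[j]),
                                    c1 = conv_par(3, 2 * w[j], w[j]),
                                    c2 = conv_par(3, w[j], w[j]))
      up_in <- w[j]
    }
  } else {
    prop <- config$arch == "proposed"
    gated <- config$arch %in% c("res_unet_attn", "proposed")
    if (prop) {
      p$stem <- stem_block_params(w[1], cin0, seed = nseed())
      p$stem_cbam <- cbam_params(w[1], config$reduction,
                                 config$spatial_divisor, seed = nseed())
    } else {
      p$entry <- residual_block_params(cin0, w[1], 1, seed = nseed())
    }
    cin <- w[1]
    lvl <- c(w[2], w[3], w[4], w5)
    for (i in 1:4) {
      p[[paste0("enc", i)]] <- residual_block_params(cin, lvl[i], 2,
                                                     seed = nseed())
      if (prop)
        p[[paste0("enc", i, "_cbam")]] <- cbam_params(lvl[i], config$reduction,
                                                      config$spatial_divisor,
                                                      seed = nseed())
      cin <- lvl[i]
    }
    if (prop) p$aspp <- aspp_params(w5, seed = nseed())
    else {
      p$neck1 <- residual_block_params(w5, w5, 1, seed = nseed())
      p$neck2 <- residual_block_params(w5, w5, 1, seed = nseed())
    }
    up_in <- w5
    for (j in 4:1) {
      nm <- paste0("dec", j)
      if (gated)
        p[[paste0(nm, "_gate")]] <- attention_gate_params(
          w[j], up_in, max(1L, w[j] %/% config$gate_divisor), seed = nseed())
      p[[nm]] <- list(up = conv_par(3, up_in, w[j]))
      p[[paste0(nm, "_rb")]] <- residual_block_params(2 * w[j], w[j], 1,
                                                      seed = nseed())
      if (prop)
        p[[paste0(nm, "_cbam")]] <- cbam_params(w[j], config$reduction,
                                                config$spatial_divisor,
                                                seed = nseed())
      up_in <- w[j]
    }
  }
  p$head <- conv_par(1, w[1], 1)
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- p
  class(model) <- "carunet_model"
  model
}

#' @export
print.carunet_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("carunet model '%s' (input %dx%d, widths %s | %d)\n",
              x$config$arch, x$config$input_size, x$config$input_size,
              paste(x$config$widths, collapse = "-"), x$config$bottleneck))
  print(pc)
  invisible(x)
}

# nested states mirroring the bn sublists of a parameter tree
make_states <- function(p) {
  if (!is.list(p)) return(NULL)
  if (all(c("gamma", "beta", "mean", "var") %in% names(p))) return(bn_state_env(p))
  out <- lapply(p, make_states)
  out[!vapply(out, is.null, TRUE)]
}

writeback_states <- function(p, st) {
  if (is.environment(st)) {
    p$mean <- st$mean
    p$var <- st$var
    return(p)
  }
  for (nm in names(st)) p[[nm]] <- writeback_states(p[[nm]], st[[nm]])
  p
}

forward_arch <- function(tp, x, nd, st, config, training) {
  slope <- config$slope
  if (config$arch == "unet") {
    act <- function(z) op_lrelu(tp, z, slope)
    skips <- list()
    cur <- x
    for (i in 1:4) {
      e <- nd[[paste0("enc", i)]]
      cur <- act(op_conv(tp, cur, e$c1$w, e$c1$b))
      cur <- act(op_conv(tp, cur, e$c2$w, e$c2$b))
      skips[[i]] <- cur
      cur <- op_maxpool2(tp, cur)
    }
    cur <- act(op_conv(tp, cur, nd$neck$c1$w, nd$neck$c1$b))
    cur <- act(op_conv(tp, cur, nd$neck$c2$w, nd$neck$c2$b))
    for (j in 4:1) {
      d <- nd[[paste0("dec", j)]]
      cur <- op_tconv2(tp, cur, d$up$w, d$up$b)
      cur <- op_concat(tp, skips[[j]], cur)
      cur <- act(op_conv(tp, cur, d$c1$w, d$c1$b))
      cur <- act(op_conv(tp, cur, d$c2$w, d$c2$b))
    }
  } else {
    prop <- config$arch == "proposed"
    gated <- config$arch %in% c("res_unet_attn", "proposed")
    if (prop) {
      cur <- fw_stem(tp, x, nd$stem, st$stem, training, slope)$out
      cur <- fw_cbam(tp, cur, nd$stem_cbam, slope)$out
    } else {
      cur <- fw_residual_block(tp, x, nd$entry, st$entry, training, slope)
    }
    skips <- list(cur)
    for (i in 1:4) {
      cur <- fw_residual_block(tp, cur, nd[[paste0("enc", i)]],
                               st[[paste0("enc", i)]], training, slope)
      if (prop) cur <- fw_cbam(tp, cur, nd[[paste0("enc", i, "_cbam")]], slope)$out
      if (i < 4) skips[[i + 1]] <- cur
    }
    cur <- if (prop) fw_aspp(tp, cur, nd$aspp, st$aspp, training)
    else {
      h <- fw_residual_block(tp, cur, nd$neck1, st$neck1, training, slope)
      fw_residual_block(tp, h, nd$neck2, st$neck2, training, slope)
    }
    for (j in 4:1) {
      nm <- paste0("dec", j)
      skip <- skips[[j]]
      if (gated)
        skip <- fw_attention_gate(tp, skip, cur, nd[[paste0(nm, "_gate")]],
                                  slope)$out
      cur <- op_upbilin2(tp, cur)
      cur <- op_conv(tp, cur, nd[[nm]]$up$w, nd[[nm]]$up$b)
      cur <- op_concat(tp, skip, cur)
      cur <- fw_residual_block(tp, cur, nd[[paste0(nm, "_rb")]],
                               st[[paste0(nm, "_rb")]], training, slope)
      if (prop) cur <- fw_cbam(tp, cur, nd[[paste0(nm, "_cbam")]], slope)$out
    }
  }
  op_sigmoid(tp, op_conv(tp, cur, nd$head$w, nd$head$b))
}

#' Run a model forward
#'
#' @param model A built `carunet_model`.
#' @param x Input: an `H x W` matrix, `H x W x 1` array or `H x W x 1 x N`
#'   batch with values in `[0, 1]`; H and W must equal the configured input
#'   size.
#' @param training If `TRUE`, batch statistics are used for normalization and
#'   the running statistics are updated.
#' @return Sigmoid probability maps with the same shape as `x`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  x <- as_t4(x)
  d <- dim(x)
  if (d[1] != model$config$input_size || d[2] != model$config$input_size ||
      d[3] != model$config$in_channels)
    stop_shape("model_forward: input must be ", model$config$input_size, "x",
               model$config$input_size, "x", model$config$in_channels)
  tp <- tape_new()
  nd <- lift(tp, model$params)
  st <- make_states(model$params)
  out <- forward_arch(tp, tn_leaf(tp, x), nd, st, model$config, training)
  if (training) model$params <- writeback_states(model$params, st)
  out$val
}

# forward returning the tape and output node; used by the trainer
model_forward_tape <- function(model, x, training = TRUE) {
  tp <- tape_new()
  nd <- lift(tp, model$params)
  st <- make_states(model$params)
  out <- forward_arch(tp, tn_leaf(tp, as_t4(x)), nd, st, model$config, training)
  list(tape = tp, out = out, nodes = nd, states = st)
}

#' Per-layer summary of a built model
#'
#' @param model A `carunet_model`.
#' @return A data frame with one row per top-level layer group: name and
#'   parameter count (trainable + non-trainable).
#' @export
model_summary <- function(model) {
  rows <- lapply(names(model$params), function(nm) {
    tr <- 0; nt <- 0
    walk_params(model$params[nm], function(path, el) {
      n2 <- path[length(path)]
      if (n2 %in% NONPARAM_NAMES) return()
      if (n2 %in% STAT_NAMES) nt <<- nt + length(el) else tr <<- tr + length(el)
    })
    data.frame(layer = nm, trainable = tr, nontrainable = nt)
  })
  out <- do.call(rbind, rows)
  out$total <- out$trainable + out$nontrainable
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the configuration and all
#' weight arrays (including batch-norm running statistics).
#'
#' @param model A `carunet_model`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `carunet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_config("checkpoint not found: ", path)
  obj <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$config <- structure(obj$config, class = "carunet_model_config")
  model$params <- obj$params
  class(model) <- "carunet_model"
  model
}

# deep copy of the weights (used for best-epoch checkpointing)
model_snapshot <- function(model) {
  list(config = model$config, params = model$params)
}

model_restore <- function(snap) {
  model <- new.env(parent = emptyenv())
  model$config <- snap$config
  model$params <- snap$params
  class(model) <- "carunet_model"
  model
}

#' Predict probability maps or binary masks
#'
#' @param object A `carunet_model`.
#' @param images A single image (matrix) or list of images, each matching the
#'   configured input size, values in `[0, 1]`.
#' @param type `"prob"` for sigmoid probability maps, `"mask"` for binary
#'   masks thresholded at `threshold`.
#' @param threshold Binarization threshold (default 0.5).
#' @param ... Unused.
#' @return A list of `H x W` matrices (probabilities or 0/1 masks).
#' @export
predict.carunet_model <- function(object, images, type = c("prob", "mask"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  if (!is.list(images)) images <- list(images)
  lapply(images, function(im) {
    m <- as.matrix(im)
    pr <- model_forward(object, m, training = FALSE)
    pr <- matrix(pr, nrow(m), ncol(m))
    if (type == "mask") (pr >= threshold) * 1 else pr
  })
}
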