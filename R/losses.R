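# The compound loss family: L_total = alpha * L_Dice + beta * L_BCE +
# gamma * L_Focal, with equal weights (1, 1, 1) across all published
# combinations; unused terms are zeroed.

check_pg <- function(P, G) {
  if (!identical(dim(P), dim(G)) || length(P) != length(G))
    stop_shape("P and G must share their shape")
  invisible(NULL)
}

#' Loss configuration
#'
#' @param alpha,beta,gamma Non-negative weights of the Dice, binary
#'   cross-entropy and focal terms; at least one must be positive. All
#'   published combinations use weight 1 on the enabled terms.
#' @param dice_epsilon Additive smoothing of the soft Dice ratio.
#' @param focal_gamma Focal focusing exponent (standard value 2).
#' @param focal_alpha Focal class-balance factor (standard value 0.25).
#' @param clip Probability clipping bound for the logarithmic terms.
#' @return A `carunet_loss_config` list.
#' @export
loss_config <- function(alpha = 1, beta = 1, gamma = 1, dice_epsilon = 1e-6,
                        focal_gamma = 2, focal_alpha = 0.25, clip = 1e-7) {
  check_that(alpha >= 0 && beta >= 0 && gamma >= 0,
             "alpha/beta/gamma: weights must be non-negative")
  check_that(alpha + beta + gamma > 0,
             "alpha/beta/gamma: at least one weight must be positive")
  check_that(dice_epsilon > 0, "dice_epsilon: must be positive")
  check_that(focal_gamma >= 0, "focal_gamma: must be non-negative")
  check_that(clip > 0 && clip < 0.5, "clip: must lie in (0, 0.5)")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 dice_epsilon = dice_epsilon, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, clip = clip),
            class = "carunet_loss_config")
}

# named loss combinations of the published grid
#' @rdname loss_config
#' @param name One of `"bce"`, `"dice"`, `"focal"`, `"bce+dice"`,
#'   `"bce+focal"`, `"dice+focal"`, `"bce+dice+focal"`.
#' @export
loss_config_by_name <- function(name) {
  parts <- strsplit(tolower(name), "+", fixed = TRUE)[[1]]
  known <- c("bce", "dice", "focal")
  check_that(length(parts) > 0 && all(parts %in% known),
             "name: unknown loss combination '", name, "'")
  loss_config(alpha = as.numeric("dice" %in% parts),
              beta = as.numeric("bce" %in% parts),
              gamma = as.numeric("focal" %in% parts))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(P*G) + eps) / (sum(P) + sum(G) + eps)`; 0 for a perfect
#' overlap and for the empty-empty case (epsilon convention), at most 1.
#'
#' @param P Probability map in `[0, 1]`.
#' @param G Binary ground-truth mask (same shape).
#' @param eps Smoothing epsilon.
#' @return A scalar in `[0, 1]`.
#' @export
dice_loss <- function(P, G, eps = 1e-6) {
  check_pg(P, G)
  1 - (2 * sum(P * G) + eps) / (sum(P) + sum(G) + eps)
}

#' Binary cross-entropy loss
#'
#' Pixel mean of `-(G log P' + (1-G) log(1-P'))` with `P'` clipped to
#' `[clip, 1-clip]`.
#'
#' @inheritParams dice_loss
#' @param clip Probability clipping bound.
#' @return A non-negative scalar.
#' @export
bce_loss <- function(P, G, clip = 1e-7) {
  check_pg(P, G)
  pc <- pmin(pmax(P, clip), 1 - clip)
  -mean(G * log(pc) + (1 - G) * log(1 - pc))
}

#' Focal loss
#'
#' Pixel mean of `-alpha_f (1 - p_t)^gamma_f log(p_t)` with `p_t = P` on
#' foreground and `1 - P` on background pixels. At `gamma_f = 0`,
#' `alpha_f = 1` it reduces exactly to the binary cross-entropy.
#'
#' @inheritParams bce_loss
#' @param focal_gamma Focusing exponent (>= 0).
#' @param focal_alpha Class-balance factor.
#' @return A non-negative scalar.
#' @export
focal_loss <- function(P, G, focal_gamma = 2, focal_alpha = 0.25,
                       clip = 1e-7) {
  check_pg(P, G)
  check_that(focal_gamma >= 0, "focal_gamma: must be non-negative")
  pt <- G * P + (1 - G) * (1 - P)
  pt <- pmin(pmax(pt, clip), 1 - clip)
  mean(-focal_alpha * (1 - pt)^focal_gamma * log(pt))
}

#' Compound loss
#'
#' Weighted sum `alpha * L_Dice + beta * L_BCE + gamma * L_Focal` of the
#' enabled components.
#'
#' @inheritParams dice_loss
#' @param cfg A [loss_config()].
#' @return A non-negative scalar.
#' @export
compound_loss <- function(P, G, cfg = loss_config()) {
  if (!inherits(cfg, "carunet_loss_config")) stop_config("cfg: expected a loss_config()")
  check_pg(P, G)
  out <- 0
  if (cfg$alpha > 0) out <- out + cfg$alpha * dice_loss(P, G, cfg$dice_epsilon)
  if (cfg$beta > 0) out <- out + cfg$beta * bce_loss(P, G, cfg$clip)
  if (cfg$gamma > 0) out <- out + cfg$gamma *
      focal_loss(P, G, cfg$focal_gamma, cfg$focal_alpha, cfg$clip)
  out
}

# tape-level compound loss used by the trainer
fw_compound_loss <- function(tp, p, g, cfg) {
  terms <- list(); ws <- numeric()
  if (cfg$alpha > 0) {
    terms <- c(terms, list(op_dice_loss(tp, p, g, cfg$dice_epsilon)))
    ws <- c(ws, cfg$alpha)
  }
  if (cfg$beta > 0) {
    terms <- c(terms, list(op_bce_loss(tp, p, g, cfg$clip)))
    ws <- c(ws, cfg$beta)
  }
  if (cfg$gamma > 0) {
    terms <- c(terms, list(op_focal_loss(tp, p, g, cfg$focal_gamma,
                                         cfg$focal_alpha, cfg$clip)))
    ws <- c(ws, cfg$gamma)
  }
  op_scalar_wsum(tp, terms, ws)
}
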