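# Minimal reverse-mode differentiation tape over dense R arrays.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; the tape records nodes in creation order, which is a
# topological order of the computation graph, so reverse iteration propagates
# gradients correctly. All tensor values are (H, W, C, N) arrays except the
# pooled (C, N) descriptors and scalar losses.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tn <- function(tp, val, parents = list(), bwd = NULL, leaf = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  nd$leaf <- leaf
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

tn_leaf <- function(tp, val) tn(tp, val, leaf = TRUE)

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tape_backward <- function(tp, out) {
  out$grad <- if (length(out$val) == 1) 1 else array(1, dim(out$val))
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd$grad)
  }
  invisible(NULL)
}

# ---- convolution ops --------------------------------------------------------

op_conv <- function(tp, x, w, b = NULL, stride = 1L, dil = 1L) {
  y <- .conv2d_fwd(x$val, w$val, stride, dil)
  if (!is.null(b)) {
    d <- dim(y)
    y <- y + bc_channel_vec(b$val, d[1], d[2])
  }
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  tn(tp, y, parents, function(g) {
    bw <- .conv2d_bwd(x$val, w$val, g, stride, dil)
    acc_grad(x, bw$dx)
    acc_grad(w, bw$dw)
    if (!is.null(b)) {
      d <- dim(g)
      acc_grad(b, reduce_hwn(g, d[1], d[2], d[3], d[4]))
    }
  })
}

op_dwconv <- function(tp, x, w, stride = 1L, dil = 1L) {
  y <- .dwconv2d_fwd(x$val, w$val, stride, dil)
  tn(tp, y, list(x, w), function(g) {
    bw <- .dwconv2d_bwd(x$val, w$val, g, stride, dil)
    acc_grad(x, bw$dx)
    acc_grad(w, bw$dw)
  })
}

op_tconv2 <- function(tp, x, w, b) {
  y <- .tconv2d_fwd(x$val, w$val)
  d <- dim(y)
  y <- y + bc_channel_vec(b$val, d[1], d[2])
  tn(tp, y, list(x, w, b), function(g) {
    bw <- .tconv2d_bwd(x$val, w$val, g)
    acc_grad(x, bw$dx)
    acc_grad(w, bw$dw)
    dg <- dim(g)
    acc_grad(b, reduce_hwn(g, dg[1], dg[2], dg[3], dg[4]))
  })
}

# ---- pooling / resampling ---------------------------------------------------

op_maxpool2 <- function(tp, x) {
  f <- .maxpool2_fwd(x$val)
  xd <- dim(x$val)
  tn(tp, f$y, list(x), function(g) acc_grad(x, .maxpool2_bwd(f$arg, g, xd)))
}

op_avgpool2 <- function(tp, x) {
  xd <- dim(x$val)
  tn(tp, .avgpool2_fwd(x$val), list(x),
     function(g) acc_grad(x, .avgpool2_bwd(g, xd)))
}

op_upnear2 <- function(tp, x) {
  xd <- dim(x$val)
  tn(tp, .upnear2_fwd(x$val), list(x),
     function(g) acc_grad(x, .upnear2_bwd(g, xd)))
}

op_upbilin2 <- function(tp, x) {
  xd <- dim(x$val)
  tn(tp, .upbilin2_fwd(x$val), list(x),
     function(g) acc_grad(x, .upbilin2_bwd(g, xd)))
}

# ---- batch normalization ----------------------------------------------------

# `state` is an environment with running `mean` and `var` (length C); in
# training mode the batch statistics (biased variance, as in common framework
# practice) normalize the map and the running statistics are updated in place.
# The running-statistics momentum is deliberately low: this trainer targets
# desk-scale regimens with few optimization steps per epoch, and the
# validation loss (computed with running statistics) must track the model
# within one plateau-patience window or the LR scheduler misfires.
op_bn <- function(tp, x, gamma, beta, state, training, momentum = 0.5,
                  eps = 1e-3) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  if (training) {
    mu <- reduce_hwn(x$val, H, W, C, N) / m
    v <- reduce_hwn(x$val^2, H, W, C, N) / m - mu^2
    v <- pmax(v, 0)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x$val - bc_channel_vec(mu, H, W)) * bc_channel_vec(inv, H, W)
  y <- bc_channel_vec(gamma$val, H, W) * xhat + bc_channel_vec(beta$val, H, W)
  dim(y) <- d
  tn(tp, y, list(x, gamma, beta), function(g) {
    acc_grad(gamma, reduce_hwn(g * xhat, H, W, C, N))
    acc_grad(beta, reduce_hwn(g, H, W, C, N))
    dxhat <- g * bc_channel_vec(gamma$val, H, W)
    if (training) {
      s1 <- reduce_hwn(dxhat, H, W, C, N)
      s2 <- reduce_hwn(dxhat * xhat, H, W, C, N)
      dx <- (dxhat - bc_channel_vec(s1 / m, H, W) -
               xhat * bc_channel_vec(s2 / m, H, W)) *
        bc_channel_vec(inv, H, W)
    } else {
      dx <- dxhat * bc_channel_vec(inv, H, W)
    }
    dim(dx) <- d
    acc_grad(x, dx)
  })
}

# ---- elementwise ops --------------------------------------------------------

op_lrelu <- function(tp, x, slope = 0.01) {
  pos <- x$val >= 0
  y <- ifelse(pos, x$val, slope * x$val)
  dim(y) <- dim(x$val)
  tn(tp, y, list(x), function(g) acc_grad(x, g * ifelse(pos, 1, slope)))
}

op_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$val))
  tn(tp, y, list(x), function(g) acc_grad(x, g * y * (1 - y)))
}

op_add <- function(tp, a, b) {
  tn(tp, a$val + b$val, list(a, b), function(g) {
    acc_grad(a, g)
    acc_grad(b, g)
  })
}

# x (H,W,C,N) * s (C,N), broadcast over space
op_mul_channel <- function(tp, x, s) {
  d <- dim(x$val)
  y <- x$val * bc_channel_mat(s$val, d[1], d[2])
  dim(y) <- d
  tn(tp, y, list(x, s), function(g) {
    dx <- g * bc_channel_mat(s$val, d[1], d[2])
    dim(dx) <- d
    acc_grad(x, dx)
    acc_grad(s, reduce_hw(g * x$val, d[1], d[2], d[3], d[4]))
  })
}

# x (H,W,C,N) * m (H,W,1,N), broadcast over channels
op_mul_spatial <- function(tp, x, m) {
  d <- dim(x$val)
  mb <- bc_spatial(m$val, d[3])
  y <- x$val * mb
  dim(y) <- d
  tn(tp, y, list(x, m), function(g) {
    dx <- g * mb
    dim(dx) <- d
    acc_grad(x, dx)
    acc_grad(m, reduce_channels(g * x$val, d[1], d[2], d[3], d[4]))
  })
}

# global average pooling -> (C, N)
op_gap <- function(tp, x) {
  d <- dim(x$val)
  tn(tp, reduce_hw(x$val, d[1], d[2], d[3], d[4]) / (d[1] * d[2]), list(x),
     function(g) {
       dx <- bc_channel_mat(g, d[1], d[2]) / (d[1] * d[2])
       dim(dx) <- d
       acc_grad(x, dx)
     })
}

# z (Cin, N), W (Cout, Cin), b (Cout) -> (Cout, N)
op_dense <- function(tp, z, w, b) {
  y <- w$val %*% z$val + b$val
  tn(tp, y, list(z, w, b), function(g) {
    acc_grad(z, t(w$val) %*% g)
    acc_grad(w, g %*% t(z$val))
    acc_grad(b, rowSums(g))
  })
}

# elementwise sigmoid on a (C, N) matrix
op_sigmoid_mat <- function(tp, x) op_sigmoid(tp, x)

op_lrelu_mat <- function(tp, x, slope = 0.01) op_lrelu(tp, x, slope)

op_concat <- function(tp, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$val
  y[, , da[3] + seq_len(db[3]), ] <- b$val
  tn(tp, y, list(a, b), function(g) {
    acc_grad(a, g[, , seq_len(da[3]), , drop = FALSE])
    acc_grad(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

op_add_list <- function(tp, xs) {
  out <- xs[[1]]
  for (i in seq_along(xs)[-1]) out <- op_add(tp, out, xs[[i]])
  out
}

# ---- loss ops (scalar outputs) ----------------------------------------------

op_dice_loss <- function(tp, p, g, eps = 1e-6) {
  gv <- g$val
  s1 <- sum(p$val * gv)
  s2 <- sum(p$val) + sum(gv)
  y <- 1 - (2 * s1 + eps) / (s2 + eps)
  tn(tp, y, list(p), function(gr) {
    dp <- -(2 * gv * (s2 + eps) - (2 * s1 + eps)) / (s2 + eps)^2
    dim(dp) <- dim(p$val)
    acc_grad(p, gr * dp)
  })
}

op_bce_loss <- function(tp, p, g, clip = 1e-7) {
  gv <- g$val
  pc <- pmin(pmax(p$val, clip), 1 - clip)
  n <- length(pc)
  y <- -mean(gv * log(pc) + (1 - gv) * log(1 - pc))
  inside <- p$val > clip & p$val < 1 - clip
  tn(tp, y, list(p), function(gr) {
    dp <- ifelse(inside, (-gv / pc + (1 - gv) / (1 - pc)) / n, 0)
    dim(dp) <- dim(p$val)
    acc_grad(p, gr * dp)
  })
}

op_focal_loss <- function(tp, p, g, gamma_f = 2, alpha_f = 0.25, clip = 1e-7) {
  gv <- g$val
  pt <- gv * p$val + (1 - gv) * (1 - p$val)
  ptc <- pmin(pmax(pt, clip), 1 - clip)
  n <- length(ptc)
  y <- mean(-alpha_f * (1 - ptc)^gamma_f * log(ptc))
  inside <- pt > clip & pt < 1 - clip
  tn(tp, y, list(p), function(gr) {
    dpt <- alpha_f * (gamma_f * (1 - ptc)^(pmax(gamma_f - 1, 0)) * log(ptc) -
                        (1 - ptc)^gamma_f / ptc) / n
    dp <- ifelse(inside, dpt * (2 * gv - 1), 0)
    dim(dp) <- dim(p$val)
    acc_grad(p, gr * dp)
  })
}

op_scalar_wsum <- function(tp, xs, ws) {
  y <- sum(vapply(seq_along(xs), function(i) ws[i] * xs[[i]]$val, 0))
  tn(tp, y, xs, function(g) {
    for (i in seq_along(xs)) acc_grad(xs[[i]], g * ws[i])
  })
}
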