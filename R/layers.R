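# Differentiable layer ops on (H, W, C) arrays.

ad_conv <- function(tape, x, w, b, k, pad) {
  y <- cpp_conv2d_forward(x$value, w$value, b$value, k, pad)
  ad_node(tape, y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    r <- cpp_conv2d_backward(x$value, w$value, g, k, pad)
    list(r$gx, r$gw, r$gb)
  })
}

ad_deform_conv <- function(tape, x, off, w, b) {
  y <- cpp_deform_conv_forward(x$value, off$value, w$value, b$value)
  ad_node(tape, y, list(x, off, w, b), function(g) {
    dim(g) <- dim(y)
    r <- cpp_deform_conv_backward(x$value, off$value, w$value, g)
    list(r$gx, r$goff, r$gw, r$gb)
  })
}

ad_maxpool2 <- function(tape, x) {
  d <- dim(x$value)
  r <- cpp_maxpool2_forward(x$value)
  ad_node(tape, r$y, list(x), function(g) {
    list(cpp_maxpool2_backward(g, r$idx, d[1], d[2], d[3]))
  })
}

ad_upsample <- function(tape, x, f) {
  d <- dim(x$value)
  y <- cpp_upsample_forward(x$value, as.integer(f))
  ad_node(tape, y, list(x), function(g) {
    dim(g) <- dim(y)
    list(cpp_upsample_backward(g, as.integer(f), d[1], d[2]))
  })
}

ad_relu <- function(tape, x) {
  m <- x$value > 0
  y <- x$value * m
  ad_node(tape, y, list(x), function(g) list(g * m))
}

ad_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  ad_node(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# channel concatenation
ad_concat <- function(tape, xs) {
  d <- dim(xs[[1]]$value)
  cs <- vapply(xs, function(x) dim(x$value)[3], 0)
  y <- array(0, c(d[1], d[2], sum(cs)))
  at <- 0L
  for (x in xs) {
    cc <- dim(x$value)[3]
    y[, , at + seq_len(cc)] <- x$value
    at <- at + cc
  }
  ad_node(tape, y, xs, function(g) {
    dim(g) <- dim(y)
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      cc <- cs[i]
      out[[i]] <- g[, , at + seq_len(cc), drop = FALSE]
      at <- at + cc
    }
    out
  })
}

# multiply feature map x (H,W,C) by a single-channel map alpha (H,W,1)
ad_scale_map <- function(tape, x, alpha) {
  a <- as.vector(alpha$value)
  d <- dim(x$value)
  y <- x$value * a   # recycles over channels (column-major: H*W fastest)
  ad_node(tape, y, list(x, alpha), function(g) {
    dim(g) <- d
    ga <- array(rowSums(matrix(g * x$value, prod(d[1:2]), d[3])),
                c(d[1], d[2], 1))
    list(g * a, ga)
  })
}

# Group normalization over (H, W, channels-in-group), affine per channel.
ad_groupnorm <- function(tape, x, gamma, beta, groups, eps = 1e-5) {
  C <- dim(x$value)[3]
  if (C %% groups != 0)
    abort_status("config", "channels not divisible by gn groups")
  y <- cpp_groupnorm_forward(x$value, gamma$value, beta$value,
                             as.integer(groups), eps)
  ad_node(tape, y, list(x, gamma, beta), function(g) {
    dim(g) <- dim(y)
    r <- cpp_groupnorm_backward(x$value, gamma$value, g,
                                as.integer(groups), eps)
    list(r$gx, r$ggamma, r$gbeta)
  })
}

# softmax over the channel dimension
ad_softmax <- function(tape, x) {
  d <- dim(x$value)
  m <- matrix(x$value, prod(d[1:2]), d[3])
  mx <- m[, 1]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, m[, c])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  y <- array(p, d)
  ad_node(tape, y, list(x), function(g) {
    dim(g) <- d
    gm <- matrix(g, prod(d[1:2]), d[3])
    dot <- rowSums(gm * p)
    list(array(p * (gm - dot), d))
  })
}

# Soft Dice loss over foreground channels: D = 1 - 2*sum(y*p)/sum(y + p),
# with y the one-hot truth and the background channel excluded.
ad_dice_loss <- function(tape, prob, onehot, fg_channels) {
  p <- prob$value[, , fg_channels, drop = FALSE]
  y <- onehot[, , fg_channels, drop = FALSE]
  inter <- sum(y * p)
  denom <- sum(y) + sum(p)
  val <- if (denom == 0) 0 else 1 - 2 * inter / denom
  ad_node(tape, val, list(prob), function(g) {
    gp <- array(0, dim(prob$value))
    if (denom > 0)
      gp[, , fg_channels] <- g * (-2) * (y * denom - inter) / denom^2
    list(gp)
  })
}

ad_wsum <- function(tape, wa, a, wb, b) {
  ad_node(tape, wa * a$value + wb * b$value, list(a, b),
          function(g) list(g * wa, g * wb))
}
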