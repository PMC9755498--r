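#' Network configuration for the dual-branch segmentation network
#'
#' The DBSN couples a shared five-block encoder with two decoders: a
#' full-resolution upper branch that produces the segmentation, and a
#' 1/16-resolution lower branch that supplies high-level shape semantics to
#' the upper branch through attention gates. Ablation flags reproduce the
#' reduced variants: \code{use_lower_branch = FALSE} drops the lower decoder
#' and the gates entirely (DBSN-LB), \code{use_attention_gates = FALSE} keeps
#' the lower decoder but fuses it by plain concatenation (DBSN-AG), and
#' \code{use_deformable = FALSE} replaces the deformable convolutions in the
#' upper path with ordinary 3x3 convolutions (DBSN-DC).
#'
#' @param in_channels input image channels (grayscale ultrasound: 1)
#' @param num_classes output classes: background, pubic symphysis, fetal head
#' @param base_channels width of the first encoder block; deeper blocks use
#'   2x, 4x, 8x, 16x this width
#' @param gn_groups group count for group normalization; must divide
#'   \code{base_channels}
#' @param use_lower_branch,use_attention_gates,use_deformable ablation flags
#' @param w_upper,w_lower collaborative-loss weights for the upper and lower
#'   branch Dice terms (defaults 1.0 and 0.2)
#' @return a \code{dbsn_config} list
#' @export
network_config <- function(in_channels = 1L, num_classes = 3L,
                           base_channels = 32L, gn_groups = NULL,
                           use_lower_branch = TRUE,
                           use_attention_gates = TRUE,
                           use_deformable = TRUE,
                           w_upper = 1.0, w_lower = 0.2) {
  if (is.null(gn_groups)) gn_groups <- min(8L, base_channels)
  if (base_channels %% gn_groups != 0)
    abort_status("config", "base_channels must be divisible by gn_groups")
  if (use_attention_gates && !use_lower_branch)
    abort_status("config", "attention gates require the lower branch")
  if (w_upper < 0 || w_lower < 0)
    abort_status("config", "loss weights must be non-negative")
  structure(list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    base_channels = as.integer(base_channels),
    gn_groups = as.integer(gn_groups),
    use_lower_branch = isTRUE(use_lower_branch),
    use_attention_gates = isTRUE(use_attention_gates),
    use_deformable = isTRUE(use_deformable),
    w_upper = w_upper, w_lower = w_lower
  ), class = "dbsn_config")
}

# fetch-or-create a parameter; creation only allowed while building
get_param <- function(net, name, shape, init = c("kaiming", "zero", "one")) {
  p <- net$params[[name]]
  if (!is.null(p)) return(p)
  if (!isTRUE(net$building))
    abort_status("config", paste("unknown parameter", name))
  init <- match.arg(init)
  v <- switch(init,
    kaiming = {
      fan_in <- prod(shape[-length(shape)])
      array(rnorm(prod(shape), 0, sqrt(2 / fan_in)), shape)
    },
    zero = array(0, shape),
    one = array(1, shape)
  )
  net$params[[name]] <- v
  v
}

pnode <- function(ctx, name, shape, init = "kaiming") {
  v <- get_param(ctx$net, name, shape, init)
  n <- ad_param(ctx$tape, v)
  ctx$pnodes[[name]] <- n
  n
}

gn_groups_for <- function(cfg, channels) min(cfg$gn_groups, channels)

conv_gn_relu <- function(ctx, x, name, cin, cout, k = 3L) {
  cfg <- ctx$net$cfg
  w <- pnode(ctx, paste0(name, ".w"), c(k, k, cin, cout))
  b <- pnode(ctx, paste0(name, ".b"), cout, "zero")
  y <- ad_conv(ctx$tape, x, w, b, k, if (k == 3L) 1L else 0L)
  ga <- pnode(ctx, paste0(name, ".gn.g"), cout, "one")
  be <- pnode(ctx, paste0(name, ".gn.b"), cout, "zero")
  ad_relu(ctx$tape, ad_groupnorm(ctx$tape, y, ga, be, gn_groups_for(cfg, cout)))
}

conv_block <- function(ctx, x, name, cin, cout) {
  h <- conv_gn_relu(ctx, x, paste0(name, ".c1"), cin, cout)
  conv_gn_relu(ctx, h, paste0(name, ".c2"), cout, cout)
}

conv1x1 <- function(ctx, x, name, cin, cout) {
  w <- pnode(ctx, paste0(name, ".w"), c(1L, 1L, cin, cout))
  b <- pnode(ctx, paste0(name, ".b"), cout, "zero")
  ad_conv(ctx$tape, x, w, b, 1L, 0L)
}

# upsample x2 then deformable (or plain) 3x3 conv + GN + ReLU: the in_upper
# path feeding each gated fusion
upper_path <- function(ctx, x, name, cin, cout) {
  cfg <- ctx$net$cfg
  up <- ad_upsample(ctx$tape, x, 2L)
  if (cfg$use_deformable) {
    ow <- pnode(ctx, paste0(name, ".off.w"), c(3L, 3L, cin, 18L), "zero")
    ob <- pnode(ctx, paste0(name, ".off.b"), 18L, "zero")
    off <- ad_conv(ctx$tape, up, ow, ob, 3L, 1L)
    w <- pnode(ctx, paste0(name, ".w"), c(3L, 3L, cin, cout))
    b <- pnode(ctx, paste0(name, ".b"), cout, "zero")
    y <- ad_deform_conv(ctx$tape, up, off, w, b)
    ga <- pnode(ctx, paste0(name, ".gn.g"), cout, "one")
    be <- pnode(ctx, paste0(name, ".gn.b"), cout, "zero")
    ad_relu(ctx$tape, ad_groupnorm(ctx$tape, y, ga, be,
                                   gn_groups_for(cfg, cout)))
  } else {
    conv_gn_relu(ctx, up, name, cin, cout)
  }
}

# additive attention gate: 1x1 projections of gating and signal to an
# intermediate width, ReLU, 1x1 to one channel, sigmoid, multiply onto signal
ag_gate <- function(ctx, gating, signal, name, channels) {
  fint <- max(channels %/% 2L, 1L)
  q <- conv1x1(ctx, gating, paste0(name, ".g"), channels, fint)
  r <- conv1x1(ctx, signal, paste0(name, ".x"), channels, fint)
  s <- ad_relu(ctx$tape, ad_add(ctx$tape, q, r))
  alpha <- ad_sigmoid(ctx$tape, conv1x1(ctx, s, paste0(name, ".psi"), fint, 1L))
  ad_scale_map(ctx$tape, signal, alpha)
}

dbsn_graph <- function(ctx, x) {
  cfg <- ctx$net$cfg
  b <- cfg$base_channels
  tape <- ctx$tape

  # shared encoder, skips taken pre-pool
  f1 <- conv_block(ctx, x, "enc1", cfg$in_channels, b)
  f2 <- conv_block(ctx, ad_maxpool2(tape, f1), "enc2", b, 2L * b)
  f3 <- conv_block(ctx, ad_maxpool2(tape, f2), "enc3", 2L * b, 4L * b)
  f4 <- conv_block(ctx, ad_maxpool2(tape, f3), "enc4", 4L * b, 8L * b)
  f5 <- conv_block(ctx, ad_maxpool2(tape, f4), "enc5", 8L * b, 16L * b)

  lower <- NULL
  if (cfg$use_lower_branch) {
    l1 <- conv_block(ctx, f5, "low1", 16L * b, 8L * b)
    l2 <- conv_block(ctx, l1, "low2", 8L * b, 4L * b)
    l3 <- conv_block(ctx, l2, "low3", 4L * b, 2L * b)
    l4 <- conv_block(ctx, l3, "low4", 2L * b, b)
    lower <- ad_softmax(tape, conv1x1(ctx, l4, "dl", b, cfg$num_classes))
  }

  # U1: encoder skip + processed 1/16-resolution signal (L1 when the lower
  # branch is active, the encoder bottleneck otherwise)
  if (cfg$use_lower_branch) {
    low_in <- conv_gn_relu(ctx, ad_upsample(tape, l1, 2L), "u1.low",
                           8L * b, 8L * b)
  } else {
    low_in <- conv_gn_relu(ctx, ad_upsample(tape, f5, 2L), "u1.bott",
                           16L * b, 8L * b)
  }
  u <- conv_block(ctx, ad_concat(tape, list(f4, low_in)), "up1", 16L * b, 8L * b)

  skips <- list(f3, f2, f1)
  lows <- if (cfg$use_lower_branch) list(l2, l3, l4) else NULL
  feat <- ctx$feat   # optional qualitative feature-map capture
  for (k in 2:4) {
    ck <- b * 2L^(4L - k)
    nm <- paste0("u", k)
    in_up <- upper_path(ctx, u, paste0(nm, ".up"), 2L * ck, ck)
    if (!is.null(feat)) {
      feat[[paste0(nm, ".in_encode")]] <- skips[[k - 1L]]$value
      feat[[paste0(nm, ".in_upper")]] <- in_up$value
    }
    if (cfg$use_lower_branch) {
      in_low <- conv_gn_relu(ctx,
        ad_upsample(tape, lows[[k - 1L]], 2L^k), paste0(nm, ".low"), ck, ck)
      fused <- if (cfg$use_attention_gates)
        ag_gate(ctx, in_up, in_low, paste0(nm, ".ag"), ck) else in_low
      if (!is.null(feat)) {
        feat[[paste0(nm, ".in_lower")]] <- in_low$value
        feat[[paste0(nm, ".in_ag")]] <- fused$value
      }
      cat_in <- ad_concat(tape, list(skips[[k - 1L]], in_up, fused))
      cin <- 3L * ck
    } else {
      cat_in <- ad_concat(tape, list(skips[[k - 1L]], in_up))
      cin <- 2L * ck
    }
    u <- conv_block(ctx, cat_in, paste0("up", k), cin, ck)
  }
  upper <- ad_softmax(tape, conv1x1(ctx, u, "du", b, cfg$num_classes))
  list(upper = upper, lower = lower)
}

#' Build a DBSN network
#'
#' Allocates and Kaiming-initializes all weights for the configured variant.
#' Initialization draws from the R random stream, so call \code{set.seed()}
#' first for reproducible weights.
#'
#' @param cfg a \code{\link{network_config}}
#' @return a \code{dbsn} object holding the configuration and parameters
#' @export
build_dbsn <- function(cfg) {
  stopifnot(inherits(cfg, "dbsn_config"))
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$params <- list()
  net$building <- TRUE
  x0 <- array(0, c(32L, 32L, cfg$in_channels))
  ctx <- list(net = net, tape = ad_tape(), pnodes = new.env())
  dbsn_graph(ctx, ad_param(ctx$tape, x0))
  net$building <- FALSE
  class(net) <- "dbsn"
  net
}

#' Forward pass of the DBSN
#'
#' @param net a \code{\link{build_dbsn}} network
#' @param image (H, W, C) array (or H x W matrix) with values in [-1, 1];
#'   H and W must be divisible by 16
#' @param with_tape keep the autodiff tape for a subsequent backward pass
#' @param debug also capture the decoder fusion inputs (in_encode, in_upper,
#'   in_lower, in_ag per level) for qualitative inspection
#' @return list with \code{upper} (H, W, num_classes probability array),
#'   \code{lower} (H/16, W/16, num_classes or NULL), when \code{debug} a
#'   named list \code{features}, and when \code{with_tape} the tape
#'   internals used by the trainer
#' @export
dbsn_forward <- function(net, image, with_tape = FALSE, debug = FALSE) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (d[1] %% 16L != 0 || d[2] %% 16L != 0)
    abort_status("shape", "input height and width must be divisible by 16")
  if (d[3] != net$cfg$in_channels) abort_status("shape", "channel mismatch")
  ctx <- list(net = net, tape = ad_tape(), pnodes = new.env(),
              feat = if (debug) new.env())
  out <- dbsn_graph(ctx, ad_param(ctx$tape, image))
  res <- list(upper = out$upper$value,
              lower = if (!is.null(out$lower)) out$lower$value else NULL)
  if (debug) res$features <- as.list(ctx$feat)
  if (with_tape) {
    res$nodes <- out
    res$tape <- ctx$tape
    res$pnodes <- ctx$pnodes
  }
  res
}

#' Write captured feature maps as PNG channel grids
#'
#' Qualitative debugging aid for the decoder fusion inputs captured with
#' \code{dbsn_forward(..., debug = TRUE)}: each feature map is tiled
#' channel-by-channel into one grayscale grid, min-max normalized.
#'
#' @param features named list of (H, W, C) arrays
#' @param dir output directory
#' @return written file paths, invisibly
#' @export
write_feature_grids <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(features), function(nm) {
    f <- features[[nm]]
    d <- dim(f)
    nc <- ceiling(sqrt(d[3]))
    nr <- ceiling(d[3] / nc)
    grid <- matrix(0, nr * d[1], nc * d[2])
    for (c in seq_len(d[3])) {
      i <- (c - 1) %/% nc
      j <- (c - 1) %% nc
      ch <- f[, , c]
      rng <- range(ch)
      if (diff(rng) > 0) ch <- (ch - rng[1]) / diff(rng)
      grid[i * d[1] + seq_len(d[1]), j * d[2] + seq_len(d[2])] <- ch
    }
    p <- file.path(dir, paste0(nm, ".png"))
    png::writePNG(grid, p)
    p
  }, "")
  invisible(paths)
}

#' Number of trainable parameters
#' @param net a \code{dbsn} network
#' @return integer parameter count
#' @export
count_parameters <- function(net) sum(vapply(net$params, length, 0L))

#' Apply an additive attention gate outside a network
#'
#' Exposes the gate used between the decoder branches as a standalone
#' operation: both inputs are projected by 1x1 convolutions to an
#' intermediate width, summed, passed through ReLU and a final 1x1
#' projection with sigmoid, and the resulting per-pixel weight in (0, 1)
#' multiplies the signal.
#'
#' @param gating (H, W, C) gating features (the upper-branch path)
#' @param signal (H, W, C) features to be re-weighted (the lower-branch path)
#' @param params list with 1x1 weights \code{wg, bg, wx, bx, wpsi, bpsi};
#'   randomly initialized when omitted
#' @return list with \code{output} (= signal * alpha) and \code{alpha}
#' @export
attention_gate <- function(gating, signal, params = NULL) {
  if (!identical(dim(gating), dim(signal)))
    abort_status("shape", "gating and signal shapes differ")
  C <- dim(signal)[3]
  fint <- max(C %/% 2L, 1L)
  if (is.null(params)) {
    params <- list(
      wg = array(rnorm(C * fint, 0, sqrt(2 / C)), c(1, 1, C, fint)),
      bg = rep(0, fint),
      wx = array(rnorm(C * fint, 0, sqrt(2 / C)), c(1, 1, C, fint)),
      bx = rep(0, fint),
      wpsi = array(rnorm(fint, 0, sqrt(2 / fint)), c(1, 1, fint, 1)),
      bpsi = 0
    )
  }
  q <- cpp_conv2d_forward(gating, params$wg, params$bg, 1L, 0L)
  r <- cpp_conv2d_forward(signal, params$wx, params$bx, 1L, 0L)
  s <- pmax(q + r, 0)
  a <- cpp_conv2d_forward(s, params$wpsi, params$bpsi, 1L, 0L)
  alpha <- 1 / (1 + exp(-a))
  list(output = signal * as.vector(alpha), alpha = alpha)
}

#' Soft Dice loss (background excluded)
#'
#' \code{1 - 2 * sum(y * p) / sum(y + p)} with the sums running over the
#' pubic-symphysis and fetal-head channels of the one-hot truth y and the
#' predicted probability map p.
#'
#' @param pred (H, W, num_classes) probability array
#' @param truth H x W integer label matrix (0 = background)
#' @return scalar in [0, 1]
#' @export
dice_loss <- function(pred, truth) {
  d <- dim(pred)
  if (!identical(d[1:2], dim(truth)))
    abort_status("shape", "prediction/truth shapes differ")
  fg <- 2:d[3]
  y <- onehot(truth, d[3])
  inter <- sum(y[, , fg] * pred[, , fg])
  denom <- sum(y[, , fg]) + sum(pred[, , fg])
  if (denom == 0) 0 else 1 - 2 * inter / denom
}

onehot <- function(truth, num_classes) {
  d <- dim(truth)
  y <- array(0, c(d, num_classes))
  for (c in seq_len(num_classes)) y[, , c] <- (truth == c - 1L) * 1
  y
}

#' Majority-vote label downsampling
#'
#' Reduces a label mask by an integer factor, assigning each cell the most
#' frequent class among its source pixels (ties go to the higher class index,
#' which favours the thin pubic symphysis over background).
#'
#' @param truth H x W integer label matrix
#' @param factor integer downsampling factor (16 for the lower branch)
#' @param num_classes number of classes
#' @return (H/factor) x (W/factor) integer label matrix
#' @export
downsample_labels <- function(truth, factor = 16L, num_classes = 3L) {
  d <- dim(truth)
  if (any(d %% factor != 0)) abort_status("shape", "dims not divisible")
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  counts <- array(0, c(h2, w2, num_classes))
  P <- matrix(0, h2, d[1]); P[cbind(rep(1:h2, each = factor), 1:d[1])] <- 1
  Q <- matrix(0, d[2], w2); Q[cbind(1:d[2], rep(1:w2, each = factor))] <- 1
  for (c in seq_len(num_classes))
    counts[, , c] <- P %*% ((truth == c - 1L) * 1) %*% Q
  # ties: higher class wins (max.col with ties.method = "last")
  cm <- matrix(counts, h2 * w2, num_classes)
  out <- matrix(max.col(cm, ties.method = "last") - 1L, h2, w2)
  storage.mode(out) <- "integer"
  out
}

#' Collaborative loss of the two decoder branches
#'
#' \code{w_upper * Dice(upper, truth) + w_lower * Dice(lower, truth16)} where
#' \code{truth16} is the ground truth downsampled 16x by per-cell majority
#' vote. Without the lower branch only the upper term is returned.
#'
#' @param out forward output (list with \code{upper} and \code{lower})
#' @param truth H x W integer label matrix at upper-branch resolution
#' @param cfg the \code{\link{network_config}} carrying the weights
#' @return scalar loss
#' @export
collaborative_loss <- function(out, truth, cfg) {
  du <- dice_loss(out$upper, truth)
  if (!cfg$use_lower_branch || is.null(out$lower)) return(cfg$w_upper * du)
  dl <- dice_loss(out$lower, downsample_labels(truth, 16L, cfg$num_classes))
  cfg$w_upper * du + cfg$w_lower * dl
}

#' Save / load network checkpoints
#'
#' A checkpoint stores the configuration and all weights; loading verifies
#' the stored configuration against \code{cfg} when supplied and fails on any
#' mismatch rather than silently partially loading.
#'
#' @param net a \code{dbsn} network
#' @param path file path
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param cfg optional \code{\link{network_config}} the checkpoint must match
#' @export
load_checkpoint <- function(path, cfg = NULL) {
  ck <- readRDS(path)
  if (!is.null(cfg) && !identical(unclass(cfg), unclass(ck$cfg)))
    abort_status("config", "checkpoint configuration mismatch")
  net <- new.env(parent = emptyenv())
  net$cfg <- ck$cfg
  net$params <- ck$params
  net$building <- FALSE
  class(net) <- "dbsn"
  net
}
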