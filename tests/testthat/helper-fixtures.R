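# Shared fixtures: exact ellipse samplers, brute-force oracles and small
# random masks, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# n points on an exact ellipse, uniform in parameter angle
ellipse_points <- function(center, a, b, theta, n = 100) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + a * cos(t) * cos(theta) - b * sin(t) * sin(theta),
        center[2] + a * cos(t) * sin(theta) + b * sin(t) * cos(theta))
}

random_ellipse <- function() {
  list(center = runif(2, 60, 400), a = runif(1, 60, 150),
       b = runif(1, 20, 55), theta = runif(1, 0, pi))
}

random_mask <- function(h, w, classes = 0:2) {
  matrix(sample(classes, h * w, replace = TRUE), h, w)
}

# brute-force tangent points: scan densely sampled boundary points for the
# extremes of the view angle from p, measured relative to the direction of
# the ellipse centre so the +-pi branch cut never splits the view cone
brute_tangents <- function(p, e, n = 720000) {
  pts <- ellipse_points(e$center, e$semi_major, e$semi_minor, e$theta, n)
  ang0 <- atan2(e$center[2] - p[2], e$center[1] - p[1])
  ang <- atan2(pts[, 2] - p[2], pts[, 1] - p[1])
  rel <- (ang - ang0 + pi) %% (2 * pi) - pi
  rbind(pts[which.min(rel), ], pts[which.max(rel), ])
}

# brute-force confusion counts by explicit per-pixel tally
brute_confusion <- function(pred, truth, class_id) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == class_id
      t_ <- truth[i, j] == class_id
      if (p && t_) tp <- tp + 1L
      else if (p) fp <- fp + 1L
      else if (t_) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# brute-force surface extraction + O(n^2) ASD in plain R
brute_surface <- function(mask, class_id) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!(mask[i, j] %in% class_id)) next
      nb_out <- i == 1 || i == h || j == 1 || j == w ||
        !(mask[i - 1, j] %in% class_id) || !(mask[i + 1, j] %in% class_id) ||
        !(mask[i, j - 1] %in% class_id) || !(mask[i, j + 1] %in% class_id)
      if (nb_out) out <- rbind(out, c(j - 1, i - 1))
    }
  }
  out
}

brute_asd <- function(a, b, class_id) {
  sa <- brute_surface(a, class_id)
  sb <- brute_surface(b, class_id)
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  d1 <- apply(sa, 1, function(p) min(sqrt((sb[, 1] - p[1])^2 +
                                          (sb[, 2] - p[2])^2)))
  d2 <- apply(sb, 1, function(p) min(sqrt((sa[, 1] - p[1])^2 +
                                          (sa[, 2] - p[2])^2)))
  (sum(d1) + sum(d2)) / (nrow(sa) + nrow(sb))
}

# central-difference gradient of f at x (arrays or vectors)
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

tiny_cfg <- function(...) network_config(base_channels = 4L, ...)
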