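# Preprocessing: deterministic resize/normalization plus stochastic
# rotation/flip augmentation applied consistently to the image, the label
# mask and any annotated key points.
#
# Affine maps are 2 x 3 matrices in (x, y) pixel-centre coordinates:
# (x', y') = L %*% (x, y) + t. Images are warped with the inverse map;
# key points are transformed with the forward map, so the two stay in
# exact correspondence.

PROC_HEIGHT <- 384L
PROC_WIDTH <- 512L

affine_identity <- function() cbind(diag(2), c(0, 0))

#' Affine building blocks for consistent image/key-point transforms
#'
#' \code{affine_rotation} rotates by \code{theta_deg} about \code{center}
#' (y-down coordinates), \code{affine_hflip} mirrors x on an image of width
#' \code{W}, \code{affine_compose} applies \code{b} then \code{a},
#' \code{affine_invert} inverts, and \code{affine_apply} maps an n x 2 matrix
#' of (x, y) points.
#'
#' @param theta_deg rotation angle in degrees
#' @param center rotation centre (x, y)
#' @name affine
#' @export
affine_rotation <- function(theta_deg, center) {
  th <- theta_deg * pi / 180
  L <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cbind(L, c(center[1], center[2]) - L %*% c(center[1], center[2]))
}

#' @rdname affine
#' @param W image width in pixels
#' @export
affine_hflip <- function(W) cbind(matrix(c(-1, 0, 0, 1), 2, 2), c(W - 1, 0))

#' @rdname affine
#' @param a,b affine maps (2 x 3)
#' @export
affine_compose <- function(a, b) {
  L <- a[, 1:2] %*% b[, 1:2]
  cbind(L, a[, 1:2] %*% b[, 3] + a[, 3])
}

#' @rdname affine
#' @export
affine_invert <- function(a) {
  Li <- solve(a[, 1:2])
  cbind(Li, -Li %*% a[, 3])
}

#' @rdname affine
#' @param pts n x 2 matrix of (x, y) points
#' @export
affine_apply <- function(a, pts) {
  pts <- matrix(pts, ncol = 2)
  t(a[, 1:2] %*% t(pts) + a[, 3])
}

warp_matrix <- function(img, forward, Ho, Wo, bilinear, fill,
                        clamp = FALSE) {
  inv <- affine_invert(forward)
  cpp_affine_warp(img, inv, as.integer(Ho), as.integer(Wo),
                  as.integer(bilinear), fill, as.integer(clamp))
}

resize_map <- function(H, W, Ho, Wo) {
  # forward map input -> output under half-pixel-centre scaling
  sx <- Wo / W; sy <- Ho / H
  cbind(matrix(c(sx, 0, 0, sy), 2, 2), c(sx * 0.5 - 0.5, sy * 0.5 - 0.5))
}

#' Resize an ultrasound frame to the processing grid and normalize
#'
#' Bilinear, anisotropic resize to \code{size} (default 384 x 512, the
#' 512 x 384 width-by-height processing resolution) followed by intensity
#' normalization v/127.5 - 1 into [-1, 1]. The acquisition aspect ratio
#' (1295:1026) differs from 4:3; the resize deliberately does not pad.
#'
#' @param image H x W numeric matrix of 8-bit intensities (0..255)
#' @param size target c(height, width)
#' @return normalized matrix of dimension \code{size}
#' @export
resize_normalize <- function(image, size = c(PROC_HEIGHT, PROC_WIDTH)) {
  if (length(image) == 0) abort_status("shape", "empty image")
  d <- dim(image)
  fwd <- resize_map(d[1], d[2], size[1], size[2])
  out <- warp_matrix(image, fwd, size[1], size[2], TRUE, 0, clamp = TRUE)
  out / 127.5 - 1
}

#' Resize a label mask (nearest neighbour)
#'
#' Labels are never interpolated; the label set can only shrink.
#' @param mask H x W integer label matrix
#' @param size target c(height, width)
#' @return resized integer label matrix
#' @export
resize_mask <- function(mask, size = c(PROC_HEIGHT, PROC_WIDTH)) {
  d <- dim(mask)
  if (identical(as.integer(d), as.integer(size))) return(mask)
  fwd <- resize_map(d[1], d[2], size[1], size[2])
  out <- warp_matrix(mask, fwd, size[1], size[2], FALSE, 0, clamp = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Scale annotated points with a resize
#' @param pts n x 2 (x, y) points on the source grid
#' @param from,to c(height, width) of source and target grids
#' @return points on the target grid
#' @export
resize_points <- function(pts, from, to = c(PROC_HEIGHT, PROC_WIDTH)) {
  affine_apply(resize_map(from[1], from[2], to[1], to[2]), pts)
}

#' Augmentation specification
#'
#' @param rotation_range_deg rotation interval in degrees (default [-30, 30])
#' @param hflip_prob probability of a horizontal flip (default 0.5)
#' @param seed optional integer; when set, \code{\link{augment}} uses it to
#'   derive its random draws
#' @return an \code{aug_spec} list
#' @export
augmentation_spec <- function(rotation_range_deg = c(-30, 30),
                              hflip_prob = 0.5, seed = NULL) {
  if (any(abs(rotation_range_deg) > 180) ||
      rotation_range_deg[1] > rotation_range_deg[2])
    abort_status("config", "invalid rotation range")
  if (hflip_prob < 0 || hflip_prob > 1)
    abort_status("config", "hflip_prob must be in [0, 1]")
  structure(list(rotation_range_deg = rotation_range_deg,
                 hflip_prob = hflip_prob, seed = seed), class = "aug_spec")
}

#' Random rotation + flip augmentation
#'
#' Draws one rotation angle uniformly from the configured range and one flip
#' decision, and applies the identical affine map to the image (bilinear,
#' fill -1), the mask (nearest, fill 0) and the key points (exact). The
#' rotation is about the image centre.
#'
#' @param image normalized H x W matrix
#' @param mask H x W integer label matrix
#' @param keypoints optional n x 2 (x, y) matrix
#' @param spec an \code{\link{augmentation_spec}}
#' @param theta_deg,flip override the random draws (used by tests)
#' @return list with image, mask, keypoints, theta_deg, flip
#' @export
augment <- function(image, mask = NULL, keypoints = NULL,
                    spec = augmentation_spec(),
                    theta_deg = NULL, flip = NULL) {
  draw <- function() {
    list(theta = runif(1, spec$rotation_range_deg[1],
                       spec$rotation_range_deg[2]),
         flip = runif(1) < spec$hflip_prob)
  }
  if (is.null(theta_deg) || is.null(flip)) {
    rd <- if (!is.null(spec$seed)) with_seed(spec$seed, draw()) else draw()
    if (is.null(theta_deg)) theta_deg <- rd$theta
    if (is.null(flip)) flip <- rd$flip
  }
  d <- dim(image)
  ctr <- c((d[2] - 1) / 2, (d[1] - 1) / 2)
  fwd <- affine_rotation(theta_deg, ctr)
  if (flip) fwd <- affine_compose(affine_hflip(d[2]), fwd)
  out <- list(
    image = warp_matrix(image, fwd, d[1], d[2], TRUE, -1),
    mask = if (!is.null(mask)) {
      m <- warp_matrix(mask, fwd, d[1], d[2], FALSE, 0)
      storage.mode(m) <- "integer"
      m
    },
    keypoints = if (!is.null(keypoints)) affine_apply(fwd, keypoints),
    theta_deg = theta_deg, flip = flip
  )
  out
}
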