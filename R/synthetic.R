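# Ultrasound-like phantom generator. Each phantom holds two bright
# ellipse-like targets -- a small filled pubic symphysis and a large
# fetal-head rim with darker interior -- inside a fan-shaped speckled field.
# Masks rasterize the exact generating ellipses and the reference key points
# and angle are computed analytically from the exact parameters, so the
# generator doubles as an independent oracle for the whole pipeline.

ellipse_quadform <- function(cx, cy, a, b, theta, x, y) {
  ct <- cos(theta); st <- sin(theta)
  xr <- (x - cx) * ct + (y - cy) * st
  yr <- -(x - cx) * st + (y - cy) * ct
  (xr / a)^2 + (yr / b)^2
}

ellipse_bbox_half <- function(a, b, theta) {
  c(sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

#' Phantom specification
#'
#' Samples a random but anatomically plausible layout: the pubic symphysis
#' (PS) up-left with its long axis pointing down toward the fetal head (FH),
#' the FH a large ellipse lower-right, both inside the ultrasound fan.
#' Rejection sampling enforces the invariants (structures inside the frame
#' and fan, disjoint interiors, the inferior PS endpoint strictly outside
#' the FH, analytic angle of progression within [60, 170] degrees). Sizes
#' other than the default 512 x 384 (width x height) scale the whole layout
#' proportionally.
#'
#' @param seed integer seed; the spec and the phantom drawn from it are a
#'   deterministic function of it
#' @param height,width image size in pixels
#' @param speckle_sigma sigma of the half-normal speckle (image units, 0..1)
#' @param blur_sigma Gaussian point-spread sigma in pixels
#' @param fan_angle_deg full opening angle of the imaging fan
#' @param max_retries rejection-sampling cap
#' @return a \code{phantom_spec} list with the exact ellipse parameters
#' @export
phantom_spec <- function(seed, height = 384L, width = 512L,
                         speckle_sigma = 0.10, blur_sigma = 1.5,
                         fan_angle_deg = 110, max_retries = 1000L) {
  sc <- width / 512
  apex <- c(width / 2, -0.18 * height)
  half_fan <- fan_angle_deg / 2 * pi / 180

  in_fan <- function(px, py) {
    ang <- abs(atan2(px - apex[1], py - apex[2]))   # from the down axis
    ang <= half_fan
  }

  draw_layout <- function() {
    # PS up-left, long axis pointing down-rightward; the FH is placed
    # relative to the inferior PS endpoint at a polar angle phi from the
    # PS axis direction, which spreads the resulting angle of progression
    # across its clinical range (head high -> small AoP, engaged -> large)
    ps_a <- runif(1, 25, 45) * sc
    ps_b <- runif(1, 8, 16) * sc
    ps_th <- runif(1, -10, 70) * pi / 180
    ps_cx <- runif(1, 95, 215) * sc
    ps_cy <- runif(1, 95, 185) * sc
    high_head <- runif(1) < 0.3
    if (high_head) {
      # head still high in the pelvis: FH far from the PS, nearly abeam of
      # the axis, giving the small end of the attainable AoP range
      ps_cx <- runif(1, 230, 390) * sc
      ps_cy <- runif(1, 90, 140) * sc
      phi <- runif(1, 60, 100) * pi / 180
      d <- runif(1, 180, 290) * sc
      fh_a <- runif(1, 90, 112) * sc
      fh_b <- runif(1, 70 * sc, min(88 * sc, fh_a - 5 * sc))
    } else {
      phi <- runif(1, -40, 100) * pi / 180
      d <- runif(1, 125, 235) * sc
      fh_a <- runif(1, 90, 150) * sc
      fh_b <- runif(1, 70 * sc, min(120 * sc, fh_a - 5 * sc))
    }
    dir_ps <- c(cos(ps_th), sin(ps_th))
    lp <- c(ps_cx, ps_cy) + ps_a * dir_ps
    ca <- cos(phi); sa <- sin(phi)
    fdir <- c(ca * dir_ps[1] - sa * dir_ps[2], sa * dir_ps[1] + ca * dir_ps[2])
    fh_th <- runif(1, 0, pi)
    list(ps = list(cx = ps_cx, cy = ps_cy, a = ps_a, b = ps_b, th = ps_th),
         fh = list(cx = lp[1] + d * fdir[1], cy = lp[2] + d * fdir[2],
                   a = fh_a, b = fh_b, th = fh_th))
  }

  layout_ok <- function(L) {
    m <- 6 * sc
    bb <- ellipse_bbox_half(L$fh$a, L$fh$b, L$fh$th)
    if (L$fh$cx - bb[1] < m || L$fh$cx + bb[1] > width - m ||
        L$fh$cy - bb[2] < m || L$fh$cy + bb[2] > height - m) return(NULL)
    bp <- ellipse_bbox_half(L$ps$a, L$ps$b, L$ps$th)
    if (L$ps$cx - bp[1] < m || L$ps$cx + bp[1] > width - m ||
        L$ps$cy - bp[2] < m || L$ps$cy + bp[2] > height - m) return(NULL)
    # fan must cover both structures
    cor <- rbind(
      c(L$fh$cx - bb[1], L$fh$cy - bb[2]), c(L$fh$cx + bb[1], L$fh$cy - bb[2]),
      c(L$fh$cx - bb[1], L$fh$cy + bb[2]), c(L$fh$cx + bb[1], L$fh$cy + bb[2]),
      c(L$ps$cx - bp[1], L$ps$cy - bp[2]), c(L$ps$cx + bp[1], L$ps$cy - bp[2]),
      c(L$ps$cx - bp[1], L$ps$cy + bp[2]), c(L$ps$cx + bp[1], L$ps$cy + bp[2]))
    if (!all(in_fan(cor[, 1], cor[, 2]))) return(NULL)
    # disjoint interiors: PS boundary samples all outside FH and vice versa
    tt <- seq(0, 2 * pi, length.out = 181L)[-181L]
    psx <- L$ps$cx + L$ps$a * cos(tt) * cos(L$ps$th) -
      L$ps$b * sin(tt) * sin(L$ps$th)
    psy <- L$ps$cy + L$ps$a * cos(tt) * sin(L$ps$th) +
      L$ps$b * sin(tt) * cos(L$ps$th)
    qf <- ellipse_quadform(L$fh$cx, L$fh$cy, L$fh$a, L$fh$b, L$fh$th, psx, psy)
    if (min(qf) <= 1.02) return(NULL)
    if (ellipse_quadform(L$ps$cx, L$ps$cy, L$ps$a, L$ps$b, L$ps$th,
                         L$fh$cx, L$fh$cy) <= 1) return(NULL)
    # analytic key points and angle
    ps_e <- list(center = c(L$ps$cx, L$ps$cy), semi_major = L$ps$a,
                 semi_minor = L$ps$b, theta = L$ps$th %% pi)
    fh_e <- list(center = c(L$fh$cx, L$fh$cy), semi_major = L$fh$a,
                 semi_minor = L$fh$b, theta = L$fh$th %% pi)
    ep <- major_axis_endpoints(ps_e)
    lab <- label_endpoints(ep[1, ], ep[2, ], fh_e$center)
    if (ellipse_quadform(L$fh$cx, L$fh$cy, L$fh$a, L$fh$b, L$fh$th,
                         lab$Lp[1], lab$Lp[2]) < 1.05^2) return(NULL)
    tp <- tryCatch(tangent_points(lab$Lp, fh_e),
                   aopseg_error = function(e) NULL)
    if (is.null(tp)) return(NULL)
    Tp <- select_tangent(lab$Up, lab$Lp, tp[1, ], tp[2, ])
    aop <- compute_aop(lab$Up, lab$Lp, Tp)
    if (aop < 60 || aop > 170) return(NULL)
    list(layout = L, Up = lab$Up, Lp = lab$Lp, Tp = Tp, aop = aop)
  }

  res <- with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_retries)) {
      found <- layout_ok(draw_layout())
      if (!is.null(found)) break
    }
    if (is.null(found)) abort_status("config", "unsatisfiable phantom spec")
    found$noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
    found
  })

  structure(list(
    seed = as.integer(seed), height = as.integer(height),
    width = as.integer(width),
    ps = res$layout$ps, fh = res$layout$fh,
    speckle_sigma = speckle_sigma, blur_sigma = blur_sigma,
    fan_angle_deg = fan_angle_deg, apex = apex,
    noise_seed = res$noise_seed,
    gt_keypoints = list(Up = res$Up, Lp = res$Lp, Tp = res$Tp),
    gt_aop_deg = res$aop
  ), class = "phantom_spec")
}

gaussian_kernel2d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Render a phantom sample from its specification
#'
#' The mask rasterizes the exact ellipse interiors on pixel centres
#' (0 background, 1 PS, 2 FH). The image places a bright filled PS blob and
#' a bright FH rim with darker interior on half-normal speckle inside the
#' fan, blurs with a Gaussian point-spread and renormalizes to [-1, 1].
#' Reference key points and the reference angle come from the exact
#' (non-rasterized) parameters.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @return a \code{synthetic_sample}: image, mask, gt_keypoints
#'   (Up, Lp, Tp), gt_aop_deg, spec, patient_id
#' @export
generate_sample <- function(spec) {
  H <- spec$height; W <- spec$width
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), W), H, W)

  q_ps <- ellipse_quadform(spec$ps$cx, spec$ps$cy, spec$ps$a, spec$ps$b,
                           spec$ps$th, x, y)
  q_fh <- ellipse_quadform(spec$fh$cx, spec$fh$cy, spec$fh$a, spec$fh$b,
                           spec$fh$th, x, y)
  mask <- matrix(0L, H, W)
  mask[q_fh <= 1] <- CLASS_FH
  mask[q_ps <= 1] <- CLASS_PS

  sc <- W / 512
  rim_px <- 6 * sc
  half_fan <- spec$fan_angle_deg / 2 * pi / 180
  fan <- abs(atan2(x - spec$apex[1], y - spec$apex[2])) <= half_fan

  img <- with_seed(spec$noise_seed, {
    base <- 0.28 + abs(matrix(rnorm(H * W, 0, spec$speckle_sigma), H, W))
    r_fh <- sqrt(q_fh)
    rim_lo <- 1 - rim_px / spec$fh$b
    base[r_fh <= 1] <- 0.12
    base[r_fh <= 1 & r_fh >= rim_lo] <- 0.88
    base[q_ps <= 1] <- 0.95
    base * fan
  })
  k <- gaussian_kernel2d(spec$blur_sigma)
  dim(img) <- c(H, W, 1L)
  dim(k) <- c(dim(k), 1L, 1L)
  img <- cpp_conv2d_forward(img, k, 0, nrow(k), (dim(k)[1] - 1L) %/% 2L)
  img <- pmin(pmax(matrix(img, H, W), 0), 1) * 2 - 1

  structure(list(image = img, mask = mask,
                 gt_keypoints = spec$gt_keypoints,
                 gt_aop_deg = spec$gt_aop_deg,
                 spec = spec, patient_id = NA_character_),
            class = "synthetic_sample")
}

#' Generate a phantom dataset
#'
#' Per-sample seeds derive deterministically from \code{base_seed}; samples
#' are assigned round-robin to synthetic patients, mimicking datasets where
#' each patient contributes several frames.
#'
#' @param n number of samples
#' @param base_seed integer seed for the whole dataset
#' @param patients number of synthetic patient identifiers
#' @param ... passed to \code{\link{phantom_spec}} (e.g. height/width)
#' @return list of \code{synthetic_sample} objects
#' @export
generate_dataset <- function(n, base_seed = 0L, patients = max(1L, n %/% 4L),
                             ...) {
  if (n == 0) return(list())
  seeds <- with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    s <- generate_sample(phantom_spec(seeds[i], ...))
    s$patient_id <- sprintf("pat%03d", ((i - 1L) %% patients) + 1L)
    s$image_id <- sprintf("img%04d", i)
    s
  })
}

#' Write a phantom dataset to disk
#'
#' Writes \code{images/<id>.png} (8-bit grayscale), \code{masks/<id>.png}
#' (labels 0/1/2) and \code{manifest.csv} with the reference endpoints,
#' tangent point, angle and generating parameters.
#'
#' @param samples list of \code{synthetic_sample}
#' @param dir output directory
#' @return the manifest data frame, invisibly
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    id <- s$image_id
    write_image_png(s$image, file.path(dir, "images", paste0(id, ".png")))
    write_mask_png(s$mask, file.path(dir, "masks", paste0(id, ".png")))
    k <- s$gt_keypoints
    data.frame(image_id = id, patient_id = s$patient_id,
               Ut_x = k$Up[1], Ut_y = k$Up[2], Lt_x = k$Lp[1],
               Lt_y = k$Lp[2], Tp_x = k$Tp[1], Tp_y = k$Tp[2],
               aop_deg = s$gt_aop_deg,
               ps_cx = s$spec$ps$cx, ps_cy = s$spec$ps$cy,
               ps_a = s$spec$ps$a, ps_b = s$spec$ps$b,
               ps_theta = s$spec$ps$th,
               fh_cx = s$spec$fh$cx, fh_cy = s$spec$fh$cy,
               fh_a = s$spec$fh$a, fh_b = s$spec$fh$b,
               fh_theta = s$spec$fh$th,
               seed = s$spec$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
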