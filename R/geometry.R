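# Ellipse fitting and angle-of-progression geometry.
#
# Conventions: 0-based pixel coordinates, x rightward, y downward, all
# geometry on pixel centres. A conic a = (A, B, C, D, E, F) represents
# A x^2 + B xy + C y^2 + D x + E y + F = 0 and is always normalized so that
# 4AC - B^2 = 1 with A > 0, which makes the interior the F(a, p) < 0 side.

#' Conic value at points
#' @param conic length-6 coefficient vector (A, B, C, D, E, F)
#' @param x,y coordinates (vectorized)
#' @return conic polynomial values; negative inside the ellipse
#' @export
conic_value <- function(conic, x, y) {
  conic[1] * x^2 + conic[2] * x * y + conic[3] * y^2 +
    conic[4] * x + conic[5] * y + conic[6]
}

normalize_conic <- function(a) {
  disc <- 4 * a[1] * a[3] - a[2]^2
  if (!is.finite(disc) || disc <= 0)
    abort_status("fit_failed", "conic is not an ellipse")
  a <- a / sqrt(disc)
  if (a[1] < 0) a <- -a
  names(a) <- c("A", "B", "C", "D", "E", "F")
  a
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic minimizing the algebraic residual sum under the quadratic
#' constraint \code{4AC - B^2 = 1}, which guarantees an ellipse (the
#' generalized-eigenproblem formulation of Fitzgibbon, in the numerically
#' stable split form of Halir & Flusser). Points are centred and scaled
#' before fitting for conditioning; returned coefficients refer to the input
#' frame and satisfy the constraint.
#'
#' @param points n x 2 matrix (or data.frame) of (x, y) with n >= 5
#' @return named length-6 coefficient vector (A, B, C, D, E, F)
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5) abort_status("fit_failed", "need at least 5 points")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  s <- sqrt(mean((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  if (!is.finite(s) || s < 1e-12)
    abort_status("fit_failed", "degenerate point scatter")
  u <- (pts[, 1] - mx) / s
  v <- (pts[, 2] - my) / s

  d1 <- cbind(u^2, u * v, v^2)
  d2 <- cbind(u, v, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t_ <- tryCatch(-solve(s3, t(s2)), error = function(e)
    abort_status("fit_failed", "singular linear block (collinear points?)"))
  m <- s1 + s2 %*% t_
  # premultiply by inv(C1), C1 the 4AC - B^2 constraint block
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  eg <- eigen(m)
  ev <- Re(eg$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  ok <- which(cond > 1e-12 & abs(Im(eg$values)) < 1e-8)
  if (length(ok) == 0) abort_status("fit_failed", "no ellipse solution")
  a1 <- ev[, ok[1]]
  a <- c(a1, as.vector(t_ %*% a1))

  # undo the normalization: conic matrix transforms as Q = T' Q' T with
  # (u, v, 1)' = T (x, y, 1)'
  q <- matrix(c(a[1], a[2] / 2, a[4] / 2,
                a[2] / 2, a[3], a[5] / 2,
                a[4] / 2, a[5] / 2, a[6]), 3, 3)
  tr <- matrix(c(1 / s, 0, 0, 0, 1 / s, 0, -mx / s, -my / s, 1), 3, 3)
  q <- t(tr) %*% q %*% tr
  normalize_conic(c(q[1, 1], 2 * q[1, 2], q[2, 2], 2 * q[1, 3], 2 * q[2, 3],
                    q[3, 3]))
}

#' Convert a conic to geometric ellipse parameters
#'
#' @param conic normalized conic coefficients (see \code{\link{fit_ellipse}})
#' @return list with \code{center} (x, y), \code{semi_major},
#'   \code{semi_minor} and \code{theta}, the major-axis orientation in
#'   radians within [0, pi). A circle (axes equal within 1e-9 relative) is
#'   reported with \code{theta = 0}.
#' @export
conic_to_geometric <- function(conic) {
  a <- conic
  disc <- 4 * a[1] * a[3] - a[2]^2
  if (!is.finite(disc) || disc <= 0)
    abort_status("fit_failed", "degenerate conic")
  if (a[1] < 0) a <- -a
  ctr <- solve(matrix(c(2 * a[1], a[2], a[2], 2 * a[3]), 2, 2), -a[4:5])
  fc <- conic_value(a, ctr[1], ctr[2])
  if (fc >= 0) abort_status("fit_failed", "degenerate conic (no interior)")
  m0 <- matrix(c(a[1], a[2] / 2, a[2] / 2, a[3]), 2, 2)
  eg <- eigen(m0, symmetric = TRUE)   # eigenvalues decreasing, both > 0
  ax <- sqrt(-fc / eg$values)         # increasing axis lengths
  semi_major <- ax[2]; semi_minor <- ax[1]
  if (abs(semi_major - semi_minor) <= 1e-9 * semi_major) {
    theta <- 0
  } else {
    v <- eg$vectors[, 2]              # eigenvector of the smaller eigenvalue
    theta <- atan2(v[2], v[1]) %% pi
    if (theta >= pi) theta <- 0
  }
  list(center = c(x = unname(ctr[1]), y = unname(ctr[2])),
       semi_major = unname(semi_major), semi_minor = unname(semi_minor),
       theta = unname(theta))
}

#' Geometric ellipse parameters to a normalized conic
#' @param center centre (x, y)
#' @param semi_major,semi_minor axis lengths (pixels)
#' @param theta major-axis orientation, radians
#' @return normalized conic coefficients
#' @export
geometric_to_conic <- function(center, semi_major, semi_minor, theta) {
  ct <- cos(theta); st <- sin(theta)
  ia <- 1 / semi_major^2; ib <- 1 / semi_minor^2
  A <- ct^2 * ia + st^2 * ib
  B <- 2 * ct * st * (ia - ib)
  C <- st^2 * ia + ct^2 * ib
  # shift to the requested centre
  x0 <- center[1]; y0 <- center[2]
  D <- -2 * A * x0 - B * y0
  E <- -B * x0 - 2 * C * y0
  F_ <- A * x0^2 + B * x0 * y0 + C * y0^2 - 1
  normalize_conic(c(A, B, C, D, E, F_))
}

#' Boundary points of the largest component of a class
#'
#' Extracts pixel centres of the boundary of the largest 8-connected
#' component of \code{class_id}: pixels of the component with at least one
#' 4-neighbour outside it (the image border counts as outside). Smaller
#' islands -- typically spurious network output -- are ignored.
#'
#' @param mask H x W integer label matrix
#' @param class_id class label to trace
#' @return n x 2 matrix of 0-based (x, y) boundary pixel centres
#' @export
mask_to_boundary <- function(mask, class_id) {
  m <- mask
  storage.mode(m) <- "integer"
  cc <- cpp_class_components(m, as.integer(class_id))
  if (length(cc$sizes) == 0)
    abort_status("empty_class", paste("no pixels of class", class_id))
  lab <- which.max(cc$sizes)
  pts <- cpp_boundary_points((cc$labels == lab) * 1L)
  colnames(pts) <- c("x", "y")
  pts
}

#' Major-axis endpoints of an ellipse
#' @param e geometric ellipse (list as from \code{\link{conic_to_geometric}})
#' @return 2 x 2 matrix, rows are the endpoints (x, y)
#' @export
major_axis_endpoints <- function(e) {
  d <- e$semi_major * c(cos(e$theta), sin(e$theta))
  rbind(e$center - d, e$center + d)
}

#' Label PS endpoints as superior (Up) and inferior (Lp)
#'
#' The inferior endpoint is the one nearer the fetal-head centre (the
#' inferior pubic-symphysis end abuts the descending head); ties are broken
#' toward larger x, then larger y.
#'
#' @param p1,p2 endpoints (x, y)
#' @param fh_center fetal-head ellipse centre (x, y)
#' @return list with \code{Up} and \code{Lp}
#' @export
label_endpoints <- function(p1, p2, fh_center) {
  d1 <- sum((p1 - fh_center)^2)
  d2 <- sum((p2 - fh_center)^2)
  pick2 <- if (d2 < d1) TRUE else if (d1 < d2) FALSE
  else if (p2[1] != p1[1]) p2[1] > p1[1] else p2[2] > p1[2]
  if (pick2) list(Up = p1, Lp = p2) else list(Up = p2, Lp = p1)
}

#' Tangent points from an external point to an ellipse
#'
#' Intersects the polar line of \code{p} with the conic: the two solutions
#' are exactly the points where lines through \code{p} touch the ellipse.
#'
#' @param p external point (x, y)
#' @param e geometric ellipse
#' @return 2 x 2 matrix, rows are the tangent points (x, y)
#' @export
tangent_points <- function(p, e) {
  a <- geometric_to_conic(e$center, e$semi_major, e$semi_minor, e$theta)
  if (conic_value(a, p[1], p[2]) <= 0)
    abort_status("lp_inside_fh", "point not strictly outside the ellipse")
  q <- matrix(c(a[1], a[2] / 2, a[4] / 2,
                a[2] / 2, a[3], a[5] / 2,
                a[4] / 2, a[5] / 2, a[6]), 3, 3)
  l <- as.vector(q %*% c(p[1], p[2], 1))   # polar line l1 x + l2 y + l3 = 0
  if (abs(l[2]) >= abs(l[1])) {
    # y = -(l1 x + l3)/l2, substitute into the conic -> quadratic in x
    r1 <- -l[1] / l[2]; r0 <- -l[3] / l[2]
    qa <- a[1] + a[2] * r1 + a[3] * r1^2
    qb <- a[2] * r0 + 2 * a[3] * r0 * r1 + a[4] + a[5] * r1
    qc <- a[3] * r0^2 + a[5] * r0 + a[6]
    xs <- quad_roots(qa, qb, qc)
    pts <- cbind(xs, r1 * xs + r0)
  } else {
    r1 <- -l[2] / l[1]; r0 <- -l[3] / l[1]
    qa <- a[3] + a[2] * r1 + a[1] * r1^2
    qb <- a[2] * r0 + 2 * a[1] * r0 * r1 + a[5] + a[4] * r1
    qc <- a[1] * r0^2 + a[4] * r0 + a[6]
    ys <- quad_roots(qa, qb, qc)
    pts <- cbind(r1 * ys + r0, ys)
  }
  colnames(pts) <- c("x", "y")
  pts
}

quad_roots <- function(a, b, c) {
  disc <- b^2 - 4 * a * c
  if (disc < 0) {
    if (disc > -1e-12 * max(b^2, 1)) disc <- 0
    else abort_status("lp_inside_fh", "no real tangency")
  }
  sq <- sqrt(disc)
  # numerically stable pair
  q <- -(b + sign(b + (b == 0)) * sq) / 2
  r1 <- q / a
  r2 <- if (q != 0) c / q else -b / a - r1
  c(r1, r2)
}

#' Choose the angle-defining tangent point
#'
#' Of the two candidate tangent points, the angle of progression uses the one
#' along the leading fetal-head contour, i.e. the candidate maximizing the
#' angle at Lp between the rays to Up and to the candidate; ties break toward
#' larger x.
#'
#' @param Up,Lp labelled pubic-symphysis endpoints
#' @param t1,t2 candidate tangent points
#' @param rule \code{"max-angle"} (default) or \code{"right-x"} (literal
#'   image-right candidate)
#' @return the selected point (x, y)
#' @export
select_tangent <- function(Up, Lp, t1, t2, rule = c("max-angle", "right-x")) {
  rule <- match.arg(rule)
  if (rule == "right-x") {
    if (t1[1] != t2[1]) return(if (t1[1] > t2[1]) t1 else t2)
    return(if (t1[2] >= t2[2]) t1 else t2)
  }
  a1 <- compute_aop(Up, Lp, t1)
  a2 <- compute_aop(Up, Lp, t2)
  if (abs(a1 - a2) < 1e-12) {
    if (t1[1] != t2[1]) return(if (t1[1] > t2[1]) t1 else t2)
    return(if (t1[2] >= t2[2]) t1 else t2)
  }
  if (a1 > a2) t1 else t2
}

#' Angle of progression from its three key points
#'
#' The angle at Lp between the ray to Up (the pubic-symphysis long axis) and
#' the ray to Tp (the fetal-head tangent), in degrees within [0, 180].
#'
#' @param Up,Lp,Tp key points (x, y)
#' @return angle in degrees
#' @export
compute_aop <- function(Up, Lp, Tp) {
  u <- c(Up[1] - Lp[1], Up[2] - Lp[2])
  v <- c(Tp[1] - Lp[1], Tp[2] - Lp[2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort_status("degenerate", "zero-length ray")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Measure the angle of progression from a label mask
#'
#' Runs the full post-processing chain: boundary extraction of the largest
#' component per class, constrained least-squares ellipse fits for the pubic
#' symphysis (class 1) and fetal head (class 2), PS major-axis endpoints,
#' inferior/superior labelling, tangency from the inferior endpoint to the
#' FH ellipse, and the three-point angle. Stage failures are reported in
#' \code{status}, never raised.
#'
#' @param mask H x W integer label matrix (0 background, 1 PS, 2 FH)
#' @param tangent_rule see \code{\link{select_tangent}}
#' @return an \code{aop_result} list: \code{status} (one of ok,
#'   empty_class, ps_fit_failed, fh_fit_failed, lp_inside_fh),
#'   \code{aop_deg}, \code{keypoints} (Up, Lp, Tp), \code{ps_ellipse},
#'   \code{fh_ellipse}
#' @export
measure_aop_from_mask <- function(mask, tangent_rule = "max-angle") {
  res <- list(status = "ok", aop_deg = NA_real_, keypoints = NULL,
              ps_ellipse = NULL, fh_ellipse = NULL)
  class(res) <- "aop_result"
  fail <- function(status) { res$status <- status; res }

  ps_b <- tryCatch(mask_to_boundary(mask, CLASS_PS),
                   aopseg_error = function(e) e)
  fh_b <- tryCatch(mask_to_boundary(mask, CLASS_FH),
                   aopseg_error = function(e) e)
  if (inherits(ps_b, "condition") || inherits(fh_b, "condition"))
    return(fail("empty_class"))

  ps_e <- tryCatch(conic_to_geometric(fit_ellipse(ps_b)),
                   aopseg_error = function(e) e)
  if (inherits(ps_e, "condition")) return(fail("ps_fit_failed"))
  res$ps_ellipse <- ps_e
  fh_e <- tryCatch(conic_to_geometric(fit_ellipse(fh_b)),
                   aopseg_error = function(e) e)
  if (inherits(fh_e, "condition")) return(fail("fh_fit_failed"))
  res$fh_ellipse <- fh_e

  ep <- major_axis_endpoints(ps_e)
  lab <- label_endpoints(ep[1, ], ep[2, ], fh_e$center)
  tp <- tryCatch(tangent_points(lab$Lp, fh_e), aopseg_error = function(e) e)
  if (inherits(tp, "condition")) return(fail("lp_inside_fh"))
  Tp <- select_tangent(lab$Up, lab$Lp, tp[1, ], tp[2, ], rule = tangent_rule)

  res$keypoints <- list(Up = unname(lab$Up), Lp = unname(lab$Lp),
                        Tp = unname(Tp))
  res$aop_deg <- compute_aop(lab$Up, lab$Lp, Tp)
  res
}

#' Batch AoP measurement to a data frame
#'
#' @param masks list of label masks
#' @param image_ids character ids, one per mask
#' @param tangent_rule see \code{\link{select_tangent}}
#' @return data.frame with columns image_id, status, aop_deg, Up_x, Up_y,
#'   Lp_x, Lp_y, Tp_x, Tp_y and the PS/FH ellipse parameters
#' @export
measure_aop_batch <- function(masks, image_ids = NULL,
                              tangent_rule = "max-angle") {
  if (is.null(image_ids)) image_ids <- sprintf("img%04d", seq_along(masks))
  if (length(masks) == 0) {
    return(data.frame(image_id = character(0), status = character(0),
                      aop_deg = numeric(0)))
  }
  rows <- lapply(seq_along(masks), function(i) {
    r <- measure_aop_from_mask(masks[[i]], tangent_rule)
    kp <- r$keypoints
    g <- function(p, j) if (is.null(kp)) NA_real_ else kp[[p]][j]
    ell <- function(e, f) if (is.null(e)) NA_real_ else switch(f,
      cx = e$center[1], cy = e$center[2], a = e$semi_major,
      b = e$semi_minor, theta = e$theta)
    data.frame(
      image_id = image_ids[i], status = r$status, aop_deg = r$aop_deg,
      Up_x = g("Up", 1), Up_y = g("Up", 2),
      Lp_x = g("Lp", 1), Lp_y = g("Lp", 2),
      Tp_x = g("Tp", 1), Tp_y = g("Tp", 2),
      ps_cx = ell(r$ps_ellipse, "cx"), ps_cy = ell(r$ps_ellipse, "cy"),
      ps_a = ell(r$ps_ellipse, "a"), ps_b = ell(r$ps_ellipse, "b"),
      ps_theta = ell(r$ps_ellipse, "theta"),
      fh_cx = ell(r$fh_ellipse, "cx"), fh_cy = ell(r$fh_ellipse, "cy"),
      fh_a = ell(r$fh_ellipse, "a"), fh_b = ell(r$fh_ellipse, "b"),
      fh_theta = ell(r$fh_ellipse, "theta"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
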