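# Ellipse fitting, tangency and angle geometry.

test_that("fit_ellipse recovers symmetric and exact ellipses", {
  # 8 points at 45-degree steps on the unit circle: symmetry forces A = C,
  # B = D = E = 0 and a centred fit
  t <- seq(0, 2 * pi, length.out = 9)[-9]
  a <- fit_ellipse(cbind(cos(t), sin(t)))
  expect_equal(a[["A"]], a[["C"]], tolerance = 1e-10)
  expect_lt(abs(a[["B"]]), 1e-10)
  expect_lt(abs(a[["D"]]), 1e-10)
  expect_lt(abs(a[["E"]]), 1e-10)
  expect_equal(unname(conic_to_geometric(a)$center), c(0, 0),
               tolerance = 1e-10)

  # exact noiseless recovery at the documented generator geometry
  g <- conic_to_geometric(fit_ellipse(
    ellipse_points(c(256, 192), 120, 70, 30 * pi / 180)))
  expect_equal(unname(g$center), c(256, 192), tolerance = 1e-6)
  expect_equal(g$semi_major, 120, tolerance = 1e-6)
  expect_equal(g$semi_minor, 70, tolerance = 1e-6)
  expect_equal(g$theta, 30 * pi / 180, tolerance = 1e-6)
})

test_that("fit_ellipse recovers the centre within 1 px under 1 px noise", {
  set.seed(11)
  pts <- ellipse_points(c(256, 192), 120, 70, 30 * pi / 180)
  pts <- pts + rnorm(length(pts), 0, 1)
  g <- conic_to_geometric(fit_ellipse(pts))
  expect_lt(sqrt(sum((g$center - c(256, 192))^2)), 1)
})

test_that("fit_ellipse rejects degenerate input", {
  expect_error(fit_ellipse(cbind(1:4, 1:4)), class = "aopseg_fit_failed")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)),
               class = "aopseg_fit_failed")
})

test_that("every fitted conic satisfies the 4AC - B^2 = 1 constraint", {
  set.seed(21)
  for (r in 1:25) {
    e <- random_ellipse()
    pts <- ellipse_points(e$center, e$a, e$b, e$theta, 60)
    if (r %% 2 == 0) pts <- pts + rnorm(length(pts), 0, 0.5)
    a <- fit_ellipse(pts)
    expect_lt(abs(4 * a[["A"]] * a[["C"]] - a[["B"]]^2 - 1), 1e-8)
  }
})

test_that("conic/geometric conversions are exact and round-trip", {
  g <- conic_to_geometric(c(1, 0, 1, 0, 0, -1))      # unit circle
  expect_equal(unname(g$center), c(0, 0))
  expect_equal(c(g$semi_major, g$semi_minor), c(1, 1))
  expect_equal(g$theta, 0)                            # circle tie-break

  g <- conic_to_geometric(normalize_conic(c(0.25, 0, 1, 0, 0, -1)))
  expect_equal(c(g$semi_major, g$semi_minor, g$theta), c(2, 1, 0),
               tolerance = 1e-12)

  # round trip at an awkward orientation; theta reported within [0, pi)
  th <- 100 * pi / 180
  g <- conic_to_geometric(geometric_to_conic(c(10, -5), 7, 3, th))
  expect_equal(unname(g$center), c(10, -5), tolerance = 1e-9)
  expect_equal(c(g$semi_major, g$semi_minor), c(7, 3), tolerance = 1e-9)
  expect_equal(g$theta, th %% pi, tolerance = 1e-9)
  expect_true(g$theta >= 0 && g$theta < pi)

  expect_error(conic_to_geometric(c(1, 0, -1, 0, 0, -1)),
               class = "aopseg_fit_failed")
})

test_that("major-axis endpoints follow the closed form", {
  circ <- list(center = c(0, 0), semi_major = 2, semi_minor = 2, theta = 0)
  expect_equal(major_axis_endpoints(circ), rbind(c(-2, 0), c(2, 0)))
  e <- list(center = c(256, 192), semi_major = 120, semi_minor = 70,
            theta = 30 * pi / 180)
  ep <- major_axis_endpoints(e)
  d <- 120 * c(cos(pi / 6), sin(pi / 6))
  expect_equal(ep, rbind(c(256, 192) - d, c(256, 192) + d), tolerance = 1e-12)
})

test_that("endpoint labelling uses FH proximity with x/y tie-breaks", {
  lab <- label_endpoints(c(0, 0), c(10, 0), c(20, 5))
  expect_equal(lab$Up, c(0, 0))
  expect_equal(lab$Lp, c(10, 0))
  # equidistant: larger x wins
  lab <- label_endpoints(c(0, 0), c(10, 0), c(5, 7))
  expect_equal(lab$Lp, c(10, 0))
  # equidistant and equal x: larger y wins
  lab <- label_endpoints(c(3, 0), c(3, 8), c(-2, 4))
  expect_equal(lab$Lp, c(3, 8))
})

test_that("tangent points satisfy the classic construction and symmetry", {
  circ <- list(center = c(0, 0), semi_major = 1, semi_minor = 1, theta = 0)
  tp <- tangent_points(c(2, 0), circ)
  tp <- tp[order(tp[, 2]), ]
  expect_equal(unname(tp), rbind(c(0.5, -sqrt(3) / 2), c(0.5, sqrt(3) / 2)),
               tolerance = 1e-9)

  # point on the major-axis extension of an axis-aligned ellipse:
  # tangent points are mirror images about that axis
  e <- list(center = c(100, 50), semi_major = 40, semi_minor = 20, theta = 0)
  tp <- tangent_points(c(180, 50), e)
  expect_equal(tp[1, 1], tp[2, 1], tolerance = 1e-9)
  expect_equal(tp[1, 2] - 50, -(tp[2, 2] - 50), tolerance = 1e-9)

  expect_error(tangent_points(c(100, 50), e), class = "aopseg_lp_inside_fh")
})

test_that("tangent points agree with a dense brute-force boundary scan", {
  e <- list(center = c(300, 200), semi_major = 110, semi_minor = 85,
            theta = 20 * pi / 180)
  p <- c(80, 60)
  tp <- tangent_points(p, e)
  bf <- brute_tangents(p, e)
  d <- sapply(1:2, function(k)
    min(sqrt(colSums((t(bf) - tp[k, ])^2))))
  expect_lt(max(d), 0.1)
  # returned points lie on the conic
  a <- geometric_to_conic(e$center, e$semi_major, e$semi_minor, e$theta)
  expect_lt(max(abs(conic_value(a, tp[, 1], tp[, 2]))), 1e-8)
})

test_that("tangency half-plane property holds", {
  set.seed(5)
  for (r in 1:10) {
    e <- random_ellipse()
    e <- list(center = e$center, semi_major = e$a, semi_minor = e$b,
              theta = e$theta)
    p <- e$center + c(2.5 * e$semi_major, 1.5 * e$semi_major)
    tp <- tangent_points(p, e)
    bd <- ellipse_points(e$center, e$semi_major, e$semi_minor, e$theta, 2000)
    for (k in 1:2) {
      v <- tp[k, ] - p
      s <- (bd[, 1] - p[1]) * v[2] - (bd[, 2] - p[2]) * v[1]
      expect_true(all(s >= -1e-6) || all(s <= 1e-6))
    }
  }
})

test_that("select_tangent maximizes the angle with a deterministic tie rule", {
  expect_equal(select_tangent(c(0, -10), c(0, 0), c(5, 5), c(5, -5)), c(5, 5))
  # mirror-symmetric candidates: equal angles, larger x wins
  expect_equal(select_tangent(c(0, -10), c(0, 0), c(-4, 6), c(4, 6)), c(4, 6))
  expect_equal(select_tangent(c(0, -10), c(0, 0), c(5, 5), c(5, -5),
                              rule = "right-x"), c(5, 5))
})

test_that("compute_aop matches hand values and is similarity invariant", {
  expect_equal(compute_aop(c(0, -1), c(0, 0), c(1, 0)), 90)
  expect_equal(compute_aop(c(0, -1), c(0, 0), c(0, 1)), 180)
  expect_equal(compute_aop(c(0, -1), c(0, 0), c(1, 1)), 135)
  expect_error(compute_aop(c(1, 1), c(1, 1), c(0, 0)),
               class = "aopseg_degenerate")

  set.seed(33)
  for (r in 1:20) {
    k <- matrix(runif(6, -50, 50), 3, 2)
    base <- compute_aop(k[1, ], k[2, ], k[3, ])
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 20); tr <- runif(2, -99, 99)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    k2 <- t(s * rot %*% t(k) + tr)
    expect_equal(compute_aop(k2[1, ], k2[2, ], k2[3, ]), base,
                 tolerance = 1e-9)
  }
})

test_that("mask_to_boundary extracts the largest component's 4-boundary", {
  m <- matrix(1L, 3, 3)
  b <- mask_to_boundary(m, 1)
  expect_equal(nrow(b), 8)                  # centre pixel excluded
  expect_false(any(b[, 1] == 1 & b[, 2] == 1))

  m <- matrix(0L, 3, 3); m[2, 2] <- 1L
  expect_equal(unname(mask_to_boundary(m, 1)), cbind(1, 1))

  # two components (20 and 5 pixels): only the larger one is traced;
  # oracle = exhaustive labelling of the fixture grid
  m <- matrix(0L, 10, 12)
  m[2:5, 2:6] <- 1L                         # 20 px block
  m[8, 8:12] <- 1L                          # 5 px strip
  b <- mask_to_boundary(m, 1)
  expect_true(all(b[, 2] <= 4))             # all from the big block (y <= 4)
  inner <- b[, 1] %in% 2:4 & b[, 2] %in% 2:3
  expect_equal(nrow(b), 20 - 2 * 3)         # block boundary = 20 - interior
  expect_error(mask_to_boundary(m, 2), class = "aopseg_empty_class")
})

test_that("measure_aop_from_mask handles phantoms, rotation and failures", {
  m <- matrix(0L, 20, 20)
  expect_equal(measure_aop_from_mask(m)$status, "empty_class")
  m[5:8, 5:8] <- 2L
  expect_equal(measure_aop_from_mask(m)$status, "empty_class")

  s <- generate_sample(phantom_spec(101))
  r <- measure_aop_from_mask(s$mask)
  expect_equal(r$status, "ok")
  expect_lt(abs(r$aop_deg - s$gt_aop_deg), 2)

  # rotating the mask by 90 degrees leaves the angle unchanged
  r90 <- measure_aop_from_mask(t(s$mask)[ncol(s$mask):1, ])
  expect_equal(r90$status, "ok")
  expect_lt(abs(r90$aop_deg - r$aop_deg), 0.5)

  # determinism: identical mask, bit-identical result
  expect_identical(measure_aop_from_mask(s$mask), r)
})

test_that("measure_aop_batch emits the documented record layout", {
  s <- generate_sample(phantom_spec(102))
  df <- measure_aop_batch(list(s$mask, matrix(0L, 8, 8)), c("a", "b"))
  expect_equal(df$status, c("ok", "empty_class"))
  expect_true(all(c("image_id", "status", "aop_deg", "Up_x", "Up_y", "Lp_x",
                    "Lp_y", "Tp_x", "Tp_y") %in% names(df)))
  expect_true(is.na(df$aop_deg[2]))
})
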