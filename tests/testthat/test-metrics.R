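# Evaluation metrics against brute-force oracles.

test_that("confusion counts match an exhaustive per-pixel tally", {
  set.seed(1)
  t_ <- random_mask(16, 16)
  expect_equal(confusion(t_, t_, 1)[c("FP", "FN")], list(FP = 0L, FN = 0L))

  p <- matrix(0L, 16, 16)
  expect_equal(confusion(p, t_, 2)$FN, sum(t_ == 2))

  for (r in 1:5) {
    p <- random_mask(16, 16); t_ <- random_mask(16, 16)
    for (cl in 0:2) expect_equal(confusion(p, t_, cl),
                                 brute_confusion(p, t_, cl))
  }
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3), 1),
               class = "aopseg_shape")
})

test_that("pixel accuracy follows its defining ratio", {
  expect_equal(pixel_accuracy(list(TP = 5, FP = 0, TN = 7, FN = 0)), 1)
  expect_equal(pixel_accuracy(list(TP = 0, FP = 1, TN = 0, FN = 1)), 0)
  expect_equal(pixel_accuracy(list(TP = 3, TN = 5, FP = 1, FN = 1)), 0.8)
  # accuracy + misclassification fraction = 1
  set.seed(2)
  p <- random_mask(12, 9); t_ <- random_mask(12, 9)
  expect_equal(multiclass_accuracy(p, t_) + mean(p != t_), 1)
})

test_that("dice scores match set-overlap arithmetic and are symmetric", {
  set.seed(3)
  t_ <- random_mask(16, 16)
  expect_equal(dice_score(t_, t_, 1:2), 1)

  # half overlap: 2 px vs 2 px sharing 1
  p <- matrix(0L, 4, 4); q <- matrix(0L, 4, 4)
  p[1, 1:2] <- 1L; q[1, 2:3] <- 1L
  expect_equal(dice_score(p, q, 1), 0.5)

  expect_equal(dice_score(matrix(0L, 3, 3), matrix(0L, 3, 3), 1), 1)

  for (r in 1:10) {
    p <- random_mask(16, 16); t_ <- random_mask(16, 16)
    for (cl in list(1, 2, 1:2)) {
      inter <- sum(p == t_ & p %in% cl)
      expect_equal(dice_score(p, t_, cl),
                   2 * inter / (sum(p %in% cl) + sum(t_ %in% cl)))
      expect_equal(dice_score(p, t_, cl), dice_score(t_, p, cl))
    }
    # pooled Dice equals the count form on summed per-class confusions
    c1 <- confusion(p, t_, 1); c2 <- confusion(p, t_, 2)
    tp <- c1$TP + c2$TP; fp <- c1$FP + c2$FP; fn <- c1$FN + c2$FN
    expect_equal(dice_score(p, t_, 1:2), 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("average surface distance matches the O(n^2) oracle", {
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  expect_equal(average_surface_distance(m, m, 1), 0)

  # two single-pixel surfaces 3 px apart: (3 + 3) / (1 + 1)
  a <- matrix(0L, 5, 9); b <- matrix(0L, 5, 9)
  a[3, 3] <- 1L; b[3, 6] <- 1L
  expect_equal(average_surface_distance(a, b, 1), 3)

  set.seed(4)
  for (r in 1:10) {
    a <- random_mask(24, 24, 0:1); b <- random_mask(24, 24, 0:1)
    expect_equal(average_surface_distance(a, b, 1), brute_asd(a, b, 1))
    expect_equal(average_surface_distance(a, b, 1),
                 average_surface_distance(b, a, 1))
  }
  expect_error(average_surface_distance(a, matrix(0L, 24, 24), 1),
               class = "aopseg_empty_class")
})

test_that("ASD is invariant under a common translation", {
  set.seed(5)
  a <- matrix(0L, 30, 30); b <- matrix(0L, 30, 30)
  a[5:12, 6:10] <- 1L; b[8:13, 9:15] <- 1L
  base <- average_surface_distance(a, b, 1)
  sh <- function(m, di, dj) {
    out <- matrix(0L, 30, 30)
    out[(5:20) + di, (5:20) + dj] <- m[5:20, 5:20]
    out
  }
  expect_equal(average_surface_distance(sh(a, 4, 7), sh(b, 4, 7), 1), base)
})

test_that("endpoint errors reproduce closed-form distances and angles", {
  pred <- list(Up = c(10, 10), Lp = c(20, 30))
  truth <- list(Ut = c(10, 10), Lt = c(20, 30))
  expect_equal(endpoint_errors(pred, truth), list(ED_U = 0, ED_L = 0, Ax = 0))

  pred$Up <- c(13, 14)
  expect_equal(endpoint_errors(pred, truth)$ED_U, 5)

  pred <- list(Up = c(0, 0), Lp = c(1, 0))
  truth <- list(Ut = c(0, 0), Lt = c(0, 1))
  expect_equal(endpoint_errors(pred, truth)$Ax, 90)
  expect_error(endpoint_errors(list(Up = c(1, 1), Lp = c(1, 1)), truth),
               class = "aopseg_degenerate")
})

test_that("angle-difference summaries use absolute errors and population sd", {
  s <- aop_error_summary(c(100, 120), c(100, 120))
  expect_equal(c(s$mean_deg, s$median_deg, s$std_deg), c(0, 0, 0))

  s <- aop_error_summary(c(102, 96, 106), c(100, 100, 100))
  expect_equal(s$mean_deg, 4)
  expect_equal(s$median_deg, 4)
  expect_equal(s$std_deg, sqrt(8 / 3))
  expect_equal(s$n, 3L)
  expect_equal(s$n_over_20, 0L)
  expect_equal(aop_error_summary(c(102, 96, 106), c(100, 100, 100),
                                 sd_type = "sample")$std_deg, 2)

  s <- aop_error_summary(c(150, 100), c(100, 99))
  expect_equal(s$n_over_20, 1L)
  expect_error(aop_error_summary(1:3, 1:2), class = "aopseg_shape")
})

test_that("segmentation_report aggregates per-image metrics", {
  set.seed(6)
  t_ <- matrix(0L, 20, 20); t_[3:6, 3:8] <- 1L; t_[10:18, 8:17] <- 2L
  r <- segmentation_report(t_, t_)
  expect_equal(r[c("acc", "dice_all", "dice_ps", "dice_fh")],
               list(acc = 1, dice_all = 1, dice_ps = 1, dice_fh = 1))
  expect_equal(r$asd, 0)
  p <- t_; p[3:6, 3:5] <- 0L
  r <- segmentation_report(p, t_)
  expect_lt(r$dice_ps, 1)
  expect_equal(r$dice_fh, 1)
  # mean aggregation option averages the two class scores
  rm_ <- segmentation_report(p, t_, dice_all = "mean")
  expect_equal(rm_$dice_all, (rm_$dice_ps + rm_$dice_fh) / 2)
})
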