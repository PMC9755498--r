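# Evaluation metrics: pixel accuracy, Dice scores, average surface distance,
# endpoint errors and angle-difference summaries.

#' One-vs-rest confusion counts for a class
#' @param pred,truth H x W integer label matrices of equal shape
#' @param class_id the positive class
#' @return list with TP, FP, TN, FN pixel counts
#' @export
confusion <- function(pred, truth, class_id) {
  if (!identical(dim(pred), dim(truth)))
    abort_status("shape", "mask shapes differ")
  p <- pred == class_id
  t_ <- truth == class_id
  list(TP = sum(p & t_), FP = sum(p & !t_),
       TN = sum(!p & !t_), FN = sum(!p & t_))
}

#' Pixel accuracy from confusion counts
#' @param c confusion counts (list with TP, FP, TN, FN)
#' @return (TP + TN) / (TP + FP + TN + FN)
#' @export
pixel_accuracy <- function(c) {
  (c$TP + c$TN) / (c$TP + c$FP + c$TN + c$FN)
}

#' Multi-class pixel accuracy
#'
#' Overall per-pixel agreement between prediction and truth, equal to the
#' one-vs-rest accuracy pooled over classes.
#' @param pred,truth label matrices
#' @return fraction in [0, 1]
#' @export
multiclass_accuracy <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    abort_status("shape", "mask shapes differ")
  mean(pred == truth)
}

#' Dice score
#'
#' \code{2 TP / (2 TP + FP + FN)} for the foreground defined by
#' \code{classes}: a single class gives the per-structure Dice, and
#' \code{classes = c(1, 2)} pools the per-class counts of pubic symphysis
#' and fetal head into the overall (micro-averaged) score — a pixel only
#' counts as TP when the predicted class matches, so PS/FH confusions are
#' penalized. For a one-hot prediction the pooled score equals
#' \code{1 - dice_loss} on the same pair. When neither mask contains any
#' foreground the score is defined as 1.
#'
#' @param pred,truth label matrices
#' @param classes class label(s) forming the foreground
#' @return fraction in [0, 1]
#' @export
dice_score <- function(pred, truth, classes) {
  if (!identical(dim(pred), dim(truth)))
    abort_status("shape", "mask shapes differ")
  denom <- sum(pred %in% classes) + sum(truth %in% classes)
  if (denom == 0) return(1)
  inter <- sum(pred == truth & pred %in% classes)
  2 * inter / denom
}

surface_points <- function(mask, class_id) {
  member <- matrix(0L, nrow(mask), ncol(mask))
  member[mask %in% class_id] <- 1L
  cpp_boundary_points(member)
}

#' Average surface distance
#'
#' Symmetrized mean Euclidean distance between the boundary pixel sets of
#' the two masks: \code{(sum of nearest distances A->B + B->A) /
#' (|S(A)| + |S(B)|)}. Surfaces include all components of the class
#' (boundary pixel = class pixel with a 4-neighbour outside the class, the
#' image border counting as outside); distances are between pixel centres.
#'
#' @param a,b label matrices
#' @param class_id class label(s) whose surfaces are compared; a vector pools
#'   the classes into one region
#' @return distance in pixels
#' @export
average_surface_distance <- function(a, b, class_id) {
  if (!identical(dim(a), dim(b))) abort_status("shape", "mask shapes differ")
  sa <- surface_points(a, class_id)
  sb <- surface_points(b, class_id)
  if (nrow(sa) == 0 || nrow(sb) == 0)
    abort_status("empty_class", "empty surface: ASD undefined")
  (sum(cpp_nearest_dists(sa, sb)) + sum(cpp_nearest_dists(sb, sa))) /
    (nrow(sa) + nrow(sb))
}

#' Per-image segmentation report
#'
#' @param pred,truth label matrices (0 background, 1 PS, 2 FH)
#' @return list with \code{acc} (multi-class pixel accuracy),
#'   \code{dice_all} (pooled over PS and FH; set \code{dice_all = "mean"}
#'   for the mean of the two per-class scores), \code{dice_ps},
#'   \code{dice_fh} and \code{asd} (pooled-foreground average surface
#'   distance, NA when either foreground is empty)
#' @param dice_all \code{"pooled"} (default) or \code{"mean"}
#' @export
segmentation_report <- function(pred, truth, dice_all = c("pooled", "mean")) {
  dice_all <- match.arg(dice_all)
  d_ps <- dice_score(pred, truth, CLASS_PS)
  d_fh <- dice_score(pred, truth, CLASS_FH)
  d_all <- if (dice_all == "pooled")
    dice_score(pred, truth, c(CLASS_PS, CLASS_FH)) else (d_ps + d_fh) / 2
  asd <- tryCatch(
    average_surface_distance(pred, truth, c(CLASS_PS, CLASS_FH)),
    aopseg_error = function(e) NA_real_)
  list(acc = multiclass_accuracy(pred, truth),
       dice_all = d_all, dice_ps = d_ps, dice_fh = d_fh, asd = asd)
}

#' Endpoint location errors
#'
#' Euclidean distances between predicted and reference pubic-symphysis
#' endpoints, and the angle between the predicted long axis
#' (Lp - Up) and the reference axis (Lt - Ut).
#'
#' @param pred list with \code{Up} and \code{Lp} (x, y)
#' @param truth list with \code{Ut} and \code{Lt} (x, y)
#' @return list with \code{ED_U}, \code{ED_L} (pixels) and \code{Ax}
#'   (degrees in [0, 180])
#' @export
endpoint_errors <- function(pred, truth) {
  ed_u <- sqrt(sum((pred$Up - truth$Ut)^2))
  ed_l <- sqrt(sum((pred$Lp - truth$Lt)^2))
  xp <- c(pred$Lp[1] - pred$Up[1], pred$Lp[2] - pred$Up[2])
  xt <- c(truth$Lt[1] - truth$Ut[1], truth$Lt[2] - truth$Ut[2])
  if (all(xp == 0) || all(xt == 0))
    abort_status("degenerate", "zero-length axis")
  # atan2 form: exact for parallel axes, stable near 0 and 180 degrees
  cross <- xp[1] * xt[2] - xp[2] * xt[1]
  ax <- atan2(abs(cross), sum(xp * xt)) * 180 / pi
  list(ED_U = ed_u, ED_L = ed_l, Ax = ax)
}

#' Summary of angle-of-progression differences
#'
#' Elementwise absolute differences between predicted and reference angles,
#' summarized by mean, median and standard deviation, plus the count of
#' cases exceeding 20 degrees.
#'
#' @param pred_aops,truth_aops equal-length vectors of angles in degrees
#' @param sd_type \code{"population"} (divide by n, default) or
#'   \code{"sample"} (n - 1)
#' @return list with mean_deg, median_deg, std_deg, n, n_over_20
#' @export
aop_error_summary <- function(pred_aops, truth_aops,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(pred_aops) != length(truth_aops) || length(pred_aops) < 1)
    abort_status("shape", "angle vectors must have equal positive length")
  d <- abs(pred_aops - truth_aops)
  n <- length(d)
  v <- if (sd_type == "population") mean((d - mean(d))^2)
  else if (n > 1) sum((d - mean(d))^2) / (n - 1) else 0
  list(mean_deg = mean(d), median_deg = median(d), std_deg = sqrt(v),
       n = n, n_over_20 = sum(d > 20))
}
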