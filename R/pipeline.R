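# Training and evaluation orchestration: patient-grouped k-fold splits,
# the Adam training loop over the collaborative loss, batch prediction with
# AoP measurement, the ablation harness and the lower-branch weight sweep.

#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 1e-4, 200 epochs,
#' batch size 1, 5-fold patient-grouped cross-validation, Kaiming
#' initialization (performed by \code{\link{build_dbsn}}).
#'
#' @param lr learning rate (Adam)
#' @param epochs training epochs
#' @param batch_size gradient-accumulation batch size
#' @param k_folds folds for patient-grouped cross-validation
#' @param seed master seed (weights, shuffling, augmentation)
#' @param augment apply rotation/flip augmentation during training
#' @param augmentation an \code{\link{augmentation_spec}}
#' @param network a \code{\link{network_config}}
#' @param input_size processing resolution c(height, width), divisible by 16
#' @param verbose log epoch losses to stderr
#' @param log_file optional path receiving structured log lines
#' @return a \code{train_config} list
#' @export
train_config <- function(lr = 1e-4, epochs = 200L, batch_size = 1L,
                         k_folds = 5L, seed = 0L, augment = TRUE,
                         augmentation = augmentation_spec(),
                         network = network_config(),
                         input_size = c(384L, 512L),
                         verbose = FALSE, log_file = NULL) {
  if (lr <= 0 || epochs < 1 || k_folds < 2 || batch_size < 1)
    abort_status("config", "invalid training configuration")
  if (any(input_size %% 16L != 0))
    abort_status("config", "input_size must be divisible by 16")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 augment = isTRUE(augment), augmentation = augmentation,
                 network = network, input_size = as.integer(input_size),
                 verbose = isTRUE(verbose), log_file = log_file),
            class = "train_config")
}

log_line <- function(cfg, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  if (isTRUE(cfg$verbose)) message(line)
  if (!is.null(cfg$log_file)) cat(line, "\n", file = cfg$log_file,
                                  append = TRUE)
  invisible(line)
}

#' Read a training configuration from a YAML file
#'
#' Keys mirror \code{\link{train_config}} argument names (the nested
#' \code{augmentation} and \code{network} blocks mirror
#' \code{\link{augmentation_spec}} and \code{\link{network_config}}).
#' Unknown keys are an error rather than being ignored.
#'
#' @param path YAML file
#' @return a \code{train_config}
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  top <- c("lr", "epochs", "batch_size", "k_folds", "seed", "augment",
           "augmentation", "network", "input_size", "verbose", "log_file")
  bad <- setdiff(names(y), top)
  if (length(bad)) abort_status("config", paste("unknown keys:",
                                                paste(bad, collapse = ", ")))
  if (!is.null(y$augmentation)) {
    bad <- setdiff(names(y$augmentation),
                   c("rotation_range_deg", "hflip_prob", "seed"))
    if (length(bad)) abort_status("config", paste("unknown augmentation keys:",
                                                  paste(bad, collapse = ", ")))
    y$augmentation <- do.call(augmentation_spec, y$augmentation)
  }
  if (!is.null(y$network)) {
    bad <- setdiff(names(y$network), names(formals(network_config)))
    if (length(bad)) abort_status("config", paste("unknown network keys:",
                                                  paste(bad, collapse = ", ")))
    y$network <- do.call(network_config, y$network)
  }
  do.call(train_config, y)
}

#' Patient-grouped k-fold assignment
#'
#' Every patient lands in exactly one fold (so no patient's images are split
#' across training and validation) and fold sizes differ by at most one
#' patient. Deterministic in \code{seed}.
#'
#' @param patient_ids character vector, one entry per image (duplicates
#'   expected) or the unique patient ids
#' @param k number of folds
#' @param seed shuffle seed
#' @return named integer vector mapping patient id to fold in 1..k
#' @export
patient_grouped_kfold <- function(patient_ids, k = 5L, seed = 0L) {
  upat <- unique(patient_ids)
  if (k < 2 || k > length(upat))
    abort_status("config", "need 2 <= k <= number of patients")
  perm <- with_seed(seed, sample(upat))
  setNames(rep_len(seq_len(k), length(perm)), perm)
}

# resize a normalized [-1, 1] image (bilinear, background fill -1)
resize_normalized <- function(img, size) {
  d <- dim(img)
  if (identical(as.integer(d), as.integer(size))) return(img)
  warp_matrix(img, resize_map(d[1], d[2], size[1], size[2]),
              size[1], size[2], TRUE, -1, clamp = TRUE)
}

adam_init <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- if (is.null(st$m[[nm]])) g * 0 else st$m[[nm]]
    v <- if (is.null(st$v[[nm]])) g * 0 else st$v[[nm]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    net$params[[nm]] <- net$params[[nm]] -
      lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(st)
}

# forward + collaborative loss on the tape; returns loss node and outputs
tape_loss <- function(net, img, truth) {
  cfg <- net$cfg
  ctx <- list(net = net, tape = ad_tape(), pnodes = new.env())
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  out <- dbsn_graph(ctx, ad_param(ctx$tape, img))
  yh <- onehot(truth, cfg$num_classes)
  fg <- 2:cfg$num_classes
  du <- ad_dice_loss(ctx$tape, out$upper, yh, fg)
  loss <- if (!is.null(out$lower)) {
    t16 <- downsample_labels(truth, 16L, cfg$num_classes)
    dl <- ad_dice_loss(ctx$tape, out$lower, onehot(t16, cfg$num_classes), fg)
    ad_wsum(ctx$tape, cfg$w_upper, du, cfg$w_lower, dl)
  } else {
    ad_wsum(ctx$tape, cfg$w_upper, du, 0, du)
  }
  list(ctx = ctx, loss = loss, out = out)
}

harvest_grads <- function(pnodes) {
  out <- list()
  for (nm in ls(pnodes)) {
    g <- pnodes[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

#' Train a DBSN on phantom (or any) samples
#'
#' Adam on the collaborative loss, batch accumulation, optional
#' rotation/flip augmentation re-drawn every presentation. Deterministic
#' given \code{cfg$seed} (weights, shuffling and augmentation all derive
#' from the master seed).
#'
#' @param samples list of samples, each with \code{image} (normalized
#'   matrix) and \code{mask} (integer label matrix)
#' @param cfg a \code{\link{train_config}}
#' @return list with \code{net} and \code{loss_log} (mean loss per epoch)
#' @export
train_model <- function(samples, cfg) {
  if (length(samples) == 0) abort_status("config", "empty training set")
  set.seed(cfg$seed)
  net <- build_dbsn(cfg$network)
  st <- adam_init()
  size <- cfg$input_size
  imgs <- lapply(samples, function(s) resize_normalized(s$image, size))
  msks <- lapply(samples, function(s) resize_mask(s$mask, size))
  n <- length(samples)
  loss_log <- numeric(cfg$epochs)
  acc <- NULL; acc_n <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    tot <- 0
    for (i in ord) {
      img <- imgs[[i]]; msk <- msks[[i]]
      if (cfg$augment) {
        au <- augment(img, msk, spec = cfg$augmentation)
        img <- au$image; msk <- au$mask
      }
      tl <- tape_loss(net, img, msk)
      tot <- tot + tl$loss$value
      ad_backward(tl$ctx$tape, tl$loss)
      g <- harvest_grads(tl$ctx$pnodes)
      if (is.null(acc)) acc <- g
      else for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n >= cfg$batch_size) {
        if (cfg$batch_size > 1L)
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / acc_n
        adam_step(net, acc, st, cfg$lr)
        acc <- NULL; acc_n <- 0L
      }
    }
    loss_log[ep] <- tot / n
    log_line(cfg, "epoch %d/%d train loss %.4f", ep, cfg$epochs, loss_log[ep])
  }
  list(net = net, loss_log = loss_log)
}

#' Train one cross-validation fold
#'
#' Trains on every patient whose fold differs from \code{fold}; asserts that
#' training and held-out patients are disjoint.
#'
#' @param samples list of samples carrying \code{patient_id}
#' @param assignment \code{\link{patient_grouped_kfold}} result
#' @param fold held-out fold index
#' @param cfg a \code{\link{train_config}}
#' @param checkpoint optional path; the trained weights are saved there
#' @return list with net, loss_log, train/validation indices
#' @export
train_fold <- function(samples, assignment, fold, cfg, checkpoint = NULL) {
  pats <- vapply(samples, function(s) s$patient_id, "")
  val <- which(assignment[pats] == fold)
  trn <- which(assignment[pats] != fold)
  if (length(trn) == 0) abort_status("config", "empty training split")
  if (length(intersect(pats[trn], pats[val])) > 0)
    abort_status("config", "patient leakage across folds")   # unreachable
  fit <- train_model(samples[trn], cfg)
  if (!is.null(checkpoint)) save_checkpoint(fit$net, checkpoint)
  list(net = fit$net, loss_log = fit$loss_log,
       train_idx = trn, val_idx = val)
}

#' Segment images and measure the angle of progression
#'
#' Argmax of the upper-branch probabilities gives the label mask, which is
#' then passed through the geometric AoP pipeline. Per-image failures are
#' reported in the \code{status} column, never raised.
#'
#' @param net a trained \code{dbsn} (or a checkpoint path)
#' @param images list of normalized image matrices at a resolution divisible
#'   by 16
#' @param image_ids optional ids
#' @param tangent_rule see \code{\link{select_tangent}}
#' @return list with \code{masks} (list of label matrices) and
#'   \code{results} (\code{\link{measure_aop_batch}} data frame)
#' @export
predict_and_measure <- function(net, images, image_ids = NULL,
                                tangent_rule = "max-angle") {
  if (is.character(net)) net <- load_checkpoint(net)
  masks <- lapply(images, function(img) {
    up <- dbsn_forward(net, img)$upper
    d <- dim(up)
    m <- matrix(max.col(matrix(up, d[1] * d[2], d[3]),
                        ties.method = "first") - 1L, d[1], d[2])
    storage.mode(m) <- "integer"
    m
  })
  list(masks = masks,
       results = measure_aop_batch(masks, image_ids, tangent_rule))
}

#' Evaluate a trained network on held-out samples
#'
#' @param net trained \code{dbsn}
#' @param samples held-out samples (with masks and analytic reference angles)
#' @param input_size evaluation resolution c(height, width)
#' @param tangent_rule see \code{\link{select_tangent}}
#' @return list with \code{per_image} data frame and \code{aggregate}
#'   metrics (acc, dice_all, dice_ps, dice_fh, asd, aop mean/median/std,
#'   n_over_20, ok_rate)
#' @export
evaluate_model <- function(net, samples, input_size = c(384L, 512L),
                           tangent_rule = "max-angle") {
  imgs <- lapply(samples, function(s) resize_normalized(s$image, input_size))
  truths <- lapply(samples, function(s) resize_mask(s$mask, input_size))
  ids <- vapply(seq_along(samples), function(i) {
    id <- samples[[i]]$image_id
    if (is.null(id)) sprintf("img%04d", i) else id
  }, "")
  pr <- predict_and_measure(net, imgs, ids, tangent_rule)
  seg <- lapply(seq_along(samples), function(i)
    segmentation_report(pr$masks[[i]], truths[[i]]))
  # endpoint errors against the analytic references, on the processing grid
  epe <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    r <- pr$results[i, ]
    if (r$status != "ok" || is.null(s$gt_keypoints))
      return(list(ED_U = NA_real_, ED_L = NA_real_, Ax = NA_real_))
    ref <- resize_points(rbind(s$gt_keypoints$Up, s$gt_keypoints$Lp),
                         dim(s$mask), input_size)
    endpoint_errors(list(Up = c(r$Up_x, r$Up_y), Lp = c(r$Lp_x, r$Lp_y)),
                    list(Ut = ref[1, ], Lt = ref[2, ]))
  })
  per <- cbind(
    data.frame(image_id = ids,
               acc = vapply(seg, `[[`, 0, "acc"),
               dice_all = vapply(seg, `[[`, 0, "dice_all"),
               dice_ps = vapply(seg, `[[`, 0, "dice_ps"),
               dice_fh = vapply(seg, `[[`, 0, "dice_fh"),
               asd = vapply(seg, `[[`, 0, "asd"),
               ed_u = vapply(epe, `[[`, 0, "ED_U"),
               ed_l = vapply(epe, `[[`, 0, "ED_L"),
               ax = vapply(epe, `[[`, 0, "Ax"),
               aop_true = vapply(samples, function(s) s$gt_aop_deg, 0)),
    pr$results[, c("status", "aop_deg")])
  ok <- per$status == "ok"
  aop_sum <- if (any(ok))
    aop_error_summary(per$aop_deg[ok], per$aop_true[ok])
  else list(mean_deg = NA_real_, median_deg = NA_real_, std_deg = NA_real_,
            n = 0L, n_over_20 = NA_integer_)
  aggregate <- list(
    acc = mean(per$acc), dice_all = mean(per$dice_all),
    dice_ps = mean(per$dice_ps), dice_fh = mean(per$dice_fh),
    asd = mean(per$asd, na.rm = TRUE),
    ed_u = mean(per$ed_u, na.rm = TRUE), ed_l = mean(per$ed_l, na.rm = TRUE),
    ax = mean(per$ax, na.rm = TRUE),
    aop_mean = aop_sum$mean_deg, aop_median = aop_sum$median_deg,
    aop_std = aop_sum$std_deg, n_over_20 = aop_sum$n_over_20,
    ok_rate = mean(ok))
  list(per_image = per, aggregate = aggregate)
}

#' Cross-validated evaluation
#'
#' Trains one model per fold and averages the per-fold aggregate metrics.
#'
#' @param samples phantom samples with patient ids
#' @param cfg a \code{\link{train_config}}
#' @return list with per-fold results and the averaged metrics
#' @export
run_cross_validation <- function(samples, cfg) {
  pats <- vapply(samples, function(s) s$patient_id, "")
  assignment <- patient_grouped_kfold(pats, cfg$k_folds, cfg$seed)
  folds <- lapply(seq_len(cfg$k_folds), function(f) {
    log_line(cfg, "fold %d/%d", f, cfg$k_folds)
    tr <- train_fold(samples, assignment, f, cfg)
    ev <- evaluate_model(tr$net, samples[tr$val_idx], cfg$input_size)
    list(fold = f, eval = ev, loss_log = tr$loss_log)
  })
  agg <- lapply(folds, function(f) unlist(f$eval$aggregate))
  list(folds = folds, mean_metrics = as.list(colMeans(do.call(rbind, agg))),
       assignment = assignment)
}

#' Ablation harness
#'
#' Trains each network variant with identical seed, split and schedule and
#' tabulates segmentation metrics, parameter counts and angle errors.
#'
#' @param samples phantom samples
#' @param variants named list of \code{\link{network_config}}s (e.g. dbsn,
#'   dbsn_ag, dbsn_lb, dbsn_dc)
#' @param cfg a \code{\link{train_config}} (its \code{network} is replaced
#'   per variant)
#' @param holdout_fold fold used for evaluation (default 1)
#' @return data frame, one row per variant
#' @export
ablation_harness <- function(samples, variants, cfg, holdout_fold = 1L) {
  pats <- vapply(samples, function(s) s$patient_id, "")
  assignment <- patient_grouped_kfold(pats, cfg$k_folds, cfg$seed)
  split_id <- paste(names(sort(assignment)), sort(assignment),
                    sep = ":", collapse = ",")
  rows <- lapply(names(variants), function(nm) {
    vcfg <- cfg
    vcfg$network <- variants[[nm]]
    log_line(cfg, "ablation variant %s", nm)
    tr <- train_fold(samples, assignment, holdout_fold, vcfg)
    ev <- evaluate_model(tr$net, samples[tr$val_idx], cfg$input_size)
    a <- ev$aggregate
    data.frame(variant = nm, acc = a$acc, dice_all = a$dice_all,
               dice_ps = a$dice_ps, dice_fh = a$dice_fh,
               n_params = count_parameters(tr$net),
               aop_mean = a$aop_mean, aop_median = a$aop_median,
               aop_std = a$aop_std, split_id = split_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standard ablation variant configurations
#' @param base_channels encoder width of the first block
#' @return named list of configs: dbsn, dbsn_ag, dbsn_lb, dbsn_dc
#' @export
ablation_variants <- function(base_channels = 32L) {
  list(
    dbsn = network_config(base_channels = base_channels),
    dbsn_ag = network_config(base_channels = base_channels,
                             use_attention_gates = FALSE),
    dbsn_lb = network_config(base_channels = base_channels,
                             use_lower_branch = FALSE,
                             use_attention_gates = FALSE),
    dbsn_dc = network_config(base_channels = base_channels,
                             use_deformable = FALSE)
  )
}

#' Sweep the lower-branch loss weight
#'
#' Trains one model per candidate weight under identical seeds and reports
#' accuracy and Dice on the held-out fold.
#'
#' @param values candidate \code{w_lower} weights
#' @param samples phantom samples
#' @param cfg a \code{\link{train_config}}
#' @param holdout_fold evaluation fold
#' @return data frame with one row per value (w_lower, acc, dice_all)
#' @export
sweep_w_lower <- function(values, samples, cfg, holdout_fold = 1L) {
  if (length(values) == 0) abort_status("config", "no weights to sweep")
  pats <- vapply(samples, function(s) s$patient_id, "")
  assignment <- patient_grouped_kfold(pats, cfg$k_folds, cfg$seed)
  rows <- lapply(values, function(w) {
    vcfg <- cfg
    vcfg$network$w_lower <- w
    log_line(cfg, "w_lower sweep: %.3f", w)
    tr <- train_fold(samples, assignment, holdout_fold, vcfg)
    ev <- evaluate_model(tr$net, samples[tr$val_idx], cfg$input_size)
    data.frame(w_lower = w, acc = ev$aggregate$acc,
               dice_all = ev$aggregate$dice_all)
  })
  do.call(rbind, rows)
}
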