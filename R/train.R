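# Cross-validated training: AdamW at a constant learning rate, step-based
# loop with epoch bookkeeping (80 steps per epoch mirrors the 500-epoch /
# 40,000-step equivalence), periodic full-volume validation Dice via the
# sliding-window inference path, and best-checkpoint-only saving.

#' Training configuration
#'
#' Defaults follow the reference regime: Adam at a constant learning rate of
#' 1e-4 with decoupled weight decay 1e-4, batch size 1, 500 epochs at 80 steps
#' each (40,000 steps), validation every 10 epochs, fivefold cross-validation.
#' The `scaled_down` profile (see [scaled_down_profile()]) shrinks everything
#' to desk scale for tests and demos.
#'
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay rate.
#' @param batch_size examples per step (the architecture targets 1).
#' @param epochs training epochs.
#' @param steps_per_epoch steps per epoch.
#' @param eval_every_epochs validation interval in epochs.
#' @param folds number of cross-validation folds.
#' @param seed master seed.
#' @param loss_weights a [loss_weights()].
#' @param crop_size augmentation crop `(z, y, x)`.
#' @param rotation_deg,scale_range augmentation ranges.
#' @param infer_crop_z,infer_taper sliding-window geometry used for
#'   validation monitoring.
#' @param scaled_down logical marker that this is the desk-scale profile.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, batch_size = 1L,
                         epochs = 500L, steps_per_epoch = 80L,
                         eval_every_epochs = 10L, folds = 5L, seed = 1L,
                         loss_weights = lobeseg::loss_weights(),
                         crop_size = c(32L, 128L, 128L),
                         rotation_deg = 10, scale_range = c(0.8, 1.2),
                         infer_crop_z = 32L, infer_taper = 8L,
                         scaled_down = FALSE) {
  assert_that(lr >= 0, "lr must be >= 0")
  assert_that(folds >= 2, "folds must be >= 2")
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 eval_every_epochs = as.integer(eval_every_epochs),
                 folds = as.integer(folds), seed = as.integer(seed),
                 loss_weights = loss_weights,
                 crop_size = as.integer(crop_size),
                 rotation_deg = rotation_deg, scale_range = scale_range,
                 infer_crop_z = as.integer(infer_crop_z),
                 infer_taper = as.integer(infer_taper),
                 scaled_down = isTRUE(scaled_down)),
            class = "train_config")
}

#' Desk-scale training and model profile
#'
#' A deliberately tiny regime that exercises every pipeline stage on one CPU:
#' depth-2 network with 8 base filters, 16 x 32 x 32 crops, 2 folds, 4 epochs
#' of 80 steps (320 steps), validation every epoch, and a learning rate of
#' 3e-3 appropriate for the small parameter count.
#'
#' @param seed master seed.
#' @return list with elements `train` (a [train_config()]) and `model`
#'   (a [model_config()]).
#' @export
scaled_down_profile <- function(seed = 1L) {
  list(train = train_config(lr = 3e-3, weight_decay = 1e-4, epochs = 4L,
                            steps_per_epoch = 80L, eval_every_epochs = 1L,
                            folds = 2L, seed = seed,
                            crop_size = c(16L, 32L, 32L),
                            infer_crop_z = 16L, infer_taper = 4L,
                            scaled_down = TRUE),
       model = model_config(depth = 2L, base_filters = 8L))
}

#' Cross-validation fold splits
#'
#' Deterministic shuffled partition of the case ids into `k` validation sets
#' whose sizes differ by at most one; each id is validated exactly once.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of `fold_split` objects with `fold_id`, `train_ids`,
#'   `val_ids`.
#' @export
make_folds <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  assert_that(n >= k, "need at least k cases")
  perm <- with_seed(derive_seed(seed, "folds"), sample(case_ids))
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  at <- 0L
  lapply(seq_len(k), function(f) {
    val <- perm[at + seq_len(sizes[f])]
    at <<- at + sizes[f]
    structure(list(fold_id = f, train_ids = setdiff(case_ids, val),
                   val_ids = val),
              class = "fold_split")
  })
}

# Preprocess one raw case into network-ready tensors.
#' Prepare a case for training or inference
#'
#' Resamples to the working grid (slice thickness, axial matrix), builds the
#' three-window composite and the t-SDF targets.
#'
#' @param ct a [ct_volume()].
#' @param labels the aligned [label_volume()] (or `NULL` for inference-only).
#' @param windows list of three [hu_window()]s.
#' @param target_slice_mm working slice thickness (mm); `NULL` keeps z as is.
#' @param axial_size `(rows, cols)` working in-plane matrix; `NULL` keeps it.
#' @param t_mm t-SDF truncation (mm).
#' @return list with `img`, `labels`, `tsdf` (label-dependent parts `NULL`
#'   when no labels are given).
#' @export
prepare_case <- function(ct, labels = NULL, windows = default_windows(),
                         target_slice_mm = 5, axial_size = c(256L, 256L),
                         t_mm = 25) {
  if (!is.null(target_slice_mm)) {
    ct <- resample_slice_thickness(ct, target_slice_mm)
    if (!is.null(labels)) labels <- resample_slice_thickness(labels, target_slice_mm)
  }
  if (!is.null(axial_size)) {
    ct <- resample_axial(ct, axial_size)
    if (!is.null(labels)) labels <- resample_axial(labels, axial_size)
  }
  img <- make_composite(ct, windows)
  list(img = img, labels = labels,
       tsdf = if (is.null(labels)) NULL else compute_tsdf(labels, t_mm))
}

validation_dice <- function(model, cases, cfg) {
  if (!length(cases)) return(NA_real_)
  per_case <- vapply(cases, function(cs) {
    pv <- sliding_window_predict(cs$img, model, overlap = 0.75,
                                 crop_z = cfg$infer_crop_z,
                                 taper = cfg$infer_taper)
    mean(soft_dice_per_class(pv$probs, cs$labels))
  }, numeric(1))
  mean(per_case)
}

#' Train one cross-validation fold
#'
#' Step-based AdamW loop over augmented crops of the fold's training cases
#' (shuffled each epoch with a fold-derived seed). At every evaluation
#' interval the mean per-class soft Dice on the fold's validation cases is
#' computed via full-volume sliding-window inference, and the checkpoint is
#' overwritten only when it improves.
#'
#' @param split a `fold_split` from [make_folds()].
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()].
#' @param data named list of prepared cases (see [prepare_case()]), indexed
#'   by the ids in `split`.
#' @param checkpoint_dir directory for `fold_<k>/best.ckpt`; `NULL` keeps the
#'   best weights in memory only.
#' @param verbose print progress lines?
#' @return list with `model` (best weights restored), `history` (data frame of
#'   step, loss and validation Dice), `best_val_dice`, `checkpoint`.
#' @export
train_fold <- function(split, cfg, model_cfg, data, checkpoint_dir = NULL,
                       verbose = FALSE) {
  assert_that(inherits(cfg, "train_config"), "cfg must be a train_config")
  train_cases <- data[split$train_ids]
  val_cases <- data[split$val_ids]
  assert_that(length(train_cases) >= 1, "empty training split")

  fold_seed <- derive_seed(cfg$seed, "fold", split$fold_id)
  model <- build_network(model_cfg, seed = fold_seed)
  params <- model_parameters(model)
  opt <- adamw_state(params)
  aug <- augment_spec(cfg$rotation_deg, cfg$scale_range, cfg$crop_size,
                      seed = fold_seed)

  total_steps <- cfg$epochs * cfg$steps_per_epoch
  eval_every <- cfg$eval_every_epochs * cfg$steps_per_epoch
  n_train <- length(train_cases)
  order <- integer(0)
  history <- list()
  best <- -Inf
  best_weights <- NULL
  ckpt_path <- NULL
  if (!is.null(checkpoint_dir)) {
    dir.create(file.path(checkpoint_dir, sprintf("fold_%d", split$fold_id)),
               recursive = TRUE, showWarnings = FALSE)
    ckpt_path <- file.path(checkpoint_dir, sprintf("fold_%d", split$fold_id),
                           "best.ckpt")
  }

  for (step in seq_len(total_steps)) {
    pos <- (step - 1L) %% n_train
    if (pos == 0L) {
      epoch <- (step - 1L) %/% cfg$steps_per_epoch + 1L
      order <- with_seed(derive_seed(fold_seed, "order", epoch),
                         sample.int(n_train))
    }
    cs <- train_cases[[order[pos + 1L]]]
    batch <- augment_triple(cs$img, cs$labels, cs$tsdf, aug, step = step)

    ag_zero_grads(params)
    out <- forward_network(model, batch$img$channels)
    loss <- ag_combined_loss(out$probs, out$tsdf, batch$labels, batch$tsdf,
                             cfg$loss_weights)
    if (!is.finite(loss$value))
      stopf("non-finite loss at step %d (fold %d)", step, split$fold_id)
    ag_backward(loss)
    opt <- adamw_step(params, opt, cfg$lr, cfg$weight_decay)

    rec <- list(step = step, loss = loss$value, val_dice = NA_real_)
    if (step %% eval_every == 0L || step == total_steps) {
      vd <- validation_dice(model, val_cases, cfg)
      rec$val_dice <- vd
      if (!is.na(vd) && vd > best) {
        best <- vd
        best_weights <- lapply(params, function(p) p$value)
        if (!is.null(ckpt_path))
          save_checkpoint(model, ckpt_path,
                          meta = list(val_dice = vd, step = step,
                                      fold = split$fold_id))
      }
      if (verbose)
        message(sprintf("fold %d step %d loss %.4f val dice %.4f",
                        split$fold_id, step, loss$value, vd))
    }
    history[[length(history) + 1L]] <- rec
  }

  if (!is.null(best_weights))
    for (nm in names(params)) params[[nm]]$value <- best_weights[[nm]]
  hist_df <- do.call(rbind, lapply(history, function(r)
    data.frame(step = r$step, loss = r$loss, val_dice = r$val_dice)))
  list(model = model, history = hist_df,
       best_val_dice = if (is.finite(best)) best else NA_real_,
       checkpoint = ckpt_path)
}
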