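# Variable-size volume prediction: overlapping z windows with a plateau/taper
# weighting profile, explicit sum-of-weights normalization, and late-fusion
# ensembling over cross-validation fold models.

#' Probability volume container
#'
#' @param probs `(class, z, y, x)` array of per-voxel class probabilities.
#' @param spacing `(sx, sy, sz)` spacing in mm.
#' @return object of class `prob_volume`.
#' @export
prob_volume <- function(probs, spacing = c(1, 1, 1)) {
  assert_that(length(dim(probs)) == 4L, "probs must be (class, z, y, x)")
  structure(list(probs = probs, spacing = as.numeric(spacing)),
            class = "prob_volume")
}

#' @export
print.prob_volume <- function(x, ...) {
  cat(sprintf("<prob_volume> %d classes, %s voxels (z,y,x)\n",
              dim(x$probs)[1], paste(dim(x$probs)[-1], collapse = "x")))
  invisible(x)
}

#' Slice weighting profile for sliding-window aggregation
#'
#' Full weight on the central `plateau` slices; a linear ramp
#' `w[i] = (i + 1) / (taper + 1)` over the `taper` leading slices, mirrored at
#' the tail — weights approach but never reach zero, so every slice retains
#' influence. A cosine ramp is available via `shape = "cosine"`.
#'
#' @param crop_z window extent in slices (default 32).
#' @param plateau central full-weight slices (default 16).
#' @param taper ramp slices per side (default 8); must satisfy
#'   `plateau + 2 * taper == crop_z`.
#' @param shape `"linear"` or `"cosine"` ramp.
#' @return numeric vector of length `crop_z`.
#' @export
make_weight_profile <- function(crop_z = 32L, plateau = 16L, taper = 8L,
                                shape = c("linear", "cosine")) {
  shape <- match.arg(shape)
  assert_that(plateau + 2L * taper == crop_z,
              "inconsistent profile geometry: plateau + 2*taper must equal crop_z")
  ramp <- if (taper == 0L) numeric(0)
  else if (shape == "linear") seq_len(taper) / (taper + 1)
  else (1 - cos(pi * seq_len(taper) / (taper + 1))) / 2
  w <- c(ramp, rep(1, plateau), rev(ramp))
  stopifnot(length(w) == crop_z)
  w
}

# Evaluate a model (or a plain function used as a stub) on a composite crop,
# returning the (class, z, y, x) probability array.
predict_crop <- function(model, x) {
  if (is.function(model)) return(model(x))
  forward_network(model, x)$probs$value
}

model_n_classes <- function(model, x) {
  dim(predict_crop(model, x))[1]
}

#' Sliding-window prediction over a full volume
#'
#' Windows of `crop_z` slices (full frame in-plane) are placed with stride
#' `crop_z * (1 - overlap)` along z, the final window snapped to the last
#' slice. Per-voxel probabilities are aggregated as
#' `sum(window prob * w) / sum(w)` using the plateau/taper profile and
#' renormalized to sum to 1. Volumes thinner than one window are zero-padded
#' (image fill -1), predicted in one window and un-padded.
#'
#' @param v a `multiwindow_volume` (use [make_composite()] first).
#' @param model a `lobeseg_model`, or a function `(3, crop_z, y, x) ->
#'   (classes, crop_z, y, x)` (useful as a stub).
#' @param overlap fractional z overlap between consecutive windows.
#' @param crop_z window extent in slices.
#' @param taper taper length of the weight profile per side.
#' @param shape taper shape, see [make_weight_profile()].
#' @return a [prob_volume()].
#' @export
sliding_window_predict <- function(v, model, overlap = 0.75, crop_z = 32L,
                                   taper = 8L, shape = "linear") {
  assert_that(inherits(v, "multiwindow_volume"), "v must be a multiwindow_volume")
  assert_that(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  x <- v$channels
  d <- dim(x)[-1]
  Z <- d[1]
  pad <- max(0L, crop_z - Z)
  if (pad > 0) {
    xp <- array(FILL_IMAGE, dim = c(dim(x)[1], crop_z, d[2], d[3]))
    xp[, seq_len(Z), , ] <- x
    x <- xp
    Zp <- crop_z
  } else Zp <- Z
  stride <- max(1L, as.integer(round(crop_z * (1 - overlap))))
  starts <- unique(c(seq(0L, Zp - crop_z, by = stride), Zp - crop_z))
  w <- make_weight_profile(crop_z, crop_z - 2L * taper, taper, shape)

  first <- predict_crop(model, x[, starts[1] + seq_len(crop_z), , , drop = FALSE])
  C <- dim(first)[1]
  acc <- array(0, dim = c(C, Zp, d[2], d[3]))
  wsum <- numeric(Zp)
  for (si in seq_along(starts)) {
    s <- starts[si]
    p <- if (si == 1L) first
         else predict_crop(model, x[, s + seq_len(crop_z), , , drop = FALSE])
    for (i in seq_len(crop_z)) {
      acc[, s + i, , ] <- acc[, s + i, , ] + w[i] * p[, i, , ]
      wsum[s + i] <- wsum[s + i] + w[i]
    }
  }
  for (i in seq_len(Zp)) acc[, i, , ] <- acc[, i, , ] / wsum[i]
  acc <- acc[, seq_len(Z), , , drop = FALSE]
  # per-voxel renormalization
  m <- matrix(acc, nrow = C)
  cs <- colSums(m)
  cs[cs == 0] <- 1
  m <- m / rep(cs, each = C)
  dim(m) <- c(C, Z, d[2], d[3])
  prob_volume(m, v$spacing)
}

#' Late-fusion ensemble prediction
#'
#' Runs [sliding_window_predict()] for every model and averages the
#' probability volumes voxelwise (arithmetic mean), then renormalizes.
#'
#' @param v a `multiwindow_volume`.
#' @param models non-empty list of models (e.g. the five fold checkpoints).
#' @param ... passed to [sliding_window_predict()].
#' @return a [prob_volume()].
#' @export
ensemble_predict <- function(v, models, ...) {
  assert_that(is.list(models) && length(models) >= 1L,
              "at least one model is required")
  acc <- NULL
  for (m in models) {
    pv <- sliding_window_predict(v, m, ...)
    acc <- if (is.null(acc)) pv$probs else acc + pv$probs
  }
  acc <- acc / length(models)
  C <- dim(acc)[1]
  mm <- matrix(acc, nrow = C)
  cs <- colSums(mm)
  cs[cs == 0] <- 1
  mm <- mm / rep(cs, each = C)
  dim(mm) <- dim(acc)
  prob_volume(mm, v$spacing)
}

#' Hard labels from a probability volume
#'
#' Per-voxel argmax; ties break toward the lowest class index, so background
#' wins a full tie.
#'
#' @param p a [prob_volume()].
#' @return a [label_volume()].
#' @export
argmax_labels <- function(p) {
  assert_that(inherits(p, "prob_volume"), "p must be a prob_volume")
  C <- dim(p$probs)[1]
  m <- matrix(p$probs, nrow = C)
  lab <- rep(0L, ncol(m))
  best <- m[1, ]
  if (C > 1) for (c in 2:C) {
    better <- m[c, ] > best
    lab[better] <- c - 1L
    best[better] <- m[c, better]
  }
  dim(lab) <- dim(p$probs)[-1]
  label_volume(lab, spacing = p$spacing)
}
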