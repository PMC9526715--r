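# Training objective: weighted combination of masked categorical
# cross-entropy, generalized soft Dice (background included, class weights
# 1/(sum g)^2), and an L1 penalty on the t-SDF regression head. Voxels
# carrying the ignore label contribute to no component, neither in value nor
# in gradient.

LOSS_EPS <- 1e-6
CE_EPS <- 1e-7

#' Loss component weights
#'
#' @param w_ce weight of the cross-entropy term.
#' @param w_dice weight of the generalized soft Dice term.
#' @param w_l1 weight of the t-SDF L1 term.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(w_ce = 1, w_dice = 1, w_l1 = 1) {
  assert_that(all(c(w_ce, w_dice, w_l1) >= 0) && (w_ce + w_dice + w_l1) > 0,
              "weights must be >= 0 with a positive sum")
  structure(list(w_ce = w_ce, w_dice = w_dice, w_l1 = w_l1),
            class = "loss_weights")
}

probs_array <- function(probs) {
  if (inherits(probs, "prob_volume")) probs$probs else probs
}

loss_inputs <- function(probs, lv) {
  p <- probs_array(probs)
  assert_that(length(dim(p)) == 4L, "probabilities must be (class, z, y, x)")
  assert_that(inherits(lv, "label_volume"), "lv must be a label_volume")
  assert_that(identical(dim(p)[-1], dim(lv$labels)),
              "probabilities and labels must be aligned")
  lab <- as.vector(lv$labels)
  keep <- lab != lv$ignore_value
  assert_that(any(keep), "undefined loss: all voxels carry the ignore label")
  list(p = p, C = dim(p)[1], lab = lab, keep = keep)
}

#' Masked categorical cross-entropy
#'
#' Mean over non-ignore voxels of `-log p(true class)`.
#'
#' @param probs per-voxel class probabilities, `(class, z, y, x)` array or
#'   `prob_volume`.
#' @param lv a [label_volume()] with the true classes.
#' @return scalar loss.
#' @export
masked_cross_entropy <- function(probs, lv) {
  io <- loss_inputs(probs, lv)
  m <- matrix(io$p, nrow = io$C)
  idx <- which(io$keep)
  pt <- m[cbind(io$lab[idx] + 1L, idx)]
  mean(-log(pmax(pt, CE_EPS)))
}

# One-hot encoding of kept voxels; ignore voxels get all-zero rows so they
# drop out of every sum.
onehot_masked <- function(lab, keep, C) {
  g <- matrix(0, nrow = C, ncol = length(lab))
  idx <- which(keep)
  g[cbind(lab[idx] + 1L, idx)] <- 1
  g
}

gdl_terms <- function(probs, lv) {
  io <- loss_inputs(probs, lv)
  m <- matrix(io$p, nrow = io$C)
  m[, !io$keep] <- 0                       # ignore voxels leave all sums
  g <- onehot_masked(io$lab, io$keep, io$C)
  sg <- rowSums(g)
  w <- 1 / (sg * sg + LOSS_EPS)
  num <- sum(w * rowSums(m * g))
  den <- sum(w * (rowSums(m) + sg))
  list(io = io, m = m, g = g, w = w, num = num, den = den)
}

#' Generalized soft Dice loss
#'
#' `1 - (2 * sum_c w_c sum_v p g + eps) / (sum_c w_c sum_v (p + g) + eps)`
#' over all classes including background, with `w_c = 1 / ((sum_v g)^2 + eps)`.
#' Exactly 0 for a perfect one-hot prediction.
#'
#' @inheritParams masked_cross_entropy
#' @return scalar loss in `[~0, ~1]`.
#' @export
generalized_soft_dice <- function(probs, lv) {
  t <- gdl_terms(probs, lv)
  1 - (2 * t$num + LOSS_EPS) / (t$den + LOSS_EPS)
}

#' L1 loss for the t-SDF regression head
#'
#' Mean absolute difference over all t-SDF channels and non-ignore voxels.
#' The target field is defined everywhere, so no class masking is applied.
#'
#' @param pred predicted t-SDF array `(channel, z, y, x)` in `[-1, 1]`.
#' @param target a `tsdf_volume` or aligned array.
#' @param lv a [label_volume()] supplying the ignore mask.
#' @return scalar loss.
#' @export
l1_tsdf <- function(pred, target, lv) {
  tg <- if (inherits(target, "tsdf_volume")) target$fields else target
  assert_that(identical(dim(pred), dim(tg)), "prediction/target shape mismatch")
  assert_that(inherits(lv, "label_volume"), "lv must be a label_volume")
  assert_that(identical(dim(pred)[-1], dim(lv$labels)),
              "t-SDF grids and labels must be aligned")
  keep <- as.vector(lv$labels) != lv$ignore_value
  assert_that(any(keep), "undefined loss: all voxels carry the ignore label")
  C <- dim(pred)[1]
  dm <- matrix(abs(pred - tg), nrow = C)
  mean(dm[, keep, drop = FALSE])
}

#' Combined segmentation + regression loss
#'
#' `w_ce * CE + w_dice * GDL + w_l1 * L1`.
#'
#' @inheritParams l1_tsdf
#' @param probs class probabilities `(class, z, y, x)`.
#' @param tsdf_pred t-SDF prediction `(channel, z, y, x)`.
#' @param tsdf_target the `tsdf_volume` target.
#' @param w a [loss_weights()].
#' @return scalar loss.
#' @export
combined_loss <- function(probs, tsdf_pred, lv, tsdf_target, w = loss_weights()) {
  assert_that(inherits(w, "loss_weights"), "w must be loss_weights")
  total <- 0
  if (w$w_ce > 0) total <- total + w$w_ce * masked_cross_entropy(probs, lv)
  if (w$w_dice > 0) total <- total + w$w_dice * generalized_soft_dice(probs, lv)
  if (w$w_l1 > 0) total <- total + w$w_l1 * l1_tsdf(tsdf_pred, tsdf_target, lv)
  total
}

# --- autograd wrappers (closed-form gradients w.r.t. the head outputs) ------

ag_masked_ce <- function(probs_node, lv) {
  val <- masked_cross_entropy(probs_node$value, lv)
  grad_fn <- function() {
    p <- probs_node$value
    C <- dim(p)[1]
    m <- matrix(p, nrow = C)
    lab <- as.vector(lv$labels)
    keep <- lab != lv$ignore_value
    idx <- which(keep)
    g <- matrix(0, nrow = C, ncol = length(lab))
    pt <- m[cbind(lab[idx] + 1L, idx)]
    g[cbind(lab[idx] + 1L, idx)] <- -1 / (pmax(pt, CE_EPS) * length(idx))
    dim(g) <- dim(p)
    g
  }
  ag_scalar(val, probs_node, grad_fn)
}

ag_soft_dice <- function(probs_node, lv) {
  t <- gdl_terms(probs_node$value, lv)
  val <- 1 - (2 * t$num + LOSS_EPS) / (t$den + LOSS_EPS)
  grad_fn <- function() {
    dden <- t$den + LOSS_EPS
    # dL/dp = -(2 w g * dden - (2 num + eps) * w) / dden^2 on kept voxels
    gm <- -(2 * t$w * t$g * dden - (2 * t$num + LOSS_EPS) * t$w) / (dden * dden)
    gm[, !t$io$keep] <- 0
    dim(gm) <- dim(probs_node$value)
    gm
  }
  ag_scalar(val, probs_node, grad_fn)
}

ag_l1_tsdf <- function(tsdf_node, tsdf_target, lv) {
  tg <- if (inherits(tsdf_target, "tsdf_volume")) tsdf_target$fields else tsdf_target
  val <- l1_tsdf(tsdf_node$value, tg, lv)
  grad_fn <- function() {
    keep <- as.vector(lv$labels) != lv$ignore_value
    C <- dim(tg)[1]
    g <- matrix(sign(tsdf_node$value - tg), nrow = C)
    g[, !keep] <- 0
    g <- g / (C * sum(keep))
    dim(g) <- dim(tg)
    g
  }
  ag_scalar(val, tsdf_node, grad_fn)
}

ag_combined_loss <- function(probs_node, tsdf_node, lv, tsdf_target, w) {
  nodes <- list()
  weights <- numeric(0)
  if (w$w_ce > 0) { nodes <- c(nodes, list(ag_masked_ce(probs_node, lv))); weights <- c(weights, w$w_ce) }
  if (w$w_dice > 0) { nodes <- c(nodes, list(ag_soft_dice(probs_node, lv))); weights <- c(weights, w$w_dice) }
  if (w$w_l1 > 0) { nodes <- c(nodes, list(ag_l1_tsdf(tsdf_node, tsdf_target, lv))); weights <- c(weights, w$w_l1) }
  ag_scale_add(nodes, weights)
}

# --- monitoring metrics ------------------------------------------------------

#' Soft Dice per class
#'
#' `2 * sum(p*g) / (sum(p) + sum(g))` per class over non-ignore voxels;
#' classes empty in both prediction and reference score 1.
#'
#' @inheritParams masked_cross_entropy
#' @return named numeric vector (background, right_lobe, left_lobe).
#' @export
soft_dice_per_class <- function(probs, lv) {
  io <- loss_inputs(probs, lv)
  m <- matrix(io$p, nrow = io$C)
  m[, !io$keep] <- 0
  g <- onehot_masked(io$lab, io$keep, io$C)
  num <- 2 * rowSums(m * g)
  den <- rowSums(m) + rowSums(g)
  out <- ifelse(den == 0, 1, num / den)
  names(out) <- names(LOBE_CLASS_MAP)[seq_len(io$C)]
  out
}

#' Soft Dice of the combined foreground (whole liver)
#'
#' Sums the two lobe probabilities into a single foreground probability and
#' scores it against the union of the lobe labels.
#'
#' @inheritParams masked_cross_entropy
#' @return scalar soft Dice.
#' @export
foreground_soft_dice <- function(probs, lv) {
  io <- loss_inputs(probs, lv)
  m <- matrix(io$p, nrow = io$C)
  pfg <- colSums(m[-1, , drop = FALSE])
  pfg[!io$keep] <- 0
  gfg <- as.numeric(io$lab %in% c(1L, 2L) & io$keep)
  den <- sum(pfg) + sum(gfg)
  if (den == 0) return(1)
  2 * sum(pfg * gfg) / den
}
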