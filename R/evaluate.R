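# Volumetry and agreement analytics: overlap metrics with ignore handling,
# volumes in ml, VD/RVD, majority-vote standard of reference, Bland-Altman
# bias/limits of agreement, OLS regression, reader agreement matrix, and a
# Shapiro-Wilk normality check.
#
# Structure selectors: class 1 = right lobe, class 2 = left lobe, and the
# "liver" structure is the union of both lobe classes.

structure_mask <- function(labels, class_id) {
  if (identical(class_id, "liver")) labels == 1L | labels == 2L
  else labels == as.integer(class_id)
}

#' Overlap metrics between a predicted and a reference label map
#'
#' Voxels carrying the reference's ignore value are excluded from TP/FP/FN
#' counting. If both masks are empty all three metrics are 1 by convention.
#'
#' @param pred predicted [label_volume()].
#' @param ref reference [label_volume()] (may contain ignore voxels).
#' @param class_id 1 (right lobe), 2 (left lobe) or `"liver"` (union of both).
#' @return named vector `(dice, precision, recall)`.
#' @export
overlap_metrics <- function(pred, ref, class_id = "liver") {
  assert_that(inherits(pred, "label_volume") && inherits(ref, "label_volume"),
              "pred and ref must be label_volumes")
  assert_that(identical(dim(pred$labels), dim(ref$labels)),
              "pred and ref must be aligned")
  keep <- ref$labels != ref$ignore_value
  a <- structure_mask(pred$labels, class_id) & keep
  b <- structure_mask(ref$labels, class_id) & keep
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  if (tp + fp + fn == 0) return(c(dice = 1, precision = 1, recall = 1))
  c(dice = 2 * tp / (2 * tp + fp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Structure volume in milliliters
#'
#' `voxel count * sx * sy * sz / 1000`.
#'
#' @param lv a [label_volume()].
#' @param class_id as in [overlap_metrics()].
#' @return volume in ml.
#' @export
volume_ml <- function(lv, class_id = "liver") {
  assert_that(inherits(lv, "label_volume"), "lv must be a label_volume")
  sum(structure_mask(lv$labels, class_id)) * prod(lv$spacing) / 1000
}

#' Volume difference and relative volume difference
#'
#' Signed convention `pred - ref`: positive when the tool over-predicts.
#'
#' @param pred_ml predicted volume (ml).
#' @param ref_ml reference volume (ml); must be positive for RVD.
#' @param absolute report absolute differences instead of signed.
#' @return named vector `(vd_ml, rvd_pct)`.
#' @export
vd_rvd <- function(pred_ml, ref_ml, absolute = FALSE) {
  assert_that(ref_ml > 0, "RVD undefined for a zero reference volume")
  vd <- pred_ml - ref_ml
  if (absolute) vd <- abs(vd)
  c(vd_ml = vd, rvd_pct = 100 * vd / ref_ml)
}

#' Majority-vote standard of reference
#'
#' Per voxel, the label chosen by a strict majority of readers (for three
#' readers: any label with at least two votes); voxels without majority are
#' set to the ignore value.
#'
#' @param readers list of aligned [label_volume()]s (>= 2 readers).
#' @return a [label_volume()] with ignore voxels where no majority exists.
#' @export
majority_vote_sor <- function(readers) {
  assert_that(is.list(readers) && length(readers) >= 2L, "need >= 2 readers")
  d <- dim(readers[[1]]$labels)
  for (r in readers)
    assert_that(identical(dim(r$labels), d), "reader volumes must be aligned")
  n <- length(readers)
  labs <- vapply(readers, function(r) as.vector(r$labels), integer(prod(d)))
  vals <- sort(unique(as.vector(labs)))
  best <- rep(0L, nrow(labs))
  best_cnt <- rep(0L, nrow(labs))
  for (v in vals) {
    cnt <- rowSums(labs == v)
    better <- cnt > best_cnt
    best[better] <- v
    best_cnt[better] <- cnt[better]
  }
  ignore <- readers[[1]]$ignore_value
  out <- ifelse(best_cnt > n / 2, best, ignore)
  out <- as.integer(out)
  dim(out) <- d
  label_volume(out, readers[[1]]$spacing, readers[[1]]$origin,
               readers[[1]]$direction, ignore)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = pred - ref`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample standard deviation).
#'
#' @param pred_mls,ref_mls equal-length numeric vectors (n >= 2).
#' @return named vector `(bias, loa_low, loa_high)`.
#' @export
bland_altman <- function(pred_mls, ref_mls) {
  assert_that(length(pred_mls) == length(ref_mls) && length(pred_mls) >= 2,
              "need two equal-length samples with n >= 2")
  d <- pred_mls - ref_mls
  bias <- mean(d)
  s <- sd(d)
  c(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Ordinary least squares agreement fit
#'
#' Simple linear regression `pred ~ ref` with R-squared and the regression
#' F-test p-value.
#'
#' @param pred_mls,ref_mls numeric vectors, n >= 3, `ref` with nonzero
#'   variance.
#' @return named vector `(slope, intercept, r2, f_pvalue)`.
#' @export
ols_fit <- function(pred_mls, ref_mls) {
  assert_that(length(pred_mls) == length(ref_mls) && length(pred_mls) >= 3,
              "need n >= 3")
  assert_that(sd(ref_mls) > 0, "degenerate fit: reference has zero variance")
  fit <- lm(pred_mls ~ ref_mls)
  # R^2 and the F statistic are computed from the sums of squares directly:
  # summary.lm() is unreliable at the degenerate extremes (constant response,
  # perfect fit) that the agreement analysis can legitimately produce
  n <- length(pred_mls)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((pred_mls - mean(pred_mls))^2)
  if (ss_tot <= 1e-12) {
    r2 <- 0                      # constant response: no explained variance
    fp <- NA_real_
  } else if (ss_res <= 1e-12 * ss_tot) {
    r2 <- 1                      # numerically perfect fit
    fp <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
    fstat <- (ss_tot - ss_res) / (ss_res / (n - 2))
    fp <- unname(pf(fstat, 1, n - 2, lower.tail = FALSE))
  }
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = r2, f_pvalue = fp)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard test, exposed for the volumetry report.
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return named vector `(W, pvalue)`.
#' @export
shapiro_wilk <- function(values) {
  assert_that(length(values) >= 3 && length(values) <= 5000,
              "Shapiro-Wilk requires 3 <= n <= 5000")
  assert_that(sd(values) > 0, "Shapiro-Wilk undefined for a constant sample")
  t <- shapiro.test(values)
  c(W = unname(t$statistic), pvalue = t$p.value)
}

#' Reader/tool agreement matrix
#'
#' For every unordered pair of entities (readers R1..Rn and the tool "AI"),
#' the upper triangle holds mean and sd of the pairwise Dice across cases and
#' the lower triangle the R-squared of an OLS fit of the paired volumes.
#' Pairwise reader-vs-reader Dice applies no ignore masking (raw annotations).
#'
#' @param readers_per_case list (cases) of lists (readers) of
#'   [label_volume()]s.
#' @param ai_per_case list (cases) of predicted [label_volume()]s.
#' @param class_id as in [overlap_metrics()].
#' @return object of class `agreement_matrix` with `entities`, `dice_mean`,
#'   `dice_sd` (upper triangles) and `r2` (lower triangle).
#' @export
agreement_matrix <- function(readers_per_case, ai_per_case, class_id = "liver") {
  n_cases <- length(readers_per_case)
  assert_that(n_cases >= 2, "need >= 2 cases for volume R-squared")
  assert_that(length(ai_per_case) == n_cases, "readers/AI case counts differ")
  n_readers <- length(readers_per_case[[1]])
  entities <- c(paste0("R", seq_len(n_readers)), "AI")
  k <- length(entities)
  get_lab <- function(e, case) {
    if (e == k) ai_per_case[[case]] else readers_per_case[[case]][[e]]
  }
  dice_mean <- dice_sd <- r2 <- matrix(NA_real_, k, k,
                                       dimnames = list(entities, entities))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dices <- vapply(seq_len(n_cases), function(case) {
        overlap_metrics(get_lab(j, case), get_lab(i, case), class_id)[["dice"]]
      }, numeric(1))
      vols_i <- vapply(seq_len(n_cases), function(case)
        volume_ml(get_lab(i, case), class_id), numeric(1))
      vols_j <- vapply(seq_len(n_cases), function(case)
        volume_ml(get_lab(j, case), class_id), numeric(1))
      dice_mean[i, j] <- mean(dices)
      dice_sd[i, j] <- sd(dices)
      # squared Pearson correlation == OLS R^2 for a simple regression, and
      # stays defined for two cases
      r2[j, i] <- if (sd(vols_i) > 0 && sd(vols_j) > 0)
        stats::cor(vols_i, vols_j)^2 else NA_real_
    }
  }
  structure(list(entities = entities, dice_mean = dice_mean,
                 dice_sd = dice_sd, r2 = r2, class_id = class_id),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  k <- length(x$entities)
  cat(sprintf("<agreement_matrix> structure: %s (upper: Dice mean +/- sd, lower: volume R^2)\n",
              x$class_id))
  m <- matrix("", k, k, dimnames = list(x$entities, x$entities))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) m[i, j] <- sprintf("%.4f+/-%.4f", x$dice_mean[i, j], x$dice_sd[i, j])
    if (j < i) m[i, j] <- sprintf("%.4f", x$r2[i, j])
  }
  print(m, quote = FALSE)
  invisible(x)
}

#' Per-case segmentation metrics against a reference
#'
#' Convenience bundle of overlap metrics, volumes, and VD/RVD for one
#' structure.
#'
#' @param pred,ref aligned [label_volume()]s.
#' @param class_id as in [overlap_metrics()].
#' @param absolute passed to [vd_rvd()].
#' @return named vector `(dice, precision, recall, pred_ml, ref_ml, vd_ml,
#'   rvd_pct)`.
#' @export
segmentation_metrics <- function(pred, ref, class_id = "liver", absolute = FALSE) {
  om <- overlap_metrics(pred, ref, class_id)
  # volumes are counted on non-ignore voxels of each map independently
  keep_ref <- ref$labels != ref$ignore_value
  pm <- sum(structure_mask(pred$labels, class_id) & keep_ref) * prod(pred$spacing) / 1000
  rm_ <- sum(structure_mask(ref$labels, class_id)) * prod(ref$spacing) / 1000
  vr <- vd_rvd(pm, rm_, absolute)
  c(om, pred_ml = pm, ref_ml = rm_, vr)
}
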