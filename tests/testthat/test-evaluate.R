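lab_of <- function(vec, d = c(2, 3, 4), spacing = c(1, 1, 1)) {
  label_volume(array(as.integer(vec), d), spacing = spacing)
}

test_that("overlap metrics match hand counting", {
  # |pred| = 6, |ref| = 4, overlap 3 in a 24-voxel grid (class 1)
  pred <- rep(0L, 24); pred[1:6] <- 1L
  ref <- rep(0L, 24); ref[4:7] <- 1L
  m <- overlap_metrics(lab_of(pred), lab_of(ref), 1L)
  expect_equal(unname(m), c(0.6, 0.5, 0.75))
  p2 <- lab_of(pred)
  expect_equal(unname(overlap_metrics(p2, p2, 1L)), c(1, 1, 1))
  disj <- rep(0L, 24); disj[10:12] <- 1L
  expect_equal(unname(overlap_metrics(lab_of(pred), lab_of(disj), 1L)),
               c(0, 0, 0))
  # empty-empty convention
  expect_equal(unname(overlap_metrics(lab_of(rep(0L, 24)),
                                      lab_of(rep(0L, 24)), 2L)), c(1, 1, 1))
})

test_that("Dice is symmetric and precision/recall swap under exchange", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_label_volume(c(4, 4, 4), p_ignore = 0)
    b <- random_label_volume(c(4, 4, 4), p_ignore = 0)
    for (cid in list(1L, 2L, "liver")) {
      ma <- overlap_metrics(a, b, cid)
      mb <- overlap_metrics(b, a, cid)
      expect_equal(ma[["dice"]], mb[["dice"]])
      expect_equal(ma[["precision"]], mb[["recall"]])
    }
  }
})

test_that("ignore voxels in the reference drop out of the counting", {
  set.seed(14)
  pred <- random_label_volume(c(4, 4, 4), p_ignore = 0)
  ref <- random_label_volume(c(4, 4, 4), p_ignore = 0)
  base <- overlap_metrics(pred, ref, "liver")
  # brute-force recount excluding nothing (no ignore present)
  a <- pred$labels %in% 1:2; b <- ref$labels %in% 1:2
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b)
  expect_equal(base[["dice"]], 2 * tp / (2 * tp + fp + fn))
  # turning background ref voxels outside pred to ignore changes nothing
  # about TP but removes those voxels: metrics computed on the rest
  ref2 <- ref$labels
  flip <- which(ref$labels == 0L & !a)[1:5]
  ref2[flip] <- 255L
  m2 <- overlap_metrics(pred, label_volume(ref2), "liver")
  expect_equal(m2[["dice"]], base[["dice"]])
})

test_that("volumes in ml follow count times voxel volume", {
  lab <- array(0L, c(10, 10, 10)); lab[seq_len(1000)] <- 1L
  lv <- label_volume(lab, spacing = c(1.5, 1.5, 5.0))
  expect_equal(volume_ml(lv, 1L), 11.25)
  expect_equal(volume_ml(lv, 2L), 0)
  set.seed(15)
  mixed <- random_label_volume(c(6, 6, 6), p_ignore = 0)
  expect_equal(volume_ml(mixed, "liver"),
               volume_ml(mixed, 1L) + volume_ml(mixed, 2L))
})

test_that("VD/RVD use the signed pred - ref convention", {
  expect_equal(unname(vd_rvd(1032, 1000)), c(32, 3.2))
  expect_equal(unname(vd_rvd(1000, 1000)), c(0, 0))
  expect_equal(unname(vd_rvd(900, 1000)), c(-100, -10))
  expect_equal(unname(vd_rvd(900, 1000, absolute = TRUE)), c(100, 10))
  expect_error(vd_rvd(1, 0), "zero reference")
})

test_that("majority voting agrees with the enumerated 27-case truth table", {
  combos <- expand.grid(r1 = 0:2, r2 = 0:2, r3 = 0:2)
  votes_truth <- apply(combos, 1, function(v) {
    tab <- table(v)
    if (max(tab) >= 2) as.integer(names(tab)[which.max(tab)]) else 255L
  })
  readers <- lapply(1:3, function(i)
    lab_of(combos[[i]], d = c(3, 3, 3)))
  sor <- majority_vote_sor(readers)
  expect_equal(as.vector(sor$labels), unname(votes_truth))
  # spot checks of the vote rule
  expect_equal(sor$labels[which(combos$r1 == 1 & combos$r2 == 1 & combos$r3 == 2)[1]], 1L)
  expect_equal(sor$labels[which(combos$r1 == 0 & combos$r2 == 1 & combos$r3 == 2)[1]], 255L)
  expect_equal(sor$labels[which(combos$r1 == 2 & combos$r2 == 2 & combos$r3 == 2)[1]], 2L)
})

test_that("Bland-Altman reproduces closed-form toy cases", {
  expect_equal(unname(bland_altman(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0))
  ba <- bland_altman(c(2, -2), c(0, 0))
  expect_equal(unname(ba), c(0, -1.96 * 2 * sqrt(2), 1.96 * 2 * sqrt(2)))
  ba5 <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_equal(unname(ba5), c(5, 5, 5))
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("OLS agreement fit matches the normal equations", {
  ref <- c(1, 2, 3, 4, 5)
  fit <- ols_fit(2 * ref + 1, ref)
  expect_equal(fit[["slope"]], 2)
  expect_equal(fit[["intercept"]], 1)
  expect_equal(fit[["r2"]], 1)
  # hand-solved normal equations on a 5-point toy set
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 2.9, 4.2, 4.8, 6.1)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  ss_res <- sum((y - ic - sl * x)^2)
  r2 <- 1 - ss_res / sum((y - mean(y))^2)
  fit2 <- ols_fit(y, x)
  expect_equal(fit2[["slope"]], sl)
  expect_equal(fit2[["intercept"]], ic)
  expect_equal(fit2[["r2"]], r2)
  expect_lt(fit2[["f_pvalue"]], 0.01)
  # uncorrelated constant prediction
  expect_equal(ols_fit(rep(3, 5), x)[["r2"]], 0)
  expect_error(ols_fit(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("Shapiro-Wilk wrapper behaves across sample shapes", {
  expect_error(shapiro_wilk(c(1, 1, 1)), "constant")
  sw <- shapiro_wilk(c(-1, 0, 1))
  expect_gt(sw[["pvalue"]], 0.05)
  set.seed(16)
  skewed <- rexp(50)^2
  expect_lt(shapiro_wilk(skewed)[["pvalue"]], 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("the agreement matrix reduces to per-pair metrics", {
  set.seed(17)
  ds <- generate_dataset(3, base_seed = 30, shape = c(8L, 16L, 16L),
                         jitter_mm = 1.5)
  rpc <- lapply(ds, `[[`, "readers")
  apc <- lapply(ds, `[[`, "truth")
  am <- agreement_matrix(rpc, apc, "liver")
  expect_equal(am$entities, c("R1", "R2", "R3", "AI"))
  expect_equal(sum(!is.na(am$dice_mean)), 6)     # C(4, 2) upper entries
  expect_equal(sum(!is.na(am$r2)), 6)
  # compositional check of one upper entry
  d12 <- vapply(1:3, function(i)
    overlap_metrics(rpc[[i]][[2]], rpc[[i]][[1]], "liver")[["dice"]],
    numeric(1))
  expect_equal(am$dice_mean["R1", "R2"], mean(d12))
  expect_equal(am$dice_sd["R1", "R2"], sd(d12))
  # identical entities agree perfectly
  same <- agreement_matrix(lapply(apc, function(t) list(t, t, t)), apc, "liver")
  expect_true(all(same$dice_mean[upper.tri(same$dice_mean)] == 1))
  expect_true(all(same$dice_sd[upper.tri(same$dice_sd)] == 0))
})
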