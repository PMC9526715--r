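onehot_probs <- function(lv, C = 3L, eps = 0) {
  d <- dim(lv$labels)
  p <- array(eps / (C - 1), c(C, d))
  m <- matrix(p, nrow = C)
  lab <- as.vector(lv$labels)
  safe <- ifelse(lab == lv$ignore_value, 0L, lab)
  m[cbind(safe + 1L, seq_along(lab))] <- 1 - eps
  array(m, c(C, d))
}

test_that("cross-entropy is 0 for one-hot truth and ln 3 for uniform guesses", {
  lv <- random_label_volume(c(4, 5, 6), p_ignore = 0)
  expect_equal(masked_cross_entropy(onehot_probs(lv), lv), 0, tolerance = 1e-6)
  uni <- array(1 / 3, c(3, dim(lv$labels)))
  expect_equal(masked_cross_entropy(uni, lv), log(3), tolerance = 1e-12)
})

test_that("flipping a voxel to ignore removes exactly its term", {
  lab <- array(c(0L, 1L), c(2, 1, 1))
  lv <- label_volume(lab)
  p <- array(c(0.7, 0.2, 0.1, 0.25, 0.5, 0.25), c(3, 2, 1, 1))
  expect_equal(masked_cross_entropy(p, lv),
               mean(c(-log(0.7), -log(0.5))), tolerance = 1e-12)
  lab2 <- lab; lab2[2, 1, 1] <- 255L
  expect_equal(masked_cross_entropy(p, label_volume(lab2)),
               -log(0.7), tolerance = 1e-12)
  lab3 <- array(255L, c(2, 1, 1))
  expect_error(masked_cross_entropy(p, label_volume(lab3)), "ignore")
})

test_that("generalized soft Dice hits its extremes", {
  lv <- random_label_volume(c(4, 4, 4), p_ignore = 0)
  expect_equal(generalized_soft_dice(onehot_probs(lv), lv), 0)
  # disjoint hard prediction: predict class (true + 1) mod 3 everywhere
  wrong <- label_volume((lv$labels + 1L) %% 3L)
  expect_equal(generalized_soft_dice(onehot_probs(wrong), lv), 1,
               tolerance = 1e-5)
})

test_that("generalized soft Dice matches the 2-voxel hand computation", {
  # voxel 1 true class A with p = (0.8, 0.2); voxel 2 true class B, p = (0.4, 0.6)
  lab <- array(c(0L, 1L), c(2, 1, 1))
  lv <- label_volume(lab)
  p <- array(c(0.8, 0.2, 0.4, 0.6), c(2, 2, 1, 1))
  # hand arithmetic: sums of g are (1, 1) so both class weights are equal;
  # numerator = 0.8 + 0.6 = 1.4; denominator = (1.2 + 1) + (0.8 + 1) = 4
  expect_equal(generalized_soft_dice(p, lv), 1 - 2 * 1.4 / 4, tolerance = 1e-5)
})

test_that("the t-SDF L1 term is a masked mean absolute difference", {
  lv <- random_label_volume(c(3, 3, 3), p_ignore = 0.2)
  ts <- compute_tsdf(label_volume(array(
    sample(c(0L, 1L, 2L), 27, TRUE), c(3, 3, 3))))
  pred <- ts$fields
  expect_equal(l1_tsdf(pred, ts, lv), 0)
  expect_equal(l1_tsdf(pred + 0.5, ts, lv), 0.5, tolerance = 1e-12)
  set.seed(8)
  q <- array(runif(length(pred), -1, 1), dim(pred))
  keep <- as.vector(lv$labels) != lv$ignore_value
  ref <- mean(matrix(abs(q - ts$fields), nrow = 2)[, keep])
  expect_equal(l1_tsdf(q, ts, lv), ref, tolerance = 1e-12)
})

test_that("combined loss composes its parts with the given weights", {
  set.seed(9)
  lv <- random_label_volume(c(4, 4, 4), p_ignore = 0.1)
  probs <- random_probs(dim(lv$labels))
  target <- compute_tsdf(label_volume(array(
    sample(c(0L, 1L, 2L), 64, TRUE), c(4, 4, 4))))
  pred <- array(runif(length(target$fields), -1, 1), dim(target$fields))
  ce <- masked_cross_entropy(probs, lv)
  gd <- generalized_soft_dice(probs, lv)
  l1 <- l1_tsdf(pred, target, lv)
  expect_equal(combined_loss(probs, pred, lv, target, loss_weights(1, 0, 0)), ce)
  expect_equal(combined_loss(probs, pred, lv, target, loss_weights(0, 0, 1)), l1)
  expect_equal(combined_loss(probs, pred, lv, target, loss_weights(1, 1, 1)),
               ce + gd + l1, tolerance = 1e-12)
  expect_error(loss_weights(0, 0, 0), "positive")
})

test_that("predictions at ignore voxels never change any loss", {
  set.seed(10)
  for (rep in 1:5) {
    lv <- random_label_volume(c(4, 4, 4), p_ignore = 0.25)
    if (!any(lv$labels == 255L)) next
    probs <- random_probs(dim(lv$labels))
    target <- compute_tsdf(label_volume(array(
      sample(c(0L, 1L, 2L), 64, TRUE), c(4, 4, 4))))
    pred <- array(runif(length(target$fields), -1, 1), dim(target$fields))
    probs2 <- probs
    ign <- which(as.vector(lv$labels) == 255L)
    m <- matrix(probs2, nrow = 3)
    m[, ign] <- random_probs(c(length(ign), 1, 1))[, , 1, 1]
    probs2 <- array(m, dim(probs))
    pred2 <- pred
    pm <- matrix(pred2, nrow = 2)
    pm[, ign] <- runif(2 * length(ign), -1, 1)
    pred2 <- array(pm, dim(pred))
    expect_equal(masked_cross_entropy(probs2, lv),
                 masked_cross_entropy(probs, lv), tolerance = 1e-12)
    expect_equal(generalized_soft_dice(probs2, lv),
                 generalized_soft_dice(probs, lv), tolerance = 1e-12)
    expect_equal(l1_tsdf(pred2, target, lv), l1_tsdf(pred, target, lv),
                 tolerance = 1e-12)
  }
})

test_that("loss gradients match finite differences", {
  set.seed(11)
  ns <- asNamespace("lobeseg")
  lv <- random_label_volume(c(3, 4, 4), p_ignore = 0.15)
  probs <- random_probs(dim(lv$labels))
  target <- compute_tsdf(label_volume(array(
    sample(c(0L, 1L, 2L), 48, TRUE), c(3, 4, 4))))
  pred <- array(runif(length(target$fields), -0.9, 0.9), dim(target$fields))

  check <- function(make_node, x0, tol = 1e-5) {
    node <- ns$ag_const(x0); node$requires <- TRUE
    loss <- make_node(node)
    ns$ag_backward(loss)
    eps <- 1e-6
    for (i in sample(length(x0), 10)) {
      xp <- x0; xp[i] <- xp[i] + eps
      xm <- x0; xm[i] <- xm[i] - eps
      num <- (make_node(ns$ag_const(xp))$value -
                make_node(ns$ag_const(xm))$value) / (2 * eps)
      expect_lt(abs(node$grad[i] - num), tol * max(1, abs(num)))
    }
  }
  check(function(n) ns$ag_masked_ce(n, lv), probs)
  check(function(n) ns$ag_soft_dice(n, lv), probs)
  check(function(n) ns$ag_l1_tsdf(n, target, lv), pred)
})
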