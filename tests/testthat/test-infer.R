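test_that("the weight profile has an exact plateau, symmetric linear tapers", {
  w <- make_weight_profile(32L, 16L, 8L)
  expect_length(w, 32)
  expect_true(all(w[9:24] == 1))                 # central 16 slices
  expect_equal(w[1], 1 / 9)                      # nearly zero, never zero
  expect_true(all(w > 0))
  expect_equal(w, rev(w))                        # w[i] == w[31 - i] (0-based)
  expect_true(all(diff(w[1:9]) >= 0))
  expect_error(make_weight_profile(32L, 16L, 7L), "geometry")
  wc <- make_weight_profile(32L, 16L, 8L, shape = "cosine")
  expect_true(all(wc[9:24] == 1) && all(wc > 0))
})

test_that("aggregation reproduces a constant stub field for many volume sizes", {
  stub <- constant_prob_stub(c(0.5, 0.3, 0.2))
  for (Z in c(32L, 40L, 64L, 100L)) {
    v <- structure(list(channels = array(0, c(3, Z, 16, 16)),
                        spacing = c(1.5, 1.5, 5)),
                   class = "multiwindow_volume")
    pv <- sliding_window_predict(v, stub, overlap = 0.75, crop_z = 32L,
                                 taper = 8L)
    expect_equal(dim(pv$probs), c(3L, Z, 16L, 16L))
    for (c in 1:3)
      expect_lt(max(abs(pv$probs[c, , , ] - c(0.5, 0.3, 0.2)[c])), 1e-6)
  }
})

test_that("window placement covers every slice with stride 8", {
  calls <- new.env(); calls$starts <- integer(0)
  probe <- function(x) {
    # channel 1 of the composite carries the (scaled) slice index
    calls$starts <- c(calls$starts, x[1, 1, 1, 1])
    d <- dim(x)[-1]
    array(1 / 3, c(3, d))
  }
  ch <- array(0, c(3, 64, 4, 4))
  for (z in 1:64) ch[1, z, , ] <- z
  v <- structure(list(channels = ch, spacing = c(1, 1, 5)),
                 class = "multiwindow_volume")
  sliding_window_predict(v, probe, overlap = 0.75, crop_z = 32L, taper = 8L)
  expect_equal(calls$starts - 1, c(0, 8, 16, 24, 32))   # 0-based starts
})

test_that("volumes thinner than a window are padded, predicted and un-padded", {
  stub <- constant_prob_stub()
  v <- structure(list(channels = array(0, c(3, 20, 8, 8)),
                      spacing = c(1, 1, 5)),
                 class = "multiwindow_volume")
  pv <- sliding_window_predict(v, stub, crop_z = 32L, taper = 8L)
  expect_equal(dim(pv$probs)[2], 20L)
  expect_lt(max(abs(pv$probs[1, , , ] - 0.5)), 1e-9)
})

test_that("ensembling averages probability fields", {
  pa <- constant_prob_stub(c(0.8, 0.1, 0.1))
  pb <- constant_prob_stub(c(0.2, 0.5, 0.3))
  v <- structure(list(channels = array(0, c(3, 32, 8, 8)),
                      spacing = c(1, 1, 5)),
                 class = "multiwindow_volume")
  one <- sliding_window_predict(v, pa, crop_z = 32L, taper = 8L)
  same <- ensemble_predict(v, list(pa), crop_z = 32L, taper = 8L)
  expect_equal(same$probs, one$probs, tolerance = 1e-12)
  five <- ensemble_predict(v, list(pa, pa, pa, pa, pa), crop_z = 32L, taper = 8L)
  expect_equal(five$probs, one$probs, tolerance = 1e-12)
  two <- ensemble_predict(v, list(pa, pb), crop_z = 32L, taper = 8L)
  expect_lt(max(abs(two$probs[1, , , ] - 0.5)), 1e-9)
  expect_lt(max(abs(two$probs[2, , , ] - 0.3)), 1e-9)
  expect_error(ensemble_predict(v, list()), "at least one")
})

test_that("argmax labelling recovers one-hot fields and breaks ties low", {
  set.seed(12)
  d <- c(4L, 5L, 6L)
  p <- random_probs(d)
  pv <- prob_volume(p, spacing = c(1, 1, 1))
  lab <- argmax_labels(pv)
  m <- matrix(p, nrow = 3)
  ref <- apply(m, 2, which.max) - 1L
  expect_equal(as.vector(lab$labels), ref)
  # uniform tie goes to background
  uni <- prob_volume(array(1 / 3, c(3, 2, 2, 2)))
  expect_true(all(argmax_labels(uni)$labels == 0L))
})

test_that("aggregated probabilities stay normalized under real models", {
  m <- build_network(model_config(depth = 2, base_filters = 8), seed = 4)
  pc <- prepared_phantom()
  pv <- sliding_window_predict(pc$img, m, overlap = 0.75, crop_z = 16L,
                               taper = 4L)
  sums <- colSums(matrix(pv$probs, nrow = 3))
  expect_true(all(abs(sums - 1) < 1e-5))
})
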