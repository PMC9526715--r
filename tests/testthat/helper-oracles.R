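# Shared fixtures and independent oracles for the test suite.

# Brute-force signed EDT: all-pairs nearest-opposite-voxel search in physical
# coordinates (voxel-center metric), vectorized over the distance matrix.
# spacing is (sx, sy, sz) matching the (z, y, x) array axes.
brute_signed_edt <- function(mask, spacing) {
  d <- dim(mask)
  sp_zyx <- rev(spacing)
  coords <- arrayInd(seq_along(mask), d)
  phys <- sweep(coords - 1, 2, sp_zyx, `*`)
  fg <- which(as.vector(mask))
  bg <- which(!as.vector(mask))
  nearest <- function(from, to) {
    pt <- t(phys[to, , drop = FALSE])
    apply(phys[from, , drop = FALSE], 1, function(p)
      sqrt(min(colSums((pt - p)^2))))
  }
  out <- numeric(length(mask))
  out[fg] <- nearest(fg, bg)
  out[bg] <- -nearest(bg, fg)
  array(out, d)
}

# Random small label volume with an optional ignore fraction.
random_label_volume <- function(d = c(6, 7, 5), spacing = c(1, 1, 1),
                                p_ignore = 0.1) {
  probs <- c(0.4, 0.3, 0.2, p_ignore)
  probs[1] <- probs[1] + (0.1 - p_ignore)
  lab <- array(sample(c(0L, 1L, 2L, 255L), prod(d), TRUE, prob = probs), d)
  label_volume(lab, spacing = spacing)
}

# Random valid probability field over C classes.
random_probs <- function(d, C = 3L) {
  p <- array(runif(C * prod(d), 0.01, 1), c(C, d))
  m <- matrix(p, nrow = C)
  m <- m / rep(colSums(m), each = C)
  array(m, c(C, d))
}

# One prepared desk-scale phantom case, memoised across test files.
.fixture_env <- new.env(parent = emptyenv())
prepared_phantom <- function(seed = 7) {
  key <- paste0("case", seed)
  if (is.null(.fixture_env[[key]])) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    .fixture_env[[key]] <- prepare_case(ph$ct, ph$truth,
                                        target_slice_mm = 5,
                                        axial_size = c(64L, 64L))
  }
  .fixture_env[[key]]
}

# Stub model: constant probability field (3 classes) regardless of input.
constant_prob_stub <- function(p3 = c(0.5, 0.3, 0.2)) {
  function(x) {
    d <- dim(x)[-1]
    array(rep(p3, prod(d)), c(length(p3), d))
  }
}
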