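# Synthetic venous-phase abdominal CT phantoms: an anisotropically spaced HU
# volume with a liver-like ellipsoid split by an oblique (optionally gently
# curved) plane into a larger right and smaller left compartment, a heart-like
# confounder blob superior to the liver, a thin diaphragm-like sheet between
# them, additive Gaussian noise, and simulated reader annotations with smooth
# boundary perturbations concentrated near the heart-adjacent top slices.

#' Phantom specification
#'
#' Defaults emulate a venous-phase abdominal CT at 1.5 x 1.5 x 5 mm spacing:
#' liver parenchyma around 120 HU, soft-tissue background around -50 HU, a
#' brighter heart-like blob (150 HU) superior to the liver, and about 65% of
#' the liver volume on the right side of the lobe division.
#'
#' @param shape `(z, y, x)` grid extent in voxels.
#' @param spacing `(sx, sy, sz)` in mm.
#' @param liver_center ellipsoid center in mm (x, y, z), `NULL` for the grid
#'   center shifted inferiorly.
#' @param liver_axes ellipsoid semi-axes in mm (x, y, z), `NULL` for ~70% of
#'   the half-extents.
#' @param right_fraction_target fraction of liver voxels labelled right lobe.
#' @param split_normal in-plane normal (x, y) of the lobe division plane.
#' @param split_bend_mm amplitude of a gentle sinusoidal bend of the division
#'   along z (0 = flat plane).
#' @param hu_liver,hu_background,hu_heart,hu_diaphragm tissue HU levels.
#' @param heart present the heart-like confounder blob?
#' @param diaphragm present the diaphragm-like sheet?
#' @param noise_sd additive Gaussian noise sd in HU.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24L, 64L, 64L), spacing = c(1.5, 1.5, 5.0),
                         liver_center = NULL, liver_axes = NULL,
                         right_fraction_target = 0.65,
                         split_normal = c(1, 0.35), split_bend_mm = 4,
                         hu_liver = 120, hu_background = -50, hu_heart = 150,
                         hu_diaphragm = 60, heart = TRUE, diaphragm = TRUE,
                         noise_sd = 15, seed = 1L) {
  assert_that(length(shape) == 3L && all(shape >= 4), "shape must be (z, y, x) >= 4")
  assert_that(right_fraction_target > 0 && right_fraction_target < 1,
              "right_fraction_target must be in (0, 1)")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  shape <- as.integer(shape)
  ext <- rev(shape) * spacing                     # physical (x, y, z) extent
  if (is.null(liver_center)) liver_center <- ext * c(0.5, 0.5, 0.42)
  if (is.null(liver_axes)) liver_axes <- ext * c(0.36, 0.33, 0.33)
  assert_that(all(liver_center - liver_axes > -1e-9) &&
                all(liver_center + liver_axes < ext + 1e-9),
              "liver ellipsoid must fit inside the grid")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 liver_center = liver_center, liver_axes = liver_axes,
                 right_fraction_target = right_fraction_target,
                 split_normal = split_normal, split_bend_mm = split_bend_mm,
                 hu_liver = hu_liver, hu_background = hu_background,
                 hu_heart = hu_heart, hu_diaphragm = hu_diaphragm,
                 heart = heart, diaphragm = diaphragm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Physical voxel-center coordinate grids (mm) for a (z, y, x) array.
coord_grids <- function(shape, spacing) {
  z <- (seq_len(shape[1]) - 1) * spacing[3]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  x <- (seq_len(shape[3]) - 1) * spacing[1]
  list(z = array(rep(z, times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape),
       x = array(rep(x, each = shape[1] * shape[2]), dim = shape))
}

ellipsoid_mask <- function(g, center_xyz, axes_xyz) {
  ((g$x - center_xyz[1]) / axes_xyz[1])^2 +
    ((g$y - center_xyz[2]) / axes_xyz[2])^2 +
    ((g$z - center_xyz[3]) / axes_xyz[3])^2 <= 1
}

#' Generate a CT phantom with ground-truth lobe labels
#'
#' Deterministic per seed. The right/left division is placed by projecting
#' liver voxels onto the in-plane split normal and cutting at the quantile
#' that realizes the requested right-lobe volume fraction (so the achieved
#' fraction matches the target to within one voxel shell).
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` (a [ct_volume()]) and `truth` (a [label_volume()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  with_seed(derive_seed(spec$seed, "phantom"), {
    g <- coord_grids(spec$shape, spec$spacing)
    liver <- ellipsoid_mask(g, spec$liver_center, spec$liver_axes)
    hu <- array(spec$hu_background, dim = spec$shape)
    ext <- rev(spec$shape) * spec$spacing

    if (spec$diaphragm) {
      # thin dome-like sheet hugging the superior liver surface
      sheet_z <- spec$liver_center[3] + spec$liver_axes[3] * 0.9
      sheet <- abs(g$z - sheet_z) < spec$spacing[3] * 0.6 & !liver
      hu[sheet] <- spec$hu_diaphragm
    }
    if (spec$heart) {
      heart_c <- c(spec$liver_center[1] * 0.8, spec$liver_center[2] * 0.9,
                   min(spec$liver_center[3] + spec$liver_axes[3] * 1.15,
                       ext[3] * 0.92))
      heart_a <- pmin(spec$liver_axes * c(0.45, 0.45, 0.5),
                      c(heart_c[1], heart_c[2], ext[3] - heart_c[3]) * 0.95)
      heart <- ellipsoid_mask(g, heart_c, pmax(heart_a, spec$spacing)) & !liver
      hu[heart] <- spec$hu_heart
    }
    hu[liver] <- spec$hu_liver
    if (spec$noise_sd > 0)
      hu <- hu + array(rnorm(length(hu), sd = spec$noise_sd), dim = spec$shape)

    # lobe split: cut the projection on the in-plane normal at the quantile
    # that realizes the right-lobe volume fraction; optional sinusoidal bend
    nrm <- spec$split_normal / sqrt(sum(spec$split_normal^2))
    proj <- nrm[1] * g$x + nrm[2] * g$y
    bend <- spec$split_bend_mm * sin(2 * pi * g$z / max(ext[3], 1))
    score <- proj + bend
    cut <- quantile(score[liver], probs = 1 - spec$right_fraction_target,
                    names = FALSE, type = 7)
    labels <- array(0L, dim = spec$shape)
    labels[liver & score >= cut] <- 1L
    labels[liver & score < cut] <- 2L

    list(ct = ct_volume(hu, spacing = spec$spacing),
         truth = label_volume(labels, spacing = spec$spacing))
  })
}

#' Reader simulation parameters
#'
#' @param boundary_jitter_mm sd (mm) of the smooth random field perturbing
#'   structure boundaries.
#' @param z_shift_prob per-slice probability of a one-slice boundary shift in
#'   the superior (heart-adjacent) third of the stack.
#' @param seed integer seed.
#' @return object of class `reader_sim`.
#' @export
reader_sim <- function(boundary_jitter_mm = 2, z_shift_prob = 0.3, seed = 1L) {
  assert_that(boundary_jitter_mm >= 0, "jitter must be >= 0")
  assert_that(z_shift_prob >= 0 && z_shift_prob <= 1, "probability in [0, 1]")
  structure(list(boundary_jitter_mm = boundary_jitter_mm,
                 z_shift_prob = z_shift_prob, seed = as.integer(seed)),
            class = "reader_sim")
}

# Smooth random field: white noise on a coarse grid, trilinearly upsampled,
# scaled to the requested sd.
smooth_field <- function(shape, spacing, sd_mm, coarse = 4L) {
  if (sd_mm <= 0) return(array(0, dim = shape))
  cd <- pmax(2L, as.integer(ceiling(shape / coarse)))
  coarse_field <- array(rnorm(prod(cd)), dim = cd)
  r <- cd / shape
  A <- diag(r)
  off <- 0.5 * r - 0.5
  f <- resample_zyx(coarse_field, shape, A, off, nearest = FALSE, clamp = TRUE)
  f * sd_mm / max(sd(as.vector(f)), 1e-9)
}

#' Simulate a human reader annotation
#'
#' The truth boundary is displaced by a smooth random field applied to the
#' signed distances of the liver and of the right/left division, and the
#' superior third of the stack occasionally takes one-slice boundary shifts,
#' mimicking inter-slice ambiguity near the heart.
#'
#' @param truth the ground-truth [label_volume()].
#' @param sim a [reader_sim()].
#' @return a simulated reader [label_volume()] (labels in `{0, 1, 2}`).
#' @export
simulate_reader <- function(truth, sim = reader_sim()) {
  assert_that(inherits(truth, "label_volume"), "truth must be a label_volume")
  assert_that(inherits(sim, "reader_sim"), "sim must be a reader_sim")
  with_seed(derive_seed(sim$seed, "reader"), {
    lab <- truth$labels
    d <- dim(lab)
    if (sim$boundary_jitter_mm > 0) {
      liver <- lab == 1L | lab == 2L
      if (any(liver) && !all(liver)) {
        f1 <- smooth_field(d, truth$spacing, sim$boundary_jitter_mm)
        d_fg <- signed_edt(liver, truth$spacing)
        new_liver <- (d_fg + f1) > 0
        right <- lab == 1L
        new_lab <- array(0L, dim = d)
        if (any(right) && any(lab == 2L)) {
          f2 <- smooth_field(d, truth$spacing, sim$boundary_jitter_mm)
          d_r <- signed_edt(right, truth$spacing)
          d_l <- signed_edt(lab == 2L, truth$spacing)
          new_lab[new_liver] <- ifelse((d_r - d_l + f2)[new_liver] > 0, 1L, 2L)
        } else {
          new_lab[new_liver] <- if (any(right)) 1L else 2L
        }
        lab <- new_lab
      }
    }
    if (sim$z_shift_prob > 0 && d[1] >= 3) {
      top <- seq.int(from = d[1] - floor(d[1] / 3) + 1L, to = d[1])
      for (z in top) {
        if (runif(1) < sim$z_shift_prob) {
          lab[z, , ] <- lab[z - 1L, , ]
        }
      }
    }
    label_volume(lab, truth$spacing, truth$origin, truth$direction,
                 truth$ignore_value)
  })
}

#' Generate a reproducible phantom dataset with simulated readers
#'
#' Geometry (semi-axes, center, right fraction) varies between cases from
#' uniform ranges; each case carries three simulated reader annotations.
#'
#' @param n number of cases.
#' @param base_seed master seed; everything derives from it.
#' @param shape,spacing grid geometry passed to [phantom_spec()].
#' @param n_readers readers simulated per case.
#' @param noise_sd HU noise sd.
#' @param jitter_mm reader boundary jitter.
#' @return list of cases, each `list(id, ct, truth, readers)`.
#' @export
generate_dataset <- function(n, base_seed = 1L, shape = c(24L, 64L, 64L),
                             spacing = c(1.5, 1.5, 5.0), n_readers = 3L,
                             noise_sd = 15, jitter_mm = 2) {
  assert_that(n >= 1, "n must be >= 1")
  lapply(seq_len(n), function(i) {
    cs <- derive_seed(base_seed, "case", i)
    ext <- rev(shape) * spacing
    pars <- with_seed(cs, list(
      axes = ext * c(runif(1, 0.30, 0.40), runif(1, 0.28, 0.38),
                     runif(1, 0.28, 0.38)),
      center = ext * c(runif(1, 0.46, 0.54), runif(1, 0.46, 0.54),
                       runif(1, 0.38, 0.46)),
      frac = runif(1, 0.55, 0.75)))
    axes <- pmin(pars$axes, pmin(pars$center, ext - pars$center) * 0.98)
    spec <- phantom_spec(shape = shape, spacing = spacing,
                         liver_center = pars$center, liver_axes = axes,
                         right_fraction_target = pars$frac,
                         noise_sd = noise_sd, seed = cs)
    ph <- generate_phantom(spec)
    readers <- lapply(seq_len(n_readers), function(r) {
      simulate_reader(ph$truth,
                      reader_sim(boundary_jitter_mm = jitter_mm,
                                 seed = derive_seed(cs, "reader", r)))
    })
    list(id = sprintf("case_%03d", i), ct = ph$ct, truth = ph$truth,
         readers = readers)
  })
}
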