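# Seeded geometric training-time augmentation: in-plane rotation, per-axis
# scaling, and random cropping, applied jointly to the image composite, the
# label map and the t-SDF targets so the three stay aligned.
#
# The t-SDF channels are transformed by interpolation rather than recomputed
# from the transformed labels; with scale factors within 0.8-1.2 the induced
# distance distortion is bounded by 20% and treated as augmentation noise.

# Out-of-field fill values: windowed image -1 (air), labels 0, t-SDF -1.
FILL_IMAGE <- -1
FILL_LABEL <- 0L
FILL_TSDF <- -1

#' Augmentation specification
#'
#' @param rotation_deg half-width of the symmetric in-plane rotation interval
#'   in degrees (angles drawn uniformly from `[-rotation_deg, rotation_deg]`).
#' @param scale_range per-axis scale interval (fractions).
#' @param crop_size `(z, y, x)` crop extent in voxels.
#' @param seed integer seed driving all random draws.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_deg = 10, scale_range = c(0.8, 1.2),
                         crop_size = c(32L, 128L, 128L), seed = 1L) {
  assert_that(is_scalar_number(rotation_deg) && rotation_deg >= 0,
              "rotation_deg must be >= 0")
  assert_that(length(scale_range) == 2L && all(scale_range > 0) &&
                scale_range[1] <= scale_range[2],
              "scale_range must be a positive increasing interval")
  assert_that(length(crop_size) == 3L && all(crop_size >= 1),
              "crop dims must be >= 1")
  structure(list(rotation_deg = rotation_deg, scale_range = as.numeric(scale_range),
                 crop_size = as.integer(crop_size), seed = as.integer(seed)),
            class = "augment_spec")
}

check_triple <- function(img, lv, tsdf) {
  assert_that(inherits(img, "multiwindow_volume") && inherits(lv, "label_volume") &&
                inherits(tsdf, "tsdf_volume"), "expected (composite, labels, tsdf)")
  d <- dim(img$channels)[-1]
  assert_that(identical(d, dim(lv$labels)) && identical(d, dim(tsdf$fields)[-1]),
              "image, labels and t-SDF must be aligned in shape")
  invisible(d)
}

apply_channels <- function(ch4d, odim, A, off, fill, clamp = FALSE) {
  nc <- dim(ch4d)[1]
  out <- array(0, dim = c(nc, odim))
  for (c in seq_len(nc)) {
    out[c, , , ] <- resample_zyx(ch4d[c, , , , drop = TRUE], odim, A, off,
                                 nearest = FALSE, fill = fill, clamp = clamp)
  }
  out
}

transform_triple <- function(img, lv, tsdf, odim, A, off, clamp = FALSE) {
  ch <- apply_channels(img$channels, odim, A, off, FILL_IMAGE, clamp)
  ch[] <- pmin(pmax(ch, -1), 1)
  lab <- resample_zyx(lv$labels, odim, A, off, nearest = TRUE,
                      fill = FILL_LABEL, clamp = clamp)
  storage.mode(lab) <- "integer"
  td <- apply_channels(tsdf$fields, odim, A, off, FILL_TSDF, clamp)
  td[] <- pmin(pmax(td, -1), 1)
  list(img = structure(list(channels = ch, spacing = img$spacing,
                            origin = img$origin, direction = img$direction),
                       class = "multiwindow_volume"),
       labels = label_volume(lab, lv$spacing, lv$origin, lv$direction,
                             lv$ignore_value),
       tsdf = structure(list(fields = td, spacing = tsdf$spacing,
                             truncation_mm = tsdf$truncation_mm),
                        class = "tsdf_volume"))
}

#' Random in-plane rotation of an aligned (image, labels, t-SDF) triple
#'
#' One axial rotation angle is drawn uniformly from the symmetric interval and
#' applied identically to all inputs (image and t-SDF trilinear, labels
#' nearest-neighbour). Rotation is restricted to the axial plane, mimicking
#' rotary patient movement about the table axis.
#'
#' @param img a `multiwindow_volume`.
#' @param lv the aligned [label_volume()].
#' @param tsdf the aligned `tsdf_volume`.
#' @param rotation_deg half-width of the angle interval in degrees.
#' @param angle optional fixed angle in degrees (overrides the random draw).
#' @return list with elements `img`, `labels`, `tsdf`.
#' @export
random_rotate <- function(img, lv, tsdf, rotation_deg = 10, angle = NULL) {
  d <- check_triple(img, lv, tsdf)
  if (is.null(angle)) angle <- runif(1, -rotation_deg, rotation_deg)
  if (angle == 0) return(list(img = img, labels = lv, tsdf = tsdf))
  th <- angle * pi / 180
  sy <- img$spacing[2]; sx <- img$spacing[1]
  Yc <- (d[2] - 1) / 2; Xc <- (d[3] - 1) / 2
  A <- diag(3)
  A[2, 2] <- cos(th);            A[2, 3] <- sin(th) * sx / sy
  A[3, 2] <- -sin(th) * sy / sx; A[3, 3] <- cos(th)
  off <- c(0,
           Yc - A[2, 2] * Yc - A[2, 3] * Xc,
           Xc - A[3, 2] * Yc - A[3, 3] * Xc)
  transform_triple(img, lv, tsdf, d, A, off, clamp = FALSE)
}

#' Random per-axis scaling of an aligned triple
#'
#' Three independent uniform factors (one per axis) resize the grids to
#' `round(dim * factor)` voxels; all inputs share the same factors.
#'
#' @inheritParams random_rotate
#' @param scale_range per-axis factor interval.
#' @param factors optional fixed `(fz, fy, fx)` factors.
#' @return list with elements `img`, `labels`, `tsdf`.
#' @export
random_scale <- function(img, lv, tsdf, scale_range = c(0.8, 1.2), factors = NULL) {
  d <- check_triple(img, lv, tsdf)
  if (is.null(factors)) factors <- runif(3, scale_range[1], scale_range[2])
  assert_that(length(factors) == 3L && all(factors > 0), "need 3 positive factors")
  if (all(factors == 1)) return(list(img = img, labels = lv, tsdf = tsdf))
  odim <- pmax(1L, as.integer(round(d * factors)))
  A <- diag(1 / factors)
  off <- 0.5 / factors - 0.5
  transform_triple(img, lv, tsdf, odim, A, off, clamp = TRUE)
}

pad_triple <- function(img, lv, tsdf, target) {
  d <- dim(lv$labels)
  if (all(d >= target)) return(list(img = img, labels = lv, tsdf = tsdf))
  nd <- pmax(d, target)
  ch <- array(FILL_IMAGE, dim = c(dim(img$channels)[1], nd))
  ch[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- img$channels
  lab <- array(FILL_LABEL, dim = nd)
  lab[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- lv$labels
  storage.mode(lab) <- "integer"
  td <- array(FILL_TSDF, dim = c(dim(tsdf$fields)[1], nd))
  td[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- tsdf$fields
  list(img = structure(list(channels = ch, spacing = img$spacing,
                            origin = img$origin, direction = img$direction),
                       class = "multiwindow_volume"),
       labels = label_volume(lab, lv$spacing, lv$origin, lv$direction,
                             lv$ignore_value),
       tsdf = structure(list(fields = td, spacing = tsdf$spacing,
                             truncation_mm = tsdf$truncation_mm),
                        class = "tsdf_volume"))
}

#' Random crop of an aligned triple
#'
#' One offset is drawn and applied to all inputs; inputs smaller than the crop
#' are padded first (image channels at -1, labels at 0, t-SDF at -1).
#'
#' @inheritParams random_rotate
#' @param crop_size `(z, y, x)` crop extent in voxels.
#' @param offset optional fixed 0-based `(z, y, x)` corner.
#' @return list with elements `img`, `labels`, `tsdf`; shapes equal `crop_size`.
#' @export
random_crop <- function(img, lv, tsdf, crop_size = c(32L, 128L, 128L), offset = NULL) {
  check_triple(img, lv, tsdf)
  crop_size <- as.integer(crop_size)
  padded <- pad_triple(img, lv, tsdf, crop_size)
  d <- dim(padded$labels$labels)
  if (is.null(offset)) {
    offset <- vapply(seq_len(3), function(i) {
      if (d[i] == crop_size[i]) 0L else sample.int(d[i] - crop_size[i] + 1L, 1L) - 1L
    }, integer(1))
  }
  offset <- as.integer(offset)
  assert_that(all(offset >= 0) && all(offset + crop_size <= d), "crop out of bounds")
  iz <- offset[1] + seq_len(crop_size[1])
  iy <- offset[2] + seq_len(crop_size[2])
  ix <- offset[3] + seq_len(crop_size[3])
  img2 <- padded$img; lv2 <- padded$labels; td2 <- padded$tsdf
  img2$channels <- img2$channels[, iz, iy, ix, drop = FALSE]
  lv2$labels <- lv2$labels[iz, iy, ix, drop = FALSE]
  td2$fields <- td2$fields[, iz, iy, ix, drop = FALSE]
  list(img = img2, labels = lv2, tsdf = td2)
}

#' Full augmentation pipeline: rotate, then scale, then crop
#'
#' Deterministic given `spec$seed` and `step`: the RNG stream is derived from
#' both so every training step has its own reproducible draws.
#'
#' @inheritParams random_rotate
#' @param spec an [augment_spec()].
#' @param step integer stream index (e.g. the training step).
#' @return list with elements `img`, `labels`, `tsdf`.
#' @export
augment_triple <- function(img, lv, tsdf, spec, step = 0L) {
  assert_that(inherits(spec, "augment_spec"), "spec must be an augment_spec")
  with_seed(derive_seed(spec$seed, "aug", step), {
    r <- random_rotate(img, lv, tsdf, spec$rotation_deg)
    s <- random_scale(r$img, r$labels, r$tsdf, spec$scale_range)
    random_crop(s$img, s$labels, s$tsdf, spec$crop_size)
  })
}
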