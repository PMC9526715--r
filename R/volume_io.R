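# Volumetric image / label-map containers and NIfTI I/O.
#
# Working conventions used everywhere in the package:
#   * voxel arrays are ordered (z, y, x) — slices are the outer loop of the
#     sliding window, so the slice index comes first;
#   * `spacing` is (sx, sy, sz) in mm, i.e. named after the physical axes,
#     with sz the slice thickness;
#   * HU values are clamped to the 12-bit scanner range [-1024, 3071] on
#     ingest;
#   * label maps use 0 = background, 1 = right lobe, 2 = left lobe and a
#     reserved ignore value (255) for voxels excluded from loss/metrics.

HU_MIN <- -1024
HU_MAX <- 3071
IGNORE_LABEL <- 255L
LOBE_CLASS_MAP <- c(background = 0L, right_lobe = 1L, left_lobe = 2L)

#' CT volume container
#'
#' @param voxels numeric 3D array in (z, y, x) order holding Hounsfield Units.
#' @param spacing numeric length-3 `(sx, sy, sz)` voxel spacing in mm.
#' @param origin numeric length-3 physical origin in mm.
#' @param direction 3x3 orientation matrix (rows/cols of the physical frame).
#' @param clamp clamp voxels into the 12-bit HU range `[-1024, 3071]`?
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3), clamp = TRUE) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "voxels must be a 3D array in (z, y, x) order")
  assert_that(all(dim(voxels) >= 1L), "every axis must have extent >= 1")
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "spacing components must be strictly positive")
  storage.mode(voxels) <- "double"
  if (clamp) voxels[] <- pmin(pmax(voxels, HU_MIN), HU_MAX)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "ct_volume")
}

#' Label volume container
#'
#' @param labels integer 3D array in (z, y, x) order with values in
#'   `{0, 1, 2, ignore_value}`.
#' @param spacing,origin,direction as in [ct_volume()].
#' @param ignore_value reserved integer marking voxels without consensus.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3), ignore_value = IGNORE_LABEL) {
  assert_that(is.array(labels) && length(dim(labels)) == 3L,
              "labels must be a 3D array in (z, y, x) order")
  storage.mode(labels) <- "integer"
  vals <- unique(as.vector(labels))
  ok <- vals %in% c(LOBE_CLASS_MAP, ignore_value)
  assert_that(all(ok), "unexpected label values: %s",
              paste(vals[!ok], collapse = ", "))
  assert_that(length(spacing) == 3L && all(spacing > 0),
              "spacing components must be strictly positive")
  structure(list(labels = labels, class_map = LOBE_CLASS_MAP,
                 ignore_value = as.integer(ignore_value),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 direction = direction),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels (z,y,x), spacing %.3g x %.3g x %.3g mm, HU [%g, %g]\n",
              paste(dim(x$voxels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels),
                      levels = c(LOBE_CLASS_MAP, x$ignore_value)))
  cat(sprintf("<label_volume> %s voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              paste(dim(x$labels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  counts:", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}

vol_array <- function(v) if (inherits(v, "label_volume")) v$labels else v$voxels

nifti_affine <- function(spacing, origin, direction) {
  rbind(cbind(direction %*% diag(spacing), origin), c(0, 0, 0, 1))
}

read_nifti_raw <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  assert_that(length(dim(arr)) == 3L, "expected a 3D image, got %dD", length(dim(arr)))
  aff <- RNifti::xform(img)
  assert_that(all(is.finite(aff)), "non-finite affine metadata in %s", path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  assert_that(all(sp > 0) && abs(det(aff[1:3, 1:3])) > 1e-12,
              "missing or singular affine in %s", path)
  direction <- aff[1:3, 1:3] %*% diag(1 / sp)
  list(zyx = aperm(arr, c(3, 2, 1)), spacing = as.numeric(sp),
       origin = as.numeric(aff[1:3, 4]), direction = direction)
}

write_nifti_raw <- function(zyx, spacing, origin, direction, path, datatype) {
  arr <- aperm(zyx, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  # RNifti composes the stored xform from the (unit-scale) sform rotation and
  # pixdim, so the affine is split into direction + spacing here.
  aff <- rbind(cbind(direction, origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a CT volume from NIfTI
#'
#' Voxels are returned in (z, y, x) order with spacing taken from the affine
#' and values clamped to the 12-bit HU range.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path) {
  raw <- read_nifti_raw(path)
  ct_volume(raw$zyx, spacing = raw$spacing, origin = raw$origin,
            direction = raw$direction, clamp = TRUE)
}

#' Write a CT volume to NIfTI
#'
#' @param v a [ct_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  assert_that(inherits(v, "ct_volume"), "v must be a ct_volume")
  write_nifti_raw(v$voxels, v$spacing, v$origin, v$direction, path, "double")
}

#' Read a label map from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file with integer labels.
#' @return a [label_volume()].
#' @export
read_labelmap <- function(path) {
  raw <- read_nifti_raw(path)
  lab <- raw$zyx
  storage.mode(lab) <- "integer"
  label_volume(lab, spacing = raw$spacing, origin = raw$origin,
               direction = raw$direction)
}

#' Write a label map to NIfTI (unsigned 8-bit)
#'
#' @param lv a [label_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(lv, path) {
  assert_that(inherits(lv, "label_volume"), "lv must be a label_volume")
  write_nifti_raw(lv$labels, lv$spacing, lv$origin, lv$direction, path, "uint8")
}

# Shared affine-resampling helper on a (z, y, x) array. `A` and `off` map
# output voxel indices (0-based) to input voxel indices.
resample_zyx <- function(zyx, odim, A, off, nearest, fill = 0, clamp = TRUE) {
  .resample_affine(zyx, as.integer(odim), A, off,
                   as.integer(nearest), fill, as.integer(clamp))
}

#' Resample to a target slice thickness
#'
#' Only the z grid changes; the number of output slices preserves the physical
#' z extent to within one slice. Intensity volumes are interpolated linearly
#' along z, label maps with nearest neighbour.
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param target_sz target slice thickness in mm.
#' @return resampled object of the same class.
#' @export
resample_slice_thickness <- function(v, target_sz) {
  assert_that(is_scalar_number(target_sz) && target_sz > 0,
              "target_sz must be a positive number")
  is_lab <- inherits(v, "label_volume")
  assert_that(is_lab || inherits(v, "ct_volume"),
              "v must be a ct_volume or label_volume")
  sz <- v$spacing[3]
  if (isTRUE(all.equal(sz, target_sz))) return(v)
  arr <- vol_array(v)
  d <- dim(arr)
  n_out <- max(1L, as.integer(round(d[1] * sz / target_sz)))
  r <- target_sz / sz
  A <- diag(c(r, 1, 1))
  off <- c(0.5 * r - 0.5, 0, 0)
  out <- resample_zyx(arr, c(n_out, d[2], d[3]), A, off,
                      nearest = is_lab, clamp = TRUE)
  new_spacing <- c(v$spacing[1], v$spacing[2], target_sz)
  if (is_lab) {
    storage.mode(out) <- "integer"
    label_volume(out, new_spacing, v$origin, v$direction, v$ignore_value)
  } else {
    ct_volume(out, new_spacing, v$origin, v$direction, clamp = FALSE)
  }
}

#' Resample axial slices to a fixed in-plane matrix
#'
#' Each axial (y, x) slice is resampled to `size = (rows, cols)`; the in-plane
#' spacing is rescaled so the physical extent is preserved. Label maps use
#' nearest-neighbour interpolation.
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param size integer 2-vector `(rows, cols)` for the (y, x) grid.
#' @return resampled object of the same class.
#' @export
resample_axial <- function(v, size = c(256L, 256L)) {
  assert_that(length(size) == 2L && all(size >= 1), "size components must be >= 1")
  is_lab <- inherits(v, "label_volume")
  assert_that(is_lab || inherits(v, "ct_volume"),
              "v must be a ct_volume or label_volume")
  arr <- vol_array(v)
  d <- dim(arr)
  rows <- as.integer(size[1]); cols <- as.integer(size[2])
  if (rows == d[2] && cols == d[3]) return(v)
  ry <- d[2] / rows
  rx <- d[3] / cols
  A <- diag(c(1, ry, rx))
  off <- c(0, 0.5 * ry - 0.5, 0.5 * rx - 0.5)
  out <- resample_zyx(arr, c(d[1], rows, cols), A, off,
                      nearest = is_lab, clamp = TRUE)
  new_spacing <- c(v$spacing[1] * rx, v$spacing[2] * ry, v$spacing[3])
  if (is_lab) {
    storage.mode(out) <- "integer"
    label_volume(out, new_spacing, v$origin, v$direction, v$ignore_value)
  } else {
    ct_volume(out, new_spacing, v$origin, v$direction, clamp = FALSE)
  }
}
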