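# Truncated signed distance field (t-SDF) regression targets.
#
# For each foreground class the signed euclidean distance (in mm, positive
# inside the class region, negative outside) is computed with an exact
# anisotropic distance transform, clipped to +/- 25 mm and rescaled to [-1, 1].
# Distance convention (voxel-center metric): an inside voxel carries the
# distance to the nearest *outside* voxel center and vice versa, which is the
# convention obtained by shifting the binary mask up by one and masking a
# multi-label EDT.

#' Signed euclidean distance transform
#'
#' @param mask logical/0-1 3D array in (z, y, x) order.
#' @param spacing `(sx, sy, sz)` voxel spacing in mm.
#' @return numeric array of signed distances in mm: positive inside the mask
#'   (distance to the nearest background voxel center), negative outside
#'   (distance to the nearest foreground voxel center).
#' @export
signed_edt <- function(mask, spacing = c(1, 1, 1)) {
  assert_that(is.array(mask) && length(dim(mask)) == 3L, "mask must be a 3D array")
  m <- as.logical(mask)
  dim(m) <- dim(mask)
  n_fg <- sum(m)
  assert_that(n_fg > 0 && n_fg < length(m),
              "degenerate mask: needs at least one foreground and one background voxel")
  sp_zyx <- rev(as.numeric(spacing))  # kernels take (sz, sy, sx) along (z, y, x)
  d_to_fg <- sqrt(.edt_sq(m, dim(m), sp_zyx))
  d_to_bg <- sqrt(.edt_sq(!m, dim(m), sp_zyx))
  out <- ifelse(m, d_to_bg, -d_to_fg)
  dim(out) <- dim(m)
  out
}

#' Truncate and rescale a distance map
#'
#' `clip(d, -t_mm, t_mm) / t_mm`, mapping the truncation band to `[-1, 1]`.
#'
#' @param d numeric array of signed distances in mm.
#' @param t_mm truncation distance in mm (default 25).
#' @return array of the same shape with values in `[-1, 1]`.
#' @export
truncate_rescale <- function(d, t_mm = 25) {
  assert_that(is_scalar_number(t_mm) && t_mm > 0, "t_mm must be > 0")
  out <- pmin(pmax(d, -t_mm), t_mm) / t_mm
  dim(out) <- dim(d)
  out
}

#' t-SDF regression targets from a label map
#'
#' One channel per foreground class (right lobe, left lobe). Ignore voxels
#' are treated as background for distance purposes; a class absent from the
#' volume yields an all `-1` channel.
#'
#' @param lv a [label_volume()].
#' @param t_mm truncation distance in mm.
#' @return object of class `tsdf_volume` with `fields` (class, z, y, x),
#'   `spacing` and `truncation_mm`.
#' @export
compute_tsdf <- function(lv, t_mm = 25) {
  assert_that(inherits(lv, "label_volume"), "lv must be a label_volume")
  classes <- LOBE_CLASS_MAP[c("right_lobe", "left_lobe")]
  d <- dim(lv$labels)
  fields <- array(-1, dim = c(length(classes), d))
  for (i in seq_along(classes)) {
    m <- lv$labels == classes[i]
    n_fg <- sum(m)
    if (n_fg == 0) next                       # absent class: all -1
    if (n_fg == length(m)) {                  # degenerate all-foreground
      fields[i, , , ] <- 1
      next
    }
    fields[i, , , ] <- truncate_rescale(signed_edt(m, lv$spacing), t_mm)
  }
  structure(list(fields = fields, spacing = lv$spacing,
                 truncation_mm = t_mm),
            class = "tsdf_volume")
}

#' @export
print.tsdf_volume <- function(x, ...) {
  cat(sprintf("<tsdf_volume> %d classes, %s voxels (z,y,x), truncation %g mm\n",
              dim(x$fields)[1], paste(dim(x$fields)[-1], collapse = "x"),
              x$truncation_mm))
  invisible(x)
}
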