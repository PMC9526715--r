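# Multi-window HU normalization: the network input is a three-channel
# composite of the same volume seen through three clinical display windows.

#' Hounsfield window
#'
#' @param center window center (WC) in HU.
#' @param width window width (WW) in HU; must be positive.
#' @param name optional display name.
#' @return object of class `hu_window`.
#' @export
hu_window <- function(center, width, name = NULL) {
  assert_that(is_scalar_number(center), "center must be a number")
  assert_that(is_scalar_number(width) && width > 0, "width must be > 0")
  structure(list(center = center, width = width, name = name),
            class = "hu_window")
}

#' Default window triple: full 12-bit range, abdominal soft tissue, liver
#'
#' Standard clinical presets; each is configurable in the run configuration.
#'
#' @return list of three [hu_window()] objects.
#' @export
default_windows <- function() {
  list(hu_window(1023.5, 4095, "full_range"),
       hu_window(40, 400, "soft_tissue"),
       hu_window(60, 160, "liver"))
}

#' Apply an HU window
#'
#' Maps HU values linearly so that the window spans `[-1, 1]` and clips:
#' `f(h) = clip((h - WC) / (WW / 2), -1, 1)`.
#'
#' @param v a [ct_volume()] or numeric array of HU values.
#' @param w a [hu_window()].
#' @return numeric array of the same shape with values in `[-1, 1]`.
#' @export
apply_window <- function(v, w) {
  assert_that(inherits(w, "hu_window"), "w must be a hu_window")
  h <- if (inherits(v, "ct_volume")) v$voxels else v
  out <- (h - w$center) / (w$width / 2)
  out[] <- pmin(pmax(out, -1), 1)
  out
}

#' Multi-window composite volume
#'
#' Stacks the three windowed views into a (channel, z, y, x) array, channel
#' order (full range, soft tissue, liver).
#'
#' @param v a [ct_volume()].
#' @param windows list of exactly three [hu_window()] objects.
#' @return object of class `multiwindow_volume` with fields `channels`
#'   (4D array, 3 channels first) and `spacing`.
#' @export
make_composite <- function(v, windows = default_windows()) {
  assert_that(inherits(v, "ct_volume"), "v must be a ct_volume")
  assert_that(is.list(windows) && length(windows) == 3L,
              "exactly three windows are required")
  d <- dim(v$voxels)
  ch <- array(0, dim = c(3L, d))
  for (i in seq_len(3)) ch[i, , , ] <- apply_window(v, windows[[i]])
  structure(list(channels = ch, spacing = v$spacing, origin = v$origin,
                 direction = v$direction),
            class = "multiwindow_volume")
}

#' @export
print.multiwindow_volume <- function(x, ...) {
  cat(sprintf("<multiwindow_volume> %d channels, %s voxels (z,y,x)\n",
              dim(x$channels)[1], paste(dim(x$channels)[-1], collapse = "x")))
  invisible(x)
}
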