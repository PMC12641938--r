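#' Scene-camera view geometry
#'
#' Describes the outward-facing scene camera of the eye tracker: frame
#' resolution in pixels and diagonal field of view in degrees. The default
#' matches a 1280 x 720 scene camera with a 100 degree diagonal FOV.
#' Degrees and pixels are related by a single linear scale factor
#' (small-angle approximation), `deg_per_px = diagonal_fov / diagonal
#' pixel length`, with a shared top-left origin and y pointing down.
#'
#' @param width_px,height_px frame size in pixels (positive).
#' @param diagonal_fov diagonal field of view in degrees, in (0, 180).
#' @return an object of class `view_geometry` with fields `width_px`,
#'   `height_px`, `diagonal_fov` and the derived `deg_per_px`.
#' @examples
#' g <- view_geometry()
#' g$deg_per_px # about 0.068 degrees per pixel
#' @export
view_geometry <- function(width_px = 1280, height_px = 720,
                          diagonal_fov = 100) {
  check_number(width_px, "width_px", lower = 1)
  check_number(height_px, "height_px", lower = 1)
  check_number(diagonal_fov, "diagonal_fov", lower = 0, upper = 180,
               closed_lower = FALSE, closed_upper = FALSE)
  diag_px <- sqrt(width_px^2 + height_px^2)
  structure(list(width_px = width_px, height_px = height_px,
                 diagonal_fov = diagonal_fov,
                 deg_per_px = diagonal_fov / diag_px),
            class = "view_geometry")
}

#' @export
print.view_geometry <- function(x, ...) {
  cat(sprintf("<view_geometry> %d x %d px, %.1f deg diagonal FOV (%.4f deg/px)\n",
              x$width_px, x$height_px, x$diagonal_fov, x$deg_per_px))
  invisible(x)
}

is_view_geometry <- function(x) inherits(x, "view_geometry")

#' Convert between degree and pixel scene coordinates
#'
#' @param xy numeric vector, matrix or data.frame of coordinates (columns
#'   x, y when two-dimensional).
#' @param geometry a [view_geometry()].
#' @return coordinates in the other unit, same shape as the input.
#' @export
deg_to_px <- function(xy, geometry) {
  stopifnot(is_view_geometry(geometry))
  xy / geometry$deg_per_px
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(xy, geometry) {
  stopifnot(is_view_geometry(geometry))
  xy * geometry$deg_per_px
}

#' Frame extent in degrees
#' @param geometry a [view_geometry()].
#' @return c(width_deg, height_deg).
#' @export
frame_extent_deg <- function(geometry) {
  stopifnot(is_view_geometry(geometry))
  c(geometry$width_px, geometry$height_px) * geometry$deg_per_px
}

# Plane angular distance in degrees between point pairs.
angular_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}
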