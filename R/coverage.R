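# Pixel-mask coverage quantification and fixation heatmaps.

BLUE_LABEL <- c(0, 0, 1)   # exact blue label (0, 0, 255) scaled to [0, 1]
COVER_COLOR <- c(1, 0, 0)  # marker paint

#' Create a mask image
#'
#' A mask image is an `height x width x 3` RGB array with values in
#' \[0, 1\]; the model region carries the exact blue label (0, 0, 255).
#'
#' @param geometry a [view_geometry()] giving the frame size.
#' @param model_circle list with `center` (pixel x, y) and `radius`
#'   (pixels); must lie inside the frame. Radius 0 yields no blue pixels.
#' @return an object of class `mask_image` (the RGB array).
#' @examples
#' m <- generate_mask_image(view_geometry(),
#'                          list(center = c(640, 360), radius = 100))
#' sum(is_blue(m)) # about pi * 100^2
#' @export
generate_mask_image <- function(geometry, model_circle) {
  abort_if(!is_view_geometry(geometry), "`geometry` must be a view_geometry")
  ctr <- as.numeric(model_circle$center)
  r <- as.numeric(model_circle$radius)
  check_number(r, "radius", lower = 0)
  w <- geometry$width_px; h <- geometry$height_px
  abort_if(ctr[1] - r < 0 || ctr[1] + r > w || ctr[2] - r < 0 ||
             ctr[2] + r > h,
           "model circle must lie inside the frame")
  img <- array(1, dim = c(h, w, 3))
  if (r > 0) {
    # pixel centers at (col - 0.5, row - 0.5)
    cx <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
    cy <- matrix(seq_len(h) - 0.5, h, w)
    inside <- (cx - ctr[1])^2 + (cy - ctr[2])^2 <= r^2
    for (k in 1:3) {
      plane <- img[, , k]
      plane[inside] <- BLUE_LABEL[k]
      img[, , k] <- plane
    }
  }
  class(img) <- c("mask_image", class(img))
  img
}

#' Classify blue-labeled pixels
#'
#' @param mask a mask image (RGB array in \[0, 1\]).
#' @param color_tol per-channel tolerance for the blue match; 0 (default)
#'   requires the exact label, a positive radius accommodates imported
#'   images with compression noise.
#' @return logical matrix of blue pixels.
#' @export
is_blue <- function(mask, color_tol = 0) {
  abs(mask[, , 1] - BLUE_LABEL[1]) <= color_tol &
    abs(mask[, , 2] - BLUE_LABEL[2]) <= color_tol &
    abs(mask[, , 3] - BLUE_LABEL[3]) <= color_tol
}

#' Paint circular fixation markers over a mask
#'
#' Applies a circular marker of `marker_size` degrees at each fixation
#' centroid, overwriting covered pixels with a non-blue cover color; the
#' input mask is left unmodified. By default `marker_size` is interpreted
#' as the angular *diameter* of the marker (radius `marker_size / 2`);
#' set `size_is` to `"radius"` for the alternative reading. Markers may be
#' placed per fixation centroid (default, sampling-rate invariant) or the
#' caller can pass raw samples restructured as fixations for a per-sample
#' mode. Markers extending beyond the frame are clipped.
#'
#' @param mask a mask image.
#' @param fixations fixation data.frame (centroids in degrees).
#' @param marker_size marker angular size in degrees (default 5).
#' @param geometry a [view_geometry()] for the degree-to-pixel map.
#' @param size_is `"diameter"` (default) or `"radius"`.
#' @return the painted mask image.
#' @export
paint_markers <- function(mask, fixations, marker_size = 5, geometry,
                          size_is = c("diameter", "radius")) {
  size_is <- match.arg(size_is)
  check_number(marker_size, "marker_size", lower = 0, closed_lower = FALSE)
  abort_if(!is_view_geometry(geometry), "`geometry` must be a view_geometry")
  h <- dim(mask)[1]; w <- dim(mask)[2]
  abort_if(h == 0 || w == 0, "mask has zero dimension")
  r_deg <- if (size_is == "diameter") marker_size / 2 else marker_size
  r_px <- r_deg / geometry$deg_per_px
  out <- mask
  if (nrow(fixations) == 0) return(out)
  px <- fixations$centroid_x / geometry$deg_per_px
  py <- fixations$centroid_y / geometry$deg_per_px
  # precompute disk offsets once (pixel-center containment)
  rr <- ceiling(r_px)
  off <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  off <- off[(off$dx)^2 + (off$dy)^2 <= r_px^2, , drop = FALSE]
  r1 <- out[, , 1]; r2 <- out[, , 2]; r3 <- out[, , 3]
  for (i in seq_along(px)) {
    # pixel whose center is nearest the centroid
    c0 <- floor(px[i]) + 1L
    r0 <- floor(py[i]) + 1L
    cols <- c0 + off$dx
    rows <- r0 + off$dy
    ok <- cols >= 1L & cols <= w & rows >= 1L & rows <= h
    idx <- rows[ok] + (cols[ok] - 1L) * h
    r1[idx] <- COVER_COLOR[1]
    r2[idx] <- COVER_COLOR[2]
    r3[idx] <- COVER_COLOR[3]
  }
  out[, , 1] <- r1; out[, , 2] <- r2; out[, , 3] <- r3
  out
}

#' Coverage fraction of the painted mask
#'
#' Quantifies how much of the model region the fixation markers covered:
#' `covered_pixels` counts pixels that are blue in the baseline and
#' non-blue in the painted image. The denominator is the total pixel count
#' of the baseline image by default, or the blue-region pixel count with
#' `denominator = "blue_region"`.
#'
#' @param baseline,painted mask images of equal dimensions.
#' @param denominator `"frame"` (all pixels, default) or `"blue_region"`.
#' @param color_tol blue-classification tolerance, see [is_blue()].
#' @return a list of class `coverage_result` with `covered_fraction`,
#'   `covered_pixels`, `total_pixels`.
#' @export
coverage_fraction <- function(baseline, painted,
                              denominator = c("frame", "blue_region"),
                              color_tol = 0) {
  denominator <- match.arg(denominator)
  abort_if(!identical(dim(baseline), dim(painted)),
           "baseline and painted masks must have equal dimensions")
  blue0 <- is_blue(baseline, color_tol)
  blue1 <- is_blue(painted, color_tol)
  covered <- sum(blue0 & !blue1)
  total <- if (denominator == "frame") length(blue0) else sum(blue0)
  frac <- if (total == 0) 0 else covered / total
  structure(list(covered_fraction = frac, covered_pixels = covered,
                 total_pixels = total),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %.2f%% (%d / %d pixels)\n",
              100 * x$covered_fraction, x$covered_pixels, x$total_pixels))
  invisible(x)
}

#' Fixation heatmap
#'
#' Accumulates an isotropic Gaussian kernel (sd `kernel_sd` degrees) at
#' each fixation location on a pixel grid. Each kernel integrates to its
#' fixation's weight (1 by default, the fixation duration with
#' `weight = "duration"`), so the unnormalized grid total equals the total
#' weight of fixations whose kernels lie within the frame. Set
#' `normalize = TRUE` to rescale the maximum to 1 for rendering.
#'
#' @param fixations fixation data.frame (degrees).
#' @param geometry a [view_geometry()].
#' @param kernel_sd kernel standard deviation, degrees (> 0).
#' @param weight `"count"` or `"duration"`.
#' @param normalize rescale maximum to 1.
#' @param downsample integer pixel stride of the heat grid (1 = full
#'   resolution).
#' @return a numeric matrix (rows = y, cols = x); empty fixations give an
#'   all-zero grid.
#' @export
fixation_heatmap <- function(fixations, geometry, kernel_sd = 1,
                             weight = c("count", "duration"),
                             normalize = FALSE, downsample = 1L) {
  weight <- match.arg(weight)
  check_number(kernel_sd, "kernel_sd", lower = 0, closed_lower = FALSE)
  step <- as.integer(downsample)
  abort_if(step < 1L, "`downsample` must be >= 1")
  h <- as.integer(ceiling(geometry$height_px / step))
  w <- as.integer(ceiling(geometry$width_px / step))
  grid <- matrix(0, h, w)
  if (nrow(fixations) == 0) return(grid)
  s_px <- kernel_sd / geometry$deg_per_px / step
  px <- fixations$centroid_x / geometry$deg_per_px / step
  py <- fixations$centroid_y / geometry$deg_per_px / step
  wts <- if (weight == "count") rep(1, nrow(fixations)) else
    fixations$duration
  ext <- ceiling(4 * s_px)
  for (i in seq_along(px)) {
    c0 <- floor(px[i]) + 1L
    r0 <- floor(py[i]) + 1L
    cols <- max(1L, c0 - ext):min(w, c0 + ext)
    rows <- max(1L, r0 - ext):min(h, r0 + ext)
    if (!length(cols) || !length(rows)) next
    kx <- exp(-((cols - 0.5 - px[i])^2) / (2 * s_px^2))
    ky <- exp(-((rows - 0.5 - py[i])^2) / (2 * s_px^2))
    grid[rows, cols] <- grid[rows, cols] +
      wts[i] * (ky %o% kx) / (2 * pi * s_px^2)
  }
  if (normalize && max(grid) > 0) grid <- grid / max(grid)
  grid
}

#' Read and write mask images as PNG
#'
#' @param mask a mask image (RGB array in \[0, 1\]).
#' @param path file path.
#' @return `read_mask_png` returns a `mask_image`; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- unclass(mask)
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  class(img) <- c("mask_image", class(img))
  img
}

#' Write a heat grid as a CSV matrix
#' @param grid heat matrix from [fixation_heatmap()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(grid, path) {
  write.table(grid, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
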