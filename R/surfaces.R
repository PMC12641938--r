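#' Area-of-interest labels
#'
#' The three scene regions used to partition fixations: the heads-up
#' display, the instrument field (the area of the surgical model) and the
#' peripheral view (everything outside immediate surgical relevance).
#' @return character vector of the three labels, in priority order.
#' @export
aoi_labels <- function() c("HUD", "instrument_field", "peripheral")

#' Labeled surface polygon
#'
#' A surface is a labeled simple polygon in pixel scene coordinates
#' (origin top-left, y down) delimiting one area of interest.
#'
#' @param label one of [aoi_labels()].
#' @param vertices numeric matrix (or coercible) with two columns (x, y in
#'   pixels) and at least three rows; must not self-intersect.
#' @return an object of class `surface`.
#' @export
surface <- function(label, vertices) {
  abort_if(!label %in% aoi_labels(),
           "`label` must be one of: ", paste(aoi_labels(), collapse = ", "))
  vertices <- as.matrix(vertices)
  abort_if(!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3,
           "`vertices` must be a numeric matrix with 2 columns and >= 3 rows")
  abort_if(any(!is.finite(vertices)), "`vertices` must be finite")
  abort_if(polygon_self_intersects(vertices),
           "`vertices` describe a self-intersecting polygon")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(label = label, vertices = vertices), class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  cat(sprintf("<surface> %s, %d vertices, area %.0f px^2\n",
              x$label, nrow(x$vertices), polygon_area(x$vertices)))
  invisible(x)
}

#' Default three-surface scene layout
#'
#' Tiles the scene frame into the three areas of interest: the heads-up
#' display as the top band of the frame, the instrument field as a centered
#' rectangle in the lower part (the surgical model sits below the display),
#' and the peripheral view as the remaining U-shaped region. The three
#' polygons are pairwise disjoint (shared edges resolved by the priority
#' HUD > instrument_field > peripheral) and their union is the full frame.
#'
#' @param geometry a [view_geometry()].
#' @return a named list of three [surface()] objects.
#' @examples
#' s <- generate_surfaces(view_geometry())
#' sum(vapply(s, function(z) polygon_area(z$vertices), 0)) # frame area
#' @export
generate_surfaces <- function(geometry) {
  abort_if(!is_view_geometry(geometry), "`geometry` must be a view_geometry")
  w <- geometry$width_px
  h <- geometry$height_px
  hud <- rbind(c(0, 0), c(w, 0), c(w, 0.55 * h), c(0, 0.55 * h))
  instr <- rbind(c(0.15 * w, 0.55 * h), c(0.85 * w, 0.55 * h),
                 c(0.85 * w, 0.90 * h), c(0.15 * w, 0.90 * h))
  periph <- rbind(c(0, 0.55 * h),
                  c(0.15 * w, 0.55 * h),
                  c(0.15 * w, 0.90 * h),
                  c(0.85 * w, 0.90 * h),
                  c(0.85 * w, 0.55 * h),
                  c(w, 0.55 * h),
                  c(w, h),
                  c(0, h))
  list(HUD = surface("HUD", hud),
       instrument_field = surface("instrument_field", instr),
       peripheral = surface("peripheral", periph))
}

#' Polygon area (shoelace formula)
#' @param vertices two-column matrix of polygon vertices.
#' @return unsigned area.
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1)) # previous vertex
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(vertices) {
  d <- diff(rbind(vertices, vertices[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(vertices))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Segment-pair intersection test for non-adjacent edges (used only to
# validate user-supplied polygons).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]
      c_ <- seg[j, 1:2]; d <- seg[j, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c_[1], c_[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c_[1], c_[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c_[1], c_[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Point-in-polygon test
#'
#' Crossing-number (even-odd ray casting) containment test, vectorized over
#' query points. Points lying exactly on a polygon edge or vertex count as
#' inside.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param vertices two-column vertex matrix of a simple polygon.
#' @param tol absolute tolerance for the on-boundary test.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, vertices, tol = 1e-9) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # boundary: point within tol of segment k
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= tol^2
    # crossing test (half-open rule avoids double counting at vertices)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * dx / ifelse(dy == 0, Inf, dy))
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Rejection-sample a point uniformly inside a polygon, keeping a margin
# from its edges so downstream jitter cannot leak across the boundary.
sample_point_in_polygon <- function(vertices, margin = 0, max_tries = 400) {
  bb <- apply(vertices, 2, range)
  for (i in seq_len(max_tries)) {
    p <- c(runif(1, bb[1, 1] + margin, bb[2, 1] - margin),
           runif(1, bb[1, 2] + margin, bb[2, 2] - margin))
    if (point_in_polygon(p[1], p[2], vertices) &&
        min_edge_distance(p, vertices) >= margin) {
      return(p)
    }
  }
  polygon_centroid(vertices)
}

min_edge_distance <- function(p, vertices) {
  v <- vertices
  n <- nrow(v)
  w <- v[c(2:n, 1), , drop = FALSE]
  dx <- w[, 1] - v[, 1]; dy <- w[, 2] - v[, 2]
  len2 <- pmax(dx^2 + dy^2, 1e-12)
  t <- pmin(1, pmax(0, ((p[1] - v[, 1]) * dx + (p[2] - v[, 2]) * dy) / len2))
  min(sqrt((p[1] - (v[, 1] + t * dx))^2 + (p[2] - (v[, 2] + t * dy))^2))
}

#' Read and write surface definition files
#'
#' Surfaces are stored as a YAML list of `{label, vertices: [[x, y], ...]}`
#' records in pixel coordinates (origin top-left, y down).
#'
#' @param surfaces a list of [surface()] objects.
#' @param path file path.
#' @return `read_surfaces` returns a named list of [surface()] objects;
#'   `write_surfaces` returns `path` invisibly.
#' @export
write_surfaces <- function(surfaces, path) {
  recs <- lapply(surfaces, function(s) {
    list(label = s$label,
         vertices = lapply(seq_len(nrow(s$vertices)),
                           function(i) as.numeric(s$vertices[i, ])))
  })
  yaml::write_yaml(unname(recs), path, precision = 15)
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path) {
  recs <- yaml::read_yaml(path)
  out <- lapply(recs, function(r) {
    surface(r$label, do.call(rbind, lapply(r$vertices, as.numeric)))
  })
  names(out) <- vapply(out, function(s) s$label, "")
  out
}
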