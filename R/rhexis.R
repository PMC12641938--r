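# Capsulorhexis tear geometry: annotations and metrics.

#' Capsulorhexis tear annotation
#'
#' A geometric record of one capsulorhexis attempt, in pixel coordinates
#' (origin top-left, y down): the forceps axis during the tear, the tear
#' displacement vector, the circle traced by the forceps travel path, the
#' ordered tear path polyline, the tear initiation point, the forceps
#' insertion wound point, and the reference length of the full
#' capsulorhexis model (by default its circumference).
#'
#' @param forceps_axis,tear_vector 2 x 2 matrices (two points each, rows =
#'   points); both segments must have nonzero length.
#' @param travel_circle list with `center` (x, y) and `radius` (> 0).
#' @param tear_path ordered polyline, matrix with >= 2 rows.
#' @param initiation_point,wound_point points (x, y).
#' @param model_reference_length positive reference length in pixels.
#' @return an object of class `tear_annotation`.
#' @export
tear_annotation <- function(forceps_axis, tear_vector, travel_circle,
                            tear_path, initiation_point, wound_point,
                            model_reference_length) {
  seg <- function(m, name) {
    m <- as.matrix(m)
    abort_if(!is.numeric(m) || !identical(dim(m), c(2L, 2L)),
             sprintf("`%s` must be a 2 x 2 numeric matrix", name))
    abort_if(sum((m[2, ] - m[1, ])^2) == 0,
             sprintf("`%s` has zero length", name))
    dimnames(m) <- NULL
    m
  }
  forceps_axis <- seg(forceps_axis, "forceps_axis")
  tear_vector <- seg(tear_vector, "tear_vector")
  tear_path <- as.matrix(tear_path)
  abort_if(nrow(tear_path) < 2 || ncol(tear_path) != 2,
           "`tear_path` must have >= 2 points with 2 columns")
  r <- as.numeric(travel_circle$radius)
  check_number(r, "travel_circle$radius", lower = 0, closed_lower = FALSE)
  check_number(model_reference_length, "model_reference_length", lower = 0,
               closed_lower = FALSE)
  structure(list(forceps_axis = forceps_axis,
                 tear_vector = tear_vector,
                 travel_circle = list(center = as.numeric(travel_circle$center),
                                      radius = r),
                 tear_path = unname(tear_path),
                 initiation_point = as.numeric(initiation_point),
                 wound_point = as.numeric(wound_point),
                 model_reference_length = model_reference_length),
            class = "tear_annotation")
}

is_tear_annotation <- function(x) inherits(x, "tear_annotation")

#' Tear angle relative to the forceps
#'
#' The angle between the tear displacement vector and the forceps axis.
#' In the default `"vector"` mode both segments are treated as directed
#' vectors (first point to second) and the angle lies in \[0, 180\]
#' degrees; small angles indicate controlled, tangential tearing aligned
#' with the forceps pull. `"line"` mode ignores direction and folds the
#' angle to \[0, 90\].
#'
#' @param annotation a [tear_annotation()].
#' @param mode `"vector"` (directed, default) or `"line"` (undirected).
#' @return angle in degrees.
#' @examples
#' a <- generate_tear_annotation(study_profiles()$attending, seed = 1)
#' tear_angle(a)
#' @export
tear_angle <- function(annotation, mode = c("vector", "line")) {
  mode <- match.arg(mode)
  abort_if(!is_tear_annotation(annotation),
           "`annotation` must be a tear_annotation")
  v1 <- annotation$forceps_axis[2, ] - annotation$forceps_axis[1, ]
  v2 <- annotation$tear_vector[2, ] - annotation$tear_vector[1, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  abort_if(n1 == 0 || n2 == 0, "segments must have nonzero length")
  cosang <- sum(v1 * v2) / (n1 * n2)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (mode == "line" && ang > 90) ang <- 180 - ang
  ang
}

# Polyline arc length.
polyline_length <- function(path) {
  if (nrow(path) < 2) return(0)
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

#' Tear diameter fraction
#'
#' Arc length of the tear path divided by the reference length of the full
#' capsulorhexis model (stored in the annotation; by convention the model
#' circle circumference, but any reference can be supplied when building
#' the annotation).
#'
#' @param annotation a [tear_annotation()].
#' @return non-negative fraction (0 for a degenerate path).
#' @export
diameter_fraction <- function(annotation) {
  abort_if(!is_tear_annotation(annotation),
           "`annotation` must be a tear_annotation")
  polyline_length(annotation$tear_path) / annotation$model_reference_length
}

#' Tear initiation distance
#'
#' Euclidean distance from the tear initiation point to the forceps
#' insertion wound, normalized by the travel-circle radius. Experts begin
#' the tear close to the wound (small values); novices farther away.
#'
#' @param annotation a [tear_annotation()].
#' @return non-negative fraction of the travel-circle radius.
#' @export
initiation_distance <- function(annotation) {
  abort_if(!is_tear_annotation(annotation),
           "`annotation` must be a tear_annotation")
  sqrt(sum((annotation$initiation_point - annotation$wound_point)^2)) /
    annotation$travel_circle$radius
}

#' Tear circularity (isoperimetric quotient)
#'
#' For a closed (or near-closed) tear path, the isoperimetric quotient
#' `4 * pi * A / P^2` with area `A` (shoelace formula) and perimeter `P`
#' of the closed polygon: 1 for a perfect circle, decreasing with
#' irregularity (a square scores `pi / 4`). Paths whose endpoint gap is
#' below `gap_tol` times the path length are closed by joining the
#' endpoints; wider gaps are rejected.
#'
#' @param tear_path polyline matrix (>= 3 points), or a
#'   [tear_annotation()] whose `tear_path` is used.
#' @param gap_tol endpoint-gap tolerance as a fraction of path length.
#' @return circularity in (0, 1\].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)
#' circularity(cbind(cos(th), sin(th))) # ~= 1
#' @export
circularity <- function(tear_path, gap_tol = 0.1) {
  if (is_tear_annotation(tear_path)) tear_path <- tear_path$tear_path
  path <- as.matrix(tear_path)
  abort_if(nrow(path) < 3, "`tear_path` must have >= 3 points")
  len <- polyline_length(path)
  gap <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  abort_if(gap > gap_tol * len,
           sprintf(paste0("tear path is not closed: endpoint gap %.3f ",
                          "exceeds %.1f%% of path length %.3f"),
                   gap, 100 * gap_tol, len))
  # drop duplicated closing point, then close by construction
  if (gap < 1e-12) path <- path[-nrow(path), , drop = FALSE]
  perim <- polyline_length(rbind(path, path[1, ]))
  area <- polygon_area(path)
  4 * pi * area / perim^2
}

#' Compute all tear metrics for an annotation
#'
#' @param annotation a [tear_annotation()].
#' @param angle_mode passed to [tear_angle()].
#' @return one-row data.frame with `angle`, `diameter_fraction`,
#'   `initiation_distance`, `circularity` (`NA` when the path is too open
#'   for a circularity score).
#' @export
tear_metrics <- function(annotation, angle_mode = "vector") {
  circ <- tryCatch(circularity(annotation), error = function(e) NA_real_)
  data.frame(angle = tear_angle(annotation, mode = angle_mode),
             diameter_fraction = diameter_fraction(annotation),
             initiation_distance = initiation_distance(annotation),
             circularity = circ)
}

#' Read and write tear annotations as JSON
#'
#' Annotations serialize to JSON objects with named coordinate arrays
#' (`forceps_axis`, `tear_vector`, `travel_circle`, `tear_path`,
#' `initiation_point`, `wound_point`, `model_reference_length`).
#'
#' @param annotation a [tear_annotation()].
#' @param path file path.
#' @return `read_tear_annotation` returns a [tear_annotation()];
#'   `write_tear_annotation` returns `path` invisibly.
#' @export
write_tear_annotation <- function(annotation, path) {
  jsonlite::write_json(
    list(forceps_axis = annotation$forceps_axis,
         tear_vector = annotation$tear_vector,
         travel_circle = annotation$travel_circle,
         tear_path = annotation$tear_path,
         initiation_point = annotation$initiation_point,
         wound_point = annotation$wound_point,
         model_reference_length = annotation$model_reference_length),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tear_annotation
#' @export
read_tear_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tear_annotation(forceps_axis = j$forceps_axis,
                  tear_vector = j$tear_vector,
                  travel_circle = j$travel_circle,
                  tear_path = j$tear_path,
                  initiation_point = j$initiation_point,
                  wound_point = j$wound_point,
                  model_reference_length = j$model_reference_length)
}
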