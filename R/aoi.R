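# AOI assignment and gaze-distribution accounting.

#' Assign fixations to labeled surfaces
#'
#' Labels each fixation by the surface polygon containing its centroid
#' (converted from degrees to pixel coordinates via the view geometry).
#' Containment is point-in-polygon with the boundary counted as inside;
#' overlapping surfaces are resolved by the priority
#' HUD > instrument_field > peripheral, and centroids matched by no surface
#' fall back to `peripheral`.
#'
#' @param fixations fixation data.frame from [detect_fixations()].
#' @param surfaces named list of [surface()] objects.
#' @param geometry a [view_geometry()]; required to convert centroids.
#' @return a data.frame with `fixation_index` and `label`.
#' @export
assign_fixations <- function(fixations, surfaces, geometry) {
  abort_if(missing(geometry) || !is_view_geometry(geometry),
           "`geometry` must be a view_geometry")
  n <- nrow(fixations)
  if (n == 0) {
    return(data.frame(fixation_index = integer(), label = character()))
  }
  px <- fixations$centroid_x / geometry$deg_per_px
  py <- fixations$centroid_y / geometry$deg_per_px
  lab <- rep("peripheral", n)
  assigned <- rep(FALSE, n)
  order_labels <- intersect(aoi_labels(), names(surfaces))
  for (l in order_labels) {
    hit <- !assigned & point_in_polygon(px, py, surfaces[[l]]$vertices)
    lab[hit] <- l
    assigned <- assigned | hit
  }
  data.frame(fixation_index = seq_len(n), label = lab)
}

#' Gaze distribution over areas of interest
#'
#' The proportion of total fixations that fell within each labeled area.
#' Proportions are count-based (each fixation weighs equally) and sum to 1
#' for non-empty input; with no assignments all proportions are `NA`.
#'
#' @param assignments data.frame from [assign_fixations()].
#' @param labels label universe (defaults to [aoi_labels()]); labels with
#'   no fixations get proportion 0.
#' @return an object of class `gaze_distribution`: a list with
#'   `proportions` (named numeric) and `assigned_count`.
#' @export
gaze_distribution <- function(assignments, labels = aoi_labels()) {
  n <- nrow(assignments)
  if (n == 0) {
    props <- setNames(rep(NA_real_, length(labels)), labels)
  } else {
    counts <- table(factor(assignments$label, levels = labels))
    props <- as.numeric(counts) / n
    names(props) <- labels
  }
  structure(list(proportions = props, assigned_count = n),
            class = "gaze_distribution")
}

#' @export
print.gaze_distribution <- function(x, ...) {
  cat(sprintf("<gaze_distribution> %d fixations\n", x$assigned_count))
  for (l in names(x$proportions)) {
    cat(sprintf("  %-17s %s\n", l,
                if (is.na(x$proportions[[l]])) "NA"
                else sprintf("%5.1f%%", 100 * x$proportions[[l]])))
  }
  invisible(x)
}

#' Write AOI assignments and distribution
#'
#' Assignments go to CSV (`fixation_index,label`); the distribution to
#' JSON.
#' @param assignments data.frame from [assign_fixations()].
#' @param distribution a [gaze_distribution()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_assignments_csv <- function(assignments, path) {
  write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments_csv
#' @export
write_distribution_json <- function(distribution, path) {
  jsonlite::write_json(
    list(proportions = as.list(distribution$proportions),
         assigned_count = distribution$assigned_count),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
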