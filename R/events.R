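#' Construct a gaze stream
#'
#' A gaze stream is a time-ordered data frame of gaze samples in scene
#' coordinates: `timestamp` (seconds, strictly increasing), `x_deg`,
#' `y_deg` (degrees, top-left origin, y down) and `confidence` (0..1).
#' The nominal sampling rate (default 200 Hz, the eye-camera frame rate)
#' is carried as an attribute.
#'
#' @param timestamp,x_deg,y_deg,confidence sample columns.
#' @param nominal_rate nominal sampling rate in Hz.
#' @return a `data.frame` of class `gaze_stream`.
#' @export
gaze_stream <- function(timestamp, x_deg, y_deg, confidence,
                        nominal_rate = 200) {
  abort_if(any(!is.finite(timestamp)), "timestamps must be finite")
  abort_if(is.unsorted(timestamp, strictly = TRUE),
           "timestamps must be strictly increasing")
  abort_if(any(confidence < 0 | confidence > 1, na.rm = TRUE),
           "confidence must lie in [0, 1]")
  check_number(nominal_rate, "nominal_rate", lower = 0, closed_lower = FALSE)
  out <- data.frame(timestamp = as.numeric(timestamp),
                    x_deg = as.numeric(x_deg),
                    y_deg = as.numeric(y_deg),
                    confidence = as.numeric(confidence))
  attr(out, "nominal_rate") <- nominal_rate
  class(out) <- c("gaze_stream", "data.frame")
  out
}

nominal_rate <- function(stream) attr(stream, "nominal_rate") %||% 200

#' Read and write gaze streams as CSV
#'
#' The on-disk dialect has the header `timestamp,x_deg,y_deg,confidence`
#' with timestamps in monotonically increasing seconds.
#'
#' @param stream a [gaze_stream()].
#' @param path file path.
#' @param nominal_rate sampling rate to attach on read (Hz).
#' @return `read_gaze_csv` returns a [gaze_stream()]; `write_gaze_csv`
#'   returns `path` invisibly.
#' @export
write_gaze_csv <- function(stream, path) {
  write.csv(as.data.frame(stream)[, c("timestamp", "x_deg", "y_deg",
                                      "confidence")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path, nominal_rate = 200) {
  d <- read.csv(path)
  need <- c("timestamp", "x_deg", "y_deg", "confidence")
  abort_if(!all(need %in% names(d)),
           "gaze CSV must have columns: ", paste(need, collapse = ", "))
  gaze_stream(d$timestamp, d$x_deg, d$y_deg, d$confidence,
              nominal_rate = nominal_rate)
}

#' Filter gaze samples by confidence
#'
#' Keeps samples whose pupil-detection confidence is at least `threshold`,
#' preserving order. The default threshold of 0.6 discards saccadic and
#' blink samples, whose confidence degrades with pupil-image quality; the
#' temporal gaps this leaves delimit fixation windows downstream.
#'
#' @param stream a [gaze_stream()].
#' @param threshold confidence threshold in \[0, 1\].
#' @return the filtered [gaze_stream()] (possibly empty).
#' @export
filter_by_confidence <- function(stream, threshold = 0.6) {
  check_number(threshold, "threshold", lower = 0, upper = 1)
  keep <- stream$confidence >= threshold
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nominal_rate") <- nominal_rate(stream)
  class(out) <- c("gaze_stream", "data.frame")
  out
}

#' Angular dispersion of a sample group
#'
#' The dispersion of a set of gaze samples is their maximum pairwise
#' angular separation on the scene plane, in degrees. This metric is
#' rotation-invariant and symmetric under sample reordering.
#'
#' @param x,y sample coordinates in degrees (at least one sample).
#' @return dispersion in degrees (0 for a single sample).
#' @export
angular_dispersion <- function(x, y) {
  abort_if(length(x) < 1L || length(x) != length(y),
           "need at least one (x, y) sample pair")
  .cpp_max_pairwise_dist(as.numeric(x), as.numeric(y))
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Groups consecutive samples into fixations wherever the angular
#' dispersion of a window stays within `max_dispersion` and its time span
#' falls in `[min_duration, max_duration]`. Windows grow greedily left to
#' right (earliest-start windows win); dwells longer than `max_duration`
#' split into consecutive capped fixations, with the remainder kept when it
#' still reaches `min_duration`. Temporal gaps longer than `gap_break`
#' (default twice the nominal sample interval; such gaps arise where
#' low-confidence samples were filtered out) always terminate a window.
#'
#' The defaults implement the classification used throughout the package:
#' maximum dispersion 1.50 degrees and duration 80 to 420 ms.
#'
#' @param stream a confidence-filtered [gaze_stream()].
#' @param max_dispersion maximum window dispersion, degrees.
#' @param min_duration,max_duration duration bounds, seconds
#'   (`min_duration < max_duration`; `max_duration` may be `Inf`).
#' @param gap_break gap that terminates a window, seconds; defaults to
#'   `2 / nominal_rate`.
#' @return a data.frame with one row per fixation: `start`, `end`,
#'   `centroid_x`, `centroid_y` (degrees), `dispersion`, `duration`,
#'   `n_samples`.
#' @examples
#' t <- seq(0, 0.2, by = 0.005)
#' s <- gaze_stream(t, rep(1, length(t)), rep(2, length(t)),
#'                  rep(1, length(t)))
#' detect_fixations(s) # one 200 ms fixation, dispersion 0
#' @export
detect_fixations <- function(stream, max_dispersion = 1.50,
                             min_duration = 0.080, max_duration = 0.420,
                             gap_break = NULL) {
  check_number(max_dispersion, "max_dispersion", lower = 0,
               closed_lower = FALSE)
  check_number(min_duration, "min_duration", lower = 0, closed_lower = FALSE)
  abort_if(!is.numeric(max_duration) || length(max_duration) != 1L ||
             is.na(max_duration) || max_duration <= min_duration,
           "`max_duration` must be a single number > `min_duration`")
  gap_break <- gap_break %||% (2 / nominal_rate(stream))
  check_number(gap_break, "gap_break", lower = 0, closed_lower = FALSE)
  empty <- data.frame(start = numeric(), end = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      dispersion = numeric(), duration = numeric(),
                      n_samples = integer())
  if (nrow(stream) == 0) return(empty)
  abort_if(is.unsorted(stream$timestamp, strictly = TRUE),
           "stream timestamps must be strictly increasing")
  win <- .cpp_idt_windows(stream$timestamp, stream$x_deg, stream$y_deg,
                          max_dispersion, min_duration, max_duration,
                          gap_break)
  if (nrow(win) == 0) return(empty)
  i <- win[, 1]; j <- win[, 2]
  cx <- numeric(nrow(win)); cy <- numeric(nrow(win))
  disp <- numeric(nrow(win))
  for (k in seq_len(nrow(win))) {
    xs <- stream$x_deg[i[k]:j[k]]; ys <- stream$y_deg[i[k]:j[k]]
    cx[k] <- mean(xs); cy[k] <- mean(ys)
    disp[k] <- .cpp_max_pairwise_dist(xs, ys)
  }
  data.frame(start = stream$timestamp[i], end = stream$timestamp[j],
             centroid_x = cx, centroid_y = cy, dispersion = disp,
             duration = stream$timestamp[j] - stream$timestamp[i],
             n_samples = j - i + 1L)
}

#' Extract saccades between consecutive fixations
#'
#' One saccade per consecutive fixation pair whose temporal gap (end of one
#' fixation to start of the next) does not exceed `max_gap`: amplitude is
#' the angular distance between the two fixation centroids, duration is the
#' gap itself. Pairs separated by longer gaps (blinks, tracking loss, large
#' reorienting gaze shifts) are not treated as measured saccades; pass
#' `max_gap = Inf` to pair every consecutive fixation regardless.
#'
#' @param fixations a time-ordered fixation data.frame from
#'   [detect_fixations()].
#' @param max_gap maximum inter-fixation gap for a pair to count as a
#'   saccade, seconds. The default 0.025 s spans saccadic durations of
#'   sub-degree shifts at 200 Hz.
#' @return a data.frame with `from_fixation`, `to_fixation` (row indices),
#'   `amplitude` (degrees), `duration` (seconds). Fewer than two fixations
#'   give an empty result.
#' @export
extract_saccades <- function(fixations, max_gap = 0.025) {
  abort_if(!is.numeric(max_gap) || length(max_gap) != 1L ||
             is.na(max_gap) || max_gap < 0,
           "`max_gap` must be a single non-negative number (Inf allowed)")
  empty <- data.frame(from_fixation = integer(), to_fixation = integer(),
                      amplitude = numeric(), duration = numeric())
  n <- nrow(fixations)
  if (is.null(n) || n < 2) return(empty)
  abort_if(is.unsorted(fixations$start),
           "fixations must be time-ordered")
  i <- seq_len(n - 1)
  gap <- fixations$start[i + 1] - fixations$end[i]
  amp <- angular_distance(fixations$centroid_x[i], fixations$centroid_y[i],
                          fixations$centroid_x[i + 1],
                          fixations$centroid_y[i + 1])
  keep <- gap <= max_gap + 1e-9
  data.frame(from_fixation = i[keep], to_fixation = i[keep] + 1L,
             amplitude = amp[keep], duration = gap[keep])
}

#' Detect blinks as confidence dropouts
#'
#' Blinks are maximal runs of samples whose confidence falls below
#' `confidence_floor` and whose time span reaches `min_duration`. Run on
#' the unfiltered stream.
#'
#' @param stream a raw (unfiltered) [gaze_stream()].
#' @param confidence_floor samples strictly below this confidence belong to
#'   a candidate blink.
#' @param min_duration minimum blink span, seconds.
#' @return a data.frame with `start`, `end`, `duration`.
#' @export
detect_blinks <- function(stream, confidence_floor = 0.1,
                          min_duration = 0.05) {
  check_number(confidence_floor, "confidence_floor", lower = 0,
               closed_lower = FALSE)
  check_number(min_duration, "min_duration", lower = 0, closed_lower = FALSE)
  empty <- data.frame(start = numeric(), end = numeric(),
                      duration = numeric())
  if (nrow(stream) == 0) return(empty)
  low <- stream$confidence < confidence_floor
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = stream$timestamp[starts[keep]],
                    end = stream$timestamp[ends[keep]])
  out$duration <- out$end - out$start
  out <- out[out$duration >= min_duration - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-session gaze metrics
#'
#' Aggregates detected events into the session-level metrics: fixation
#' count, mean fixation duration, mean saccade amplitude, blink rate
#' (blinks per minute) and total session duration. Means over empty event
#' sets are reported as `NA`.
#'
#' @param fixations,saccades,blinks event data.frames from
#'   [detect_fixations()], [extract_saccades()], [detect_blinks()].
#' @param total_duration session duration in seconds (> 0).
#' @return an object of class `session_metrics` (a one-row data.frame with
#'   columns `fixation_count`, `mean_fixation_duration`,
#'   `mean_saccade_amplitude`, `blink_rate`, `total_duration`).
#' @export
session_metrics <- function(fixations, saccades, blinks, total_duration) {
  check_number(total_duration, "total_duration", lower = 0,
               closed_lower = FALSE)
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  out <- data.frame(
    fixation_count = nrow(fixations),
    mean_fixation_duration = mean_or_na(fixations$duration),
    mean_saccade_amplitude = mean_or_na(saccades$amplitude),
    blink_rate = nrow(blinks) / (total_duration / 60),
    total_duration = total_duration)
  class(out) <- c("session_metrics", "data.frame")
  out
}

#' Write detected events as CSV
#'
#' Emits all event kinds in one file with the columns
#' `kind,start,end,centroid_x,centroid_y,dispersion,duration,amplitude`
#' (fields not applicable to a kind are empty).
#'
#' @param fixations,saccades,blinks event data.frames.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(fixations, saccades, blinks, path) {
  blank <- function(n) rep(NA_real_, n)
  f <- data.frame(kind = rep("fixation", nrow(fixations)),
                  start = fixations$start, end = fixations$end,
                  centroid_x = fixations$centroid_x,
                  centroid_y = fixations$centroid_y,
                  dispersion = fixations$dispersion,
                  duration = fixations$duration,
                  amplitude = blank(nrow(fixations)))
  s <- data.frame(kind = rep("saccade", nrow(saccades)),
                  start = blank(nrow(saccades)), end = blank(nrow(saccades)),
                  centroid_x = blank(nrow(saccades)),
                  centroid_y = blank(nrow(saccades)),
                  dispersion = blank(nrow(saccades)),
                  duration = saccades$duration,
                  amplitude = saccades$amplitude)
  b <- data.frame(kind = rep("blink", nrow(blinks)),
                  start = blinks$start, end = blinks$end,
                  centroid_x = blank(nrow(blinks)),
                  centroid_y = blank(nrow(blinks)),
                  dispersion = blank(nrow(blinks)),
                  duration = blinks$duration,
                  amplitude = blank(nrow(blinks)))
  write.csv(rbind(f, s, b), path, row.names = FALSE)
  invisible(path)
}
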