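#' Expertise profile for the synthetic-data generator
#'
#' An expertise profile collects the group-level gaze and capsulorhexis
#' parameters that drive session synthesis: mean fixation (dwell) duration,
#' expected fixation count, mean saccade amplitude, the distribution of
#' fixations over the three areas of interest (heads-up display, instrument
#' field, peripheral), the tear-angle distribution, the tear length as a
#' fraction of the capsulorhexis model, blink rate, within-fixation jitter
#' and the visual sampling strategy (feed-forward experts alternate rapidly
#' between regions; reactive novices dwell on the tool tip).
#'
#' The `sd_*` / `aoi_sd` fields are between-subject standard deviations:
#' each generated session draws its own subject-level parameters from
#' Normal(mean, sd) (suitably truncated), so cohorts of sessions reproduce
#' both the group mean and the between-subject spread. Set them to 0 for
#' sessions pinned exactly at the group mean.
#'
#' @param label group name, e.g. "attending".
#' @param mean_fixation_duration mean dwell duration in seconds; must lie in
#'   the detectable range (0.08, 0.42).
#' @param fixation_count expected number of fixations in a full session
#'   (descriptive; session length is set separately in [generate_session()]).
#' @param mean_saccade_amplitude mean inter-dwell jump in degrees.
#' @param aoi_proportions named numeric vector over `HUD`,
#'   `instrument_field`, `peripheral`; non-negative, summing to 1.
#' @param strategy `"feed_forward"` or `"reactive"`; controls how long gaze
#'   stays within one area of interest before relocating.
#' @param tear_angle_mean,tear_angle_sd tear angle relative to the forceps
#'   axis, degrees (vector angle on \[0, 180\]).
#' @param diameter_fraction_mean tear arc length as a fraction of the full
#'   capsulorhexis model circumference.
#' @param blink_rate blinks per minute.
#' @param noise_sd within-fixation gaze jitter, degrees.
#' @param sd_fixation_duration,sd_saccade_amplitude,aoi_sd,diameter_fraction_sd
#'   between-subject standard deviations (see Details); default 0.
#' @return an object of class `expertise_profile`.
#' @seealso [study_profiles()] for the five built-in training-level profiles.
#' @export
expertise_profile <- function(label,
                              mean_fixation_duration,
                              fixation_count,
                              mean_saccade_amplitude,
                              aoi_proportions,
                              strategy = c("reactive", "feed_forward"),
                              tear_angle_mean,
                              tear_angle_sd,
                              diameter_fraction_mean,
                              blink_rate = 10,
                              noise_sd = 0.15,
                              sd_fixation_duration = 0,
                              sd_saccade_amplitude = 0,
                              aoi_sd = 0,
                              diameter_fraction_sd = 0) {
  abort_if(!is.character(label) || length(label) != 1L || !nzchar(label),
           "`label` must be a non-empty string")
  strategy <- match.arg(strategy)
  check_number(mean_fixation_duration, "mean_fixation_duration",
               lower = 0.08, upper = 0.42,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(fixation_count, "fixation_count", lower = 0)
  check_number(mean_saccade_amplitude, "mean_saccade_amplitude", lower = 0,
               closed_lower = FALSE)
  check_number(tear_angle_mean, "tear_angle_mean", lower = 0, upper = 180)
  check_number(tear_angle_sd, "tear_angle_sd", lower = 0)
  check_number(diameter_fraction_mean, "diameter_fraction_mean", lower = 0,
               closed_lower = FALSE)
  check_number(blink_rate, "blink_rate", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sd_fixation_duration, "sd_fixation_duration", lower = 0)
  check_number(sd_saccade_amplitude, "sd_saccade_amplitude", lower = 0)
  check_number(aoi_sd, "aoi_sd", lower = 0)
  check_number(diameter_fraction_sd, "diameter_fraction_sd", lower = 0)

  abort_if(!is.numeric(aoi_proportions) ||
             !setequal(names(aoi_proportions), aoi_labels()),
           "`aoi_proportions` must be a numeric vector named HUD, ",
           "instrument_field, peripheral")
  aoi_proportions <- aoi_proportions[aoi_labels()]
  abort_if(any(!is.finite(aoi_proportions)) || any(aoi_proportions < 0),
           "`aoi_proportions` must be finite and non-negative")
  abort_if(abs(sum(aoi_proportions) - 1) > 1e-9,
           sprintf("`aoi_proportions` must sum to 1 (got %.10f)",
                   sum(aoi_proportions)))

  structure(list(label = label,
                 mean_fixation_duration = mean_fixation_duration,
                 sd_fixation_duration = sd_fixation_duration,
                 fixation_count = fixation_count,
                 mean_saccade_amplitude = mean_saccade_amplitude,
                 sd_saccade_amplitude = sd_saccade_amplitude,
                 aoi_proportions = aoi_proportions,
                 aoi_sd = aoi_sd,
                 strategy = strategy,
                 tear_angle_mean = tear_angle_mean,
                 tear_angle_sd = tear_angle_sd,
                 diameter_fraction_mean = diameter_fraction_mean,
                 diameter_fraction_sd = diameter_fraction_sd,
                 blink_rate = blink_rate,
                 noise_sd = noise_sd),
            class = "expertise_profile")
}

is_expertise_profile <- function(x) inherits(x, "expertise_profile")

#' @export
print.expertise_profile <- function(x, ...) {
  cat(sprintf("<expertise_profile> %s (%s)\n", x$label, x$strategy))
  cat(sprintf("  fixation duration %.3f +/- %.3f s, saccade %.3f +/- %.3f deg\n",
              x$mean_fixation_duration, x$sd_fixation_duration,
              x$mean_saccade_amplitude, x$sd_saccade_amplitude))
  cat(sprintf("  AOI: HUD %.1f%%, instrument %.1f%%, peripheral %.1f%%\n",
              100 * x$aoi_proportions[["HUD"]],
              100 * x$aoi_proportions[["instrument_field"]],
              100 * x$aoi_proportions[["peripheral"]]))
  cat(sprintf("  tear angle %.1f +/- %.1f deg, diameter fraction %.3f\n",
              x$tear_angle_mean, x$tear_angle_sd, x$diameter_fraction_mean))
  invisible(x)
}

#' Built-in training-level profiles of the study cohort
#'
#' Returns the five expertise profiles (PGY2, PGY3, PGY4, fellow,
#' attending) parameterized with the published group summaries: fixation
#' duration (attending 0.118 +/- 0.016 s, PGY2 0.286 +/- 0.152 s), saccade
#' amplitude (PGY2 0.294 +/- 0.053 deg; fellow 0.122 +/- 0.022; attending
#' 0.126 +/- 0.018), HUD/instrument-field fixation shares (attending
#' 77.2 +/- 4.09% / 16.6 +/- 5.5%; PGY2 43.4 +/- 8.32% / 36.4 +/- 12.1%),
#' tear angles (PGY2 88.4 +/- 14.3 through attending 6.0 +/- 1.58 deg) and
#' tear diameter fractions (PGY2 14.6 +/- 3.5% up to attending
#' 57.6 +/- 16.4%). Group parameters that were not published (intermediate
#' groups' AOI shares, saccade lengths, diameter fractions, fixation
#' durations) are filled with monotone interpolations consistent with the
#' published ordering; blink rate and within-fixation jitter, for which no
#' values were published, default to 10 blinks/min and 0.15 deg.
#'
#' @return a named list of [expertise_profile()] objects.
#' @examples
#' names(study_profiles())
#' study_profiles()$attending
#' @export
study_profiles <- function() {
  list(
    pgy2 = expertise_profile(
      label = "pgy2",
      mean_fixation_duration = 0.286, sd_fixation_duration = 0.152,
      fixation_count = 2400,
      mean_saccade_amplitude = 0.294, sd_saccade_amplitude = 0.053,
      aoi_proportions = c(HUD = 0.434, instrument_field = 0.364,
                          peripheral = 0.202),
      aoi_sd = 0.0832,
      strategy = "reactive",
      tear_angle_mean = 88.4, tear_angle_sd = 14.3,
      diameter_fraction_mean = 0.146, diameter_fraction_sd = 0.035),
    pgy3 = expertise_profile(
      label = "pgy3",
      mean_fixation_duration = 0.220, sd_fixation_duration = 0.080,
      fixation_count = 2791,
      mean_saccade_amplitude = 0.230, sd_saccade_amplitude = 0.045,
      aoi_proportions = c(HUD = 0.520, instrument_field = 0.310,
                          peripheral = 0.170),
      aoi_sd = 0.070,
      strategy = "reactive",
      tear_angle_mean = 70.4, tear_angle_sd = 7.30,
      diameter_fraction_mean = 0.250, diameter_fraction_sd = 0.060),
    pgy4 = expertise_profile(
      label = "pgy4",
      mean_fixation_duration = 0.170, sd_fixation_duration = 0.050,
      fixation_count = 2200,
      mean_saccade_amplitude = 0.180, sd_saccade_amplitude = 0.035,
      aoi_proportions = c(HUD = 0.600, instrument_field = 0.260,
                          peripheral = 0.140),
      aoi_sd = 0.065,
      strategy = "reactive",
      tear_angle_mean = 48.4, tear_angle_sd = 4.03,
      diameter_fraction_mean = 0.350, diameter_fraction_sd = 0.070),
    fellow = expertise_profile(
      label = "fellow",
      mean_fixation_duration = 0.140, sd_fixation_duration = 0.030,
      fixation_count = 1800,
      mean_saccade_amplitude = 0.122, sd_saccade_amplitude = 0.022,
      aoi_proportions = c(HUD = 0.700, instrument_field = 0.200,
                          peripheral = 0.100),
      aoi_sd = 0.055,
      strategy = "feed_forward",
      tear_angle_mean = 18.4, tear_angle_sd = 2.7,
      diameter_fraction_mean = 0.466, diameter_fraction_sd = 0.0844),
    attending = expertise_profile(
      label = "attending",
      mean_fixation_duration = 0.118, sd_fixation_duration = 0.016,
      fixation_count = 1355,
      mean_saccade_amplitude = 0.126, sd_saccade_amplitude = 0.018,
      aoi_proportions = c(HUD = 0.772, instrument_field = 0.166,
                          peripheral = 0.062),
      aoi_sd = 0.0409,
      strategy = "feed_forward",
      tear_angle_mean = 6.0, tear_angle_sd = 1.58,
      diameter_fraction_mean = 0.576, diameter_fraction_sd = 0.164)
  )
}
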