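# Session synthesis: dwell/saccade/blink sequences with ground-truth logs.

# Confidence levels emitted by the generator. Saccadic samples carry low
# confidence (pupil detection degrades during fast motion) and blink
# samples near-zero confidence, so the default 0.6 confidence filter
# removes both and the resulting temporal gaps delimit fixation windows.
GEN_CONF_DWELL <- c(0.80, 1.00)
GEN_CONF_SACCADE <- 0.35
GEN_CONF_BLINK <- 0.02

# Log-sd of the within-session dwell-duration distribution (truncated
# log-normal on the detectable range); the location parameter is solved
# per session so the truncated mean hits the subject-level target.
GEN_DWELL_SIGMA <- 0.45

# Saccadic main sequence used to size large relocation shifts:
# duration ~ 21 ms + 2.2 ms/deg.
mainseq_duration <- function(amplitude_deg) 0.021 + 0.0022 * amplitude_deg

#' Generate a synthetic gaze session with ground truth
#'
#' Synthesizes one eye-tracking session for an expertise profile: a gaze
#' stream sampled at the nominal rate (default 200 Hz) together with a
#' ground-truth event log. The session alternates dwells (whose durations
#' follow a truncated log-normal on the detectable 80-420 ms range with
#' mean matched to the subject-level fixation duration), saccadic
#' transitions of 2-3 low-confidence samples (mean jump amplitude matched
#' to the subject-level saccade amplitude), occasional large relocations to
#' a new area of interest (dwell counts per area follow the profile's AOI
#' proportions; relocation durations follow the saccadic main sequence) and
#' blinks (confidence dropouts of 100-300 ms at the profile's blink rate).
#' Dwell centroids carry Gaussian within-fixation jitter of `noise_sd`
#' degrees. Between-subject variation: each session first draws its own
#' subject-level mean fixation duration, saccade amplitude and HUD share
#' from the profile's `sd_*` fields.
#'
#' Identical `(profile, seed)` pairs reproduce byte-identical output.
#'
#' @param profile an [expertise_profile()].
#' @param geometry a [view_geometry()].
#' @param surfaces a named list of [surface()] polygons covering the AOI
#'   labels (default [generate_surfaces()]).
#' @param duration requested session length, seconds (> 0).
#' @param seed integer random seed.
#' @param nominal_rate sampling rate, Hz.
#' @return a list with elements `stream` (a [gaze_stream()]) and `truth`
#'   (a data.frame event log with columns `kind` in fixation/saccade/blink,
#'   `start`, `end`, `x`, `y` (true centroid, degrees), `amplitude`
#'   (degrees, saccades), `aoi`), plus the drawn subject-level parameters
#'   as attribute `subject`.
#' @examples
#' s <- generate_session(study_profiles()$attending, view_geometry(),
#'                       duration = 10, seed = 1)
#' head(s$stream); table(s$truth$kind)
#' @export
generate_session <- function(profile, geometry = view_geometry(),
                             surfaces = generate_surfaces(geometry),
                             duration, seed, nominal_rate = 200) {
  abort_if(!is_expertise_profile(profile),
           "`profile` must be an expertise_profile")
  abort_if(!is_view_geometry(geometry), "`geometry` must be a view_geometry")
  check_number(duration, "duration", lower = 0, closed_lower = FALSE)
  check_number(seed, "seed")
  abort_if(!all(aoi_labels() %in% names(surfaces)),
           "`surfaces` must cover the AOI labels: ",
           paste(aoi_labels(), collapse = ", "))
  withr::with_seed(as.integer(seed), {
    generate_session_impl(profile, geometry, surfaces, duration,
                          nominal_rate)
  })
}

generate_session_impl <- function(profile, geometry, surfaces, duration,
                                  rate) {
  dt <- 1 / rate
  n_total <- floor(duration / dt) # last usable sample index (0-based)
  labels <- aoi_labels()
  polys_deg <- lapply(surfaces[labels],
                      function(s) s$vertices * geometry$deg_per_px)
  margin <- max(4 * profile$noise_sd, 0.5) # degrees kept off AOI edges

  # subject-level draws (between-subject variation)
  m_fix <- rnorm_trunc(1, profile$mean_fixation_duration,
                       profile$sd_fixation_duration, 0.085, 0.405)
  m_sacc <- rnorm_trunc(1, profile$mean_saccade_amplitude,
                        profile$sd_saccade_amplitude, 0.02, Inf)
  probs <- profile$aoi_proportions
  if (profile$aoi_sd > 0) {
    h <- rnorm_trunc(1, probs[["HUD"]], profile$aoi_sd, 0.01, 0.98)
    rest <- probs[c("instrument_field", "peripheral")]
    rest <- rest / sum(rest) * (1 - h)
    probs <- c(HUD = h, rest)
  }
  probs <- probs[labels]

  mu <- solve_trunc_lnorm_mu(m_fix, GEN_DWELL_SIGMA, 0.08, 0.42)

  # Instrument-field dwell placement: reactive (novice) profiles
  # concentrate on the tear site at the edge of the capsulorhexis model,
  # feed-forward (expert) profiles distribute over the whole model area.
  instr_cluster <- c(geometry$width_px / 2 + 0.18 * geometry$height_px,
                     0.72 * geometry$height_px) * geometry$deg_per_px
  instr_cluster_sd <- 0.05 * geometry$height_px * geometry$deg_per_px
  draw_point <- function(aoi) {
    poly <- polys_deg[[aoi]]
    if (aoi == "instrument_field" && profile$strategy == "reactive") {
      for (i in 1:50) {
        p <- rnorm(2, instr_cluster, instr_cluster_sd)
        if (point_in_polygon(p[1], p[2], poly) &&
            min_edge_distance(p, poly) >= margin) {
          return(p)
        }
      }
    }
    sample_point_in_polygon(poly, margin)
  }

  # mean AOI run length (dwells before relocating); feed-forward experts
  # alternate between regions more rapidly
  run_len <- if (profile$strategy == "feed_forward") 8 else 18
  # blink probability per dwell boundary: calibrated so the expected blink
  # count matches blink_rate over the session
  cycle <- m_fix + 2.5 * dt
  p_blink <- min(0.5, profile$blink_rate / 60 * cycle)

  cur_aoi <- sample(labels, 1, prob = probs)
  pos <- draw_point(cur_aoi)

  ts <- list(); xs <- list(); ys <- list(); cf <- list()
  ev <- list()
  cursor <- 0L # next free sample index (0-based)
  ne <- 0L
  push <- function(t, x, y, conf) {
    k <- length(ts) + 1L
    ts[[k]] <<- t; xs[[k]] <<- x; ys[[k]] <<- y; cf[[k]] <<- conf
  }
  log_event <- function(kind, start, end, x = NA_real_, y = NA_real_,
                        amplitude = NA_real_, aoi = NA_character_) {
    ne <<- ne + 1L
    ev[[ne]] <<- data.frame(kind = kind, start = start, end = end,
                            x = x, y = y, amplitude = amplitude, aoi = aoi)
  }

  repeat {
    # ---- dwell ----
    d <- rtrunc_lnorm(1, mu, GEN_DWELL_SIGMA, 0.08, 0.42)
    n_samp <- as.integer(round(d / dt)) + 1L
    truncated <- FALSE
    if (cursor + n_samp - 1L > n_total) {
      n_samp <- n_total - cursor + 1L
      truncated <- TRUE
    }
    if (n_samp >= 1L) {
      tt <- (cursor:(cursor + n_samp - 1L)) * dt
      if (profile$noise_sd > 0) {
        # bounded tremor/drift jitter: truncated at 2 sd, since eye-tracker
        # within-fixation noise has no Gaussian tails (fast excursions are
        # saccades and are modeled separately)
        s_n <- profile$noise_sd
        jx <- rnorm_trunc(n_samp, 0, s_n, -2 * s_n, 2 * s_n)
        jy <- rnorm_trunc(n_samp, 0, s_n, -2 * s_n, 2 * s_n)
      } else {
        jx <- jy <- numeric(n_samp)
      }
      push(tt, pos[1] + jx, pos[2] + jy,
           runif(n_samp, GEN_CONF_DWELL[1], GEN_CONF_DWELL[2]))
      span <- (n_samp - 1L) * dt
      if (span >= 0.08 - 1e-9) {
        log_event("fixation", tt[1], tt[n_samp], pos[1], pos[2],
                  aoi = cur_aoi)
      }
      cursor <- cursor + n_samp
    }
    if (truncated || cursor > n_total) break

    # ---- boundary event: blink, relocation or within-AOI saccade ----
    if (runif(1) < p_blink) {
      n_b <- as.integer(round(runif(1, 0.10, 0.30) / dt)) + 1L
      n_b <- min(n_b, n_total - cursor + 1L)
      if (n_b < 2L) break
      tt <- (cursor:(cursor + n_b - 1L)) * dt
      push(tt, rep(pos[1], n_b), rep(pos[2], n_b),
           rep(GEN_CONF_BLINK, n_b))
      log_event("blink", tt[1], tt[n_b])
      cursor <- cursor + n_b
    } else if (runif(1) < 1 / run_len) {
      # relocate to a (possibly different) area of interest
      new_aoi <- sample(labels, 1, prob = probs)
      new_pos <- draw_point(new_aoi)
      amp <- angular_distance(pos[1], pos[2], new_pos[1], new_pos[2])
      k <- max(5L, as.integer(round(mainseq_duration(amp) / dt)))
      k <- min(k, n_total - cursor + 1L)
      if (k < 1L) break
      frac <- seq_len(k) / (k + 1)
      tt <- (cursor:(cursor + k - 1L)) * dt
      push(tt, pos[1] + frac * (new_pos[1] - pos[1]),
           pos[2] + frac * (new_pos[2] - pos[2]),
           rep(GEN_CONF_SACCADE, k))
      log_event("saccade", tt[1] - dt, tt[k] + dt, amplitude = amp,
                aoi = new_aoi)
      cursor <- cursor + k
      pos <- new_pos
      cur_aoi <- new_aoi
    } else {
      # small within-AOI saccadic step
      amp <- rgamma(1, shape = 4, rate = 4 / m_sacc)
      new_pos <- step_within_polygon(pos, amp, polys_deg[[cur_aoi]], margin)
      amp <- angular_distance(pos[1], pos[2], new_pos[1], new_pos[2])
      k <- sample(2:3, 1)
      k <- min(k, n_total - cursor + 1L)
      if (k < 1L) break
      frac <- seq_len(k) / (k + 1)
      tt <- (cursor:(cursor + k - 1L)) * dt
      push(tt, pos[1] + frac * (new_pos[1] - pos[1]),
           pos[2] + frac * (new_pos[2] - pos[2]),
           rep(GEN_CONF_SACCADE, k))
      log_event("saccade", tt[1] - dt, tt[k] + dt, amplitude = amp,
                aoi = cur_aoi)
      cursor <- cursor + k
      pos <- new_pos
    }
    if (cursor > n_total) break
  }

  stream <- gaze_stream(unlist(ts), unlist(xs), unlist(ys), unlist(cf),
                        nominal_rate = rate)
  truth <- if (ne > 0) do.call(rbind, ev[seq_len(ne)]) else
    data.frame(kind = character(), start = numeric(), end = numeric(),
               x = numeric(), y = numeric(), amplitude = numeric(),
               aoi = character())
  rownames(truth) <- NULL
  out <- list(stream = stream, truth = truth)
  attr(out, "subject") <- list(mean_fixation_duration = m_fix,
                               mean_saccade_amplitude = m_sacc,
                               aoi_proportions = probs)
  out
}

# Propose a step of fixed length from `pos` staying inside the polygon
# (with margin); direction resampled on failure, falling back to a step
# toward the polygon centroid.
step_within_polygon <- function(pos, len, vertices, margin,
                                max_tries = 20) {
  for (i in seq_len(max_tries)) {
    theta <- runif(1, 0, 2 * pi)
    p <- pos + len * c(cos(theta), sin(theta))
    if (point_in_polygon(p[1], p[2], vertices) &&
        min_edge_distance(p, vertices) >= margin) {
      return(p)
    }
  }
  ctr <- polygon_centroid(vertices)
  u <- ctr - pos
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) return(pos)
  pos + min(len, nu) * u / nu
}

#' Generate a synthetic capsulorhexis tear annotation
#'
#' Draws one tear annotation for an expertise profile: the true tear angle
#' comes from Normal(`tear_angle_mean`, `tear_angle_sd`) truncated to
#' \[0, 180\] degrees (vector angle between tear direction and forceps
#' axis); the tear path is an arc of the forceps travel circle whose length
#' is the drawn diameter fraction times the model circumference; the
#' initiation point sits close to the forceps insertion wound for
#' feed-forward (expert) profiles and farther for reactive (novice) ones.
#'
#' @param profile an [expertise_profile()].
#' @param seed integer random seed.
#' @param geometry a [view_geometry()] locating the model in the frame.
#' @return a [tear_annotation()].
#' @examples
#' a <- generate_tear_annotation(study_profiles()$attending, seed = 1)
#' tear_angle(a)
#' @export
generate_tear_annotation <- function(profile, seed,
                                     geometry = view_geometry()) {
  abort_if(!is_expertise_profile(profile),
           "`profile` must be an expertise_profile")
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed), {
    ctr <- c(geometry$width_px / 2, geometry$height_px * 0.72)
    r <- round(0.18 * geometry$height_px)
    theta <- rnorm_trunc(1, profile$tear_angle_mean, profile$tear_angle_sd,
                         0, 180)
    frac <- rnorm_trunc(1, profile$diameter_fraction_mean,
                        profile$diameter_fraction_sd, 0.02, 1)
    # wound (forceps insertion) just outside the travel circle, to the right
    wound <- ctr + c(1.15 * r, 0)
    # initiation point on the circle: experts begin near the wound
    beta_sd <- if (profile$strategy == "feed_forward") 20 else 45
    beta0 <- if (profile$strategy == "feed_forward") 0 else 120
    beta <- (beta0 + rnorm(1, 0, beta_sd)) * pi / 180
    start_ang <- beta
    span <- frac * 2 * pi
    m <- max(50L, as.integer(ceiling(span / (2 * pi) * 240)))
    angs <- start_ang + seq(0, span, length.out = m)
    path <- cbind(ctr[1] + r * cos(angs), ctr[2] + r * sin(angs))
    initiation <- path[1, ]
    # forceps axis: from the wound toward the current tear point
    tear_pt <- path[m, ]
    fdir <- tear_pt - wound
    fang <- atan2(fdir[2], fdir[1])
    forceps <- rbind(wound, tear_pt)
    # tear vector at angle theta from the forceps direction
    tang <- fang + theta * pi / 180
    tear_vec <- rbind(tear_pt,
                      tear_pt + 0.2 * r * c(cos(tang), sin(tang)))
    tear_annotation(forceps_axis = forceps,
                    tear_vector = tear_vec,
                    travel_circle = list(center = ctr, radius = r),
                    tear_path = path,
                    initiation_point = initiation,
                    wound_point = wound,
                    model_reference_length = 2 * pi * r)
  })
}

#' Generate a cohort of synthetic sessions
#'
#' Generates `n_per_group` sessions per profile with distinct,
#' reproducibly derived seeds (`base_seed` combined with a stable hash of
#' the group label and the replicate index), along with a manifest
#' recording every seed and the generation parameters.
#'
#' @param profiles a list of [expertise_profile()] objects with distinct
#'   labels.
#' @param n_per_group sessions per profile (>= 1).
#' @param base_seed integer base seed.
#' @param duration session length in seconds.
#' @param geometry a [view_geometry()].
#' @param surfaces surface set (default [generate_surfaces()]).
#' @param nominal_rate sampling rate, Hz.
#' @return a list with `sessions` (list of [generate_session()] results,
#'   named `<label>_<replicate>`) and `manifest` (data.frame with columns
#'   `label`, `replicate`, `seed`, `duration`, `nominal_rate`).
#' @export
generate_cohort <- function(profiles, n_per_group, base_seed,
                            duration = 300, geometry = view_geometry(),
                            surfaces = generate_surfaces(geometry),
                            nominal_rate = 200) {
  check_number(n_per_group, "n_per_group", lower = 1)
  check_number(base_seed, "base_seed")
  labs <- vapply(profiles, function(p) p$label, "")
  abort_if(anyDuplicated(labs) > 0, "profile labels must be distinct")
  manifest <- do.call(rbind, lapply(labs, function(lab) {
    data.frame(label = lab, replicate = seq_len(n_per_group),
               seed = vapply(seq_len(n_per_group),
                             function(r) derive_seed(base_seed, lab, r),
                             integer(1)),
               duration = duration, nominal_rate = nominal_rate)
  }))
  sessions <- vector("list", nrow(manifest))
  names(sessions) <- paste(manifest$label, manifest$replicate, sep = "_")
  for (i in seq_len(nrow(manifest))) {
    p <- profiles[[match(manifest$label[i], labs)]]
    sessions[[i]] <- generate_session(p, geometry, surfaces, duration,
                                      seed = manifest$seed[i],
                                      nominal_rate = nominal_rate)
  }
  list(sessions = sessions, manifest = manifest)
}

#' Write a cohort manifest as JSON
#'
#' @param cohort result of [generate_cohort()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  jsonlite::write_json(cohort$manifest, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
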