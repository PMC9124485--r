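#' Size-standardized spontaneous activity from a tracked movement summary
#'
#' Activity is the average speed in body lengths per minute:
#' total tracked distance (pixels) converted to cm by the camera calibration,
#' divided by the fish's total length and by the window duration. Time spent
#' invisible (inside the shelter) contributes zero distance but full time to
#' the denominator, so sheltering reads as inactivity.
#'
#' @param total_distance_px tracked distance over the window (pixels).
#' @param calibration_cm_per_px pixel-to-distance calibration.
#' @param total_length_cm fish total length (cm).
#' @param duration_min window duration (min), including invisible time.
#' @return activity in BL min-1.
#' @export
compute_activity <- function(total_distance_px, calibration_cm_per_px,
                             total_length_cm, duration_min) {
  if (any(duration_min <= 0)) {
    stop("input error: duration_min must be > 0", call. = FALSE)
  }
  if (any(total_length_cm <= 0)) {
    stop("input error: total_length_cm must be > 0", call. = FALSE)
  }
  if (any(total_distance_px < 0)) {
    stop("input error: total_distance_px must be >= 0", call. = FALSE)
  }
  (total_distance_px * calibration_cm_per_px / total_length_cm) / duration_min
}

#' Subtract a fish's inactive control value from its activity
#'
#' Automated trackers register minor postural adjustments and water-flow
#' buffeting as movement; a per-fish 'inactive control value' (mean tracked
#' movement over at least three ~10 min periods of visually confirmed
#' inactivity) is subtracted from every activity measurement and the result
#' floored at zero.
#'
#' @param activity raw activity (BL min-1), vectorized.
#' @param control_value the fish's inactive control value (BL min-1, >= 0).
#' @return corrected activity, `max(activity - control_value, 0)`.
#' @export
apply_inactive_control <- function(activity, control_value) {
  if (any(control_value < 0)) {
    stop("input error: control_value must be >= 0", call. = FALSE)
  }
  pmax(activity - control_value, 0)
}

#' Inactive control value from confirmed-inactive tracking periods
#'
#' @param period_activities tracked movement (BL min-1) over each visually
#'   confirmed inactive period; at least 3 periods are required.
#' @return the mean, to be passed to [apply_inactive_control()].
#' @export
inactive_control_value <- function(period_activities) {
  if (length(period_activities) < 3) {
    stop("input error: need >= 3 confirmed-inactive periods", call. = FALSE)
  }
  mean(period_activities)
}

#' Sheltering fraction from tracker invisible time
#'
#' The fraction of the measurement window the fish was invisible to the
#' tracker, i.e. inside its opaque shelter.
#'
#' @param invisible_time_min invisible time (min).
#' @param duration_min window duration (min).
#' @return fraction in 0..1.
#' @export
compute_sheltering <- function(invisible_time_min, duration_min) {
  if (any(duration_min <= 0)) {
    stop("input error: duration_min must be > 0", call. = FALSE)
  }
  if (any(invisible_time_min < 0 | invisible_time_min > duration_min)) {
    stop("input error: invisible_time_min must be within [0, duration_min]",
         call. = FALSE)
  }
  invisible_time_min / duration_min
}

#' Mean vigilance score
#'
#' Eel activity proxy: each 30-min spot observation is scored 1 (fish out of
#' shelter), 0.5 (head out) or 0 (fully enclosed); the phase score is the
#' arithmetic mean.
#'
#' @param scores vector of values in {0, 0.5, 1}.
#' @return mean score, or NA for an empty vector (missing, not an error).
#' @export
score_vigilance <- function(scores) {
  if (length(scores) == 0) return(NA_real_)
  if (!all(scores %in% c(0, 0.5, 1))) {
    stop("input error: vigilance scores must be in {0, 0.5, 1}",
         call. = FALSE)
  }
  mean(scores)
}

#' Daily feeding fraction from pellet counts
#'
#' Fraction of the offered ration consumed in 24 h, from counting the
#' remaining pellets (or worms).
#'
#' @param ration_count pellets offered (> 0).
#' @param remaining_count pellets left after 24 h (0..ration_count).
#' @return (ration - remaining) / ration.
#' @export
compute_feeding <- function(ration_count, remaining_count) {
  if (any(ration_count <= 0)) {
    stop("input error: ration_count must be > 0", call. = FALSE)
  }
  if (any(remaining_count < 0 | remaining_count > ration_count)) {
    stop("input error: remaining_count must be within [0, ration_count]",
         call. = FALSE)
  }
  (ration_count - remaining_count) / ration_count
}

#' Restrict samples to the day or night measurement window
#'
#' The daytime window is 09:00-16:00 and the nighttime window 19:00-06:00
#' (wrapping midnight); both are half-open, `[start, end)`, so a boundary
#' sample is counted once. The first hour and last 1.5 h of each light phase
#' are thereby excluded from measurement, avoiding feeding/cleaning
#' disturbances.
#'
#' @param clock_s time of day in seconds since midnight (0..86400),
#'   vectorized; "HH:MM" or "HH:MM:SS" strings are also accepted.
#' @param phase "day" or "night".
#' @return logical vector: inside the phase's measurement window.
#' @export
clip_phase_window <- function(clock_s, phase = c("day", "night")) {
  phase <- match.arg(phase)
  if (is.character(clock_s)) {
    parts <- strsplit(clock_s, ":", fixed = TRUE)
    clock_s <- vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] * 3600 + p[2] * 60 + if (length(p) > 2) p[3] else 0
    }, numeric(1))
  }
  clock_s <- clock_s %% 86400
  if (phase == "day") {
    clock_s >= 9 * 3600 & clock_s < 16 * 3600
  } else {
    clock_s >= 19 * 3600 | clock_s < 6 * 3600
  }
}

#' Mean daily water temperature from four readings
#'
#' Average of the morning (~09:00) and evening (~17:00) spot readings and the
#' recorded daily minimum and maximum (the chiller's setpoint hysteresis).
#'
#' @param morning_c,evening_c spot readings (deg C).
#' @param daily_min_c,daily_max_c recorded extremes (deg C); min must not
#'   exceed max.
#' @return arithmetic mean of the four values.
#' @export
mean_daily_temperature <- function(morning_c, evening_c, daily_min_c,
                                   daily_max_c) {
  if (any(daily_min_c > daily_max_c)) {
    stop("input error: daily_min_c must not exceed daily_max_c",
         call. = FALSE)
  }
  (morning_c + evening_c + daily_min_c + daily_max_c) / 4
}

#' Reduce track summaries to a tidy activity summary table
#'
#' Convenience wrapper applying [compute_activity()], the inactive-control
#' correction and [compute_sheltering()] to a table of per-window track
#' summaries.
#'
#' @param tracks data.frame with fish_id, phase, temp_c, total_distance_px,
#'   calibration_cm_per_px, duration_min, invisible_time_min.
#' @param lengths data.frame with fish_id, total_length_cm.
#' @param controls optional data.frame with fish_id, control_value
#'   (BL min-1) for the inactive-control subtraction.
#' @return data.frame: fish_id, phase, temp_c, activity, shelter_fraction,
#'   corrected (logical).
#' @export
summarize_tracks <- function(tracks, lengths, controls = NULL) {
  tl <- lengths$total_length_cm[match(tracks$fish_id, lengths$fish_id)]
  if (anyNA(tl)) {
    stop("input error: missing total length for some fish_id", call. = FALSE)
  }
  act <- compute_activity(tracks$total_distance_px,
                          tracks$calibration_cm_per_px, tl,
                          tracks$duration_min)
  corrected <- FALSE
  if (!is.null(controls)) {
    ctl <- controls$control_value[match(tracks$fish_id, controls$fish_id)]
    ctl[is.na(ctl)] <- 0
    act <- apply_inactive_control(act, ctl)
    corrected <- TRUE
  }
  data.frame(fish_id = tracks$fish_id, phase = tracks$phase,
             temp_c = tracks$temp_c, activity = act,
             shelter_fraction = compute_sheltering(tracks$invisible_time_min,
                                                   tracks$duration_min),
             corrected = corrected, stringsAsFactors = FALSE)
}
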