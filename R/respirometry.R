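#' Respirometer geometry
#'
#' Chamber and fish dimensions needed to convert a volumetric oxygen decline
#' into a mass-specific uptake rate. The effective (water) volume is the
#' chamber volume minus the fish's body volume, with body volume defaulting to
#' body mass at a tissue density of 1 kg L-1.
#'
#' @param chamber_volume_l chamber volume (L).
#' @param body_mass_kg fish body mass (kg).
#' @param body_volume_l fish body volume (L); defaults to `body_mass_kg / 1`.
#' @return a `respirometer_geometry` list with `effective_volume_l`.
#' @export
respirometer_geometry <- function(chamber_volume_l, body_mass_kg,
                                  body_volume_l = body_mass_kg / 1.0) {
  if (!is.numeric(body_mass_kg) || body_mass_kg <= 0) {
    stop("geometry error: body_mass_kg must be > 0", call. = FALSE)
  }
  eff <- chamber_volume_l - body_volume_l
  if (!is.numeric(eff) || eff <= 0) {
    stop("geometry error: effective volume (chamber - body) must be > 0",
         call. = FALSE)
  }
  structure(list(chamber_volume_l = chamber_volume_l,
                 body_mass_kg = body_mass_kg,
                 body_volume_l = body_volume_l,
                 effective_volume_l = eff),
            class = "respirometer_geometry")
}

#' Intermittent-closed cycle plan
#'
#' Timing of the automated measure/flush cycle. The first
#' `equilibration_exclusion_s` seconds of every closed period (the mixing /
#' equilibration phase after the flush) are excluded from slope fitting.
#'
#' @param closed_duration_s closed (measurement) period duration (s).
#' @param flush_duration_s flush (re-oxygenation) period duration (s).
#' @param equilibration_exclusion_s leading exclusion within each closed
#'   period (s); default 300 (5 min).
#' @return a `cycle_plan` list.
#' @export
cycle_plan <- function(closed_duration_s, flush_duration_s,
                       equilibration_exclusion_s = 300) {
  if (closed_duration_s <= equilibration_exclusion_s) {
    stop("cycle_plan: closed_duration_s must exceed equilibration_exclusion_s",
         call. = FALSE)
  }
  if (flush_duration_s < 0) {
    stop("cycle_plan: flush_duration_s must be >= 0", call. = FALSE)
  }
  structure(list(closed_duration_s = closed_duration_s,
                 flush_duration_s = flush_duration_s,
                 equilibration_exclusion_s = equilibration_exclusion_s),
            class = "cycle_plan")
}

#' Locate closed-period windows in an oxygen trace
#'
#' Windows start at `t0_s + k * (closed + flush)` and span the closed
#' duration, truncated to the trace extent. Windows too short to leave at
#' least 2 minutes of data after the equilibration exclusion are dropped with
#' a message.
#'
#' @param trace an oxygen trace data.frame with `time_s`.
#' @param plan a [cycle_plan()].
#' @param t0_s start time of the first closed period; defaults to the first
#'   sample time.
#' @return data.frame (window_index, start_s, end_s) of usable closed windows.
#' @export
segment_cycles <- function(trace, plan, t0_s = NULL) {
  if (is.null(trace) || nrow(trace) == 0) {
    stop("input error: empty oxygen trace", call. = FALSE)
  }
  stopifnot(inherits(plan, "cycle_plan"))
  if (is.null(t0_s)) t0_s <- min(trace$time_s)
  t_end <- max(trace$time_s)
  cycle_s <- plan$closed_duration_s + plan$flush_duration_s
  starts <- seq(t0_s, t_end, by = cycle_s)
  ends <- pmin(starts + plan$closed_duration_s, t_end)
  keep <- (ends - starts) >= plan$equilibration_exclusion_s + 120
  if (any(!keep)) {
    message(sprintf(
      "segment_cycles: dropped %d window(s) shorter than exclusion + 120 s",
      sum(!keep)))
  }
  if (!any(keep)) {
    warning("segment_cycles: no usable closed windows in trace",
            call. = FALSE)
    return(data.frame(window_index = integer(0), start_s = numeric(0),
                      end_s = numeric(0)))
  }
  data.frame(window_index = seq_len(sum(keep)),
             start_s = starts[keep], end_s = ends[keep])
}

#' Fit the oxygen decline slope of one closed period
#'
#' Ordinary least-squares line on (time, oxygen) after discarding the leading
#' equilibration seconds; time is rescaled to hours so the slope is in
#' mg O2 L-1 h-1.
#'
#' @param samples data.frame with `time_s` and `o2_mg_per_l` for one window.
#' @param exclusion_s leading seconds to discard (equilibration).
#' @return list(slope, r2, n, ok). `ok = FALSE` (with NA slope) when fewer
#'   than 10 samples remain -- a QC outcome, not an error.
#' @export
fit_slope <- function(samples, exclusion_s = 300) {
  t0 <- min(samples$time_s)
  use <- samples[samples$time_s >= t0 + exclusion_s, , drop = FALSE]
  if (nrow(use) < 10) {
    return(list(slope = NA_real_, r2 = NA_real_, n = nrow(use), ok = FALSE))
  }
  th <- (use$time_s - min(use$time_s)) / 3600
  fit <- stats::lm(use$o2_mg_per_l ~ th)
  ss_tot <- sum((use$o2_mg_per_l - mean(use$o2_mg_per_l))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]), r2 = r2, n = nrow(use), ok = TRUE)
}

#' Blank-correct a raw slope and scale to mass-specific oxygen uptake
#'
#' `mo2 = (blank_slope - raw_slope) * effective_volume_l / body_mass_kg`.
#' A negative corrected rate (blank declining faster than the fish chamber)
#' is flagged as a QC failure rather than clamped, keeping the problem
#' visible.
#'
#' @param raw_slope fish-chamber slope (mg O2 L-1 h-1, expected <= 0).
#' @param blank_slope blank-chamber slope (mg O2 L-1 h-1, expected <= 0).
#' @param geometry a [respirometer_geometry()].
#' @return list(mo2, qc_pass); `mo2` is NA when `qc_pass` is FALSE.
#' @export
blank_correct_and_scale <- function(raw_slope, blank_slope, geometry) {
  stopifnot(inherits(geometry, "respirometer_geometry"))
  mo2 <- (blank_slope - raw_slope) * geometry$effective_volume_l /
    geometry$body_mass_kg
  if (is.na(mo2) || mo2 < 0) {
    list(mo2 = NA_real_, qc_pass = FALSE)
  } else {
    list(mo2 = mo2, qc_pass = TRUE)
  }
}

#' Extract per-closed-period oxygen uptake from a trace
#'
#' Segments the trace into closed windows, fits each window's decline slope
#' (after the equilibration exclusion), applies the blank correction and
#' geometry scaling, and returns one row per measurement interval with QC
#' flags (minimum r-squared, non-negative corrected rate).
#'
#' @param trace oxygen trace data.frame (time_s, o2_mg_per_l, temp_c,
#'   chamber_id).
#' @param plan a [cycle_plan()].
#' @param geometry a [respirometer_geometry()].
#' @param blank_slope background respiration slope to subtract
#'   (mg O2 L-1 h-1); use [match_blank()] to fill per-interval blanks instead.
#' @param t0_s start of the first closed period.
#' @param min_r2 minimum coefficient of determination for a slope to pass QC
#'   (the acceptance cutoff is not standardized in the field; 0.9 is applied
#'   and recorded as an assumption).
#' @return data.frame of intervals: chamber_id, interval_index, start_s,
#'   end_s, mean_temp_c, raw_slope, r2, n_samples, blank_slope, mo2, qc_pass.
#' @export
extract_mo2 <- function(trace, plan, geometry, blank_slope = 0,
                        t0_s = NULL, min_r2 = 0.9) {
  windows <- segment_cycles(trace, plan, t0_s)
  if (nrow(windows) == 0) {
    return(data.frame(chamber_id = character(0), interval_index = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      mean_temp_c = numeric(0), raw_slope = numeric(0),
                      r2 = numeric(0), n_samples = integer(0),
                      blank_slope = numeric(0), mo2 = numeric(0),
                      qc_pass = logical(0)))
  }
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    win <- trace[trace$time_s >= windows$start_s[i] &
                   trace$time_s < windows$end_s[i], , drop = FALSE]
    sl <- fit_slope(win, plan$equilibration_exclusion_s)
    if (!sl$ok) {
      return(data.frame(chamber_id = trace$chamber_id[1],
                        interval_index = windows$window_index[i],
                        start_s = windows$start_s[i], end_s = windows$end_s[i],
                        mean_temp_c = mean(win$temp_c),
                        raw_slope = NA_real_, r2 = NA_real_, n_samples = sl$n,
                        blank_slope = blank_slope, mo2 = NA_real_,
                        qc_pass = FALSE, stringsAsFactors = FALSE))
    }
    bc <- blank_correct_and_scale(sl$slope, blank_slope, geometry)
    r2_pass <- !is.na(sl$r2) && sl$r2 >= min_r2
    qc <- bc$qc_pass && r2_pass
    data.frame(chamber_id = trace$chamber_id[1],
               interval_index = windows$window_index[i],
               start_s = windows$start_s[i], end_s = windows$end_s[i],
               mean_temp_c = mean(win$temp_c),
               raw_slope = sl$slope, r2 = sl$r2, n_samples = sl$n,
               r2_pass = r2_pass, blank_slope = blank_slope,
               mo2 = if (qc) bc$mo2 else NA_real_,
               qc_pass = qc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign each fish interval the temporally nearest blank slope
#'
#' A fishless blank chamber is run alongside the fish chambers; each fish
#' interval receives the raw slope of the blank interval whose midpoint is
#' nearest in time (ties broken toward the earlier blank). If no blank
#' intervals are supplied, the blank slope is set to 0 with a warning.
#'
#' @param intervals fish interval table from [extract_mo2()].
#' @param blank_intervals blank-chamber interval table from [extract_mo2()]
#'   (its `raw_slope` column is used).
#' @param geometry a [respirometer_geometry()]; when given, `mo2` and
#'   `qc_pass` are recomputed with the matched blanks.
#' @return `intervals` with `blank_slope` filled (and `mo2` updated when
#'   `geometry` is supplied).
#' @export
match_blank <- function(intervals, blank_intervals, geometry = NULL) {
  if (is.null(blank_intervals) || nrow(blank_intervals) == 0) {
    warning("match_blank: no blank intervals available; using blank slope 0",
            call. = FALSE)
    intervals$blank_slope <- 0
  } else {
    bmid <- (blank_intervals$start_s + blank_intervals$end_s) / 2
    ord <- order(bmid)
    bmid <- bmid[ord]
    bslope <- blank_intervals$raw_slope[ord]
    fmid <- (intervals$start_s + intervals$end_s) / 2
    idx <- vapply(fmid, function(m) {
      d <- abs(bmid - m)
      which(d == min(d))[1]  # earlier blank wins ties
    }, integer(1))
    intervals$blank_slope <- bslope[idx]
  }
  if (!is.null(geometry)) {
    # re-derive mo2/qc with the matched blanks; qc needs both the slope
    # quality flag set upstream and a non-negative corrected rate
    r2_pass <- if ("r2_pass" %in% names(intervals)) {
      intervals$r2_pass
    } else !is.na(intervals$r2)
    for (i in seq_len(nrow(intervals))) {
      if (is.na(intervals$raw_slope[i]) || !isTRUE(r2_pass[i])) {
        intervals$mo2[i] <- NA_real_
        intervals$qc_pass[i] <- FALSE
        next
      }
      bc <- blank_correct_and_scale(intervals$raw_slope[i],
                                    intervals$blank_slope[i], geometry)
      intervals$mo2[i] <- bc$mo2
      intervals$qc_pass[i] <- bc$qc_pass
    }
  }
  intervals
}

#' Read an oxygen trace from a long-format CSV
#'
#' Expects columns time_s, o2_mg_per_l, temp_c, chamber_id; lines starting
#' with `#` are treated as header comments.
#'
#' @param path CSV path.
#' @param chamber_id optional chamber to select from a multi-chamber file.
#' @return an oxygen trace data.frame.
#' @export
read_oxygen_trace <- function(path, chamber_id = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "o2_mg_per_l", "temp_c", "chamber_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("input error: trace CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(chamber_id)) df <- df[df$chamber_id == chamber_id, ]
  if (any(diff(df$time_s) <= 0)) {
    stop("input error: time_s must be strictly increasing within a trace",
         call. = FALSE)
  }
  if (any(df$o2_mg_per_l < 0)) {
    stop("input error: o2_mg_per_l must be >= 0", call. = FALSE)
  }
  df
}
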