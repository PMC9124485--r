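#' Configuration for the synthetic winter-dormancy experiment generator
#'
#' Describes a simulated population of fish and the conditions of an acute
#' cooling + cold acclimation respirometry/behaviour experiment. The model
#' generated from this configuration is: per-fish SMR follows an Arrhenius-like
#' Q10 curve, `smr_i(T) = smr_ref_i * q10_smr_true^((T - t_ref_c)/10)`,
#' optionally suppressed by a fixed fraction below a threshold temperature
#' (metabolic rate depression, MRD); oxygen uptake during a measurement
#' interval is `smr_i(T) * exp(b_i * activity)` with multiplicative lognormal
#' noise; interval-level spontaneous activity is gamma distributed with a mean
#' set by the diel phase and damped by a logistic function of temperature,
#' truncated to exact zero below a tracker detection floor.
#'
#' @param n_fish number of fish.
#' @param temps_c strictly decreasing acute-cooling condition temperatures
#'   (deg C). The warmest is also used for the rewarmed condition and the
#'   coldest for the cold-acclimated condition.
#' @param t_ref_c reference temperature for `smr_ref` (deg C).
#' @param smr_ref population mean SMR at `t_ref_c` (mg O2 kg-1 h-1).
#' @param smr_cv inter-fish coefficient of variation of SMR (fraction).
#' @param q10_smr_true passive thermal sensitivity (Q10) of SMR.
#' @param activity_cost_b exponent of the activity -> oxygen-uptake coupling
#'   (per activity unit); `b_cv` gives its inter-fish CV.
#' @param b_cv inter-fish CV of the coupling exponent.
#' @param activity_day,activity_night mean spontaneous activity at `t_ref_c`
#'   by diel phase (activity units: body lengths per minute for tracked fish,
#'   percent time moving for eels -- the coupling model is unit agnostic).
#' @param dormancy_midpoint_c,dormancy_steepness midpoint (deg C) and
#'   steepness (per deg C) of the logistic decline of activity with cooling.
#' @param activity_floor tracker detection floor: interval activity below this
#'   is recorded as exactly zero (emulates the inactive-control subtraction).
#' @param mrd_enabled if `TRUE`, SMR is actively suppressed below
#'   `mrd_threshold_c` by fraction `mrd_suppression` (0-1).
#' @param mrd_threshold_c,mrd_suppression see `mrd_enabled`.
#' @param acclimation_factor multiplier applied to SMR in the cold-acclimated
#'   condition (1 = no compensation, matching the finding that SMR is
#'   unchanged after 4-6 weeks of cold acclimation).
#' @param noise_sigma_mo2 sd (log scale) of multiplicative lognormal
#'   measurement noise on oxygen uptake.
#' @param activity_shape gamma shape for interval-level activity.
#' @param intervals_per_phase measurement intervals per diel phase per
#'   temperature condition.
#' @param mass_mean_kg,mass_cv,length_mean_cm,length_cv body size
#'   distributions.
#' @param seed RNG seed; generation is reproducible given the seed.
#' @return an object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_fish = 4, intervals_per_phase = 5)
#' sim <- generate_pairs(cfg)
#' head(sim$pairs)
#' @export
synth_config <- function(n_fish = 12,
                         temps_c = c(14, 11, 8, 5, 2.5),
                         t_ref_c = 14,
                         smr_ref = 100,
                         smr_cv = 0.15,
                         q10_smr_true = 2.5,
                         activity_cost_b = 0.2,
                         b_cv = 0.1,
                         activity_day = 1,
                         activity_night = 2,
                         dormancy_midpoint_c = 7,
                         dormancy_steepness = 3,
                         activity_floor = 0.1,
                         mrd_enabled = FALSE,
                         mrd_threshold_c = 8,
                         mrd_suppression = 0.4,
                         acclimation_factor = 1,
                         noise_sigma_mo2 = 0.08,
                         activity_shape = 2,
                         intervals_per_phase = 20,
                         mass_mean_kg = 0.008,
                         mass_cv = 0.2,
                         length_mean_cm = 8,
                         length_cv = 0.1,
                         seed = 1L) {
  cfg <- list(
    n_fish = as.integer(n_fish), temps_c = as.numeric(temps_c),
    t_ref_c = t_ref_c, smr_ref = smr_ref, smr_cv = smr_cv,
    q10_smr_true = q10_smr_true, activity_cost_b = activity_cost_b,
    b_cv = b_cv, activity_day = activity_day, activity_night = activity_night,
    dormancy_midpoint_c = dormancy_midpoint_c,
    dormancy_steepness = dormancy_steepness, activity_floor = activity_floor,
    mrd_enabled = isTRUE(mrd_enabled), mrd_threshold_c = mrd_threshold_c,
    mrd_suppression = mrd_suppression, acclimation_factor = acclimation_factor,
    noise_sigma_mo2 = noise_sigma_mo2, activity_shape = activity_shape,
    intervals_per_phase = as.integer(intervals_per_phase),
    mass_mean_kg = mass_mean_kg, mass_cv = mass_cv,
    length_mean_cm = length_mean_cm, length_cv = length_cv,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a synthetic generator configuration
#'
#' @param cfg a `synth_config`.
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_synth_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid synth_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_fish) || cfg$n_fish < 1) fail("n_fish", "must be >= 1")
  if (length(cfg$temps_c) < 2 || any(diff(cfg$temps_c) >= 0)) {
    fail("temps_c", "must be a strictly decreasing sequence")
  }
  for (f in c("smr_ref", "q10_smr_true", "activity_shape")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be > 0")
  }
  for (f in c("smr_cv", "b_cv", "noise_sigma_mo2", "activity_floor",
              "activity_day", "activity_night")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  if (cfg$mrd_suppression < 0 || cfg$mrd_suppression >= 1) {
    fail("mrd_suppression", "must be in [0, 1)")
  }
  if (cfg$dormancy_steepness <= 0) fail("dormancy_steepness", "must be > 0")
  if (cfg$acclimation_factor <= 0) fail("acclimation_factor", "must be > 0")
  if (cfg$intervals_per_phase < 1) fail("intervals_per_phase", "must be >= 1")
  if (cfg$mass_mean_kg <= 0) fail("mass_mean_kg", "must be > 0")
  if (cfg$length_mean_cm <= 0) fail("length_mean_cm", "must be > 0")
  invisible(cfg)
}

#' Logistic cold-damping scaler for activity
#'
#' Fraction of warm-water activity retained at `temp_c`:
#' `1 / (1 + exp(-steepness * (temp_c - midpoint)))`. Approaches 1 well above
#' the dormancy midpoint and 0 well below it.
#'
#' @param temp_c temperature (deg C), vectorized.
#' @param cfg a `synth_config`.
#' @return values in (0, 1).
#' @export
activity_scaler <- function(temp_c, cfg) {
  stats::plogis(cfg$dormancy_steepness * (temp_c - cfg$dormancy_midpoint_c))
}

#' True (generator) SMR of a fish at a temperature
#'
#' The ground-truth standard metabolic rate:
#' `smr_ref_i * q10^((T - t_ref)/10)`, multiplied by `(1 - mrd_suppression)`
#' when MRD is enabled and `T < mrd_threshold_c`.
#'
#' @param fish one row of the fish-truth table (or any list with `smr_ref_i`).
#' @param temp_c temperature (deg C), vectorized.
#' @param cfg a `synth_config`.
#' @return SMR in mg O2 kg-1 h-1.
#' @export
true_smr <- function(fish, temp_c, cfg) {
  smr <- fish$smr_ref_i * cfg$q10_smr_true^((temp_c - cfg$t_ref_c) / 10)
  if (cfg$mrd_enabled) {
    smr <- smr * ifelse(temp_c < cfg$mrd_threshold_c,
                        1 - cfg$mrd_suppression, 1)
  }
  smr
}

# draw the per-fish ground-truth table
generate_fish_truth <- function(cfg) {
  data.frame(
    fish_id = sprintf("f%02d", seq_len(cfg$n_fish)),
    smr_ref_i = rlnorm_mean_cv(cfg$n_fish, cfg$smr_ref, cfg$smr_cv),
    b_i = rlnorm_mean_cv(cfg$n_fish, cfg$activity_cost_b, cfg$b_cv),
    mass_kg = rlnorm_mean_cv(cfg$n_fish, cfg$mass_mean_kg, cfg$mass_cv),
    total_length_cm = rlnorm_mean_cv(cfg$n_fish, cfg$length_mean_cm,
                                     cfg$length_cv),
    stringsAsFactors = FALSE
  )
}

# gamma interval activity with tracker floor; mean <= 0 gives exact zeros
draw_activity <- function(n, mean, shape, floor) {
  if (mean <= 0) return(rep(0, n))
  x <- stats::rgamma(n, shape = shape, rate = shape / mean)
  x[x < floor] <- 0
  x
}

#' Generate paired activity / oxygen-uptake records with known truth
#'
#' Simulates the core record of the analysis: one measurement interval's
#' spontaneous activity paired with its oxygen uptake, for every fish x
#' temperature condition x diel phase x interval. Conditions are the acute
#' cooling steps (`acute_<T>`), a cold-acclimated re-measurement at the
#' coldest temperature (`acclimated_<T>`) and an acute rewarming at the
#' warmest (`rewarmed_<T>`), with unchanged fish-level truth (no thermal
#' compensation unless `acclimation_factor != 1`).
#'
#' @param cfg a `synth_config`.
#' @return a list with elements `pairs` (data.frame: fish_id, condition,
#'   temp_c, phase, interval, activity, mo2) and `truth` (the fish-truth
#'   table, for recovery tests).
#' @export
generate_pairs <- function(cfg) {
  validate_synth_config(cfg)
  with_seed(cfg$seed, {
    truth <- generate_fish_truth(cfg)
    conds <- data.frame(
      condition = c(paste0("acute_", num_label(cfg$temps_c)),
                    paste0("acclimated_", num_label(min(cfg$temps_c))),
                    paste0("rewarmed_", num_label(max(cfg$temps_c)))),
      temp_c = c(cfg$temps_c, min(cfg$temps_c), max(cfg$temps_c)),
      smr_mult = c(rep(1, length(cfg$temps_c)), cfg$acclimation_factor, 1),
      stringsAsFactors = FALSE
    )
    out <- vector("list", nrow(conds) * cfg$n_fish * 2L)
    k <- 0L
    for (ci in seq_len(nrow(conds))) {
      scl <- activity_scaler(conds$temp_c[ci], cfg)
      for (fi in seq_len(cfg$n_fish)) {
        smr <- true_smr(truth[fi, ], conds$temp_c[ci], cfg) * conds$smr_mult[ci]
        for (phase in c("day", "night")) {
          lvl <- if (phase == "day") cfg$activity_day else cfg$activity_night
          act <- draw_activity(cfg$intervals_per_phase, lvl * scl,
                               cfg$activity_shape, cfg$activity_floor)
          noise <- if (cfg$noise_sigma_mo2 > 0) {
            exp(stats::rnorm(cfg$intervals_per_phase, 0, cfg$noise_sigma_mo2))
          } else rep(1, cfg$intervals_per_phase)
          k <- k + 1L
          out[[k]] <- data.frame(
            fish_id = truth$fish_id[fi],
            condition = conds$condition[ci],
            temp_c = conds$temp_c[ci],
            phase = phase,
            interval = seq_len(cfg$intervals_per_phase),
            activity = act,
            mo2 = smr * exp(truth$b_i[fi] * act) * noise,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    list(pairs = do.call(rbind, out[seq_len(k)]), truth = truth)
  })
}

#' Generate a daily behavioural cooling trial with known truth
#'
#' Emulates an acute 1 deg C per day cooling trial in behavioural arenas:
#' per fish x temperature x diel phase spontaneous activity (same
#' logistic-damped gamma model as [generate_pairs()]), sheltering fraction
#' (one minus the activity scaler, with bounded noise), a vigilance score
#' (mean of per-observation scores in {0, 0.5, 1} whose probabilities follow
#' the activity scaler), and a daily feeding fraction (binomial pellet counts
#' on a fixed ration with a logistic cold decline in feeding probability).
#'
#' @param cfg a `synth_config`.
#' @param temps_c temperatures of the daily cooling steps; defaults to 1 deg C
#'   steps from the warmest to the coldest configured condition temperature.
#' @param n_pellets pellets offered per day (ration of ~0.5% body mass).
#' @param shelter_sd sd of the additive noise on the sheltering fraction.
#' @param vigilance_obs number of scored observations per phase (one per
#'   30 min of a measurement window).
#' @return a list with `behaviour` (fish_id, temp_c, phase, activity,
#'   shelter_fraction, vigilance), `feeding` (fish_id, temp_c,
#'   feeding_fraction) and `truth`.
#' @export
generate_behavior_trial <- function(cfg,
                                    temps_c = seq(max(cfg$temps_c),
                                                  min(cfg$temps_c), by = -1),
                                    n_pellets = 20,
                                    shelter_sd = 0.05,
                                    vigilance_obs = 14) {
  validate_synth_config(cfg)
  if (any(diff(temps_c) >= 0)) {
    stop("invalid configuration: field 'temps_c' must be strictly decreasing",
         call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    truth <- generate_fish_truth(cfg)
    grid <- expand.grid(fish_id = truth$fish_id, temp_c = temps_c,
                        phase = c("day", "night"), stringsAsFactors = FALSE)
    scl <- activity_scaler(grid$temp_c, cfg)
    lvl <- ifelse(grid$phase == "day", cfg$activity_day, cfg$activity_night)
    grid$activity <- vapply(seq_len(nrow(grid)), function(i) {
      draw_activity(1, lvl[i] * scl[i], cfg$activity_shape, cfg$activity_floor)
    }, numeric(1))
    grid$shelter_fraction <- pmin(pmax(
      1 - scl + stats::rnorm(nrow(grid), 0, shelter_sd), 0), 1)
    grid$vigilance <- vapply(scl, function(s) {
      mean(sample(c(0, 0.5, 1), vigilance_obs, replace = TRUE,
                  prob = c((1 - s)^2, 2 * s * (1 - s), s^2)))
    }, numeric(1))
    feed <- expand.grid(fish_id = truth$fish_id, temp_c = temps_c,
                        stringsAsFactors = FALSE)
    p_feed <- activity_scaler(feed$temp_c, cfg)
    feed$feeding_fraction <-
      stats::rbinom(nrow(feed), n_pellets, p_feed) / n_pellets
    list(behaviour = grid, feeding = feed, truth = truth)
  })
}

#' Simulate an intermittent-closed respirometry oxygen trace
#'
#' Produces the raw time series a chamber optode would record: during each
#' closed period the oxygen concentration declines linearly at
#' `mo2_true * mass / effective_volume + |background_slope|` (mg O2 L-1 h-1),
#' optionally distorted by an exponential mixing transient after the flush;
#' during flush periods oxygen is restored to the saturation level. Gaussian
#' sensor noise is added pointwise.
#'
#' @param mo2_true mass-specific oxygen uptake of the fish
#'   (mg O2 kg-1 h-1); 0 for a blank chamber.
#' @param geometry a [respirometer_geometry()].
#' @param plan a [cycle_plan()].
#' @param n_cycles number of closed+flush cycles.
#' @param background_slope background (microbial) respiration as an oxygen
#'   decline rate (mg O2 L-1 h-1, sign ignored).
#' @param sensor_sd Gaussian sd of the optode reading (mg O2 L-1).
#' @param o2_saturation_mg_l oxygen level restored by each flush.
#' @param temp_c chamber temperature recorded alongside oxygen.
#' @param sample_interval_s optode sampling interval.
#' @param transient_amp,transient_tau_s amplitude (mg O2 L-1) and time
#'   constant (s) of an exponential equilibration transient at the start of
#'   each closed period (0 disables it).
#' @param chamber_id chamber label.
#' @param is_blank flag the trace as a fishless blank.
#' @param seed RNG seed for the sensor noise.
#' @return an `oxygen_trace`: a data.frame (time_s, o2_mg_per_l, temp_c,
#'   chamber_id) with attributes `is_blank` and `chamber_id`.
#' @export
simulate_oxygen_trace <- function(mo2_true, geometry, plan,
                                  n_cycles = 3,
                                  background_slope = 0,
                                  sensor_sd = 0,
                                  o2_saturation_mg_l = 10,
                                  temp_c = 14,
                                  sample_interval_s = 5,
                                  transient_amp = 0,
                                  transient_tau_s = 60,
                                  chamber_id = "ch1",
                                  is_blank = mo2_true == 0,
                                  seed = 1L) {
  stopifnot(inherits(geometry, "respirometer_geometry"),
            inherits(plan, "cycle_plan"))
  if (mo2_true < 0) stop("mo2_true must be >= 0", call. = FALSE)
  slope_h <- mo2_true * geometry$body_mass_kg / geometry$effective_volume_l +
    abs(background_slope)
  cycle_s <- plan$closed_duration_s + plan$flush_duration_s
  time_s <- seq(0, n_cycles * cycle_s - sample_interval_s,
                by = sample_interval_s)
  in_cycle <- time_s %% cycle_s
  closed <- in_cycle < plan$closed_duration_s
  o2 <- rep(o2_saturation_mg_l, length(time_s))
  o2[closed] <- o2_saturation_mg_l - slope_h * in_cycle[closed] / 3600 +
    transient_amp * exp(-in_cycle[closed] / transient_tau_s)
  if (sensor_sd > 0) {
    o2 <- with_seed(seed, o2 + stats::rnorm(length(o2), 0, sensor_sd))
  }
  o2 <- pmax(o2, 0)
  trace <- data.frame(time_s = time_s, o2_mg_per_l = o2, temp_c = temp_c,
                      chamber_id = chamber_id, stringsAsFactors = FALSE)
  attr(trace, "is_blank") <- isTRUE(is_blank)
  attr(trace, "chamber_id") <- chamber_id
  class(trace) <- c("oxygen_trace", "data.frame")
  trace
}
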