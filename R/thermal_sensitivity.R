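#' Q10 temperature quotient of a rate
#'
#' `Q10 = (rate_cold / rate_warm)^(10 / (temp_cold - temp_warm))`: the factor
#' by which the rate changes per 10 deg C. Passive (Arrhenius) effects on
#' ectotherm metabolism give Q10 around 2-3; values above 3.5 are commonly
#' taken to indicate active metabolic rate depression.
#'
#' @param rate_cold,rate_warm rates at the cold and warm endpoints (> 0).
#' @param temp_cold_c,temp_warm_c endpoint temperatures (deg C),
#'   `temp_cold_c < temp_warm_c`.
#' @return dimensionless Q10 (vectorized).
#' @examples
#' q10(50, 4, 100, 14)   # rate halves over 10 deg C -> Q10 = 2
#' @export
q10 <- function(rate_cold, temp_cold_c, rate_warm, temp_warm_c) {
  if (any(temp_cold_c >= temp_warm_c)) {
    stop("input error: temp_cold_c must be below temp_warm_c", call. = FALSE)
  }
  if (any(rate_cold <= 0 | rate_warm <= 0)) {
    stop("input error: rates must be > 0", call. = FALSE)
  }
  (rate_cold / rate_warm)^(10 / (temp_cold_c - temp_warm_c))
}

#' Default temperature intervals for thermal-sensitivity analysis
#'
#' Builds the standard set of named intervals from a condition table:
#' full cooling (warmest to coldest acute step), the warm and cold halves
#' split at a mid temperature, cold acclimation (warm acute to cold
#' acclimated) and acute rewarming (cold acclimated to rewarmed warm).
#'
#' @param conditions data.frame with columns `condition` and `temp_c`
#'   (unique rows), e.g. `unique(pairs[c("condition", "temp_c")])`.
#' @param mid_temp_c temperature splitting the cooling range; defaults to the
#'   median acute step.
#' @return data.frame: label, condition_warm, condition_cold.
#' @export
default_intervals <- function(conditions, mid_temp_c = NULL) {
  conditions <- unique(conditions[, c("condition", "temp_c")])
  acute <- conditions[grepl("^acute_", conditions$condition), ]
  acute <- acute[order(-acute$temp_c), ]
  if (nrow(acute) < 2) stop("need at least 2 acute conditions", call. = FALSE)
  if (is.null(mid_temp_c)) {
    mid_temp_c <- acute$temp_c[ceiling(nrow(acute) / 2)]
  }
  mid <- acute$condition[which.min(abs(acute$temp_c - mid_temp_c))]
  warmest <- acute$condition[1]
  coldest <- acute$condition[nrow(acute)]
  iv <- data.frame(
    label = c("full_cooling", "warm_half", "cold_half"),
    condition_warm = c(warmest, warmest, mid),
    condition_cold = c(coldest, mid, coldest),
    stringsAsFactors = FALSE
  )
  accl <- conditions$condition[grepl("^acclimated_", conditions$condition)]
  rewa <- conditions$condition[grepl("^rewarmed_", conditions$condition)]
  if (length(accl) == 1) {
    iv <- rbind(iv, data.frame(label = "acclimation",
                               condition_warm = warmest,
                               condition_cold = accl))
    if (length(rewa) == 1) {
      iv <- rbind(iv, data.frame(label = "rewarming",
                                 condition_warm = rewa,
                                 condition_cold = accl))
    }
  }
  iv
}

#' Per-fish Q10 across named temperature intervals
#'
#' For each interval and estimation method, computes each fish's Q10 from its
#' own SMR estimates (and measured endpoint temperatures) at the interval's
#' warm and cold conditions, then the mean and s.e.m. across fish. Fish
#' missing an endpoint are dropped and counted.
#'
#' @param smr SMR-estimate table (from [smr_individual()] or
#'   [smr_all_methods()]): needs fish_id, condition, temp_c, method, value.
#'   Fallback rows (method `lowest20_mo2` with a fallback provenance) are
#'   treated as part of the extrapolated-individual series.
#' @param intervals data.frame (label, condition_warm, condition_cold), e.g.
#'   from [default_intervals()].
#' @param threshold Q10 threshold above which metabolic rate depression is
#'   inferred (default 3.5).
#' @return data.frame per interval x method: label, method, n_fish,
#'   n_dropped, mean_q10, sem_q10, frac_above_threshold, mrd_flag; the
#'   per-fish Q10 vectors are attached as the `per_fish` attribute (a named
#'   list of data.frames).
#' @export
q10_per_fish <- function(smr, intervals, threshold = 3.5) {
  smr <- smr[smr$scope == "fish" & !is.na(smr$value), ]
  # a fallback row stands in for the extrapolated estimate of that fish/cond
  smr$series <- ifelse(
    smr$method == "extrapolated_individual" |
      grepl("^fallback", smr$provenance), "extrapolated_individual",
    smr$method)
  out <- list()
  per_fish <- list()
  for (i in seq_len(nrow(intervals))) {
    for (m in unique(smr$series)) {
      sm <- smr[smr$series == m, ]
      warm <- sm[sm$condition == intervals$condition_warm[i], ]
      cold <- sm[sm$condition == intervals$condition_cold[i], ]
      ids <- intersect(warm$fish_id, cold$fish_id)
      n_all <- length(union(warm$fish_id, cold$fish_id))
      if (length(ids) < 2) {
        if (n_all > 0) {
          message(sprintf(
            "q10_per_fish: interval %s method %s: fewer than 2 usable fish",
            intervals$label[i], m))
        }
        next
      }
      w <- warm[match(ids, warm$fish_id), ]
      c_ <- cold[match(ids, cold$fish_id), ]
      qs <- q10(c_$value, c_$temp_c, w$value, w$temp_c)
      key <- paste(intervals$label[i], m, sep = ".")
      per_fish[[key]] <- data.frame(fish_id = ids, q10 = qs,
                                    stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        label = intervals$label[i], method = m,
        n_fish = length(ids), n_dropped = n_all - length(ids),
        mean_q10 = mean(qs), sem_q10 = sem(qs),
        frac_above_threshold = mean(qs > threshold),
        mrd_flag = mean(qs) > threshold,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "per_fish") <- per_fish
  attr(res, "threshold") <- threshold
  res
}

#' Classify a Q10 result against the metabolic-rate-depression threshold
#'
#' A mean Q10 strictly above the threshold (default 3.5) flags active
#' metabolic rate depression (MRD); at or below it, the decline is consistent
#' with passive physicochemical slowing. The verdict also reports the
#' fraction of individual fish above the threshold, since individuals
#' commonly straddle it.
#'
#' @param mean_q10 mean Q10 across fish.
#' @param per_fish_q10 optional vector of individual Q10 values.
#' @param threshold MRD inference threshold (default 3.5; boundary value is
#'   classified passive).
#' @return list(mrd_flag, verdict, mean_q10, frac_above).
#' @export
classify_mrd <- function(mean_q10, per_fish_q10 = NULL, threshold = 3.5) {
  if (!is.finite(mean_q10) || mean_q10 <= 0) {
    stop("input error: mean_q10 must be a positive number", call. = FALSE)
  }
  flag <- mean_q10 > threshold
  frac <- if (is.null(per_fish_q10)) NA_real_ else
    mean(per_fish_q10 > threshold)
  verdict <- sprintf(
    "%s: mean Q10 = %.2f (threshold %.1f)%s",
    if (flag) "MRD-flagged" else "passive",
    mean_q10, threshold,
    if (!is.na(frac)) sprintf("; %.0f%% of individuals above threshold",
                              100 * frac) else "")
  list(mrd_flag = flag, verdict = verdict, mean_q10 = mean_q10,
       frac_above = frac)
}

#' Arrhenius breakpoint detection in an SMR-temperature relationship
#'
#' Transforms mean SMR by temperature to Arrhenius axes (reciprocal absolute
#' temperature vs natural-log rate) and compares a single straight line
#' against a continuous one-breakpoint piecewise line. The break location is
#' found by grid search over interior temperatures at 0.1 deg C resolution;
#' model selection uses the small-sample-corrected Akaike criterion (AICc).
#' At most one break is considered, and only when at least 7 points are
#' available (AICc for the 4-parameter broken-line model is undefined below
#' that).
#'
#' @param temp_c temperatures (deg C), at least 5 distinct values.
#' @param rate mean SMR (or other rate, > 0) at each temperature.
#' @param grid_res_c grid resolution for the break search (deg C).
#' @param edge_c margin keeping the break strictly inside the range (deg C).
#' @return list(points, breakpoint_c, segment_slopes, aicc_0, aicc_1,
#'   n_breaks, note). `segment_slopes` are on Arrhenius axes
#'   (d ln rate / d (1/T_K)); `breakpoint_c` is NA when the 0-break model is
#'   selected.
#' @export
arrhenius_breakpoints <- function(temp_c, rate, grid_res_c = 0.1,
                                  edge_c = 0.5) {
  if (length(temp_c) < 5) {
    return(list(points = NULL, breakpoint_c = NA_real_,
                segment_slopes = NA_real_, aicc_0 = NA_real_,
                aicc_1 = NA_real_, n_breaks = 0L,
                note = "fewer than 5 temperatures; no breakpoint analysis"))
  }
  if (any(rate <= 0)) stop("input error: rates must be > 0", call. = FALSE)
  ord <- order(temp_c)
  temp_c <- temp_c[ord]
  rate <- rate[ord]
  x <- 1 / (temp_c + 273.15)
  yl <- log(rate)
  n <- length(x)
  aicc <- function(rss, k) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  fit0 <- stats::lm(yl ~ x)
  rss0 <- sum(stats::residuals(fit0)^2)
  a0 <- aicc(rss0, 3)  # intercept + slope + sigma
  best <- list(aicc = Inf, bp = NA_real_, slopes = NA_real_)
  if (n >= 7) {
    cand <- seq(min(temp_c) + edge_c, max(temp_c) - edge_c, by = grid_res_c)
    for (bc in cand) {
      xb <- 1 / (bc + 273.15)
      z <- pmax(x - xb, 0)  # continuous at the break
      fit1 <- stats::lm(yl ~ x + z)
      rss1 <- sum(stats::residuals(fit1)^2)
      a1 <- aicc(rss1, 5)  # + slope change + break location
      if (a1 < best$aicc) {
        cf <- stats::coef(fit1)
        best <- list(aicc = a1, bp = bc,
                     slopes = c(cold = unname(cf[2] + cf[3]),
                                warm = unname(cf[2])))
      }
    }
  }
  if (is.finite(best$aicc) && best$aicc < a0) {
    list(points = data.frame(inv_t_k = x, ln_rate = yl, temp_c = temp_c),
         breakpoint_c = best$bp, segment_slopes = best$slopes,
         aicc_0 = a0, aicc_1 = best$aicc, n_breaks = 1L, note = "")
  } else {
    list(points = data.frame(inv_t_k = x, ln_rate = yl, temp_c = temp_c),
         breakpoint_c = NA_real_,
         segment_slopes = c(all = unname(stats::coef(fit0)[2])),
         aicc_0 = a0, aicc_1 = if (is.finite(best$aicc)) best$aicc else
           NA_real_,
         n_breaks = 0L,
         note = if (n < 7) "1-break model needs >= 7 points" else "")
  }
}

#' Contrast routine-metabolic-rate Q10 with activity-controlled Q10
#'
#' Computes the mean per-fish Q10 of routine metabolic rate (all oxygen
#' uptake values, activity uncontrolled) and of each activity-controlled SMR
#' method over the same intervals. When activity declines with cooling,
#' routine Q10 is inflated relative to SMR Q10 -- the confound the
#' activity-controlled methods exist to remove.
#'
#' @param pairs activity/oxygen-uptake pair table.
#' @param intervals interval table; default [default_intervals()] on the
#'   pairs' conditions.
#' @param band optional overlap band passed to [smr_all_methods()].
#' @param threshold MRD threshold.
#' @return the [q10_per_fish()] table over all methods including `routine`.
#' @export
q10_of_routine_vs_smr <- function(pairs, intervals = NULL, band = NULL,
                                  threshold = 3.5) {
  if (is.null(intervals)) {
    intervals <- default_intervals(unique(pairs[c("condition", "temp_c")]))
  }
  per_fish_routine <- do.call(rbind, lapply(split(pairs, pairs$fish_id),
                                            routine_mr))
  est <- rbind(smr_individual(pairs), per_fish_routine)
  if (!is.null(band)) {
    est <- rbind(est, do.call(rbind, lapply(split(pairs, pairs$fish_id),
                                            activity_controlled_mr, band)))
  }
  q10_per_fish(est, intervals, threshold = threshold)
}
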