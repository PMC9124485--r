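#' Detect a cold behavioural steady state (dormancy threshold)
#'
#' A species' dormancy threshold is the warmest temperature at which a
#' behavioural metric has already reached its cold steady state: every tested
#' temperature at or below the threshold is statistically indistinguishable
#' from the value at the coldest temperature. Each non-coldest temperature is
#' compared with the coldest by a within-fish paired two-sided test
#' (each fish its own control), Bonferroni-adjusted across the tested
#' temperatures; the threshold is the warmest temperature of the contiguous
#' non-significant run extending up from the coldest. If even the
#' second-coldest temperature differs significantly, no threshold is
#' reported.
#'
#' The paired-test engine substitutes for a Gamma-family mixed model with the
#' same inferential target (per-temperature contrast vs the coldest with fish
#' as its own control); `test` switches between the t-test on per-fish
#' differences (default) and the Wilcoxon signed-rank test for heavy-tailed
#' metrics.
#'
#' @param data data.frame with fish_id, temp_c, value (one metric, one diel
#'   phase).
#' @param alpha family-wise significance level (default 0.05).
#' @param test "t" (paired t on differences) or "wilcoxon".
#' @param min_fish minimum number of paired fish (default 5).
#' @return list(threshold_temp_c (NA if none), comparisons (data.frame:
#'   temp_c, n_pairs, p_raw, p_adj, significant), n_fish, alpha).
#' @export
detect_cold_steady_state <- function(data, alpha = 0.05,
                                     test = c("t", "wilcoxon"),
                                     min_fish = 5) {
  test <- match.arg(test)
  temps <- sort(unique(data$temp_c))
  if (length(temps) < 2) {
    stop("input error: need at least 2 temperatures", call. = FALSE)
  }
  coldest <- temps[1]
  tested <- temps[-1]
  ref <- data[data$temp_c == coldest, ]
  m <- length(tested)
  rows <- lapply(tested, function(tt) {
    cur <- data[data$temp_c == tt, ]
    ids <- intersect(ref$fish_id, cur$fish_id)
    if (length(ids) < min_fish) {
      return(data.frame(temp_c = tt, n_pairs = length(ids),
                        p_raw = NA_real_, p_adj = NA_real_,
                        significant = NA))
    }
    p <- paired_p(cur$value[match(ids, cur$fish_id)],
                  ref$value[match(ids, ref$fish_id)], test)
    p_adj <- min(1, p * m)  # Bonferroni across tested temperatures
    data.frame(temp_c = tt, n_pairs = length(ids), p_raw = p, p_adj = p_adj,
               significant = p_adj < alpha)
  })
  comp <- do.call(rbind, rows)
  if (all(is.na(comp$significant))) {
    warning("detect_cold_steady_state: insufficient pairing at all ",
            "temperatures", call. = FALSE)
    return(list(threshold_temp_c = NA_real_, comparisons = comp,
                n_fish = length(unique(data$fish_id)), alpha = alpha))
  }
  # contiguous non-significant run upward from the coldest tested temperature
  threshold <- NA_real_
  for (i in seq_len(nrow(comp))) {
    if (isTRUE(comp$significant[i]) || is.na(comp$significant[i])) break
    threshold <- comp$temp_c[i]
  }
  list(threshold_temp_c = threshold, comparisons = comp,
       n_fish = length(unique(data$fish_id)), alpha = alpha)
}

#' Mean transition (inactive or fasting) temperature across fish
#'
#' For each fish cooled through a strictly decreasing temperature sequence,
#' the transition temperature is the warmest temperature at which the metric
#' first falls to or below `zero_tol` *and stays there* at every colder
#' tested temperature (a fish that resumes activity or feeding at a colder
#' temperature has not yet transitioned). The population value is the mean
#' across transitioned fish; fish that never transition are counted but
#' excluded from the mean, and the population is flagged as not having
#' transitioned when fewer than half the fish did.
#'
#' @param data data.frame with fish_id, temp_c, value for one metric during
#'   monotone cooling.
#' @param zero_tol threshold under which the metric counts as zero (default
#'   0; raise to accommodate a tracker noise floor).
#' @return list(mean_temp_c, sem, n_transitioned, n_total,
#'   population_transitioned, per_fish).
#' @export
mean_transition_temperature <- function(data, zero_tol = 0) {
  per_fish <- lapply(split(data, data$fish_id), function(df) {
    df <- df[order(-df$temp_c), ]
    if (any(diff(df$temp_c) >= 0)) {
      stop("input error: temperature sequence must be strictly decreasing ",
           "within each fish", call. = FALSE)
    }
    zero <- df$value <= zero_tol
    # warmest onset that persists at all colder temperatures
    persistent <- rev(cumprod(rev(zero))) == 1
    if (any(persistent)) df$temp_c[which(persistent)[1]] else NA_real_
  })
  tt <- unlist(per_fish)
  n_total <- length(tt)
  n_trans <- sum(!is.na(tt))
  list(mean_temp_c = if (n_trans > 0) mean(tt, na.rm = TRUE) else NA_real_,
       sem = sem(tt),
       n_transitioned = n_trans, n_total = n_total,
       population_transitioned = n_trans / n_total >= 0.5,
       per_fish = data.frame(fish_id = names(per_fish),
                             transition_temp_c = unname(tt),
                             stringsAsFactors = FALSE))
}

#' Day-night contrast of a behavioural metric at each temperature
#'
#' Within-fish paired comparison of daytime vs nighttime values at each
#' temperature, Bonferroni-adjusted across temperatures -- the test behind
#' the "significant diel difference" annotations on cooling curves.
#'
#' @param data data.frame with fish_id, temp_c, phase ("day"/"night"), value.
#' @param alpha significance level.
#' @param test "t" or "wilcoxon".
#' @return data.frame: temp_c, n_pairs, p_raw, p_adj, significant;
#'   temperatures missing a phase are skipped.
#' @export
diel_contrast <- function(data, alpha = 0.05, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  temps <- sort(unique(data$temp_c))
  rows <- lapply(temps, function(tt) {
    day <- data[data$temp_c == tt & data$phase == "day", ]
    night <- data[data$temp_c == tt & data$phase == "night", ]
    ids <- intersect(day$fish_id, night$fish_id)
    if (length(ids) < 2) return(NULL)
    p <- paired_p(day$value[match(ids, day$fish_id)],
                  night$value[match(ids, night$fish_id)], test)
    data.frame(temp_c = tt, n_pairs = length(ids), p_raw = p)
  })
  comp <- do.call(rbind, rows)
  if (is.null(comp)) return(NULL)
  m <- nrow(comp)
  comp$p_adj <- pmin(1, comp$p_raw * m)
  comp$significant <- comp$p_adj < alpha
  comp
}
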