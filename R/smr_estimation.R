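#' Fit the exponential activity-metabolism relationship y = a * exp(b * x)
#'
#' Nonlinear least squares of oxygen uptake on spontaneous activity, the core
#' of activity-controlled SMR estimation: the intercept `a` is the
#' extrapolated oxygen uptake at zero activity (SMR) and `b` the cost of
#' activity. Starting values come from the log-linear regression
#' `ln y ~ x`; the significance of the activity effect (`p_value`) is the
#' two-sided test of the log-linear slope, which is also the natural scale on
#' which the multiplicative noise is additive.
#'
#' @param activity activity values (x).
#' @param mo2 oxygen uptake values (y, > 0), same length.
#' @param min_n minimum number of pairs (default 5).
#' @param min_spread minimum standard deviation of activity for the slope to
#'   be identifiable.
#' @return list(a, b, n, r2, p_value, converged). Unidentifiable or failed
#'   fits return `converged = FALSE` (never an error).
#' @export
fit_exponential <- function(activity, mo2, min_n = 5, min_spread = 1e-6) {
  ok <- is.finite(activity) & is.finite(mo2) & mo2 > 0
  x <- activity[ok]
  y <- mo2[ok]
  n <- length(x)
  bad <- list(a = NA_real_, b = NA_real_, n = n, r2 = NA_real_,
              p_value = NA_real_, converged = FALSE)
  if (n < min_n || stats::sd(x) <= min_spread) return(bad)
  loglin <- stats::lm(log(y) ~ x)
  cf <- stats::coef(loglin)
  # residual variance ~ 0: a perfect exponential relationship; summary()'s
  # t-test degenerates, so report p = 0 directly
  p_value <- if (stats::sigma(loglin) < 1e-10) {
    0
  } else {
    stats::summary.lm(loglin)$coefficients["x", "Pr(>|t|)"]
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * x),
                      start = list(a = exp(cf[[1]]), b = cf[[2]]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  est <- stats::coef(fit)
  if (!is.finite(est[["a"]]) || est[["a"]] <= 0) return(bad)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(a = est[["a"]], b = est[["b"]], n = n, r2 = r2, p_value = p_value,
       converged = TRUE)
}

smr_row <- function(scope, fish_id, condition, temp_c, method, value, n,
                    provenance = "") {
  data.frame(scope = scope, fish_id = fish_id, condition = condition,
             temp_c = temp_c, method = method, value = value, n = n,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' SMR of the lowest-20 oxygen uptake subset
#'
#' Mean of the 20 smallest oxygen uptake values at a condition; when fewer
#' than 20 pairs exist, all are used and the provenance notes the count.
#'
#' @param pairs data.frame with at least `mo2` (and optionally fish_id,
#'   condition, temp_c used for labelling).
#' @param k subset size (default 20).
#' @return one SMR-estimate row (scope, fish_id, condition, temp_c, method,
#'   value, n, provenance).
#' @export
smr_lowest20_mo2 <- function(pairs, k = 20) {
  y <- sort(pairs$mo2)
  use <- utils::head(y, k)
  smr_row(if (length(unique(pairs$fish_id)) == 1) "fish" else "group",
          if (length(unique(pairs$fish_id)) == 1) pairs$fish_id[1] else NA,
          pairs$condition[1], pairs$temp_c[1], "lowest20_mo2",
          mean(use), length(use),
          if (length(y) < k) sprintf("only %d pairs available", length(y))
          else "")
}

#' SMR from the lowest-20 spontaneous activity subset
#'
#' Mean oxygen uptake of the 20 pairs with the lowest activity. Ties in
#' activity are broken by lower oxygen uptake, then by earlier interval.
#'
#' @inheritParams smr_lowest20_mo2
#' @return one SMR-estimate row.
#' @export
smr_lowest20_activity <- function(pairs, k = 20) {
  tie3 <- if ("interval" %in% names(pairs)) pairs$interval else
    seq_len(nrow(pairs))
  ord <- order(pairs$activity, pairs$mo2, tie3)
  use <- pairs$mo2[utils::head(ord, k)]
  smr_row(if (length(unique(pairs$fish_id)) == 1) "fish" else "group",
          if (length(unique(pairs$fish_id)) == 1) pairs$fish_id[1] else NA,
          pairs$condition[1], pairs$temp_c[1], "lowest20_activity",
          mean(use), length(use),
          if (nrow(pairs) < k) sprintf("only %d pairs available", nrow(pairs))
          else "")
}

#' Individual extrapolated SMR with lowest-20 fallback
#'
#' For each fish at each condition, fits the exponential activity-metabolism
#' relationship and takes the intercept `a` as SMR when the fit converged and
#' the activity effect is significant (p < alpha). Otherwise (typically a
#' small spread of activity in the cold) the estimate falls back to the
#' lowest-20 oxygen uptake mean, recorded in the provenance.
#'
#' @param pairs activity/oxygen-uptake pair table (fish_id, condition,
#'   temp_c, activity, mo2).
#' @param condition optional single condition to restrict to.
#' @param alpha significance level for the activity effect (default 0.05).
#' @param min_n minimum pairs for fitting.
#' @return data.frame of per-fish SMR estimates with method
#'   `extrapolated_individual` or the fallback `lowest20_mo2`.
#' @export
smr_individual <- function(pairs, condition = NULL, alpha = 0.05, min_n = 5) {
  if (!is.null(condition)) pairs <- pairs[pairs$condition %in% condition, ]
  out <- list()
  for (cond in unique(pairs$condition)) {
    pc <- pairs[pairs$condition == cond, ]
    for (f in unique(pc$fish_id)) {
      pf <- pc[pc$fish_id == f, ]
      fit <- fit_exponential(pf$activity, pf$mo2, min_n = min_n)
      if (fit$converged && !is.na(fit$p_value) && fit$p_value < alpha) {
        out[[length(out) + 1L]] <- smr_row(
          "fish", f, cond, pf$temp_c[1], "extrapolated_individual",
          fit$a, fit$n, "")
      } else {
        fb <- smr_lowest20_mo2(pf)
        fb$provenance <- paste0("fallback: ",
                                if (!fit$converged) "fit not converged"
                                else "activity effect not significant")
        out[[length(out) + 1L]] <- fb
      }
    }
  }
  if (!length(out)) {
    warning("smr_individual: no usable estimates", call. = FALSE)
    return(NULL)
  }
  do.call(rbind, out)
}

#' Group (pooled) extrapolated SMR
#'
#' One exponential fit per condition pooling all fish's activity /
#' oxygen-uptake pairs; the pooled intercept is the group SMR.
#'
#' @inheritParams smr_individual
#' @return data.frame of per-condition group SMR estimates (method
#'   `extrapolated_group`).
#' @export
smr_group <- function(pairs, condition = NULL, min_n = 5) {
  if (!is.null(condition)) pairs <- pairs[pairs$condition %in% condition, ]
  out <- list()
  for (cond in unique(pairs$condition)) {
    pc <- pairs[pairs$condition == cond, ]
    if (length(unique(pc$fish_id)) < 2) {
      warning(sprintf("smr_group: fewer than 2 fish at condition %s", cond),
              call. = FALSE)
      next
    }
    fit <- fit_exponential(pc$activity, pc$mo2, min_n = min_n)
    if (!fit$converged) {
      out[[length(out) + 1L]] <- smr_row("group", NA, cond, pc$temp_c[1],
                                         "extrapolated_group", NA_real_,
                                         fit$n, "fit not converged")
    } else {
      out[[length(out) + 1L]] <- smr_row("group", NA, cond, pc$temp_c[1],
                                         "extrapolated_group", fit$a, fit$n,
                                         "")
    }
  }
  do.call(rbind, out)
}

#' Activity-controlled metabolic rate within an overlapping activity band
#'
#' Mean oxygen uptake of pairs whose activity falls inside a narrow band
#' occupied at every compared temperature (e.g. 0.8-1.8 BL min-1, or 0-5% of
#' time moving for eels). Controls for activity without extrapolating.
#'
#' @param pairs pair table for one fish or the whole group.
#' @param band numeric length-2, `c(lo, hi)` with `lo < hi`; inclusive.
#' @return one SMR-estimate row per condition present (method
#'   `overlap_band`); conditions with an empty band get NA with a diagnostic
#'   provenance listing occupancy.
#' @export
activity_controlled_mr <- function(pairs, band) {
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("input error: band must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  out <- list()
  for (cond in unique(pairs$condition)) {
    pc <- pairs[pairs$condition == cond, ]
    inband <- pc[pc$activity >= band[1] & pc$activity <= band[2], ]
    scope <- if (length(unique(pc$fish_id)) == 1) "fish" else "group"
    fid <- if (scope == "fish") pc$fish_id[1] else NA
    if (nrow(inband) == 0) {
      out[[length(out) + 1L]] <- smr_row(
        scope, fid, cond, pc$temp_c[1], "overlap_band", NA_real_, 0L,
        sprintf("band [%g, %g] unoccupied (activity range %.3g-%.3g)",
                band[1], band[2], min(pc$activity), max(pc$activity)))
    } else {
      out[[length(out) + 1L]] <- smr_row(
        scope, fid, cond, pc$temp_c[1], "overlap_band",
        mean(inband$mo2), nrow(inband), "")
    }
  }
  do.call(rbind, out)
}

#' Widest activity band occupied at every condition
#'
#' Helper for choosing the overlap band of [activity_controlled_mr()]: the
#' intersection of the per-condition activity ranges. Never applied silently.
#'
#' @param pairs pair table.
#' @param min_per_condition require at least this many pairs inside the band
#'   at each condition before returning it.
#' @return `c(lo, hi)`, or NULL when no common band exists.
#' @export
suggest_activity_band <- function(pairs, min_per_condition = 3) {
  rngs <- do.call(rbind, lapply(split(pairs$activity, pairs$condition), range))
  lo <- max(rngs[, 1])
  hi <- min(rngs[, 2])
  if (lo >= hi) return(NULL)
  counts <- vapply(split(pairs, pairs$condition), function(pc) {
    sum(pc$activity >= lo & pc$activity <= hi)
  }, numeric(1))
  if (any(counts < min_per_condition)) return(NULL)
  c(lo, hi)
}

#' Routine metabolic rate
#'
#' Mean of all oxygen uptake values at each condition, with no control for
#' activity. Always at least as large as the extrapolated SMR when activity
#' carries a positive metabolic cost.
#'
#' @param pairs pair table.
#' @return one SMR-estimate row per condition (method `routine`).
#' @export
routine_mr <- function(pairs) {
  out <- lapply(unique(pairs$condition), function(cond) {
    pc <- pairs[pairs$condition == cond, ]
    scope <- if (length(unique(pc$fish_id)) == 1) "fish" else "group"
    smr_row(scope, if (scope == "fish") pc$fish_id[1] else NA, cond,
            pc$temp_c[1], "routine", mean(pc$mo2), nrow(pc), "")
  })
  do.call(rbind, out)
}

#' All SMR / metabolic-rate estimates in one tidy table
#'
#' Runs the individual extrapolation (with fallback), pooled group
#' extrapolation, both lowest-20 subsets (per fish), the overlap-band
#' activity-controlled mean (per fish, if a band is given) and routine
#' metabolic rate, and binds them into one table.
#'
#' @inheritParams smr_individual
#' @param band optional activity band for [activity_controlled_mr()].
#' @return data.frame of SMR estimates across methods.
#' @export
smr_all_methods <- function(pairs, band = NULL, alpha = 0.05) {
  per_fish <- split(pairs, pairs$fish_id)
  res <- list(
    smr_individual(pairs, alpha = alpha),
    smr_group(pairs),
    do.call(rbind, lapply(per_fish, function(pf) {
      do.call(rbind, lapply(split(pf, pf$condition), smr_lowest20_mo2))
    })),
    do.call(rbind, lapply(per_fish, function(pf) {
      do.call(rbind, lapply(split(pf, pf$condition), smr_lowest20_activity))
    })),
    routine_mr(pairs)
  )
  if (!is.null(band)) {
    res[[length(res) + 1L]] <- do.call(rbind, lapply(per_fish, function(pf) {
      activity_controlled_mr(pf, band)
    }))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
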