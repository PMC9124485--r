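make_panel <- function(temps, value_fn, n_fish = 8, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_fish), function(f) {
    data.frame(fish_id = sprintf("f%02d", f), temp_c = temps,
               value = value_fn(temps, f), stringsAsFactors = FALSE)
  }))
}

test_that("steady-state detection spans all temperatures when nothing changes", {
  temps <- c(14, 12, 10, 8, 6, 4, 2)
  # each fish holds its own constant value at every temperature
  d <- make_panel(temps, function(tt, f) rep(f / 10, length(tt)))
  res <- detect_cold_steady_state(d)
  expect_equal(res$threshold_temp_c, 14)
  expect_true(all(!res$comparisons$significant))
  expect_true(all(res$comparisons$p_adj == 1))
})

test_that("a clear behavioural step puts the threshold at the plateau edge", {
  temps <- c(14, 12, 10, 8, 6, 4, 2)
  d <- make_panel(temps, function(tt, f) {
    ifelse(tt >= 8, 5 + stats::rnorm(length(tt), 0, 0.3), 0)
  }, seed = 101)
  res <- detect_cold_steady_state(d)
  expect_equal(res$threshold_temp_c, 6)
  comp <- res$comparisons
  expect_true(all(comp$significant[comp$temp_c >= 8]))
  expect_true(all(!comp$significant[comp$temp_c <= 6]))
  # Bonferroni: adjusted p is the raw p times the number of comparisons
  expect_equal(comp$p_adj, pmin(1, comp$p_raw * nrow(comp)))

  # threshold is invariant under positive affine rescaling of the metric
  d2 <- d; d2$value <- 3.7 * d$value + 12
  expect_equal(detect_cold_steady_state(d2)$threshold_temp_c, 6)

  # the Wilcoxon engine agrees on this unambiguous step
  expect_equal(detect_cold_steady_state(d, test = "wilcoxon")$threshold_temp_c,
               6)
})

test_that("no threshold is reported when even the second-coldest differs", {
  temps <- c(14, 10, 6, 2)
  d <- make_panel(temps, function(tt, f) tt + stats::rnorm(length(tt), 0, 0.1),
                  seed = 103)
  res <- detect_cold_steady_state(d)
  expect_true(is.na(res$threshold_temp_c))
  expect_true(all(res$comparisons$significant))
  expect_error(detect_cold_steady_state(d[d$temp_c == 2, ]), "2 temperatures")
})

test_that("family-wise error stays controlled under the null", {
  set.seed(211)
  temps <- c(14, 12, 10, 8, 6, 4, 2)
  reps <- 500
  any_sig <- vapply(seq_len(reps), function(r) {
    d <- make_panel(temps, function(tt, f) stats::rnorm(length(tt)),
                    seed = 1000 + r)
    any(detect_cold_steady_state(d)$comparisons$significant, na.rm = TRUE)
  }, logical(1))
  # Bonferroni guarantees FWER <= alpha; allow binomial slack over 500 reps
  expect_lt(mean(any_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("transition temperature is the warmest persistent-zero onset", {
  mk <- function(fish_id, temps, values) {
    data.frame(fish_id = fish_id, temp_c = temps, value = values)
  }
  temps <- c(10, 9, 8, 7, 6, 5, 4)
  d <- rbind(
    mk("a", temps, c(2, 2, 1, 0, 0, 0, 0)),   # transitions at 7
    mk("b", temps, c(2, 1, 0, 0, 0, 0, 0)),   # transitions at 8
    mk("c", temps, c(2, 2, 2, 0, 0, 0, 0)),   # transitions at 7
    mk("d", temps, c(2, 2, 2, 1, 0, 0, 0)))   # transitions at 6
  res <- mean_transition_temperature(d)
  expect_equal(res$mean_temp_c, mean(c(7, 8, 7, 6)))
  expect_equal(res$n_transitioned, 4)
  expect_true(res$population_transitioned)
  expect_equal(sort(res$per_fish$transition_temp_c), c(6, 7, 7, 8))

  # a fish that resumes activity at a colder temperature has not transitioned
  d2 <- rbind(mk("a", temps, c(2, 0, 0, 1, 0, 0, 0)),  # onset only at 6
              mk("b", temps, c(2, 2, 2, 2, 2, 2, 1)))  # never reaches zero
  res2 <- mean_transition_temperature(d2)
  expect_equal(res2$per_fish$transition_temp_c[res2$per_fish$fish_id == "a"],
               6)
  expect_equal(res2$n_transitioned, 1)
  expect_equal(res2$n_total, 2)
  expect_true(res2$population_transitioned)  # exactly half counts

  # tracker noise floor: small residuals below zero_tol count as zero
  d3 <- mk("a", temps, c(2, 2, 0.05, 0.04, 0.02, 0.05, 0.01))
  expect_true(is.na(mean_transition_temperature(d3)$per_fish$transition_temp_c))
  expect_equal(mean_transition_temperature(d3, zero_tol = 0.1)$mean_temp_c, 8)

  expect_error(mean_transition_temperature(mk("a", c(5, 5), c(1, 0))),
               "strictly decreasing")
})

test_that("diel contrasts flag day-night differences only where they exist", {
  set.seed(307)
  temps <- c(14, 10, 6)
  d <- do.call(rbind, lapply(1:8, function(f) {
    do.call(rbind, lapply(temps, function(tt) {
      day <- if (tt >= 10) 1 + stats::rnorm(1, 0, 0.1) else 0.2 +
        stats::rnorm(1, 0, 0.05)
      night <- if (tt >= 10) 3 + stats::rnorm(1, 0, 0.1) else 0.2 +
        stats::rnorm(1, 0, 0.05)
      data.frame(fish_id = sprintf("f%02d", f), temp_c = tt,
                 phase = c("day", "night"), value = c(day, night))
    }))
  }))
  comp <- diel_contrast(d)
  expect_true(all(comp$significant[comp$temp_c >= 10]))
  expect_false(comp$significant[comp$temp_c == 6])
  expect_equal(comp$p_adj, pmin(1, comp$p_raw * nrow(comp)))
})

test_that("the synthetic cooling trial yields a detectable activity plateau", {
  cfg <- synth_config(n_fish = 12, dormancy_midpoint_c = 7,
                      dormancy_steepness = 5, seed = 61)
  trial <- generate_behavior_trial(cfg)
  act <- trial$behaviour[trial$behaviour$phase == "night",
                         c("fish_id", "temp_c", "activity")]
  names(act)[3] <- "value"
  res <- detect_cold_steady_state(act)
  expect_false(is.na(res$threshold_temp_c))
  # plateau edge sits near the generator's damping midpoint
  expect_lte(abs(res$threshold_temp_c - cfg$dormancy_midpoint_c), 2)
})
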