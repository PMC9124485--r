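test_that("exponential fit recovers exact relationships and flags bad input", {
  x <- c(0, 2, 5, 10, 12)
  fit <- fit_exponential(x, 50 * exp(0.1 * x))
  expect_true(fit$converged)
  expect_equal(fit$a, 50, tolerance = 1e-8)
  expect_equal(fit$b, 0.1, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$p_value, 0.05)

  same <- fit_exponential(rep(1, 10), rexp(10) + 1)
  expect_false(same$converged)
  few <- fit_exponential(1:3, exp(1:3))
  expect_false(few$converged)
})

test_that("fit recovers intercept and slope under multiplicative noise", {
  set.seed(17)
  a <- 100; b <- 0.2; n <- 40
  reps <- 200
  ahat <- bhat <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rgamma(n, 2, rate = 2 / 1.5)
    y <- a * exp(b * x) * exp(rnorm(n, 0, 0.08))
    f <- fit_exponential(x, y)
    ahat[r] <- f$a
    bhat[r] <- f$b
  }
  expect_gte(mean(abs(ahat - a) / a < 0.1), 0.9)
  expect_lt(abs(mean(ahat) - a) / a, 0.03)  # intercept bias under 3%
  expect_lt(abs(mean(bhat) - b) / b, 0.05)  # slope bias under 5%
})

test_that("individual SMR uses the extrapolation when significant, else the lowest-20 fallback", {
  set.seed(23)
  x <- rgamma(40, 2, rate = 1)
  good <- data.frame(fish_id = "f1", condition = "acute_14", temp_c = 14,
                     interval = 1:40, activity = x,
                     mo2 = 90 * exp(0.25 * x) * exp(rnorm(40, 0, 0.05)))
  est <- smr_individual(good)
  expect_equal(est$method, "extrapolated_individual")
  expect_equal(est$value, fit_exponential(good$activity, good$mo2)$a)

  flat <- good
  flat$activity <- 0  # no spread: unidentifiable, must fall back
  est2 <- smr_individual(flat)
  expect_match(est2$provenance, "fallback")
  expect_equal(est2$value, smr_lowest20_mo2(flat)$value)
})

test_that("noiseless synthetic data is recovered to 1e-6 relative error", {
  cfg <- noiseless_config(n_fish = 3, seed = 29)
  sim <- generate_pairs(cfg)
  est <- smr_individual(sim$pairs)
  for (i in seq_len(nrow(est))) {
    fish <- sim$truth[sim$truth$fish_id == est$fish_id[i], ]
    expect_equal(est$value[i], true_smr(fish, est$temp_c[i], cfg),
                 tolerance = 1e-6)
  }
})

test_that("group SMR is the pooled fit and matches individuals when homogeneous", {
  cfg <- noiseless_config(n_fish = 4, seed = 37)
  pairs <- generate_pairs(cfg)$pairs
  warm <- pairs[pairs$condition == "acute_14", ]
  grp <- smr_group(warm)
  expect_equal(grp$value, fit_exponential(warm$activity, warm$mo2)$a)
  ind <- smr_individual(warm)
  expect_equal(rep(grp$value, nrow(ind)), ind$value, tolerance = 1e-6)
})

test_that("lowest-20 subsets match the brute-force sort oracle", {
  p <- function(mo2, act = seq_along(mo2)) {
    data.frame(fish_id = "f", condition = "c", temp_c = 5,
               interval = seq_along(mo2), activity = act, mo2 = mo2)
  }
  expect_equal(smr_lowest20_mo2(p(rep(30, 20)))$value, 30)
  expect_equal(smr_lowest20_mo2(p(40:1))$value, mean(1:20))
  small <- smr_lowest20_mo2(p(1:7))
  expect_equal(small$value, mean(1:7))
  expect_match(small$provenance, "7")
  set.seed(5)
  for (i in 1:10) {
    v <- runif(60, 10, 200)
    a <- runif(60, 0, 3)
    expect_equal(smr_lowest20_mo2(p(v, a))$value, mean(sort(v)[1:20]))
    expect_equal(smr_lowest20_activity(p(v, a))$value,
                 mean(v[order(a, v)][1:20]))
  }
  # all activities tied: tie rule picks the 20 lowest uptake values
  v <- runif(40, 10, 200)
  expect_equal(smr_lowest20_activity(p(v, rep(1, 40)))$value,
               mean(sort(v)[1:20]))
})

test_that("activity-controlled band mean controls activity without extrapolating", {
  set.seed(13)
  x <- runif(50, 0.8, 1.8)
  inband <- data.frame(fish_id = "f", condition = "acute_8", temp_c = 8,
                       interval = 1:50, activity = x,
                       mo2 = 80 * exp(0.2 * x))
  got <- activity_controlled_mr(inband, c(0.8, 1.8))
  expect_equal(got$value, mean(80 * exp(0.2 * x)))  # closed-form, no noise
  empty <- activity_controlled_mr(inband, c(5, 6))
  expect_true(is.na(empty$value))
  expect_match(empty$provenance, "unoccupied")
  expect_error(activity_controlled_mr(inband, c(2, 1)), "band")
  band <- suggest_activity_band(inband)
  expect_true(band[1] < band[2])
})

test_that("routine rate sits above activity-controlled and extrapolated SMR", {
  single <- data.frame(fish_id = "f", condition = "c", temp_c = 10,
                       interval = 1, activity = 0.5, mo2 = 77)
  expect_equal(routine_mr(single)$value, 77)

  # expectation ordering: routine >= low-band mean >= extrapolated intercept
  set.seed(19)
  reps <- 100
  diffs <- t(vapply(seq_len(reps), function(r) {
    x <- rgamma(40, 2, rate = 2 / 1.5)
    d <- data.frame(fish_id = "f", condition = "c", temp_c = 10,
                    interval = 1:40, activity = x,
                    mo2 = 100 * exp(0.2 * x) * exp(rnorm(40, 0, 0.08)))
    rt <- routine_mr(d)$value
    bd <- activity_controlled_mr(d, c(0, 1))$value
    sm <- fit_exponential(d$activity, d$mo2)$a
    c(rt - bd, bd - sm)
  }, numeric(2)))
  expect_lt(t.test(diffs[, 1], alternative = "greater")$p.value, 0.01)
  expect_lt(t.test(diffs[, 2], alternative = "greater")$p.value, 0.01)
})

test_that("the combined estimate table carries every method", {
  pairs <- generate_pairs(small_config(n_fish = 3, seed = 43))$pairs
  tab <- smr_all_methods(pairs, band = c(0.8, 1.8))
  expect_setequal(
    unique(tab$method),
    c("extrapolated_individual", "extrapolated_group", "lowest20_mo2",
      "lowest20_activity", "routine", "overlap_band"))
})
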