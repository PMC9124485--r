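test_that("closed-period segmentation finds the expected windows", {
  plan <- cycle_plan(900, 300)
  tr <- data.frame(time_s = seq(0, 3599, 5), o2_mg_per_l = 8, temp_c = 10,
                   chamber_id = "ch1")
  win <- segment_cycles(tr, plan, t0_s = 0)
  expect_equal(nrow(win), 3)
  expect_equal(win$start_s, c(0, 1200, 2400))

  short <- tr[tr$time_s < 300, ]
  expect_warning(w <- suppressMessages(segment_cycles(short, plan, 0)),
                 "no usable")
  expect_equal(nrow(w), 0)
  expect_error(segment_cycles(tr[0, ], plan), "empty")
})

test_that("windows never overlap and never exceed the closed duration", {
  set.seed(42)
  for (i in 1:20) {
    closed <- sample(500:2000, 1)
    flush <- sample(60:600, 1)
    plan <- cycle_plan(closed, flush, 300)
    tr <- data.frame(time_s = seq(0, sample(3000:20000, 1), 5),
                     o2_mg_per_l = 8, temp_c = 10, chamber_id = "c")
    win <- suppressMessages(suppressWarnings(segment_cycles(tr, plan, 0)))
    if (nrow(win) == 0) next
    expect_true(all(win$end_s - win$start_s <= closed))
    if (nrow(win) > 1) {
      expect_true(all(win$start_s[-1] >= win$end_s[-nrow(win)]))
    }
  }
})

test_that("slope fitting matches the closed-form least-squares oracle", {
  # exact line: 8.0 -> 7.5 mg/L over half an hour
  t_s <- seq(0, 1800, 10)
  o2 <- 8 - 0.5 * t_s / 1800
  sl <- fit_slope(data.frame(time_s = t_s, o2_mg_per_l = o2), exclusion_s = 0)
  expect_equal(sl$slope, -1.0, tolerance = 1e-12)
  expect_equal(sl$r2, 1, tolerance = 1e-12)

  flat <- fit_slope(data.frame(time_s = t_s, o2_mg_per_l = 8),
                    exclusion_s = 0)
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  # noisy line vs normal equations computed independently
  set.seed(1)
  o2n <- 8 - 1.2 * t_s / 3600 + rnorm(length(t_s), 0, 0.01)
  sl <- fit_slope(data.frame(time_s = t_s, o2_mg_per_l = o2n),
                  exclusion_s = 300)
  keep <- t_s >= 300
  th <- (t_s[keep] - 300) / 3600
  y <- o2n[keep]
  beta <- (sum(th * y) - sum(th) * sum(y) / length(y)) /
    (sum(th^2) - sum(th)^2 / length(th))
  expect_equal(sl$slope, beta, tolerance = 1e-10)
})

test_that("too-sparse windows are flagged rather than raising", {
  few <- data.frame(time_s = seq(0, 400, 50), o2_mg_per_l = 8)
  sl <- fit_slope(few, exclusion_s = 300)
  expect_false(sl$ok)
  expect_true(is.na(sl$slope))
})

test_that("blank correction and mass scaling follow the standard formula", {
  geom <- respirometer_geometry(0.9 + 0.045, 0.045)
  expect_equal(geom$effective_volume_l, 0.9)
  expect_equal(blank_correct_and_scale(-1.0, -0.1, geom)$mo2, 18.0)
  expect_equal(blank_correct_and_scale(-0.5, -0.5, geom)$mo2, 0)
  g2 <- respirometer_geometry(1.01, 0.01)
  expect_equal(blank_correct_and_scale(-1.0, 0, g2)$mo2, 100.0)
  # blank declining faster than fish chamber: QC failure, not clamping
  bad <- blank_correct_and_scale(-0.1, -0.5, geom)
  expect_false(bad$qc_pass)
  expect_true(is.na(bad$mo2))
  # linear in effective volume, inverse in mass
  expect_equal(blank_correct_and_scale(-1, 0, respirometer_geometry(2.01, 0.01))$mo2,
               2 * blank_correct_and_scale(-1, 0, respirometer_geometry(1.01, 0.01))$mo2)
  expect_equal(blank_correct_and_scale(-1, 0, respirometer_geometry(1.02, 0.02))$mo2,
               blank_correct_and_scale(-1, 0, respirometer_geometry(1.01, 0.01))$mo2 / 2)
})

test_that("geometry invariants are enforced", {
  expect_error(respirometer_geometry(0.05, 0.1), "effective volume")
  expect_error(respirometer_geometry(1, 0), "body_mass_kg")
})

test_that("blank matching picks the temporally nearest blank, earlier on ties", {
  mk <- function(starts, slopes) {
    data.frame(chamber_id = "b", interval_index = seq_along(starts),
               start_s = starts, end_s = starts + 600,
               mean_temp_c = 10, raw_slope = slopes, r2 = 1,
               n_samples = 100, r2_pass = TRUE, blank_slope = 0,
               mo2 = NA_real_, qc_pass = TRUE)
  }
  fish <- mk(c(0, 1000, 2000), c(-1, -1, -1))
  one_blank <- mk(500, -0.05)
  expect_equal(match_blank(fish, one_blank)$blank_slope, rep(-0.05, 3))

  # fish midpoint 1300 equidistant from blank midpoints 800 and 1800
  fish2 <- mk(1000, -1)
  blanks <- mk(c(500, 1500), c(-0.02, -0.08))
  expect_equal(match_blank(fish2, blanks)$blank_slope, -0.02)

  # randomized interleavings vs brute-force minimum |dt| search
  set.seed(9)
  for (i in 1:10) {
    fs <- mk(sort(runif(6, 0, 10000)), rep(-1, 6))
    bs <- mk(sort(runif(4, 0, 10000)), runif(4, -0.1, 0))
    got <- match_blank(fs, bs)$blank_slope
    fmid <- (fs$start_s + fs$end_s) / 2
    bmid <- (bs$start_s + bs$end_s) / 2
    want <- vapply(fmid, function(m) {
      bs$raw_slope[which.min(abs(bmid - m))]
    }, numeric(1))
    expect_equal(got, want)
  }
  expect_warning(match_blank(fish, fish[0, ]), "no blank")
})

test_that("equilibration exclusion removes transient bias, never adds it", {
  geom <- respirometer_geometry(1.01, 0.01)
  plan <- cycle_plan(1200, 300)
  tr <- simulate_oxygen_trace(100, geom, plan, sensor_sd = 0,
                              transient_amp = 0.3, transient_tau_s = 90)
  win <- tr[tr$time_s < 1200, ]
  err <- function(excl) {
    abs(fit_slope(win, exclusion_s = excl)$slope - (-1.0))
  }
  expect_lt(err(300), err(0))
})
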