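# surface-dominated trace where every ZOC sub-window sees mostly surface
zoc_fixture <- function(offset = 0) {
  s <- trap_series(depth = 30, descent = 20, bottom = 20, ascent = 20,
                   dt = 1, pad = 600, n_dives = 6, gap = 540)
  s$depth <- s$depth + offset
  s
}

test_that("a constant zero offset is removed exactly", {
  shifted <- zoc_fixture(offset = 2)
  truth <- zoc_fixture(offset = 0)
  z <- zero_offset_correct(shifted, window = 3600, quantile = 0.05)
  expect_lt(max(abs(z$series$depth - truth$depth)), 1e-9)
  expect_equal(unique(z$offset), 2)
})

test_that("correction of an undrifted series is the identity and is idempotent", {
  s <- zoc_fixture()
  z <- zero_offset_correct(s, window = 3600)
  expect_lt(max(abs(z$series$depth - s$depth)), 1e-9)

  sim <- quick_sim(seed = 6, days = 3, noise = 0.1,
                   drift = list(type = "linear", magnitude = 2))
  z1 <- zero_offset_correct(sim$series)
  z2 <- zero_offset_correct(z1$series)
  expect_lt(max(abs(z2$series$depth - z1$series$depth)), 1e-6)
})

test_that("a window longer than the deployment falls back to one global offset", {
  s <- zoc_fixture(offset = 1.5)
  expect_warning(z <- zero_offset_correct(s, window = 1e6), "global offset")
  expect_equal(length(unique(z$offset)), 1)
  expect_lt(abs(unique(z$offset) - 1.5), 1e-9)
})

test_that("simulated drift is corrected to small max-depth errors", {
  cfg <- sim_config(seed = 13, deployment_days = 4, sampling_interval = 5,
                    noise_sd = 0.1,
                    drift_spec = list(type = "linear", magnitude = 3))
  sim <- simulate_deployment(cfg)
  res <- process_dives(sim$series)
  m <- match_dives_to_truth(res$dives, sim$truth)
  err <- abs(m$max_depth - sim$truth$dives$max_depth[m$truth_row])
  expect_gte(mean(err <= 0.5), 0.99)
})

test_that("a single square dive is detected with its duration and depth", {
  t <- 0:200
  d <- ifelse(t >= 60 & t < 120, 20, 0)
  s <- depth_series(t, d)
  dv <- detect_dives(s, threshold = 5)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$max_depth, 20)
  expect_lt(abs((dv$end - dv$start) - 60), 1.5)
})

test_that("traces never exceeding the threshold yield no dives", {
  s <- depth_series(0:100, rep(c(0, 4.9), length.out = 101))
  expect_equal(nrow(detect_dives(s, threshold = 5)), 0)
})

test_that("single-sample spikes are dropped at 1 Hz but kept at 5 s sampling", {
  t1 <- 0:60
  d <- numeric(61); d[30] <- 12
  expect_equal(nrow(detect_dives(depth_series(t1, d))), 0)
  t5 <- seq(0, 300, by = 5)
  d5 <- numeric(61); d5[30] <- 12
  expect_equal(nrow(detect_dives(depth_series(t5, d5))), 1)
})

test_that("detection agrees with a brute-force scan on a simulated deployment", {
  sim <- quick_sim(seed = 17, days = 2)
  dv <- detect_dives(sim$series)
  bf <- brute_force_dives(sim$series, threshold = 5, min_samples = 2)
  expect_equal(nrow(dv), nrow(bf))
  expect_equal(dv$start, bf$start)
  expect_equal(dv$end, bf$end)
  expect_equal(dv$max_depth, bf$max_depth)
  expect_equal(nrow(dv), nrow(sim$truth$dives))
})

test_that("trapezoid phases have the analytic bottom interval and descent rate", {
  s <- trap_series(depth = 60, descent = 30, bottom = 90, ascent = 30,
                   dt = 1, pad = 60)
  dv <- segment_phases(s, detect_dives(s), bottom_fraction = 0.8)
  # bottom = flat 90 s plus the two 6 s shoulders where depth >= 48 m
  expect_lt(abs(dv$bottom_time - 102), 2)
  expect_equal(dv$descent_rate, 2)
  expect_equal(dv$descent_distance, dv$ascent_distance)  # symmetry
  # phase durations partition the dive
  expect_lt(abs(dv$descent_duration + dv$bottom_time + dv$ascent_duration -
                  dv$duration), 1 + 1e-9)
})

test_that("a V-dive's bottom phase is just the shoulder crossing time", {
  t <- 0:180
  d <- approx(c(60, 90, 120), c(0, 60, 0), xout = t, rule = 2)$y
  dv <- segment_phases(depth_series(t, d), detect_dives(depth_series(t, d)))
  # depth >= 48 m only while crossing the top 20% at 2 m/s: 12 s total
  expect_lte(dv$bottom_time, 2 * 0.2 * 60 / 2 + 2)
})

test_that("dives too short to segment are flagged and excluded from rates", {
  t5 <- seq(0, 300, by = 5)
  d5 <- numeric(61); d5[30] <- 12
  s <- depth_series(t5, d5)
  dv <- segment_phases(s, detect_dives(s))
  expect_false(dv$valid_phases)
  expect_true(is.na(dv$descent_rate))
})

test_that("phase durations sum to dive duration for every simulated dive", {
  sim <- quick_sim(seed = 19, days = 2, noise = 0.1)
  res <- process_dives(sim$series)
  dv <- res$dives[res$dives$valid_phases, ]
  gap <- abs(dv$descent_duration + dv$bottom_time + dv$ascent_duration -
               dv$duration)
  expect_lt(max(gap), series_interval(sim$series) + 1e-9)
})

test_that("capture probability matches the logistic form exactly", {
  expect_equal(capture_probability(6.06 / 4.67), 0.5, tolerance = 1e-12)
  expect_equal(capture_probability(0), exp(-6.06) / (1 + exp(-6.06)),
               tolerance = 1e-12)
  expect_lt(capture_probability(6), 1)     # stays bounded at high rates
  expect_gt(capture_probability(6), capture_probability(3))
  expect_identical(capture_probability(100), 1)  # saturates gracefully
  r <- seq(0, 5, by = 0.1)
  expect_true(all(diff(capture_probability(r)) > 0))
  expect_true(all(capture_probability(r) > 0 & capture_probability(r) < 1))
  expect_error(capture_probability(-0.1), "non-negative")
  expect_error(capture_probability(NaN), "finite")
})
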