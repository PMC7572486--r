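test_that("config validation rejects impossible settings", {
  expect_error(sim_config(sampling_interval = 2), "1 or 5")
  expect_error(sim_config(dive_duration_mean = 120, trip_duration_mean = 1),
               "exceeds mean trip duration")
  expect_error(sim_config(drift_spec = list(type = "sine", magnitude = 1)),
               "unknown drift type")
  expect_error(sim_config(benthic_fraction = 1.2))
  expect_silent(sim_config(benthic_fraction = 1))
})

test_that("noise-free all-benthic deployment has flat bottoms at the seafloor and zero surface depth", {
  cfg <- sim_config(seed = 1, deployment_days = 2, sampling_interval = 5,
                    benthic_fraction = 1, noise_sd = 0)
  sim <- simulate_deployment(cfg)
  td <- sim$truth$dives
  expect_true(all(td$label == "benthic"))
  for (i in seq_len(min(nrow(td), 50))) {
    sel <- sim$series$time >= td$bottom_start[i] &
      sim$series$time <= td$bottom_end[i]
    expect_equal(sim$series$depth[sel],
                 rep(td$max_depth[i], sum(sel)), tolerance = 1e-12)
  }
  # depth is exactly 0 outside dives
  in_dive <- rep(FALSE, nrow(sim$series))
  for (i in seq_len(nrow(td))) {
    in_dive[sim$series$time > td$start[i] &
              sim$series$time < td$end[i]] <- TRUE
  }
  expect_identical(unique(sim$series$depth[!in_dive]), 0)
})

test_that("a fixed seed reproduces the deployment bit for bit", {
  cfg <- sim_config(seed = 42, deployment_days = 2, noise_sd = 0.1,
                    drift_spec = list(type = "random_walk", magnitude = 2))
  a <- simulate_deployment(cfg)
  b <- simulate_deployment(cfg)
  expect_identical(a$series$depth, b$series$depth)
  expect_identical(a$truth$dives, b$truth$dives)
  expect_identical(a$truth$drift, b$truth$drift)
})

test_that("true benthic labels recover the configured fraction", {
  cfg <- sim_config(seed = 7, n_individuals = 4, deployment_days = 12,
                    benthic_fraction = 0.78, noise_sd = 0)
  sims <- simulate_cohort(cfg)
  lab <- unlist(lapply(sims, function(s) s$truth$dives$label))
  expect_gt(length(lab), 5000)
  se <- sqrt(0.78 * 0.22 / length(lab))
  expect_lt(abs(mean(lab == "benthic") - 0.78), 3 * se)
})

test_that("trips, haul-outs and nothing else tile the deployment span", {
  sim <- quick_sim(seed = 3, days = 8)
  spans <- rbind(sim$truth$trips[c("start", "end")],
                 sim$truth$haulouts[c("start", "end")])
  spans <- spans[order(spans$start), ]
  expect_equal(spans$start[-1], spans$end[-nrow(spans)])
  expect_equal(min(spans$start), 0)
  expect_equal(max(spans$end), max(sim$series$time))
  # every true dive lies inside a true trip
  td <- sim$truth$dives
  inside <- vapply(seq_len(nrow(td)), function(i) {
    any(td$start[i] >= sim$truth$trips$start &
          td$end[i] <= sim$truth$trips$end)
  }, logical(1))
  expect_true(all(inside))
})

test_that("every true dive exceeds the 5 m detection threshold by construction", {
  sim <- quick_sim(seed = 5, days = 6)
  expect_true(all(sim$truth$dives$max_depth >= 5))
  expect_true(all(sim$truth$dives$max_depth >= 8))
})

test_that("per-day dive count at default settings matches the analytic rate", {
  cfg <- sim_config(seed = 11, n_individuals = 4, deployment_days = 10,
                    noise_sd = 0)
  sims <- simulate_cohort(cfg)
  per_ind <- vapply(sims, function(s) {
    full <- s$truth$trips[!s$truth$trips$partial, , drop = FALSE]
    n <- sum(s$truth$dives$trip %in% which(!s$truth$trips$partial))
    n / (sum(full$end - full$start) / 86400)
  }, numeric(1))
  ex <- expected_dive_stats(cfg)
  se <- sd(per_ind) / sqrt(length(per_ind))
  expect_lt(abs(mean(per_ind) - ex$dives_per_day_at_sea), 3 * se)
})

test_that("linear drift ramps to its magnitude and leaves the input unmodified", {
  s <- trap_series()
  out <- inject_drift(s, list(type = "linear", magnitude = 3))
  expect_equal(out$depth[nrow(out)] - s$depth[nrow(s)], 3)
  expect_equal(out$depth[1], s$depth[1])
  expect_identical(unique(s$depth[s$time < 30]), 0)  # input untouched
  curve <- attr(out, "drift_curve")
  expect_equal(out$depth - s$depth, curve)
})

test_that("no-op and random-walk drift behave as specified", {
  s <- trap_series()
  expect_equal(inject_drift(s, list(type = "none", magnitude = 0))$depth,
               s$depth)
  set.seed(9)
  a <- inject_drift(s, list(type = "random_walk", magnitude = 2))
  set.seed(9)
  b <- inject_drift(s, list(type = "random_walk", magnitude = 2))
  expect_identical(attr(a, "drift_curve"), attr(b, "drift_curve"))
  expect_equal(max(abs(attr(a, "drift_curve"))),
               max(abs(a$depth - s$depth)))
  expect_error(inject_drift(s, list(type = "step", magnitude = 1)),
               "unknown drift type")
})

test_that("synthetic monthly covariates are seeded, complete and tidy", {
  m <- simulate_monthly_covariates(c("SSTa", "SOI"), 2000:2005, seed = 4)
  expect_equal(nrow(m), 2 * 6 * 12)
  expect_false(anyDuplicated(m[c("variable", "year", "month")]) > 0)
  m2 <- simulate_monthly_covariates(c("SSTa", "SOI"), 2000:2005, seed = 4)
  expect_identical(m, m2)
})
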