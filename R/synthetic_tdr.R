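#' Configuration for the synthetic deployment generator
#'
#' Parameters of the seeded generator used to validate the pipeline. The
#' defaults emulate a multi-week deployment on a lactating female Australian
#' fur seal: alternating haul-outs (about 1-3 days ashore) and foraging
#' trips (6 h to 10 days at sea, mean about 2.7 days); within trips, mostly
#' square-profile benthic dives to a per-trip seafloor depth drawn from
#' 28-102 m, interleaved with shallower V-profile pelagic dives; roughly
#' 78% of dives benthic, a mean dive duration near 2.8 min, and a dive
#' cycle yielding about 244 dives per day at sea with about 44% of time at
#' sea spent diving.
#'
#' Benthic dive duration is emergent: seafloor depth divided by the drawn
#' descent/ascent rates, inflated by the bottom-time fraction.
#' `dive_duration_mean` is the configured sanity target used for validation
#' and by [expected_dive_stats()].
#'
#' @param seed integer; fixes all randomness.
#' @param n_individuals number of deployments in a cohort.
#' @param deployment_days length of each deployment.
#' @param sampling_interval seconds between samples, 1 or 5.
#' @param trip_duration_mean,trip_duration_sd hours; lognormal trip lengths.
#' @param haulout_duration_mean,haulout_duration_sd hours; lognormal
#'   haul-out lengths.
#' @param seafloor_depth_range metres, `c(low, high)`; per-trip seafloor
#'   depth is uniform on this range and constant within a trip.
#' @param pelagic_depth_fraction pelagic maximum depth as a fraction of the
#'   local seafloor depth.
#' @param benthic_fraction probability a dive is benthic (target PBD).
#' @param dive_duration_mean minutes; configured mean dive duration target.
#' @param bottom_time_fraction_benthic,bottom_time_fraction_pelagic mean
#'   fraction of a dive spent in the bottom phase.
#' @param descent_rate_mean,descent_rate_sd m/s; per-dive descent and
#'   ascent rates.
#' @param surface_interval_mean seconds between dives within a trip.
#' @param drift_spec `list(type, magnitude)`, type one of `"none"`,
#'   `"linear"`, `"random_walk"`; magnitude in metres.
#' @param noise_sd metres of Gaussian sensor noise added last.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 1L,
                       deployment_days = 32,
                       sampling_interval = 5,
                       trip_duration_mean = 64.8,
                       trip_duration_sd = 40,
                       haulout_duration_mean = 36,
                       haulout_duration_sd = 12,
                       seafloor_depth_range = c(28, 102),
                       pelagic_depth_fraction = 0.4,
                       benthic_fraction = 0.782,
                       dive_duration_mean = 2.8,
                       bottom_time_fraction_benthic = 0.5,
                       bottom_time_fraction_pelagic = 0.1,
                       descent_rate_mean = 1.4,
                       descent_rate_sd = 0.15,
                       surface_interval_mean = 200,
                       drift_spec = list(type = "none", magnitude = 0),
                       noise_sd = 0.1) {
  stopifnot(deployment_days > 0, trip_duration_mean > 0,
            trip_duration_sd > 0, haulout_duration_mean > 0,
            haulout_duration_sd > 0, dive_duration_mean > 0,
            length(seafloor_depth_range) == 2,
            seafloor_depth_range[1] > 0,
            diff(seafloor_depth_range) >= 0,
            pelagic_depth_fraction > 0, pelagic_depth_fraction < 1,
            benthic_fraction > 0, benthic_fraction <= 1,
            bottom_time_fraction_benthic > 0,
            bottom_time_fraction_benthic < 1,
            bottom_time_fraction_pelagic > 0,
            bottom_time_fraction_pelagic < 1,
            descent_rate_mean > 0, descent_rate_sd >= 0,
            surface_interval_mean > 0, noise_sd >= 0)
  if (!sampling_interval %in% c(1, 5)) {
    stop("sampling_interval must be 1 or 5 s")
  }
  if (dive_duration_mean / 60 > trip_duration_mean) {
    stop("mean dive duration exceeds mean trip duration")
  }
  if (!drift_spec$type %in% c("none", "linear", "random_walk")) {
    stop("unknown drift type: ", drift_spec$type)
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# fixed second-moment jitter of the per-dive draws, shared by the
# generator and its analytic expectations
.sim_jitter <- list(benthic_depth_sd = 1.5,
                    bf_benthic_sd = 0.05, bf_benthic_lim = c(0.25, 0.75),
                    bf_pelagic_sd = 0.03, bf_pelagic_lim = c(0.02, 0.3),
                    pelagic_depth_lsd = 0.15,
                    rate_clamp = c(0.5, 1.6))

# E[g(clamp(X))] for X ~ N(mean, sd) clamped to [lo, hi], by quadrature
.e_clamped <- function(g, mean, sd, lo, hi) {
  if (sd == 0) return(g(min(max(mean, lo), hi)))
  x <- seq(mean - 8 * sd, mean + 8 * sd, length.out = 4001)
  w <- stats::dnorm(x, mean, sd)
  sum(g(pmin(pmax(x, lo), hi)) * w) / sum(w)
}

#' Analytic expectations implied by a generator configuration
#'
#' Expectations of the dive renewal process, used as the reference values
#' in parameter-recovery checks. Within a trip, the dive rate follows the
#' renewal theorem (one dive per expected dive cycle at that trip's
#' seafloor depth); across trips, rates are averaged over the uniform
#' seafloor-depth distribution weighted by time at sea, which the
#' quadrature below integrates exactly up to grid-snapping of phase
#' durations. The clamped-normal descent-rate and bottom-fraction draws
#' enter through their exact expectations.
#'
#' @param config a [sim_config()].
#' @return list with elements `benthic_duration_s`, `pelagic_duration_s`,
#'   `dive_duration_s` (dive-weighted mean), `dives_per_day_at_sea`,
#'   `prop_time_diving` (time-at-sea weighted).
#' @export
expected_dive_stats <- function(config) {
  j <- .sim_jitter
  rm <- config$descent_rate_mean
  e_inv_rate <- .e_clamped(function(x) 1 / x, rm, config$descent_rate_sd,
                           j$rate_clamp[1] * rm, j$rate_clamp[2] * rm)
  e_inv_bfb <- .e_clamped(function(x) 1 / (1 - x),
                          config$bottom_time_fraction_benthic,
                          j$bf_benthic_sd,
                          j$bf_benthic_lim[1], j$bf_benthic_lim[2])
  e_inv_bfp <- .e_clamped(function(x) 1 / (1 - x),
                          config$bottom_time_fraction_pelagic,
                          j$bf_pelagic_sd,
                          j$bf_pelagic_lim[1], j$bf_pelagic_lim[2])
  pel_jit <- exp(j$pelagic_depth_lsd^2 / 2)
  f <- config$benthic_fraction
  D <- seq(config$seafloor_depth_range[1], config$seafloor_depth_range[2],
           length.out = 2001)
  b_dur <- D * 2 * e_inv_rate * e_inv_bfb
  p_dur <- config$pelagic_depth_fraction * D * pel_jit *
    2 * e_inv_rate * e_inv_bfp
  dur <- f * b_dur + (1 - f) * p_dur
  cycle <- dur + config$surface_interval_mean
  e_inv_cycle <- mean(1 / cycle)
  list(benthic_duration_s = mean(b_dur / cycle) / e_inv_cycle,
       pelagic_duration_s = mean(p_dur / cycle) / e_inv_cycle,
       dive_duration_s = mean(dur / cycle) / e_inv_cycle,
       dives_per_day_at_sea = 86400 * e_inv_cycle,
       prop_time_diving = mean(dur / cycle))
}

# lognormal parameterised by mean and sd on the natural scale
.rlnorm_ms <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

.rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# snap a duration (s) to the sampling grid, at least `min_mult` intervals
.snap <- function(x, dt, min_mult = 1) {
  pmax(round(x / dt), min_mult) * dt
}

#' Simulate one TDR deployment with ground truth
#'
#' Generates an alternating haul-out / foraging-trip renewal process over
#' the deployment span. Within each trip the seafloor depth is drawn once
#' (uniform over `seafloor_depth_range`) and dives are placed sequentially,
#' benthic with probability `benthic_fraction`: benthic dives are
#' trapezoids descending to the seafloor with a long flat bottom, pelagic
#' dives are near-V profiles to `pelagic_depth_fraction` of the seafloor.
#' Phase durations are snapped to the sampling grid so the true maximum
#' depth is always sampled. Depth is exactly 0 at the surface before drift
#' and noise are added (drift first, then Gaussian noise); the wet flag is
#' `TRUE` during trips and `FALSE` during haul-outs.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed` (used for per-individual
#'   substreams).
#' @param individual_id identifier for the generated series.
#'
#' @return `list(series, truth)` where `series` is a [depth_series()] and
#'   `truth` a `truth_bundle`: `dives` (surface start/end, analytic 5 m
#'   crossing times `start_thr`/`end_thr`, `max_depth`, bottom interval,
#'   realised descent/ascent rates, `label`, owning `trip`), `trips` and
#'   `haulouts` (start, end, `partial` flag for spans truncated by the
#'   deployment), and `drift` (metres per sample).
#' @export
simulate_deployment <- function(config, seed = NULL,
                                individual_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  dt <- config$sampling_interval
  span <- round(config$deployment_days * 86400 / dt) * dt
  n <- as.integer(span / dt) + 1L
  tgrid <- (seq_len(n) - 1) * dt
  depth <- numeric(n)
  wet <- logical(n)

  thr_lo <- 6.5 * 3600          # shortest trip kept above the 6 h cut
  thr_hi <- 10 * 86400
  trips <- list(); haulouts <- list(); dives <- list()
  t_cur <- 0
  state <- "haulout"            # deployments start ashore
  trip_i <- 0L
  while (t_cur < span) {
    if (state == "haulout") {
      d <- .rlnorm_ms(1, config$haulout_duration_mean * 3600,
                      config$haulout_duration_sd * 3600)
      d <- .snap(min(max(d, 3600), 4 * 86400), dt)
      end <- min(t_cur + d, span)
      haulouts[[length(haulouts) + 1L]] <-
        c(start = t_cur, end = end, partial = as.numeric(end < t_cur + d))
      t_cur <- end
      state <- "trip"
    } else {
      d <- .rlnorm_ms(1, config$trip_duration_mean * 3600,
                      config$trip_duration_sd * 3600)
      d <- .snap(min(max(d, thr_lo), thr_hi), dt)
      end <- min(t_cur + d, span)
      trip_i <- trip_i + 1L
      trips[[trip_i]] <-
        c(start = t_cur, end = end, partial = as.numeric(end < t_cur + d))
      wet[tgrid >= t_cur & tgrid < end] <- TRUE
      seafloor <- stats::runif(1, config$seafloor_depth_range[1],
                               config$seafloor_depth_range[2])
      t_d <- t_cur + .surface_gap(config, dt)
      repeat {
        g <- .draw_dive(config, seafloor, dt)
        if (t_d + g$total + 2 * dt > end) break
        i0 <- as.integer(t_d / dt) + 1L
        nodes_t <- t_d + cumsum(c(0, g$desc, g$bottom, g$asc))
        ii <- (i0 + 1L):(i0 + g$total / dt - 1L)
        depth[ii] <- stats::approx(nodes_t, c(0, g$depth, g$depth, 0),
                                   xout = tgrid[ii])$y
        dives[[length(dives) + 1L]] <- data.frame(
          start = t_d, end = t_d + g$total,
          start_thr = t_d + 5 / (g$depth / g$desc),
          end_thr = t_d + g$total - 5 / (g$depth / g$asc),
          max_depth = g$depth,
          bottom_start = nodes_t[2], bottom_end = nodes_t[3],
          descent_rate = g$depth / g$desc,
          ascent_rate = g$depth / g$asc,
          label = g$label, trip = trip_i)
        t_d <- t_d + g$total + .surface_gap(config, dt)
      }
      t_cur <- end
      state <- "haulout"
    }
  }

  truth <- list(
    dives = do.call(rbind, dives),
    trips = as.data.frame(do.call(rbind, trips)),
    haulouts = as.data.frame(do.call(rbind, haulouts)),
    drift = numeric(n))
  truth$trips$partial <- truth$trips$partial > 0
  truth$haulouts$partial <- truth$haulouts$partial > 0

  series <- depth_series(tgrid, depth, wet = wet,
                         individual_id = individual_id)
  if (config$drift_spec$type != "none") {
    series <- inject_drift(series, config$drift_spec)
    truth$drift <- attr(series, "drift_curve")
  }
  if (config$noise_sd > 0) {
    series$depth <- series$depth + stats::rnorm(n, 0, config$noise_sd)
  }
  class(truth) <- "truth_bundle"
  list(series = series, truth = truth)
}

# surface interval between dives: gamma with a floor of two samples
.surface_gap <- function(config, dt) {
  floor_s <- max(15, 2 * dt)
  scale <- max(config$surface_interval_mean - floor_s, 1) / 2
  .snap(floor_s + stats::rgamma(1, shape = 2, scale = scale), dt, 2)
}

# one dive's grid-snapped geometry
.draw_dive <- function(config, seafloor, dt) {
  j <- .sim_jitter
  rm <- config$descent_rate_mean
  benthic <- stats::runif(1) < config$benthic_fraction
  rate_d <- .rnorm_clamped(1, rm, config$descent_rate_sd,
                           j$rate_clamp[1] * rm, j$rate_clamp[2] * rm)
  rate_a <- .rnorm_clamped(1, rm, config$descent_rate_sd,
                           j$rate_clamp[1] * rm, j$rate_clamp[2] * rm)
  if (benthic) {
    depth <- max(8, seafloor + stats::rnorm(1, 0, j$benthic_depth_sd))
    bf <- .rnorm_clamped(1, config$bottom_time_fraction_benthic,
                         j$bf_benthic_sd,
                         j$bf_benthic_lim[1], j$bf_benthic_lim[2])
  } else {
    depth <- config$pelagic_depth_fraction * seafloor *
      exp(stats::rnorm(1, 0, j$pelagic_depth_lsd))
    depth <- min(max(depth, 8), 0.9 * seafloor)
    bf <- .rnorm_clamped(1, config$bottom_time_fraction_pelagic,
                         j$bf_pelagic_sd,
                         j$bf_pelagic_lim[1], j$bf_pelagic_lim[2])
  }
  desc <- .snap(depth / rate_d, dt)
  asc <- .snap(depth / rate_a, dt)
  bottom <- .snap(bf / (1 - bf) * (desc + asc), dt)
  list(depth = depth, desc = desc, bottom = bottom, asc = asc,
       total = desc + bottom + asc,
       label = if (benthic) "benthic" else "pelagic")
}

#' Add sensor zero-offset drift to a depth series
#'
#' Creates the slow pressure-sensor drift that the zero-offset correction
#' stage must remove: after injection, surface samples no longer read 0 m.
#' The input series is not modified.
#'
#' @param series a [depth_series()].
#' @param drift_spec `list(type, magnitude)`: `"none"` returns the input
#'   unchanged; `"linear"` ramps from 0 to `magnitude` metres over the
#'   deployment; `"random_walk"` is a Gaussian random walk whose step size
#'   is scaled so its standard deviation over the deployment is
#'   `magnitude` metres.
#' @return the drifted series, with the applied per-sample drift stored in
#'   attribute `"drift_curve"`.
#' @export
inject_drift <- function(series, drift_spec) {
  stopifnot(inherits(series, "depth_series"))
  n <- nrow(series)
  curve <- switch(drift_spec$type,
    none = numeric(n),
    linear = drift_spec$magnitude * (seq_len(n) - 1) / (n - 1),
    random_walk = cumsum(stats::rnorm(n, 0,
                                      drift_spec$magnitude / sqrt(n))),
    stop("unknown drift type: ", drift_spec$type))
  out <- series
  out$depth <- out$depth + curve
  attr(out, "drift_curve") <- curve
  out
}

#' Simulate a cohort of deployments
#'
#' Runs [simulate_deployment()] for `config$n_individuals` animals, each on
#' its own substream derived from the master seed by a fixed offset.
#'
#' @param config a [sim_config()].
#' @return list of `list(series, truth)` elements, one per individual.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lapply(seq_len(config$n_individuals), function(i) {
    simulate_deployment(config, seed = config$seed + 1000L * i,
                        individual_id = sprintf("sim%02d", i))
  })
}

#' Write a simulated deployment and its ground truth to disk
#'
#' The depth series and the truth sidecars (dives, trips, haul-outs, drift)
#' are written as delimited text in the shared table dialect.
#'
#' @param sim result of [simulate_deployment()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulated_deployment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- attr(sim$series, "individual_id")
  write_depth_series(sim$series, file.path(dir, paste0(id, "_depth.csv")))
  write_table(sim$truth$dives, file.path(dir, paste0(id, "_true_dives.csv")))
  write_table(sim$truth$trips, file.path(dir, paste0(id, "_true_trips.csv")))
  write_table(sim$truth$haulouts,
              file.path(dir, paste0(id, "_true_haulouts.csv")))
  write_table(data.frame(time = sim$series$time, drift = sim$truth$drift),
              file.path(dir, paste0(id, "_drift.csv")))
  invisible(dir)
}

#' Simulate monthly environmental covariate series
#'
#' Fabricates monthly series (variable, year, month, value) with seasonal
#' cycle, slow trend and noise, for testing the covariate builder. Not a
#' model of any real oceanographic field.
#'
#' @param variables character vector of variable names.
#' @param years integer vector of calendar years to cover.
#' @param seed integer seed.
#' @return data frame with columns `variable`, `year`, `month`, `value`.
#' @export
simulate_monthly_covariates <- function(variables, years, seed = 1L) {
  set.seed(as.integer(seed))
  out <- lapply(seq_along(variables), function(k) {
    grid <- expand.grid(month = 1:12, year = years)
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 2)
    trend <- stats::runif(1, -0.05, 0.05)
    idx <- (grid$year - min(years)) * 12 + grid$month
    data.frame(variable = variables[k],
               year = grid$year, month = grid$month,
               value = amp * sin(2 * pi * grid$month / 12 + phase) +
                 trend * idx + stats::rnorm(nrow(grid), 0, 0.4))
  })
  do.call(rbind, out)
}
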