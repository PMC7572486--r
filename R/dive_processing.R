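#' Zero-offset correction of sensor drift
#'
#' Pressure sensors drift slowly, so surface readings wander away from 0 m.
#' The offset is estimated as a running lower quantile of depth: the
#' `quantile` of depth is taken in sub-windows of `window / 18` seconds
#' (10 min at the default 3 h window -- short enough to track a slow
#' random walk, long enough that surface samples dominate the lower tail),
#' the sub-window estimates are median-smoothed over three sub-windows to
#' suppress occasional dive-contaminated estimates, and the result is
#' interpolated to every sample and subtracted. Samples correcting below
#' 0 m are clamped to 0.
#'
#' Offset estimates smaller in magnitude than `deadband` (default 0.1 m,
#' below the depth resolution of archival tags) are treated as no drift
#' and snapped to 0: this keeps the lower quantile of surface noise from
#' being mistaken for drift and makes the correction idempotent.
#'
#' @param series a [depth_series()].
#' @param window window length in seconds (>= 60); if longer than the
#'   deployment, a single global offset is used with a warning.
#' @param quantile lower quantile in (0, 0.5] used as the surface estimate.
#' @param deadband metres; offset estimates below this are taken as 0.
#' @return list with `series` (corrected) and `offset` (the per-sample
#'   offset curve that was subtracted, for audit).
#' @export
zero_offset_correct <- function(series, window = 10800, quantile = 0.05,
                                deadband = 0.1) {
  stopifnot(inherits(series, "depth_series"), window >= 60,
            quantile > 0, quantile <= 0.5, deadband >= 0)
  t <- series$time
  span <- t[length(t)] - t[1]
  sub <- window / 18
  if (window >= span) {
    warning("ZOC window exceeds deployment span; using a global offset")
    g <- stats::quantile(series$depth, quantile, names = FALSE)
    off <- rep(if (abs(g) < deadband) 0 else g, nrow(series))
  } else {
    bins <- floor((t - t[1]) / sub)
    ub <- sort(unique(bins))
    centres <- (ub + 0.5) * sub + t[1]
    grp <- split(series$depth, factor(bins, levels = ub))
    q <- vapply(grp, stats::quantile, numeric(1),
                probs = quantile, names = FALSE)
    if (length(q) >= 3) q <- stats::runmed(q, k = 3, endrule = "median")
    q[abs(q) < deadband] <- 0
    off <- stats::approx(centres, q, xout = t, rule = 2)$y
  }
  off[abs(off) < .Machine$double.eps^0.5] <- 0
  out <- series
  out$depth <- pmax(out$depth - off, 0)
  list(series = out, offset = off)
}

#' Detect dives in a corrected depth series
#'
#' A dive is a maximal run of consecutive samples deeper than `threshold`
#' (default 5 m, excluding surface activity); its boundaries are the
#' threshold crossings, reported at the first and last above-threshold
#' sample. Single-sample runs are kept at 5 s sampling but dropped as noise
#' spikes at 1 Hz.
#'
#' @param series a zero-offset-corrected [depth_series()].
#' @param threshold metres.
#' @return data frame of dive segments ordered by start time: `dive_id`,
#'   `start`, `end` (times of first/last sample beyond threshold),
#'   `start_idx`, `end_idx` (row indices into `series`), `n_samples`,
#'   `max_depth`, `post_dive_duration` (gap to the next dive start, `NA`
#'   for the last dive).
#' @export
detect_dives <- function(series, threshold = 5) {
  stopifnot(inherits(series, "depth_series"), threshold > 0)
  deep <- series$depth > threshold
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (series_interval(series) < 2.5) keep <- keep & r$lengths > 1L
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(dive_id = integer(), start = numeric(),
                      end = numeric(), start_idx = integer(),
                      end_idx = integer(), n_samples = integer(),
                      max_depth = numeric(),
                      post_dive_duration = numeric()))
  }
  max_depth <- vapply(seq_along(starts), function(i) {
    max(series$depth[starts[i]:ends[i]])
  }, numeric(1))
  st <- series$time[starts]
  data.frame(dive_id = seq_along(starts),
             start = st, end = series$time[ends],
             start_idx = starts, end_idx = ends,
             n_samples = ends - starts + 1L,
             max_depth = max_depth,
             post_dive_duration = c(st[-1], NA) - series$time[ends])
}

#' Segment a dive into descent, bottom and ascent phases
#'
#' The bottom phase spans the first to the last sample at or beyond
#' `bottom_fraction` of the dive's maximum depth; descent is everything
#' before it and ascent everything after. Distances are measured from the
#' boundary samples' depths (the observed 5 m crossings), not from 0 m, so
#' the unobserved 0-5 m transit is never extrapolated.
#'
#' @param series the corrected [depth_series()].
#' @param dives dive table from [detect_dives()].
#' @param bottom_fraction fraction of maximum depth defining the bottom
#'   phase (default 0.8).
#' @return `dives` with added columns: `duration` (s), `bottom_start`,
#'   `bottom_end`, `bottom_time` (s), `descent_distance`,
#'   `ascent_distance` (m), `descent_duration`, `ascent_duration` (s),
#'   `descent_rate`, `ascent_rate` (m/s), and `valid_phases` (FALSE for
#'   dives of fewer than 3 samples, which are excluded from rate metrics).
#' @export
segment_phases <- function(series, dives, bottom_fraction = 0.8) {
  stopifnot(inherits(series, "depth_series"),
            bottom_fraction > 0, bottom_fraction < 1)
  n <- nrow(dives)
  cols <- c("bottom_start", "bottom_end", "bottom_time",
            "descent_distance", "ascent_distance",
            "descent_duration", "ascent_duration",
            "descent_rate", "ascent_rate")
  for (cl in cols) dives[[cl]] <- rep(NA_real_, n)
  dives$duration <- dives$end - dives$start
  dives$valid_phases <- dives$n_samples >= 3L
  for (i in seq_len(n)) {
    if (!dives$valid_phases[i]) next
    idx <- dives$start_idx[i]:dives$end_idx[i]
    d <- series$depth[idx]
    tt <- series$time[idx]
    cut <- bottom_fraction * dives$max_depth[i]
    at_bottom <- which(d >= cut)
    b0 <- at_bottom[1]
    b1 <- at_bottom[length(at_bottom)]
    dives$bottom_start[i] <- tt[b0]
    dives$bottom_end[i] <- tt[b1]
    dives$bottom_time[i] <- tt[b1] - tt[b0]
    dives$descent_distance[i] <- d[b0] - d[1]
    dives$ascent_distance[i] <- d[b1] - d[length(d)]
    dives$descent_duration[i] <- tt[b0] - tt[1]
    dives$ascent_duration[i] <- tt[length(tt)] - tt[b1]
    if (dives$descent_duration[i] > 0) {
      dives$descent_rate[i] <-
        dives$descent_distance[i] / dives$descent_duration[i]
    }
    if (dives$ascent_duration[i] > 0) {
      dives$ascent_rate[i] <-
        dives$ascent_distance[i] / dives$ascent_duration[i]
    }
  }
  dives
}

#' Prey-capture success probability of a benthic dive
#'
#' Logistic model of the probability that a benthic dive captures prey,
#' driven by descent rate (m/s), with coefficients estimated from
#' animal-borne video validation: p = plogis(coef * r + intercept) with
#' coef = 4.67 and intercept = -6.06 by default.
#'
#' @param rate descent rate(s) in m/s; must be finite and non-negative.
#' @param coef logistic slope on descent rate.
#' @param intercept logistic intercept.
#' @return probabilities in (0, 1), same length as `rate`.
#' @export
capture_probability <- function(rate, coef = 4.67, intercept = -6.06) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("descent rate must be finite and non-negative")
  }
  stats::plogis(coef * rate + intercept)
}

#' Run correction, detection and phase segmentation on one series
#'
#' Convenience wrapper: [zero_offset_correct()], [detect_dives()],
#' [segment_phases()], then [capture_probability()] on every dive with a
#' valid descent rate (the probability is only meaningful for benthic
#' dives and is used downstream only for them).
#'
#' @param series a raw [depth_series()].
#' @param config a [pipeline_config()].
#' @return list with `series` (corrected), `offset`, and `dives` (table
#'   with phases and `p_capture`).
#' @export
process_dives <- function(series, config = pipeline_config()) {
  z <- zero_offset_correct(series, config$zoc_window, config$zoc_quantile)
  dives <- detect_dives(z$series, config$dive_threshold)
  dives <- segment_phases(z$series, dives, config$bottom_fraction)
  dives$p_capture <- NA_real_
  ok <- dives$valid_phases & is.finite(dives$descent_rate) &
    dives$descent_rate >= 0
  dives$p_capture[ok] <- capture_probability(
    dives$descent_rate[ok], config$capture_coef_rate,
    config$capture_intercept)
  if (isTRUE(config$duration_from_surface)) {
    ext <- ifelse(ok, config$dive_threshold / dives$descent_rate +
                    config$dive_threshold /
                      pmax(dives$ascent_rate, 1e-6), 0)
    dives$duration <- dives$duration + ext
  }
  list(series = z$series, offset = z$offset, dives = dives)
}
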