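#' Benthic dive rate of a foraging trip
#'
#' Vertical distance travelled per hour of benthic diving:
#' `b = sum(d_i + a_i) / sum(t_i)` over the trip's benthic dives, with
#' descent distance `d_i` and ascent distance `a_i` in metres and dive
#' duration `t_i` in hours. With `denominator = "trip"`, the summed
#' vertical distance is divided by the whole trip duration instead, a
#' variant some effort summaries use.
#'
#' @param descent_distance,ascent_distance metres, benthic dives only.
#' @param duration_s benthic dive durations in seconds.
#' @param trip_duration_h trip duration in hours (needed for
#'   `denominator = "trip"`).
#' @param denominator `"dive"` (the definition) or `"trip"`.
#' @return b in m/h, or `NA` if there are no benthic dives (undefined is
#'   missing, never 0).
#' @export
benthic_dive_rate <- function(descent_distance, ascent_distance,
                              duration_s, trip_duration_h = NULL,
                              denominator = c("dive", "trip")) {
  denominator <- match.arg(denominator)
  if (!length(duration_s)) return(NA_real_)
  vertical <- sum(descent_distance + ascent_distance)
  if (denominator == "dive") {
    vertical / sum(duration_s / 3600)
  } else {
    if (is.null(trip_duration_h)) stop("trip_duration_h required")
    vertical / trip_duration_h
  }
}

#' Foraging Trip Success Index
#'
#' Summed prey-capture probabilities of a trip's benthic dives per hour of
#' benthic diving: `FTSI = sum(p_i) / sum(t_i)` with `t_i` in hours.
#' Capture probabilities are only validated for benthic dives, so only
#' benthic dives enter both sums.
#'
#' @param p capture probabilities of the benthic dives.
#' @param duration_s their durations in seconds.
#' @return FTSI in 1/h, or `NA` with no benthic dives.
#' @export
trip_ftsi <- function(p, duration_s) {
  if (!length(p)) return(NA_real_)
  stopifnot(length(p) == length(duration_s))
  sum(p) / sum(duration_s / 3600)
}

#' Foraging Trip Efficiency Index
#'
#' Summed benthic capture probabilities divided by the benthic dive rate
#' (the effort measure): `FTEI = sum(p_i) / b`. Success per metre of
#' vertical effort.
#'
#' @param p capture probabilities of the benthic dives.
#' @param b benthic dive rate in m/h.
#' @return FTEI, or `NA` when `b` is missing or non-positive.
#' @export
trip_ftei <- function(p, b) {
  if (!length(p) || is.na(b) || b <= 0) return(NA_real_)
  sum(p) / b
}

#' Per-trip activity metrics
#'
#' `PBD` (proportion of the trip's dives classified benthic),
#' `prop_time_diving` (summed dive durations over trip duration) and `N`
#' (dive count).
#'
#' @param labels dive labels of the trip.
#' @param duration_s dive durations in seconds.
#' @param trip_duration_h trip duration in hours.
#' @return list `(PBD, prop_time_diving, N)`.
#' @export
trip_activity_metrics <- function(labels, duration_s, trip_duration_h) {
  N <- length(labels)
  if (N == 0) stop("a finalised trip cannot have zero dives")
  list(PBD = sum(labels == "benthic") / N,
       prop_time_diving = sum(duration_s) / (trip_duration_h * 3600),
       N = N)
}

#' Compute all foraging indices for finalised trips
#'
#' Appends `N`, `n_benthic`, `PBD`, `prop_time_diving`, `b` (m/h),
#' `FTSI` (1/h), `FTEI` and `sum_p` to the trip table. Only dives with
#' valid phases and a benthic label enter the effort/success sums;
#' undefined indices (e.g. FTEI of a trip with no benthic dives) are
#' missing, never 0.
#'
#' @param trips finalised trip table (see [finalise_trips()]).
#' @param dives labelled dive table.
#' @param config a [pipeline_config()].
#' @return the augmented trip table; non-foraging trips keep `NA` metrics.
#' @export
compute_trip_metrics <- function(trips, dives, config = pipeline_config()) {
  for (cl in c("N", "PBD", "prop_time_diving", "b", "FTSI", "FTEI",
               "sum_p")) {
    trips[[cl]] <- NA_real_
  }
  for (i in seq_len(nrow(trips))) {
    if (trips$status[i] != "foraging_trip") next
    sel <- which(dives$trip_id == trips$trip_id[i])
    act <- trip_activity_metrics(dives$label[sel], dives$duration[sel],
                                 trips$duration_h[i])
    trips$N[i] <- act$N
    trips$PBD[i] <- act$PBD
    trips$prop_time_diving[i] <- act$prop_time_diving
    ben <- sel[dives$label[sel] == "benthic" & dives$valid_phases[sel]]
    if (length(ben)) {
      trips$b[i] <- benthic_dive_rate(
        dives$descent_distance[ben], dives$ascent_distance[ben],
        dives$duration[ben], trip_duration_h = trips$duration_h[i],
        denominator = config$rate_denominator)
      trips$sum_p[i] <- sum(dives$p_capture[ben])
      trips$FTSI[i] <- trip_ftsi(dives$p_capture[ben],
                                 dives$duration[ben])
      trips$FTEI[i] <- trip_ftei(dives$p_capture[ben], trips$b[i])
    }
  }
  trips
}

#' Correlation audit of the index building blocks
#'
#' Pairwise Pearson correlations among the per-trip sums entering the
#' effort, success and efficiency indices: summed vertical distance
#' `sum(d_i + a_i)`, summed capture probability `sum(p_i)` and summed
#' benthic dive duration `sum(t_i)`. Reported for audit; the indices are
#' only weakly redundant when these are weakly correlated.
#'
#' @param trips trip table from [compute_trip_metrics()] (needs `b`,
#'   `sum_p`, and benthic dive durations via `b`/`FTSI`), or a data frame
#'   with columns `sum_vertical`, `sum_p`, `sum_t`.
#' @param dives labelled dive table (used when `trips` lacks the sums).
#' @return data frame `var1`, `var2`, `r` (NA with a note when a column
#'   is constant); requires at least 3 foraging trips.
#' @export
metric_correlation_check <- function(trips, dives = NULL) {
  if (!all(c("sum_vertical", "sum_p", "sum_t") %in% names(trips))) {
    stopifnot(!is.null(dives))
    ft <- trips[trips$status == "foraging_trip", , drop = FALSE]
    sums <- t(vapply(ft$trip_id, function(id) {
      ben <- which(dives$trip_id == id & dives$label == "benthic" &
                     dives$valid_phases)
      c(sum_vertical = sum(dives$descent_distance[ben] +
                             dives$ascent_distance[ben]),
        sum_p = sum(dives$p_capture[ben]),
        sum_t = sum(dives$duration[ben]))
    }, numeric(3)))
    trips <- as.data.frame(sums)
  }
  if (nrow(trips) < 3) stop("need at least 3 trips")
  pairs <- utils::combn(c("sum_vertical", "sum_p", "sum_t"), 2)
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ], r = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    x <- trips[[pairs[1, k]]]
    y <- trips[[pairs[2, k]]]
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      out$r[k] <- stats::cor(x, y)
    }
  }
  out
}
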