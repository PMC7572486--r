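#' Run the full dive-processing pipeline on one deployment
#'
#' End-to-end chain: zero-offset correction, dive detection and phase
#' segmentation, wet/dry partition, haul-out and candidate-trip
#' segmentation, per-trip benthic/pelagic classification, trip
#' finalisation and the foraging effort/success/efficiency indices.
#'
#' @param series a raw [depth_series()].
#' @param config a [pipeline_config()].
#' @return list: `series` (corrected), `offset`, `dives` (with phases,
#'   labels, index and capture probability), `haulouts`, `trips` (with
#'   `b`, `FTSI`, `FTEI`, `PBD`, `prop_time_diving`, `N`),
#'   `classification_audit`.
#' @export
run_pipeline <- function(series, config = pipeline_config()) {
  proc <- process_dives(series, config)
  wd <- find_wet_dry(proc$series)
  ho <- build_haulouts(wd, config$min_haulout_duration)
  bt <- build_trips(ho$intervals, proc$dives, config$min_trip_duration)
  cls <- classify_dives(bt$dives, bt$trips, config)
  trips <- finalise_trips(bt$trips, cls$dives)
  trips <- compute_trip_metrics(trips, cls$dives, config)
  list(series = proc$series, offset = proc$offset, dives = cls$dives,
       haulouts = ho$haulouts, trips = trips,
       classification_audit = cls$audit)
}

#' Match detected dives to ground-truth dives
#'
#' Pairs each detected dive with the unique true dive whose interval
#' contains its start, for validating detection and classification
#' against a simulator truth bundle.
#'
#' @param dives detected dive table.
#' @param truth a `truth_bundle` from [simulate_deployment()].
#' @return `dives` with columns `truth_row` (index into `truth$dives`,
#'   `NA` for spurious detections) and `true_label`.
#' @export
match_dives_to_truth <- function(dives, truth) {
  td <- truth$dives
  idx <- findInterval(dives$start, td$start)
  ok <- idx >= 1 & dives$start <= td$end[pmax(idx, 1)]
  dives$truth_row <- ifelse(ok, idx, NA_integer_)
  dives$true_label <- td$label[dives$truth_row]
  dives
}

#' Summarise a processed cohort
#'
#' Cohort-level means of the headline quantities: dives per day at sea,
#' proportion of time at sea spent diving, proportion of benthic dives,
#' mean benthic dive rate, trip durations and counts.
#'
#' @param results list of [run_pipeline()] outputs, one per individual.
#' @return one-row data frame of cohort summaries.
#' @export
summarise_cohort <- function(results) {
  all_trips <- do.call(rbind, lapply(seq_along(results), function(i) {
    tr <- results[[i]]$trips
    tr$individual <- i
    tr
  }))
  ft <- all_trips[all_trips$status == "foraging_trip" & !all_trips$partial,
                  , drop = FALSE]
  n_dives <- sum(vapply(results, function(r) nrow(r$dives), numeric(1)))
  data.frame(
    n_individuals = length(results),
    n_foraging_trips = sum(all_trips$status == "foraging_trip"),
    n_dives = n_dives,
    mean_trip_duration_days = mean(ft$duration_h) / 24,
    dives_per_day_at_sea = sum(ft$N) / (sum(ft$duration_h) / 24),
    prop_time_diving = stats::weighted.mean(ft$prop_time_diving,
                                            ft$duration_h),
    mean_pbd = mean(ft$PBD),
    mean_dive_rate = mean(ft$b, na.rm = TRUE),
    median_ftsi = stats::median(ft$FTSI, na.rm = TRUE),
    median_ftei = stats::median(ft$FTEI, na.rm = TRUE))
}
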