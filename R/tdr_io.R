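#' Construct a depth series
#'
#' The central container of the pipeline: one time-depth recorder (TDR)
#' deployment for one individual, as a data frame with strictly increasing
#' timestamps (epoch seconds, UTC), depth in metres (may be negative before
#' zero-offset correction) and an optional per-sample wet flag. Devices that
#' only log while wet are represented either by `wet = FALSE` samples or by
#' recording gaps; see [find_wet_dry()].
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param depth numeric vector of depths in metres, positive downwards.
#' @param wet optional logical vector, `TRUE` while the animal is in the
#'   water. `NULL` if the deployment has no wet/dry channel.
#' @param individual_id identifier of the instrumented animal.
#'
#' @return A `depth_series` object: a data frame with columns `time`,
#'   `depth` and (if supplied) `wet`, plus attributes `individual_id` and
#'   `interval` (the modal sampling interval in seconds).
#' @export
depth_series <- function(time, depth, wet = NULL, individual_id = "ind1") {
  time <- as.numeric(time)
  depth <- as.numeric(depth)
  if (length(time) != length(depth)) {
    stop("`time` and `depth` must have equal length")
  }
  if (length(time) < 2L) {
    stop("a depth series needs at least 2 samples")
  }
  if (anyNA(time) || any(!is.finite(depth))) {
    stop("timestamps and depths must be finite")
  }
  dt <- diff(time)
  if (any(dt < 0)) stop("timestamps must be strictly increasing")
  if (any(dt == 0)) stop("duplicate timestamps")
  df <- data.frame(time = time, depth = depth)
  if (!is.null(wet)) {
    if (length(wet) != length(time)) stop("`wet` must match `time` in length")
    df$wet <- as.logical(wet)
  }
  interval <- as.numeric(stats::median(dt))
  if (!isTRUE(all.equal(interval, 1)) && !isTRUE(all.equal(interval, 5))) {
    warning(sprintf("nominal sampling interval %.3g s is neither 1 nor 5 s",
                    interval))
  }
  structure(df,
            individual_id = as.character(individual_id),
            interval = interval,
            class = c("depth_series", "data.frame"))
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> individual %s: %d samples @ %g s, %.2f days, depth %.1f-%.1f m\n",
              attr(x, "individual_id"), nrow(x), attr(x, "interval"),
              diff(range(x$time)) / 86400, min(x$depth), max(x$depth)))
  invisible(x)
}

#' Sampling interval of a depth series
#' @param series a [depth_series()].
#' @return nominal sampling interval in seconds.
#' @export
series_interval <- function(series) attr(series, "interval")

#' Pipeline configuration
#'
#' All tunable thresholds of the processing pipeline in one flat object.
#' Defaults reproduce the analysis constants: a 5 m minimum dive threshold,
#' foraging trips of at least 6 h in the water with at least one benthic
#' dive, haul-outs of at least 10 min dry, and prey-capture logistic
#' coefficients 4.67 (descent rate, m/s) and -6.06 (intercept).
#'
#' @param dive_threshold metres; depths beyond this count as diving.
#' @param min_trip_duration hours; minimum wet period for a foraging trip.
#' @param min_haulout_duration minutes; minimum dry period for a haul-out.
#' @param bottom_fraction fraction of maximum depth defining the bottom
#'   phase of a dive.
#' @param zoc_window seconds; moving window for zero-offset correction.
#' @param zoc_quantile lower quantile used as the surface estimate, in
#'   (0, 0.5].
#' @param kde_bandwidth_rule bandwidth selector for the classifier density,
#'   `"silverman"` (nrd0) or `"sj"`.
#' @param min_dives_for_kde minimum dives per trip before kernel density
#'   classification is attempted.
#' @param capture_coef_rate logistic coefficient on descent rate (per m/s).
#' @param capture_intercept logistic intercept.
#' @param duration_from_surface logical; if `TRUE`, dive durations span the
#'   full surface-to-surface excursion extrapolated through the 0-5 m
#'   transit; by default durations span the observed above-threshold
#'   segment.
#' @param rate_denominator `"dive"` divides vertical distance by summed
#'   benthic dive durations (the printed definition); `"trip"` divides by
#'   trip duration.
#'
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dive_threshold = 5,
                            min_trip_duration = 6,
                            min_haulout_duration = 10,
                            bottom_fraction = 0.8,
                            zoc_window = 10800,
                            zoc_quantile = 0.05,
                            kde_bandwidth_rule = "silverman",
                            min_dives_for_kde = 10,
                            capture_coef_rate = 4.67,
                            capture_intercept = -6.06,
                            duration_from_surface = FALSE,
                            rate_denominator = "dive") {
  stopifnot(dive_threshold > 0, min_trip_duration > 0,
            min_haulout_duration > 0,
            bottom_fraction > 0, bottom_fraction < 1,
            zoc_window >= 60,
            zoc_quantile > 0, zoc_quantile <= 0.5,
            min_dives_for_kde >= 1)
  kde_bandwidth_rule <- match.arg(kde_bandwidth_rule, c("silverman", "sj"))
  rate_denominator <- match.arg(rate_denominator, c("dive", "trip"))
  structure(list(dive_threshold = dive_threshold,
                 min_trip_duration = min_trip_duration,
                 min_haulout_duration = min_haulout_duration,
                 bottom_fraction = bottom_fraction,
                 zoc_window = zoc_window,
                 zoc_quantile = zoc_quantile,
                 kde_bandwidth_rule = kde_bandwidth_rule,
                 min_dives_for_kde = min_dives_for_kde,
                 capture_coef_rate = capture_coef_rate,
                 capture_intercept = capture_intercept,
                 duration_from_surface = duration_from_surface,
                 rate_denominator = rate_denominator),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a flat key/value document whose keys are the arguments of
#' [pipeline_config()]; absent keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Read a depth series from a delimited text file
#'
#' Expects a comma-separated file with a header and columns `time` (epoch
#' seconds or ISO-8601 UTC), `depth_m`, and optionally `wet` (logical).
#' Timestamps must be strictly increasing; duplicates are an error. A
#' nominal interval other than 1 or 5 s (within 10%) only warns.
#'
#' @param path file to read.
#' @param individual_id identifier stored on the result; defaults to the
#'   file name without extension.
#' @return a [depth_series()].
#' @export
read_depth_series <- function(path, individual_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("time", "depth_m")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  tm <- df$time
  if (is.character(tm)) {
    parsed <- as.POSIXct(tm, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      stop(sprintf("unparseable timestamp at line %d: '%s'",
                   bad[1] + 1L, tm[bad[1]]))
    }
    tm <- as.numeric(parsed)
  }
  bad <- which(!is.finite(df$depth_m))
  if (length(bad)) {
    stop(sprintf("non-finite depth at line %d", bad[1] + 1L))
  }
  dup <- which(diff(tm) == 0)
  if (length(dup)) {
    stop(sprintf("duplicate timestamp at line %d", dup[1] + 2L))
  }
  if (any(diff(tm) < 0)) stop("timestamps are not increasing")
  if (is.null(individual_id)) {
    individual_id <- sub("\\.[^.]*$", "", basename(path))
  }
  wet <- if ("wet" %in% names(df)) as.logical(df$wet) else NULL
  # depth_series() itself warns on a nominal interval other than 1/5 s
  depth_series(tm, df$depth_m, wet = wet, individual_id = individual_id)
}

#' Write a depth series to a delimited text file
#'
#' @param series a [depth_series()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_depth_series <- function(series, path) {
  df <- as.data.frame(series)
  names(df)[names(df) == "depth"] <- "depth_m"
  write_table(df, path)
}

#' Write a homogeneous record table
#'
#' One tabular dialect for all pipeline outputs (dives, trips, haul-outs,
#' covariates): comma separated, header row, locale-independent numbers,
#' missing values as empty fields (missing is never written as 0).
#'
#' @param records a data frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a record table written by [write_table()]
#'
#' @param path file to read.
#' @return a data frame; empty fields become `NA`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
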