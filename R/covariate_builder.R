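#' Standardise monthly covariate series
#'
#' Puts environmental variables on a common scale before seasonal
#' aggregation. `"zscore"` (default) centres and scales each variable by
#' its mean and standard deviation over the whole study period;
#' `"anomaly"` instead removes each variable's climatological monthly
#' mean (leaving anomalies in the variable's own units).
#'
#' @param series data frame `variable`, `year`, `month`, `value`.
#' @param method `"zscore"` or `"anomaly"`.
#' @return the series with `value` standardised.
#' @export
standardise_monthly <- function(series, method = c("zscore", "anomaly")) {
  method <- match.arg(method)
  stopifnot(all(c("variable", "year", "month", "value") %in% names(series)))
  if (any(series$month < 1 | series$month > 12)) {
    stop("months must be in 1..12")
  }
  if (anyDuplicated(series[c("variable", "year", "month")])) {
    stop("duplicate (variable, year, month) entries")
  }
  for (v in unique(series$variable)) {
    sel <- series$variable == v
    x <- series$value[sel]
    if (sum(sel) < 2) stop("variable ", v, " has fewer than 2 values")
    if (method == "zscore") {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        stop("variable ", v, " has zero variance")
      }
      series$value[sel] <- (x - mean(x)) / s
    } else {
      mo <- series$month[sel]
      clim <- vapply(split(x, mo), mean, numeric(1))
      series$value[sel] <- x - clim[as.character(mo)]
    }
  }
  series
}

#' Seasonal or annual mean of a monthly series
#'
#' Austral seasons by calendar month: winter is June-August, spring is
#' September-November; `"annual"` averages all 12 months. The mean is
#' missing unless every required month of that year is present.
#'
#' @param series data frame `variable`, `year`, `month`, `value`.
#' @param variable which variable to aggregate.
#' @param season `"winter"`, `"spring"` or `"annual"`.
#' @param year calendar year.
#' @return the mean, or `NA` if any required month is absent.
#' @export
seasonal_mean <- function(series, variable,
                          season = c("winter", "spring", "annual"),
                          year) {
  season <- match.arg(season)
  months <- switch(season, winter = 6:8, spring = 9:11, annual = 1:12)
  sel <- series$variable == variable & series$year == year &
    series$month %in% months
  if (sum(sel) < length(months)) return(NA_real_)
  mean(series$value[sel])
}

#' Assemble the per-year covariate table
#'
#' One row per study year. Local-scale variables (e.g. SSTa, chl-a, SSHa,
#' zonal wind) contribute their current winter mean plus the spring means
#' of the one and two preceding years (`<var>_winter`, `<var>_spring1`,
#' `<var>_spring2`); large-scale climate indices (e.g. SOI, SAM, IOD)
#' contribute annual means at lags 0, 1 and 2 (`<var>_0`, `<var>_1`,
#' `<var>_2`). Missing upstream months propagate to missing cells, and
#' rows with any missing lagged value are flagged.
#'
#' @param series standardised monthly series (see
#'   [standardise_monthly()]).
#' @param years integer vector of study years; the series should cover
#'   `min(years) - 2` onwards for complete lags.
#' @param local_vars,large_vars character vectors naming the variables in
#'   `series` to treat at local and large scale.
#' @return data frame, one row per year, with an `incomplete` flag.
#' @export
assemble_covariate_table <- function(series, years, local_vars,
                                     large_vars) {
  rows <- lapply(years, function(y) {
    row <- list(year = y)
    for (v in local_vars) {
      row[[paste0(v, "_winter")]] <- seasonal_mean(series, v, "winter", y)
      row[[paste0(v, "_spring1")]] <-
        seasonal_mean(series, v, "spring", y - 1)
      row[[paste0(v, "_spring2")]] <-
        seasonal_mean(series, v, "spring", y - 2)
    }
    for (v in large_vars) {
      for (k in 0:2) {
        row[[paste0(v, "_", k)]] <-
          seasonal_mean(series, v, "annual", y - k)
      }
    }
    as.data.frame(row)
  })
  tab <- do.call(rbind, rows)
  tab$incomplete <- apply(is.na(tab), 1, any)
  tab
}

#' Join trips to the covariate table
#'
#' Each trip is assigned the covariate row of the calendar year in which
#' it starts (trips last days, never spanning a year boundary in an
#' April-August sampling season). The join is a left join: the trip count
#' is unchanged, and trips from years absent in the table get missing
#' covariates.
#'
#' @param trips trip table with a `start` column in epoch seconds.
#' @param covariates table from [assemble_covariate_table()].
#' @param origin POSIXct/character origin that trip time 0 corresponds
#'   to, used to convert `start` to a calendar year.
#' @return the model-ready table: trips with a `year` column and all
#'   covariates appended.
#' @export
join_trips <- function(trips, covariates, origin = "2000-01-01") {
  origin <- as.POSIXct(origin, tz = "UTC")
  trips$year <- as.integer(format(origin + trips$start, "%Y",
                                  tz = "UTC"))
  out <- merge(trips, covariates, by = "year", all.x = TRUE, sort = FALSE)
  out[order(out$start), , drop = FALSE]
}
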