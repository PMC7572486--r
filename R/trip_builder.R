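#' Partition a deployment into wet and dry intervals
#'
#' If the series carries a wet flag, intervals are maximal runs of the
#' flag. Without a flag, devices that only record while wet leave gaps:
#' any recording gap longer than twice the nominal sampling interval is
#' inferred to be a dry interval. The returned intervals contiguously
#' cover the deployment span; an interval's end is the start of the next.
#'
#' @param series a [depth_series()].
#' @return data frame with columns `start`, `end` (seconds), `state`
#'   (`"wet"` or `"dry"`), ordered in time.
#' @export
find_wet_dry <- function(series) {
  stopifnot(inherits(series, "depth_series"))
  t <- series$time
  if (!is.null(series$wet)) {
    r <- rle(series$wet)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    start <- t[starts_i]
    end <- c(start[-1], t[length(t)])
    df <- data.frame(start = start, end = end,
                     state = ifelse(r$values, "wet", "dry"))
  } else {
    dt <- series_interval(series)
    gap_after <- which(diff(t) > 2 * dt)
    bounds <- sort(c(t[1], t[gap_after], t[gap_after + 1L], t[length(t)]))
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    state <- rep(c("wet", "dry"), length.out = length(start))
    df <- data.frame(start = start, end = end, state = state)
  }
  df[df$end > df$start, , drop = FALSE]
}

#' Extract haul-outs and absorb short dry spells
#'
#' Dry intervals of at least `min_minutes` (default 10) become haul-outs.
#' Shorter dry spells -- e.g. a salt-water switch drying while the animal
#' rests at the surface -- are treated as in-trip surface time: they are
#' relabelled wet and merged with the flanking wet intervals.
#'
#' @param intervals wet/dry intervals from [find_wet_dry()].
#' @param min_minutes minimum dry duration for a haul-out.
#' @return list with `haulouts` (data frame `haulout_id`, `start`, `end`,
#'   `duration_min`) and `intervals` (the merged wet/dry partition).
#' @export
build_haulouts <- function(intervals, min_minutes = 10) {
  stopifnot(min_minutes > 0)
  st <- intervals$state
  short_dry <- st == "dry" &
    (intervals$end - intervals$start) < min_minutes * 60
  st[short_dry] <- "wet"
  # merge consecutive intervals that now share a state
  keep <- c(TRUE, st[-1] != st[-length(st)])
  grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
  merged <- data.frame(
    start = vapply(split(intervals$start, grp), min, numeric(1)),
    end = vapply(split(intervals$end, grp), max, numeric(1)),
    state = st[keep])
  rownames(merged) <- NULL
  dry <- merged[merged$state == "dry", , drop = FALSE]
  haulouts <- data.frame(
    haulout_id = seq_len(nrow(dry)),
    start = dry$start, end = dry$end,
    duration_min = (dry$end - dry$start) / 60)
  list(haulouts = haulouts, intervals = merged)
}

#' Build candidate foraging trips from wet intervals
#'
#' Wet intervals of at least `min_hours` (default 6) containing at least
#' one detected dive become trip candidates; shorter or dive-less wet
#' periods are rejected with a reason. The requirement that a foraging
#' trip contains a benthic dive is applied later, in [finalise_trips()],
#' once dives are classified. Trips truncated by the deployment start or
#' end are flagged `partial`.
#'
#' @param intervals merged intervals from [build_haulouts()].
#' @param dives dive table from [detect_dives()]/[segment_phases()].
#' @param min_hours minimum wet duration of a foraging trip.
#' @return list with `trips` (data frame `trip_id`, `start`, `end`,
#'   `duration_h`, `n_dives`, `status`, `reason`, `partial`) and `dives`
#'   (the input with a `trip_id` column).
#' @export
build_trips <- function(intervals, dives, min_hours = 6) {
  stopifnot(min_hours > 0)
  wet <- intervals[intervals$state == "wet", , drop = FALSE]
  wet$trip_id <- seq_len(nrow(wet))
  dives$trip_id <- rep(NA_integer_, nrow(dives))
  if (nrow(dives)) {
    for (i in seq_len(nrow(wet))) {
      inside <- dives$start >= wet$start[i] & dives$start < wet$end[i]
      dives$trip_id[inside] <- wet$trip_id[i]
    }
    if (anyNA(dives$trip_id)) {
      stop("dive not contained in any wet interval: inconsistent input")
    }
  }
  n_dives <- vapply(wet$trip_id,
                    function(id) sum(dives$trip_id == id, na.rm = TRUE),
                    numeric(1))
  dur_h <- (wet$end - wet$start) / 3600
  lo <- min(intervals$start)
  hi <- max(intervals$end)
  status <- ifelse(dur_h >= min_hours & n_dives >= 1,
                   "candidate", "rejected")
  reason <- rep(NA_character_, nrow(wet))
  reason[dur_h < min_hours] <- "too_short"
  reason[dur_h >= min_hours & n_dives == 0] <- "no_dives"
  trips <- data.frame(trip_id = wet$trip_id,
                      start = wet$start, end = wet$end,
                      duration_h = dur_h, n_dives = n_dives,
                      status = status, reason = reason,
                      partial = wet$start <= lo | wet$end >= hi)
  list(trips = trips, dives = dives)
}

#' Finalise foraging trips after dive classification
#'
#' Candidates with at least one benthic dive become foraging trips; the
#' rest are rejected (`reason = "no_benthic"`). Every dive in a candidate
#' must carry a label.
#'
#' @param trips trip table from [build_trips()].
#' @param dives classified dive table (column `label`).
#' @return `trips` with updated `status`/`reason` and a `n_benthic`
#'   column.
#' @export
finalise_trips <- function(trips, dives) {
  if (is.null(dives$label)) stop("dives carry no labels; classify first")
  trips$n_benthic <- NA_real_
  for (i in seq_len(nrow(trips))) {
    if (trips$status[i] != "candidate") next
    lab <- dives$label[which(dives$trip_id == trips$trip_id[i])]
    if (anyNA(lab)) {
      stop("unlabelled dive in candidate trip ", trips$trip_id[i])
    }
    # dives flagged "unclassified" (unresolvable phases) are tolerated but
    # cannot satisfy the benthic requirement
    trips$n_benthic[i] <- sum(lab == "benthic")
    if (trips$n_benthic[i] >= 1) {
      trips$status[i] <- "foraging_trip"
    } else {
      trips$status[i] <- "rejected"
      trips$reason[i] <- "no_benthic"
    }
  }
  trips
}
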