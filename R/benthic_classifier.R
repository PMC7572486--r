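#' Bottom-time-weighted maximum-depth index of a dive
#'
#' The classification index: the dive's maximum depth weighted by the
#' proportion of the dive spent in the bottom phase,
#' `max_depth * bottom_time / duration`. Square benthic dives (deep, long
#' flat bottom) score high; V-shaped pelagic dives (shallower, brief
#' bottom) score low, which makes the per-trip distribution of the index
#' bimodal.
#'
#' @param max_depth metres.
#' @param bottom_time seconds.
#' @param duration seconds, > 0.
#' @return index in metres, vectorised.
#' @export
dive_index <- function(max_depth, bottom_time, duration) {
  if (any(duration <= 0, na.rm = TRUE)) {
    stop("dive duration must be positive")
  }
  max_depth * bottom_time / duration
}

#' Classify one trip's dives as benthic or pelagic
#'
#' Indices are normalised by the trip maximum to [0, 1] (so bandwidth
#' selection behaves consistently across trips over different seafloor
#' depths), a Gaussian kernel density is estimated, and its local maxima
#' with height at least 5% of the tallest peak are taken as modes. With
#' two or more modes, the split point is the nadir -- the density minimum
#' between the two most prominent modes -- and dives with a normalised
#' index beyond the nadir are benthic, the rest pelagic. Degenerate cases
#' fall back to all-benthic (the species is predominantly benthic) and
#' are flagged via `method`: fewer than `min_dives` dives
#' (`fallback_insufficient`), or a unimodal/constant index distribution
#' (`fallback_all_benthic`).
#'
#' @param index vector of dive index values (metres) for one trip.
#' @param bandwidth_rule `"silverman"` (stats::bw.nrd0) or `"sj"`.
#' @param min_dives minimum dives for density estimation (default 10).
#' @param prominence minimum mode height as a fraction of the tallest
#'   peak.
#' @return a `trip_classification` list: `labels` (per dive), `method`,
#'   `normalised_index`, `bandwidth`, `mode_locations`, `nadir` (on the
#'   normalised scale; `NA` under fallback).
#' @export
classify_trip <- function(index, bandwidth_rule = "silverman",
                          min_dives = 10, prominence = 0.05) {
  stopifnot(length(index) >= 1, all(is.finite(index)), all(index >= 0))
  bandwidth_rule <- match.arg(bandwidth_rule, c("silverman", "sj"))
  out <- list(normalised_index = NULL, bandwidth = NA_real_,
              mode_locations = numeric(), nadir = NA_real_,
              labels = NULL, method = NA_character_)
  mx <- max(index)
  z <- if (mx > 0) index / mx else index
  out$normalised_index <- z
  fallback <- function(method) {
    out$labels <- rep("benthic", length(index))
    out$method <- method
    class(out) <- "trip_classification"
    out
  }
  if (length(index) < min_dives) return(fallback("fallback_insufficient"))
  if (stats::sd(z) < 1e-12) return(fallback("fallback_all_benthic"))
  bw <- switch(bandwidth_rule,
               silverman = stats::bw.nrd0(z),
               sj = tryCatch(stats::bw.SJ(z),
                             error = function(e) stats::bw.nrd0(z)))
  den <- stats::density(z, bw = bw, n = 512, from = -0.1, to = 1.1)
  out$bandwidth <- bw
  y <- den$y
  m <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) m <- c(1L, m)
  if (y[length(y)] > y[length(y) - 1L]) m <- c(m, length(y))
  prom <- .peak_prominence(y, m)
  keep <- prom >= prominence * max(y)
  m <- m[keep]; prom <- prom[keep]
  out$mode_locations <- den$x[m]
  if (length(m) < 2) return(fallback("fallback_all_benthic"))
  top2 <- sort(m[order(prom, decreasing = TRUE)][1:2])
  between <- top2[1]:top2[2]
  nadir_i <- between[which.min(y[between])]
  out$nadir <- den$x[nadir_i]
  out$labels <- ifelse(z > out$nadir, "benthic", "pelagic")
  out$method <- "kde_nadir"
  class(out) <- "trip_classification"
  out
}

# topographic prominence of each local maximum of a curve: height above
# the key saddle, i.e. the lowest point that must be crossed to reach
# higher ground; flank wiggles on a mode score near 0, true modes score
# their full height above the valley between them
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    saddle <- -Inf
    for (side in c(-1L, 1L)) {
      i <- p
      lowest <- h
      repeat {
        i <- i + side
        if (i < 1L || i > length(y)) break
        if (y[i] > h) {
          saddle <- max(saddle, lowest)
          break
        }
        lowest <- min(lowest, y[i])
      }
    }
    if (is.finite(saddle)) h - saddle else h
  }, numeric(1))
}

#' Classify every trip's dives in a deployment
#'
#' Computes the dive index from phase metrics and runs [classify_trip()]
#' independently within each candidate trip (per-trip classification
#' absorbs individual and between-trip variation in seafloor depth).
#' Dives with invalid phases, or outside any trip, are labelled
#' `"unclassified"`.
#'
#' @param dives dive table with `trip_id` (from [build_trips()]) and
#'   phase columns (from [segment_phases()]).
#' @param trips trip table from [build_trips()].
#' @param config a [pipeline_config()].
#' @return list with `dives` (labelled, plus `index_value` in metres) and
#'   `audit` (per-trip data frame: `trip_id`, `method`, `bandwidth`,
#'   `nadir`, `n_modes`).
#' @export
classify_dives <- function(dives, trips, config = pipeline_config()) {
  dives$index_value <- NA_real_
  ok <- dives$valid_phases
  dives$index_value[ok] <- dive_index(dives$max_depth[ok],
                                      dives$bottom_time[ok],
                                      dives$duration[ok])
  dives$label <- "unclassified"
  audits <- list()
  for (id in trips$trip_id[trips$status == "candidate"]) {
    sel <- which(dives$trip_id == id & ok & is.finite(dives$index_value))
    if (!length(sel)) next
    cl <- classify_trip(dives$index_value[sel],
                        bandwidth_rule = config$kde_bandwidth_rule,
                        min_dives = config$min_dives_for_kde)
    dives$label[sel] <- cl$labels
    audits[[length(audits) + 1L]] <- data.frame(
      trip_id = id, method = cl$method, bandwidth = cl$bandwidth,
      nadir = cl$nadir, n_modes = length(cl$mode_locations))
  }
  list(dives = dives,
       audit = if (length(audits)) do.call(rbind, audits) else
         data.frame(trip_id = integer(), method = character(),
                    bandwidth = numeric(), nadir = numeric(),
                    n_modes = integer()))
}
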