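#!/usr/bin/env Rscript

# Step 3: haul-out / trip segmentation and benthic-pelagic classification.
#
# Wet periods of >= 6 h containing dives become candidate foraging trips;
# dry spells of >= 10 min become haul-outs. Each candidate trip's dives
# are then classified by splitting the bottom-time-weighted maximum-depth
# index at the nadir of its density, and candidates with at least one
# benthic dive are finalised as foraging trips.

library(tdrforage)

cfg <- pipeline_config()
dive_dir <- "scratch/dives"
dir.create("results", showWarnings = FALSE)

ids <- sub("_dives\\.csv$", "",
           list.files(dive_dir, pattern = "_dives\\.csv$"))
stopifnot(length(ids) > 0)

all_trips <- list(); all_haulouts <- list(); all_audit <- list()
for (id in ids) {
  series <- read_depth_series(file.path(dive_dir, paste0(id, "_zoc.csv")),
                              individual_id = id)
  dives <- read_table(file.path(dive_dir, paste0(id, "_dives.csv")))
  ho <- build_haulouts(find_wet_dry(series), cfg$min_haulout_duration)
  bt <- build_trips(ho$intervals, dives, cfg$min_trip_duration)
  cls <- classify_dives(bt$dives, bt$trips, cfg)
  trips <- finalise_trips(bt$trips, cls$dives)
  trips$individual_id <- id
  ho$haulouts$individual_id <- id
  cls$audit$individual_id <- id
  write_table(cls$dives, file.path(dive_dir, paste0(id, "_dives.csv")))
  all_trips[[id]] <- trips
  all_haulouts[[id]] <- ho$haulouts
  all_audit[[id]] <- cls$audit
}

trips <- do.call(rbind, all_trips)
write_table(trips, "results/trips.csv")
write_table(do.call(rbind, all_haulouts), "results/haulouts.csv")
write_table(do.call(rbind, all_audit), "results/classification_audit.csv")

n_forage <- sum(trips$status == "foraging_trip")
cat(sprintf(paste0(
  "%d wet periods segmented across %d individuals: %d foraging trips, ",
  "%d rejected (%s)\n",
  "%d haul-outs; classification audit in ",
  "results/classification_audit.csv\n"),
  nrow(trips), length(ids), n_forage, sum(trips$status == "rejected"),
  paste(names(table(trips$reason)), table(trips$reason),
        sep = "=", collapse = ", "),
  sum(vapply(all_haulouts, nrow, numeric(1)))))
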