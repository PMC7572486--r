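#!/usr/bin/env Rscript

# Step 5: seasonal, lagged environmental covariates and the model-ready
# trip table.
#
# Builds standardised monthly series for four local-scale variables
# (winter means; 1- and 2-year lagged spring means) and three large-scale
# climate indices (annual means at lags 0-2), then joins each trip to the
# covariate row of its starting calendar year. The joined table is what a
# mixed-model analysis of effort/success/efficiency would consume.

library(tdrforage)

seed <- 2024L
local_vars <- c("SSTa", "chla", "SSHa", "wind_u")
large_vars <- c("SOI", "SAM", "IOD")
years <- 1998:2002
origin <- "2000-01-01"  # deployment time zero

monthly <- simulate_monthly_covariates(c(local_vars, large_vars),
                                       c(years[1] - 2, years[1] - 1, years),
                                       seed = seed + 1L)
monthly <- standardise_monthly(monthly)
covs <- assemble_covariate_table(monthly, years, local_vars, large_vars)
write_table(covs, "results/covariates.csv")

trips <- read_table("results/trips.csv")
model_ready <- join_trips(trips[trips$status == "foraging_trip", ],
                          covs, origin = origin)
write_table(model_ready, "results/model_ready_trips.csv")

cat(sprintf(paste0(
  "covariate table: %d years x %d columns (%d rows incomplete lags)\n",
  "model-ready table: %d trips x %d columns in ",
  "results/model_ready_trips.csv\n"),
  nrow(covs), ncol(covs), sum(covs$incomplete),
  nrow(model_ready), ncol(model_ready)))
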