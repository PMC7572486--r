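mk_series <- function(vars = c("SSTa", "SOI"), years = 1998:2021,
                      seed = 10) {
  simulate_monthly_covariates(vars, years, seed = seed)
}

test_that("z-scoring centres and scales each variable over the study period", {
  m <- mk_series()
  z <- standardise_monthly(m)
  for (v in unique(z$variable)) {
    x <- z$value[z$variable == v]
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-12)
  }
})

test_that("a standard-normal input is near-idempotent under z-scoring", {
  set.seed(6)
  m <- data.frame(variable = "x", year = rep(2000:2021, each = 12),
                  month = rep(1:12, 22), value = rnorm(264))
  z <- standardise_monthly(m)
  expect_lt(max(abs(z$value - m$value)), 0.15)
})

test_that("degenerate monthly series are rejected", {
  one <- data.frame(variable = "x", year = 2000, month = 6, value = 1)
  expect_error(standardise_monthly(one), "fewer than 2")
  flat <- data.frame(variable = "x", year = 2000, month = 1:12, value = 2)
  expect_error(standardise_monthly(flat), "zero variance")
  dup <- data.frame(variable = "x", year = 2000, month = c(1, 1),
                    value = 1:2)
  expect_error(standardise_monthly(dup), "duplicate")
})

test_that("seasonal means average exactly the season's months and propagate gaps", {
  m <- data.frame(variable = "x", year = 2005, month = 1:12,
                  value = c(rep(0, 5), 1, 2, 3, 10, 20, 30, 0))
  expect_equal(seasonal_mean(m, "x", "winter", 2005), 2)   # Jun-Aug
  expect_equal(seasonal_mean(m, "x", "spring", 2005), 20)  # Sep-Nov
  gap <- m[m$month != 7, ]
  expect_true(is.na(seasonal_mean(gap, "x", "winter", 2005)))
  const <- data.frame(variable = "soi", year = 2005, month = 1:12,
                      value = 3.5)
  expect_equal(seasonal_mean(const, "soi", "annual", 2005), 3.5)
})

test_that("lagged columns equal the unlagged values of earlier years", {
  m <- standardise_monthly(mk_series(c("SSTa", "chla", "SOI", "SAM"),
                                     1996:2021))
  tab <- assemble_covariate_table(m, 1998:2021,
                                  local_vars = c("SSTa", "chla"),
                                  large_vars = c("SOI", "SAM"))
  for (y in 2000:2021) {
    for (v in c("SSTa", "chla")) {
      for (k in 1:2) {
        expect_equal(
          tab[[paste0(v, "_spring", k)]][tab$year == y],
          seasonal_mean(m, v, "spring", y - k),
          info = sprintf("%s lag %d year %d", v, k, y))
      }
    }
    for (v in c("SOI", "SAM")) {
      for (k in 0:2) {
        expect_equal(tab[[paste0(v, "_", k)]][tab$year == y],
                     seasonal_mean(m, v, "annual", y - k))
      }
    }
  }
})

test_that("the assembled table equals a brute-force recomputation", {
  m <- standardise_monthly(mk_series(c("SSTa", "SOI"), 2000:2012, seed = 3))
  tab <- assemble_covariate_table(m, 2002:2012, "SSTa", "SOI")
  for (y in 2002:2012) {
    # independent loop oracle straight over the monthly rows
    pick <- function(v, yy, months) {
      vals <- vapply(months, function(mo) {
        r <- m$value[m$variable == v & m$year == yy & m$month == mo]
        if (length(r) == 1) r else NA_real_
      }, numeric(1))
      mean(vals)
    }
    expect_equal(tab$SSTa_winter[tab$year == y], pick("SSTa", y, 6:8))
    expect_equal(tab$SSTa_spring1[tab$year == y], pick("SSTa", y - 1, 9:11))
    expect_equal(tab$SSTa_spring2[tab$year == y], pick("SSTa", y - 2, 9:11))
    expect_equal(tab$SOI_0[tab$year == y], pick("SOI", y, 1:12))
    expect_equal(tab$SOI_2[tab$year == y], pick("SOI", y - 2, 1:12))
  }
})

test_that("years without enough history get flagged missing lags", {
  m <- standardise_monthly(mk_series(c("SSTa"), 2000:2005))
  tab <- assemble_covariate_table(m, 2000:2005, "SSTa", character(0))
  expect_true(is.na(tab$SSTa_spring1[tab$year == 2000]))
  expect_true(is.na(tab$SSTa_spring2[tab$year == 2001]))
  expect_true(tab$incomplete[tab$year == 2000])
  expect_false(tab$incomplete[tab$year == 2003])
})

test_that("joining covariates to trips preserves the trip count", {
  m <- standardise_monthly(mk_series(years = 1998:2021))
  tab <- assemble_covariate_table(m, 2000:2002, "SSTa", "SOI")
  # trips starting over three calendar years from a 2000-01-01 origin
  trips <- data.frame(trip_id = 1:6,
                      start = c(0, 20, 400, 500, 900, 1000) * 86400,
                      status = "foraging_trip")
  joined <- join_trips(trips, tab, origin = "2000-01-01")
  expect_equal(nrow(joined), nrow(trips))
  expect_equal(joined$year,
               c(2000, 2000, 2001, 2001, 2002, 2002))
  expect_false(anyNA(joined$SSTa_winter))
  # a trip from a year outside the table keeps missing covariates
  trips2 <- rbind(trips, data.frame(trip_id = 7, start = 1500 * 86400,
                                    status = "foraging_trip"))
  joined2 <- join_trips(trips2, tab)
  expect_equal(nrow(joined2), 7)
  expect_true(is.na(joined2$SSTa_winter[joined2$trip_id == 7]))
})
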