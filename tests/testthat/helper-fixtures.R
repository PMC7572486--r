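# Hand-built depth traces with analytically known geometry.

# One or more identical trapezoid dives (descend/bottom/ascend, seconds)
# separated and flanked by surface time. All durations should be multiples
# of dt so node depths are sampled exactly.
trap_series <- function(depth = 60, descent = 30, bottom = 90, ascent = 30,
                        dt = 1, pad = 60, n_dives = 1, gap = 60,
                        wet = FALSE, id = "fix1") {
  cycle <- descent + bottom + ascent + gap
  total <- pad + n_dives * cycle + pad
  t <- seq(0, total, by = dt)
  d <- numeric(length(t))
  starts <- pad + (seq_len(n_dives) - 1) * cycle
  for (s in starts) {
    nodes_t <- s + cumsum(c(0, descent, bottom, ascent))
    sel <- t > s & t < s + descent + bottom + ascent
    d[sel] <- approx(nodes_t, c(0, depth, depth, 0), xout = t[sel])$y
  }
  depth_series(t, d, wet = if (wet) rep(TRUE, length(t)) else NULL,
               individual_id = id)
}

# Series from alternating wet/dry blocks given in hours, at interval dt.
# Wet blocks get one 20 m square dive per `dive_every` seconds so that
# trip candidacy rules can fire (`dive_every = NULL` for no dives at
# all); dry blocks are depth 0.
flag_series <- function(blocks_h, states, dt = 5, dive_every = 1800,
                        dive_depth = 20, dive_len = 60, id = "fix2") {
  stopifnot(length(blocks_h) == length(states))
  t <- numeric(0); d <- numeric(0); w <- logical(0)
  t0 <- 0
  for (i in seq_along(blocks_h)) {
    len <- round(blocks_h[i] * 3600 / dt) * dt
    tt <- seq(t0, t0 + len - dt, by = dt)
    dd <- numeric(length(tt))
    if (states[i] == "wet" && !is.null(dive_every)) {
      ds <- seq(t0 + 300, t0 + len - dive_len - 300, by = dive_every)
      for (s in ds) dd[tt > s & tt < s + dive_len] <- dive_depth
    }
    t <- c(t, tt); d <- c(d, dd)
    w <- c(w, rep(states[i] == "wet", length(tt)))
    t0 <- t0 + len
  }
  depth_series(t, d, wet = w, individual_id = id)
}

# Brute-force dive scan used as the detection oracle: a dive is a maximal
# run of samples beyond the threshold, found by an explicit loop.
brute_force_dives <- function(series, threshold = 5, min_samples = 1) {
  out <- list()
  run <- integer(0)
  for (i in seq_len(nrow(series))) {
    if (series$depth[i] > threshold) {
      run <- c(run, i)
    } else if (length(run)) {
      if (length(run) >= min_samples) {
        out[[length(out) + 1]] <- c(start = series$time[run[1]],
                                    end = series$time[run[length(run)]],
                                    max_depth = max(series$depth[run]))
      }
      run <- integer(0)
    }
  }
  if (length(run) >= min_samples) {
    out[[length(out) + 1]] <- c(start = series$time[run[1]],
                                end = series$time[run[length(run)]],
                                max_depth = max(series$depth[run]))
  }
  as.data.frame(do.call(rbind, out))
}

# small standard simulation shared by several tests
quick_sim <- function(seed = 42, days = 3, dt = 5, noise = 0,
                      drift = list(type = "none", magnitude = 0), ...) {
  simulate_deployment(sim_config(seed = seed, deployment_days = days,
                                 sampling_interval = dt, noise_sd = noise,
                                 drift_spec = drift, ...))
}
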