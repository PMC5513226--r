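# Shared fixture builders: tiny deterministic tracks, a Gaussian UD, and the
# independent oracles used against the implementation paths.

# A track visiting the given positions at consecutive schedule slots.
# positions: matrix/data.frame with x, y; one row per fix.
make_track <- function(positions, start = "2014-02-01",
                       schedule = "two_hour", bird_id = "T1") {
  hours <- schedule_hours(schedule)
  day_hours <- sort(hours[hours != 0])
  n <- nrow(positions)
  per_day <- length(day_hours) + 1L
  days <- ceiling(n / per_day)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  off <- c(day_hours, 24L) * 3600
  ts <- t0 + rep((seq_len(days) - 1L) * 86400, each = per_day) +
    rep(off, days)
  track(bird_id, ts[seq_len(n)], positions[, 1], positions[, 2],
        schedule = schedule)
}

# A track with one fix per day at the given daily positions (hour 12:00).
make_daily_track <- function(x, y, start = "2014-02-01", bird_id = "T1") {
  t0 <- as.POSIXct(paste(start, "12:00:00"), tz = "UTC")
  track(bird_id, t0 + (seq_along(x) - 1) * 86400, x, y)
}

# Phase-structured synthetic day schedule: positions per day as a list of
# per-day matrices (each n_hours+1 rows: daytime fixes then midnight roost).
make_day_track <- function(day_positions, start = "2014-02-01",
                           schedule = "two_hour", bird_id = "T1") {
  mat <- do.call(rbind, day_positions)
  make_track(mat, start = start, schedule = schedule, bird_id = bird_id)
}

# An isotropic Gaussian UD built directly (not through the kernel fitter).
gaussian_ud <- function(sigma, cell = sigma / 10, extent = 6 * sigma) {
  ud <- make_ud_grid(c(-extent, extent), c(-extent, extent), cell)
  dx <- stats::dnorm(ud$x, 0, sigma)
  dy <- stats::dnorm(ud$y, 0, sigma)
  ud$values <- outer(dx, dy)
  ud$values <- ud$values / sum(ud$values)
  ud
}

# Dense-sampling oracle for segment/region interaction: nq points along the
# closed segment, each tested for containment in the closed region.
dense_oracle_circle <- function(x1, y1, x2, y2, cx, cy, r, nq = 10000) {
  t <- seq(0, 1, length.out = nq)
  px <- x1 + t * (x2 - x1)
  py <- y1 + t * (y2 - y1)
  any((px - cx)^2 + (py - cy)^2 <= r^2)
}

# Brute-force logistic MLE by coarse-to-fine grid search on the
# log-likelihood; independent of stats::glm. The intercept and slope are
# strongly correlated (a ridge along b0 ~ -mean(day)*b1), so the slope grid
# must stay much finer than the intercept grid at every refinement.
grid_logistic <- function(flag, day) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * day
    sum(flag * eta - log1p(exp(eta)))
  }
  b0r <- c(-6, 6); b1r <- c(-0.3, 0.3)
  steps <- list(c(0.2, 0.01), c(0.02, 0.001), c(0.002, 1e-4), c(2e-4, 1e-5))
  for (s in steps) {
    b0s <- seq(b0r[1], b0r[2], by = s[1])
    b1s <- seq(b1r[1], b1r[2], by = s[2])
    vals <- outer(b0s, b1s, Vectorize(ll))
    k <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    b0 <- b0s[k[1]]; b1 <- b1s[k[2]]
    b0r <- b0 + c(-4, 4) * s[1]
    b1r <- b1 + c(-4, 4) * s[2]
  }
  c(b0 = b0, b1 = b1)
}

# Classify one population of simulated birds against the distance-based
# buffers using true onsets; returns pooled segment records.
classify_population <- function(sampling, seed, n_birds = 20,
                                gps_sigma = 10) {
  cfg <- sim_config(n_birds = n_birds, seed = seed,
                    habitat_sampling = sampling, gps_sigma = gps_sigma)
  pop <- simulate_population(cfg)
  do.call(rbind, lapply(seq_along(pop$tracks), function(i) {
    tr <- pop$tracks[[i]]
    tru <- pop$truth[[i]]
    ph <- delineate_phases(tr, list(nest_x = tru$nest[1],
                                    nest_y = tru$nest[2],
                                    laying_onset = tru$laying_onset,
                                    incubation_onset = tru$incubation_onset))
    buf <- suppressMessages(build_buffers(tru$nest, NULL, "rio_grande"))
    classify_segments(tr, ph, buf)
  }))
}
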