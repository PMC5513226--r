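#' Truth-tagged synthetic GPS tracks
#'
#' Generates per-female GPS tracks that emulate the monitoring design the
#' pipeline expects: fixes at fixed clock hours (hourly 0600-2000 plus one
#' midnight roost fix by default, or 2-h increments), ~45 days of prenesting
#' movement as a biased correlated random walk around a range center,
#' ~10-14 laying days with one daily nest visit while roosting elsewhere,
#' ~26-28 incubation days with every fix at the nest, and isotropic GPS
#' error on every emitted position. The `habitat_sampling` switch creates
#' the two worlds the inference layer discriminates: under `"sampling"`,
#' prenesting days include nest-area visits at a rate that grows as laying
#' approaches; under `"none"` the walk ignores the future nest site.
#'
#' @name synthetic_tracks
NULL

#' Simulation configuration
#'
#' Defaults describe a plausible nesting female: gamma step lengths with
#' mean 200 m per move, wrapped-Cauchy turning concentration 0.5, mild
#' attraction to the range center, three roost sites, nest offset
#' exponentially distributed around 400 m from the range center, 10-m GPS
#' error, and a 2% daily incubation failure hazard.
#'
#' @param n_birds number of females.
#' @param schedule `"hourly"` or `"two_hour"`.
#' @param start_date first tracked (prenesting) day.
#' @param prenesting_days,laying_days_mean,incubation_days_min,incubation_days_max
#'   phase durations (days); laying length is drawn near its mean and
#'   clamped to 10-14.
#' @param step_shape,step_scale gamma step-length parameters (meters).
#' @param turn_rho wrapped-Cauchy turning-angle concentration in [0, 1).
#' @param attraction weight in [0, 1] pulling each step toward the range
#'   center.
#' @param n_roosts,roost_radius roost sites per female, placed within
#'   `roost_radius` meters of the range center (and kept at least 120 m from
#'   the nest).
#' @param nest_offset_mean mean (m) of the exponential nest offset from the
#'   range center.
#' @param habitat_sampling `"none"` or `"sampling"`.
#' @param sampling_rate,sampling_decay visit probability on the day `d`
#'   before laying is `sampling_rate * exp(-(d - 1) / sampling_decay)`.
#' @param visit_sd SD (m) of sampling-visit positions around the nest.
#' @param gps_sigma GPS error SD per axis (m).
#' @param fail_prob daily incubation failure probability (possible from the
#'   third incubation day, so every emitted attempt is field-observable).
#' @param seed master seed; per-bird streams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 20L,
                       schedule = c("hourly", "two_hour"),
                       start_date = as.Date("2014-02-01"),
                       prenesting_days = 45L,
                       laying_days_mean = 12,
                       incubation_days_min = 26L,
                       incubation_days_max = 28L,
                       step_shape = 2, step_scale = 100,
                       turn_rho = 0.5,
                       attraction = 0.1,
                       n_roosts = 3L, roost_radius = 700,
                       nest_offset_mean = 400,
                       habitat_sampling = c("none", "sampling"),
                       sampling_rate = 0.6, sampling_decay = 12,
                       visit_sd = 20,
                       gps_sigma = 10,
                       fail_prob = 0.02,
                       seed = 1L) {
  cfg <- list(n_birds = as.integer(n_birds), schedule = match.arg(schedule),
              start_date = as.Date(start_date),
              prenesting_days = as.integer(prenesting_days),
              laying_days_mean = laying_days_mean,
              incubation_days_min = as.integer(incubation_days_min),
              incubation_days_max = as.integer(incubation_days_max),
              step_shape = step_shape, step_scale = step_scale,
              turn_rho = turn_rho, attraction = attraction,
              n_roosts = as.integer(n_roosts), roost_radius = roost_radius,
              nest_offset_mean = nest_offset_mean,
              habitat_sampling = match.arg(habitat_sampling),
              sampling_rate = sampling_rate, sampling_decay = sampling_decay,
              visit_sd = visit_sd, gps_sigma = gps_sigma,
              fail_prob = fail_prob, seed = as.integer(seed))
  stopifnot(cfg$step_shape > 0, cfg$step_scale > 0,
            cfg$turn_rho >= 0, cfg$turn_rho < 1,
            cfg$attraction >= 0, cfg$attraction <= 1,
            cfg$gps_sigma >= 0, cfg$n_birds >= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate one female
#'
#' @param config a [sim_config()].
#' @param bird_id identifier.
#' @param seed per-bird seed (derived from the master seed by
#'   [simulate_population()]).
#' @return list with `track` (a `track`) and `truth` (nest, onsets, fate,
#'   sampling flag, per-prenesting-day true minimum distance to the nest).
#' @export
simulate_female <- function(config, bird_id = "B01", seed = config$seed) {
  set.seed(seed)
  hours <- schedule_hours(config$schedule)
  day_hours <- sort(hours[hours != 0])

  center <- c(0, 0)
  ang <- stats::runif(1, 0, 2 * pi)
  nest <- center + stats::rexp(1, 1 / config$nest_offset_mean) *
    c(cos(ang), sin(ang))
  roosts <- matrix(NA_real_, config$n_roosts, 2)
  for (k in seq_len(config$n_roosts)) {
    for (try in 1:50) {
      a <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 100, config$roost_radius)
      cand <- center + r * c(cos(a), sin(a))
      if (sqrt(sum((cand - nest)^2)) >= 120) break
    }
    roosts[k, ] <- cand
  }

  laying_len <- max(10L, min(14L, as.integer(round(
    stats::rnorm(1, config$laying_days_mean, 1)))))
  inc_len <- sample(seq(config$incubation_days_min,
                        config$incubation_days_max), 1)
  fail_day <- NA_integer_
  for (d in seq_len(inc_len)) {
    if (d < 3) next # failures before the onset rule can register are unobservable
    if (stats::runif(1) < config$fail_prob) { fail_day <- d; break }
  }
  fate <- if (is.na(fail_day)) "success" else "fail"
  if (!is.na(fail_day)) inc_len <- fail_day

  laying_onset <- config$start_date + config$prenesting_days
  incubation_onset <- laying_onset + laying_len
  n_days <- config$prenesting_days + laying_len + inc_len
  dates <- config$start_date + seq_len(n_days) - 1L

  # warm up the walk so prenesting starts in the stationary regime
  pos <- center + stats::rnorm(2, 0, 100)
  heading <- stats::runif(1, 0, 2 * pi)
  crw_step <- function(pos, heading, target = NULL) {
    len <- stats::rgamma(1, config$step_shape, scale = config$step_scale)
    turn <- rwcauchy(1, config$turn_rho)
    heading <- heading + turn
    u <- c(cos(heading), sin(heading))
    pull <- if (is.null(target)) center - pos else target - pos
    np <- sqrt(sum(pull^2))
    if (np > 0) pull <- pull / np
    dir <- (1 - config$attraction) * u + config$attraction * pull
    nd <- sqrt(sum(dir^2))
    if (nd > 0) dir <- dir / nd
    list(pos = pos + len * dir, heading = atan2(dir[2], dir[1]))
  }
  # burn in the full daily cycle (daytime CRW steps plus the nightly snap to
  # the nearest roost): the tracked process equilibrates jointly under both,
  # and warming up the walk alone leaves a day trend in the null world
  for (i in 1:30) {
    for (hi in seq_along(day_hours)) {
      st <- crw_step(pos, heading)
      pos <- st$pos; heading <- st$heading
    }
    dr <- rowSums(sweep(roosts, 2, pos)^2)
    pos <- roosts[which.min(dr), ]
    heading <- stats::runif(1, 0, 2 * pi)
  }

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  per_day_off <- c(day_hours, 24L) * 3600
  ts <- t0 + rep((seq_len(n_days) - 1L) * 86400, each = length(per_day_off)) +
    rep(per_day_off, n_days)
  px <- numeric(length(ts)); py <- numeric(length(ts))
  true_min <- rep(NA_real_, config$prenesting_days)

  for (di in seq_len(n_days)) {
    date <- dates[di]
    phase <- if (di <= config$prenesting_days) "prenesting"
    else if (di <= config$prenesting_days + laying_len) "laying"
    else "incubation"
    day_before <- config$prenesting_days - di + 1L # valid in prenesting

    visit_idx <- 0L
    if (phase == "laying") {
      visit_idx <- sample(seq_along(day_hours), 1)
    } else if (phase == "prenesting" &&
               config$habitat_sampling == "sampling") {
      p <- config$sampling_rate * exp(-(day_before - 1) / config$sampling_decay)
      if (stats::runif(1) < p) visit_idx <- sample(seq_along(day_hours), 1)
    }

    day_true <- matrix(NA_real_, length(day_hours) + 1L, 2)
    for (hi in seq_along(day_hours)) {
      if (phase == "incubation") {
        pos <- nest
      } else if (hi == visit_idx) {
        pos <- if (phase == "laying") nest
        else nest + stats::rnorm(2, 0, config$visit_sd)
        heading <- stats::runif(1, 0, 2 * pi)
      } else {
        st <- crw_step(pos, heading)
        pos <- st$pos; heading <- st$heading
      }
      day_true[hi, ] <- pos
    }
    # midnight roost fix (belongs to this day)
    if (phase == "incubation") {
      pos <- nest
    } else {
      dr <- rowSums(sweep(roosts, 2, pos)^2)
      pos <- roosts[which.min(dr), ]
      heading <- stats::runif(1, 0, 2 * pi)
    }
    day_true[nrow(day_true), ] <- pos

    at <- (di - 1L) * nrow(day_true) + seq_len(nrow(day_true))
    px[at] <- day_true[, 1]
    py[at] <- day_true[, 2]
    if (phase == "prenesting") {
      true_min[day_before] <- sqrt(min((day_true[, 1] - nest[1])^2 +
                                         (day_true[, 2] - nest[2])^2))
    }
  }

  gx <- px + stats::rnorm(length(px), 0, config$gps_sigma)
  gy <- py + stats::rnorm(length(py), 0, config$gps_sigma)

  list(
    track = track(bird_id, ts, gx, gy, schedule = config$schedule),
    truth = list(bird_id = bird_id, nest = nest,
                 laying_onset = laying_onset,
                 incubation_onset = incubation_onset,
                 fate = fate,
                 habitat_sampling = config$habitat_sampling,
                 daily_min_distance = true_min)
  )
}

# wrapped-Cauchy deviates (Best-Fisher inversion)
rwcauchy <- function(n, rho) {
  if (rho == 0) return(stats::runif(n, -pi, pi))
  u <- stats::runif(n)
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
}

#' Simulate a population and optionally write the CSV dialects
#'
#' Each bird draws from its own stream, seeded deterministically from the
#' master seed and the bird index, so per-bird output is reproducible under
#' reordering; identical seeds give byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; writes `fixes.csv`, `nests.csv`
#'   (package dialects) and `truth.csv`.
#' @return list with `tracks` (list of `track`), `truth` (list per bird),
#'   `nests` (a `nest_attempts` table).
#' @export
simulate_population <- function(config, dir = NULL) {
  ids <- sprintf("SIM%03d", seq_len(config$n_birds))
  seeds <- (as.numeric(config$seed) * 48271 +
              seq_len(config$n_birds) * 104729) %% 2147483647
  birds <- lapply(seq_len(config$n_birds), function(i) {
    simulate_female(config, bird_id = ids[i], seed = as.integer(seeds[i]))
  })
  tracks <- lapply(birds, `[[`, "track")
  names(tracks) <- ids
  truth <- lapply(birds, `[[`, "truth")
  nests <- data.frame(
    bird_id = ids,
    nest_x = vapply(truth, function(t) t$nest[1], numeric(1)),
    nest_y = vapply(truth, function(t) t$nest[2], numeric(1)),
    laying_onset = as.Date(vapply(truth, function(t) format(t$laying_onset),
                                  character(1))),
    incubation_onset = as.Date(vapply(truth,
                                      function(t) format(t$incubation_onset),
                                      character(1))),
    fate = vapply(truth, `[[`, character(1), "fate"),
    stringsAsFactors = FALSE
  )
  nests$attempt_index <- 1L
  class(nests) <- c("nest_attempts", "data.frame")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fixes(tracks, file.path(dir, "fixes.csv"))
    write_nests(nests, file.path(dir, "nests.csv"))
    tr <- data.frame(bird_id = ids,
                     nest_x = nests$nest_x, nest_y = nests$nest_y,
                     laying_onset = format(nests$laying_onset),
                     incubation_onset = format(nests$incubation_onset),
                     fate = nests$fate,
                     habitat_sampling = config$habitat_sampling)
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  list(tracks = tracks, truth = truth, nests = nests)
}
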