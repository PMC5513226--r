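# Day-structured fixture: 9 fixes/day (two_hour schedule). Each element of
# `days` is a function(day_index) returning a 9x2 matrix of positions.
build_phase_track <- function(n_days, pos_fun, start = "2014-02-01") {
  make_day_track(lapply(seq_len(n_days), pos_fun), start = start,
                 schedule = "two_hour")
}

far <- function() cbind(stats::runif(9, 500, 900), stats::runif(9, 500, 900))

test_that("incubation onset is the first all-within day starting a run", {
  set.seed(1)
  nest <- c(0, 0)
  # days 1..9 far away, days 10..14 all fixes within 15 m
  tr <- build_phase_track(14, function(d) {
    if (d < 10) far() else cbind(stats::runif(9, -15, 15) * 0.7,
                                 stats::runif(9, -15, 15) * 0.7)
  })
  expect_equal(detect_incubation_onset(tr, nest),
               as.Date("2014-02-01") + 9)

  # never within 50 m -> no onset
  tr2 <- build_phase_track(10, function(d) far())
  expect_null(detect_incubation_onset(tr2, nest))

  # 8 of 9 fixes within, one at 200 m -> that day does not qualify
  tr3 <- build_phase_track(6, function(d) {
    if (d < 3) far() else {
      m <- cbind(stats::runif(9, -10, 10), stats::runif(9, -10, 10))
      if (d == 3) m[5, ] <- c(200, 0)
      m
    }
  })
  expect_equal(detect_incubation_onset(tr3, nest),
               as.Date("2014-02-01") + 3)

  expect_error(detect_incubation_onset(tr[0, ], nest), "empty")
})

test_that("a single quiet day does not trigger onset under the run guard", {
  set.seed(2)
  nest <- c(0, 0)
  tr <- build_phase_track(10, function(d) {
    if (d == 3 || d >= 8) cbind(stats::runif(9, -10, 10),
                                stats::runif(9, -10, 10))
    else far()
  })
  expect_equal(detect_incubation_onset(tr, nest, min_run = 2),
               as.Date("2014-02-01") + 7)
  # literal single-day rule picks the quiet day
  expect_equal(detect_incubation_onset(tr, nest, min_run = 1),
               as.Date("2014-02-01") + 2)
})

test_that("laying onset is the visit run touching incubation", {
  set.seed(3)
  nest <- c(0, 0)
  visit_day <- function() {
    m <- far()
    m[4, ] <- c(10, 0)    # one daytime visit
    m[9, ] <- c(400, 400) # roost elsewhere
    m
  }
  inc_day <- function() cbind(stats::runif(9, -10, 10),
                              stats::runif(9, -10, 10))
  start <- as.Date("2014-02-01")
  # visits on days 5..9 (index), incubation from day 10
  tr <- build_phase_track(14, function(d) {
    if (d >= 10) inc_day() else if (d >= 5) visit_day() else far()
  })
  io <- start + 9
  expect_equal(detect_laying_onset(tr, nest, 50, io), start + 4)

  # no visits at all -> fallback to incubation onset
  tr2 <- build_phase_track(14, function(d) if (d >= 10) inc_day() else far())
  expect_equal(suppressMessages(detect_laying_onset(tr2, nest, 50, io)), io)

  # visits 2..4, gap, visits 7..9 -> the run touching incubation wins
  tr3 <- build_phase_track(14, function(d) {
    if (d >= 10) inc_day()
    else if ((d >= 2 && d <= 4) || d >= 7) visit_day()
    else far()
  })
  expect_equal(detect_laying_onset(tr3, nest, 50, io), start + 6)

  # a daytime visit whose roost is also at the nest is not a laying day
  tr4 <- build_phase_track(14, function(d) {
    if (d >= 10) inc_day() else if (d >= 5) {
      m <- visit_day(); m[9, ] <- c(5, 5); m
    } else far()
  })
  expect_equal(suppressMessages(detect_laying_onset(tr4, nest, 50, io)), io)
})

test_that("phase tags partition fixes and days-before-laying is a bijection", {
  cfg <- sim_config(n_birds = 1, seed = 9)
  sim <- simulate_female(cfg, "P1", seed = 9)
  tru <- sim$truth
  ph <- delineate_phases(sim$track,
                         list(nest_x = tru$nest[1], nest_y = tru$nest[2],
                              laying_onset = tru$laying_onset,
                              incubation_onset = tru$incubation_onset))
  f <- ph$fixes
  expect_true(all(f$phase %in% c("prenesting", "laying", "incubation", "other")))
  pre <- f[f$phase == "prenesting", ]
  expect_setequal(unique(pre$days_before_laying), 1:45)
  # bijection date <-> index
  m <- unique(pre[, c("day", "days_before_laying")])
  expect_equal(nrow(m), 45)
  expect_equal(as.integer(ph$laying_onset - m$day), m$days_before_laying)
  # non-prenesting fixes carry no index
  expect_true(all(is.na(f$days_before_laying[f$phase != "prenesting"])))
})

test_that("late capture yields a truncated prenesting record", {
  cfg <- sim_config(n_birds = 1, seed = 13)
  sim <- simulate_female(cfg, "P2", seed = 13)
  tru <- sim$truth
  # drop the first 20 tracked days: 25 prenesting days remain
  keep <- fix_day(sim$track$timestamp) >= as.Date("2014-02-01") + 20
  tr <- sim$track[keep, ]
  class(tr) <- c("track", "data.frame")
  ph <- delineate_phases(tr,
                         list(nest_x = tru$nest[1], nest_y = tru$nest[2],
                              laying_onset = tru$laying_onset,
                              incubation_onset = tru$incubation_onset))
  d <- fix_nest_distances(tr, tru$nest, ph)
  s <- summarize_prenesting(d)
  expect_equal(s$days_prenest, 25)
  expect_true(all(ph$fixes$days_before_laying <= 25, na.rm = TRUE))
})

test_that("phase windows are half-open at day resolution", {
  cfg <- sim_config(n_birds = 1, seed = 21)
  sim <- simulate_female(cfg, "P3", seed = 21)
  tru <- sim$truth
  ph <- delineate_phases(sim$track,
                         list(nest_x = tru$nest[1], nest_y = tru$nest[2],
                              laying_onset = tru$laying_onset,
                              incubation_onset = tru$incubation_onset))
  f <- ph$fixes
  expect_true(all(f$day[f$phase == "prenesting"] < tru$laying_onset))
  expect_true(all(f$day[f$phase == "laying"] >= tru$laying_onset))
  expect_true(all(f$day[f$phase == "laying"] < tru$incubation_onset))
  expect_true(all(f$day[f$phase == "incubation"] >= tru$incubation_onset))
})
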