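test_that("equivalent radius converts area to the equal-area circle", {
  expect_equal(equivalent_radius(pi), 1)
  # the typical incubation extent of 1.46 ha
  expect_equal(equivalent_radius(14600), sqrt(14600 / pi), tolerance = 1e-12)
  expect_equal(equivalent_radius(14600), 68.17, tolerance = 1e-3)
  expect_error(equivalent_radius(0), "positive")
  expect_error(equivalent_radius(-3), "positive")
})

test_that("buffer sets carry the five regions with the right radii", {
  sigma <- 30
  ud <- gaussian_ud(sigma, cell = 2)
  bs <- build_buffers(c(0, 0), incubation_ud = ud, subspecies = "eastern",
                      bird_id = "B1")
  expect_setequal(names(bs$regions),
                  c("kernel95_equiv_circle", "kernel75_polygon",
                    "mean_incubation_circle", "fixed_100m", "fixed_500m"))
  expect_equal(bs$regions$mean_incubation_circle$r, 55.24)
  expect_equal(bs$regions$fixed_100m$r, 100)
  expect_equal(bs$regions$fixed_500m$r, 500)
  # Gaussian 95% area -> equivalent radius sqrt(qchisq(.95,2)) * sigma
  expect_equal(bs$regions$kernel95_equiv_circle$r,
               sqrt(stats::qchisq(0.95, 2)) * sigma, tolerance = 0.05)

  bs_rg <- build_buffers(c(10, 10), incubation_ud = ud,
                         subspecies = "rio_grande")
  expect_equal(bs_rg$regions$mean_incubation_circle$r, 70.82)
  expect_error(build_buffers(c(0, 0), ud, subspecies = "merriams"),
               "subspecies")

  # without an incubation UD only the distance-based circles exist
  bs3 <- suppressMessages(build_buffers(c(0, 0), NULL, "eastern"))
  expect_setequal(names(bs3$regions),
                  c("mean_incubation_circle", "fixed_100m", "fixed_500m"))
})

test_that("segment-circle classification matches hand geometry", {
  # closest approach 50 m < 60 -> hit
  expect_true(segment_intersects_circle(0, 0, 200, 0, 100, 50, 60))
  # closest approach 80 m > 60 -> miss
  expect_false(segment_intersects_circle(0, 0, 200, 0, 100, 80, 60))
  # containment counts under closed semantics, not under boundary
  expect_true(segment_intersects_circle(-10, 0, 10, 0, 0, 0, 500, "closed"))
  expect_false(segment_intersects_circle(-10, 0, 10, 0, 0, 0, 500, "boundary"))
  # crossing counts under both
  expect_true(segment_intersects_circle(-600, 0, 600, 0, 0, 0, 500, "boundary"))
})

test_that("classification is invariant to translation and rotation", {
  set.seed(4)
  for (i in 1:200) {
    seg <- stats::runif(4, -300, 300)
    cen <- stats::runif(2, -300, 300)
    r <- stats::runif(1, 10, 250)
    base <- segment_intersects_circle(seg[1], seg[2], seg[3], seg[4],
                                      cen[1], cen[2], r)
    dx <- stats::runif(1, -1e4, 1e4); dy <- stats::runif(1, -1e4, 1e4)
    expect_identical(
      segment_intersects_circle(seg[1] + dx, seg[2] + dy, seg[3] + dx,
                                seg[4] + dy, cen[1] + dx, cen[2] + dy, r),
      base)
    th <- stats::runif(1, 0, 2 * pi)
    rot <- function(x, y) c(cos(th) * x - sin(th) * y,
                            sin(th) * x + cos(th) * y)
    a <- rot(seg[1], seg[2]); b <- rot(seg[3], seg[4]); cc <- rot(cen[1], cen[2])
    expect_identical(
      segment_intersects_circle(a[1], a[2], b[1], b[2], cc[1], cc[2], r),
      base)
  }
})

test_that("concentric regions are monotone: a hit on the smaller circle
           implies a hit on the larger", {
  set.seed(5)
  for (i in 1:300) {
    seg <- stats::runif(4, -400, 400)
    r1 <- stats::runif(1, 20, 150)
    r2 <- r1 + stats::runif(1, 1, 200)
    h1 <- segment_intersects_circle(seg[1], seg[2], seg[3], seg[4], 0, 0, r1)
    h2 <- segment_intersects_circle(seg[1], seg[2], seg[3], seg[4], 0, 0, r2)
    if (h1) expect_true(h2)
  }
})

test_that("polygon-region classification handles crossing, containment, holes", {
  square <- list(list(x = c(-100, 100, 100, -100, -100),
                      y = c(-100, -100, 100, 100, -100)))
  expect_true(segment_intersects_polygon(-200, 0, 200, 0, square))
  expect_true(segment_intersects_polygon(-10, -10, 10, 10, square)) # inside
  expect_false(segment_intersects_polygon(-10, -10, 10, 10, square,
                                          mode = "boundary"))
  expect_false(segment_intersects_polygon(-200, 150, 200, 150, square))
  # annulus: hole from -50..50; a segment wholly inside the hole misses
  annulus <- c(square, list(list(x = c(-50, 50, 50, -50, -50),
                                 y = c(-50, -50, 50, 50, -50))))
  expect_false(point_in_rings(0, 0, annulus))
  expect_true(point_in_rings(75, 0, annulus))
  expect_false(segment_intersects_polygon(-20, 0, 20, 0, annulus))
  expect_true(segment_intersects_polygon(-75, 0, 75, 0, annulus))
})

test_that("segments form only within prenesting days and carry start-day
           attribution", {
  cfg <- sim_config(n_birds = 1, seed = 17)
  sim <- simulate_female(cfg, "S1", seed = 17)
  tru <- sim$truth
  ph <- delineate_phases(sim$track,
                         list(nest_x = tru$nest[1], nest_y = tru$nest[2],
                              laying_onset = tru$laying_onset,
                              incubation_onset = tru$incubation_onset))
  bs <- suppressMessages(build_buffers(tru$nest, NULL, "rio_grande"))
  segs <- classify_segments(sim$track, ph, bs)
  f <- ph$fixes
  pre_fixes <- sum(f$phase == "prenesting")
  # hourly schedule: 16 fixes/day over 45 days; one fewer segment per day gap
  expect_equal(nrow(segs), pre_fixes - 1)
  expect_true(all(segs$day_before_laying %in% 1:45))
  # flags defined for every region
  expect_true(all(!is.na(segs$mean_incubation_circle)))
  # monotone by construction: fixed_100m hit implies fixed_500m hit
  expect_true(all(segs$fixed_500m[segs$fixed_100m == 1] == 1))
})

test_that("zero-length segments classify by point containment", {
  ts <- as.POSIXct("2014-02-01 06:00:00", tz = "UTC") + c(0, 3600)
  tr <- track("Z", ts, c(10, 10), c(0, 0))
  ph <- list(fixes = data.frame(timestamp = tr$timestamp,
                                day = fix_day(tr$timestamp),
                                phase = "prenesting",
                                days_before_laying = c(5L, 5L)))
  bs <- suppressMessages(build_buffers(c(0, 0), NULL, "rio_grande"))
  segs <- classify_segments(tr, ph, bs)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$fixed_100m, 1L)   # point at 10 m is inside
  expect_equal(segs$mean_incubation_circle, 1L)
})

test_that("intersection frequencies aggregate per day and region", {
  rec <- data.frame(bird_id = "A",
                    day_before_laying = rep(1:5, each = 2),
                    fixed_100m = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0))
  fr <- intersection_frequencies(rec, regions = "fixed_100m", days = 1:5)
  expect_equal(fr$frequency, c(1, 0, 0.5, 0, 0))
  expect_equal(fr$n_segments, rep(2L, 5))

  # all-zero flags give all-zero frequencies
  rec$fixed_100m <- 0
  fr0 <- intersection_frequencies(rec, regions = "fixed_100m", days = 1:5)
  expect_true(all(fr0$frequency == 0))

  # days without segments are missing, not zero
  fr6 <- intersection_frequencies(rec, regions = "fixed_100m", days = 1:6)
  expect_true(is.na(fr6$frequency[6]))
})

test_that("a bird drifting toward the nest shows non-decreasing interaction
           frequency as laying approaches", {
  # one daily segment moving linearly from 2000 m to 50 m over 45 days
  d <- seq(2000, 50, length.out = 45)
  rec <- data.frame(
    bird_id = "D",
    day_before_laying = 45:1,
    fixed_500m = vapply(seq_len(45), function(i) {
      as.integer(segment_intersects_circle(d[i], 0, d[i], 100, 0, 0, 500))
    }, integer(1)))
  fr <- intersection_frequencies(rec, regions = "fixed_500m", days = 1:45)
  fr <- fr[order(-fr$day_before_laying), ]
  expect_true(all(diff(fr$frequency) >= 0))
  expect_equal(fr$frequency[fr$day_before_laying == 1], 1)
  expect_equal(fr$frequency[fr$day_before_laying == 45], 0)
})
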