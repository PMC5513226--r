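test_that("two-fix bridge matches the analytic time-integrated density", {
  s2m <- 0.5           # m^2/s
  loc <- 10            # m
  T <- 3600
  tr <- track("BB", as.POSIXct(c("2014-02-01 06:00:00", "2014-02-01 07:00:00"),
                               tz = "UTC"), c(0, 1000), c(0, 0))
  grid <- make_ud_grid(c(-150, 1150), c(-150, 150), 5)
  ud <- fit_brownian_bridge(tr, location_error = loc, grid = grid,
                            sigma2m = s2m)
  expect_lt(abs(ud_mass(ud) - 1), 1e-6)

  # oracle: fine midpoint quadrature over alpha at every grid cell
  nal <- 2000
  al <- (seq_len(nal) - 0.5) / nal
  mx <- 1000 * al
  sd_al <- sqrt(T * s2m * al * (1 - al) + ((1 - al)^2 + al^2) * loc^2)
  oracle <- matrix(0, length(grid$x), length(grid$y))
  for (j in seq_len(nal)) {
    oracle <- oracle + outer(stats::dnorm(grid$x, mx[j], sd_al[j]),
                             stats::dnorm(grid$y, 0, sd_al[j])) / nal
  }
  oracle <- oracle * 25 # cell mass
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(ud$values - oracle)), 1e-3 * max(oracle))

  # mid-line positional SD equals the bridge closed form: T*s2m/4 motion
  # variance plus the endpoint-error propagation (1-a)^2+a^2 = 1/2 at mid
  imid <- which.min(abs(grid$x - 500))
  col_mass <- ud$values[imid, ]
  sd_emp <- sqrt(sum(col_mass * grid$y^2) / sum(col_mass))
  expect_equal(sd_emp, sqrt(s2m * T / 4 + loc^2 / 2), tolerance = 0.02)
})

test_that("zero movement collapses the bridge to the location-error kernel", {
  ts <- as.POSIXct("2014-02-01 06:00:00", tz = "UTC") + (0:9) * 3600
  tr <- track("Z", ts, rep(100, 10), rep(-50, 10))
  ud <- fit_brownian_bridge(tr, location_error = 10,
                            grid = list(cell_size = 2, pad = 60), sigma2m = 0)
  peak <- which(ud$values == max(ud$values), arr.ind = TRUE)[1, ]
  expect_equal(ud$x[peak[1]], 100, tolerance = 2)
  expect_equal(ud$y[peak[2]], -50, tolerance = 2)
  # ~all mass within 4 location-error SDs
  d2 <- outer((ud$x - 100)^2, (ud$y + 50)^2, `+`)
  expect_gt(sum(ud$values[d2 <= (4 * 10)^2]), 0.999)
})

test_that("leave-one-out ML recovers a known motion variance", {
  set.seed(42)
  s2m <- 0.5
  dt <- 3600
  n <- 200
  x <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(s2m * dt))))
  y <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(s2m * dt))))
  loc <- 10
  ts <- as.POSIXct("2014-02-01 00:00:00", tz = "UTC") + (0:(n - 1)) * dt
  tr <- track("V", ts, x + stats::rnorm(n, 0, loc), y + stats::rnorm(n, 0, loc))
  est <- nestmove:::estimate_sigma2m(as.numeric(tr$timestamp), tr$x, tr$y,
                                     loc, 2:(n - 1))
  expect_equal(est, s2m, tolerance = 0.2)
})

test_that("fixed kernel equals the average of per-point Gaussians", {
  set.seed(7)
  pts <- data.frame(x = stats::rnorm(40, 0, 30), y = stats::rnorm(40, 0, 30))
  h <- 12
  ud <- fit_fixed_kernel(pts, bandwidth = h,
                         grid = list(cell_size = h / 3, pad = 8 * h))
  expect_lt(abs(ud_mass(ud) - 1), 1e-6)
  # oracle: direct summation at 100 query cells well inside the support
  set.seed(8)
  qi <- sample(which(abs(ud$x) < 60), 100, replace = TRUE)
  qj <- sample(which(abs(ud$y) < 60), 100, replace = TRUE)
  for (k in 1:100) {
    direct <- mean(stats::dnorm(ud$x[qi[k]], pts$x, h) *
                     stats::dnorm(ud$y[qj[k]], pts$y, h))
    grid_val <- ud$values[qi[k], qj[k]] / (ud$cell_size^2)
    expect_equal(grid_val, direct, tolerance = 1e-6)
  }
})

test_that("a single point with bandwidth h gives an isotropic Gaussian", {
  h <- 25
  ud <- fit_fixed_kernel(data.frame(x = 0, y = 0), bandwidth = h,
                         grid = list(cell_size = h / 10, pad = 6 * h))
  direct <- outer(stats::dnorm(ud$x, 0, h), stats::dnorm(ud$y, 0, h)) *
    ud$cell_size^2
  direct <- direct / sum(direct)
  expect_lt(max(abs(ud$values - direct)), 1e-3 * max(direct))
})

test_that("reference bandwidth needs spread and enough points", {
  expect_error(fit_fixed_kernel(data.frame(x = rep(1, 8), y = rep(2, 8))),
               "bandwidth")
  expect_error(fit_fixed_kernel(data.frame(x = 1:3, y = 1:3)), "at least 5")
})

test_that("well-separated clusters split the core isopleth", {
  set.seed(11)
  h <- 10
  a <- data.frame(x = stats::rnorm(60, 0, h), y = stats::rnorm(60, 0, h))
  b <- data.frame(x = stats::rnorm(60, 10 * h * 10, h),
                  y = stats::rnorm(60, 0, h))
  ud <- fit_fixed_kernel(rbind(a, b), bandwidth = h,
                         grid = list(cell_size = 5, pad = 5 * h))
  iso50 <- extract_isopleth(ud, 0.50)
  expect_gte(length(iso50$rings), 2)
  iso95 <- extract_isopleth(ud, 0.95)
  expect_true(contains_point(iso95, c(0, 0)))
  expect_true(contains_point(iso95, c(1000, 0)))
})

test_that("Gaussian isopleth areas match the chi-square closed form", {
  sigma <- 100
  ud <- gaussian_ud(sigma, cell = sigma / 10)
  for (lev in c(0.50, 0.95)) {
    iso <- extract_isopleth(ud, lev)
    expect_equal(iso$area_ha,
                 pi * stats::qchisq(lev, 2) * sigma^2 / 1e4,
                 tolerance = 0.03)
    expect_lt(abs(iso$mass - lev), max(ud$values) + 1e-12)
  }
})

test_that("isopleths nest and areas grow with level", {
  cfg <- sim_config(n_birds = 1, seed = 31)
  sim <- simulate_female(cfg, "N1", seed = 31)
  pre <- sim$track[1:200, ]
  class(pre) <- c("track", "data.frame")
  ud <- suppressMessages(fit_brownian_bridge(pre))
  expect_lt(abs(ud_mass(ud) - 1), 1e-6)
  isos <- lapply(c(0.50, 0.75, 0.95, 0.99), function(l) extract_isopleth(ud, l))
  areas <- vapply(isos, function(i) i$area_ha, numeric(1))
  expect_true(all(diff(areas) >= 0))
  # geometric nesting: every vertex of the 50% outline is inside the 95%
  ring_pts <- do.call(rbind, lapply(isos[[1]]$rings, function(r)
    cbind(r$x, r$y)))
  idx <- seq(1, nrow(ring_pts), length.out = 25)
  for (k in idx) {
    expect_true(point_in_rings(ring_pts[k, 1], ring_pts[k, 2],
                               isos[[3]]$rings, eps = 1e-6))
  }
})

test_that("uniform UD isopleth area is the level times the support area", {
  ud <- make_ud_grid(c(0, 1000), c(0, 500), 10)
  ud$values[] <- 1
  ud$values <- ud$values / sum(ud$values)
  iso <- extract_isopleth(ud, 0.75)
  support_ha <- length(ud$x) * length(ud$y) * 100 / 1e4
  expect_equal(iso$area_ha, 0.75 * support_ha, tolerance = 0.01)
})

test_that("isopleth levels outside (0,1) are rejected", {
  ud <- gaussian_ud(50, cell = 10)
  expect_error(extract_isopleth(ud, 0))
  expect_error(extract_isopleth(ud, 1.2))
})

test_that("point membership honors mode, exterior, and the out-of-core case", {
  sigma <- 100
  ud <- gaussian_ud(sigma, cell = sigma / 10)
  isos <- lapply(c(0.50, 0.95, 0.99), function(l) extract_isopleth(ud, l))
  names(isos) <- c("50", "95", "99")
  expect_true(all(vapply(isos, function(i) contains_point(i, c(0, 0)),
                         logical(1))))
  expect_false(any(vapply(isos, function(i) contains_point(i, c(1e4, 1e4)),
                          logical(1))))
  # a nest can sit outside the 50% core yet inside the 95% and 99% ranges
  r_between <- sigma * sqrt((stats::qchisq(0.5, 2) + stats::qchisq(0.95, 2)) / 2)
  m <- nest_range_membership(c(r_between, 0), isos)
  expect_equal(m$inside, c(FALSE, TRUE, TRUE))
})

test_that("UD grids and isopleths export as plain text", {
  ud <- gaussian_ud(30, cell = 10, extent = 90)
  f <- withr::local_tempfile(fileext = ".txt")
  write_ud(ud, f)
  head <- readLines(f, n = 4)
  expect_match(head[2], "cell_size 10")
  g <- withr::local_tempfile(fileext = ".json")
  write_isopleths(extract_isopleth(ud, 0.95), g)
  expect_match(readLines(g), "MultiPolygon", all = FALSE)
})
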