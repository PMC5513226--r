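#' Nest-distance summaries
#'
#' Per-fix, per-day, and period summaries of Euclidean distance from the
#' nest: the engine behind the per-bird prenesting summary tables (mean and
#' SD of distance over all prenesting fixes, the overall minimum and the day
#' before laying on which it occurs, and nest membership in the prenesting
#' range isopleths).
#'
#' @name nest_metrics
NULL

#' Per-fix distances from the nest
#'
#' Euclidean distance of every fix from the nest, with phase tags carried
#' over. With `apply_exclusion`, fixes strictly closer than `exclusion`
#' meters are flagged excluded — the GPS-accuracy rule used for
#' incubation-period summaries. Prenesting summaries use all fixes: the
#' published per-bird minima go below 10 m, so the exclusion is not global.
#'
#' @param track a `track`.
#' @param nest numeric `c(x, y)` in meters.
#' @param phases a `phase_labels` for the same track.
#' @param exclusion exclusion distance in meters.
#' @param apply_exclusion flag fixes closer than `exclusion` as excluded.
#' @return data.frame: `timestamp`, `day`, `phase`, `days_before_laying`,
#'   `distance`, `excluded`.
#' @export
fix_nest_distances <- function(track, nest, phases,
                               exclusion = 10, apply_exclusion = FALSE) {
  if (length(nest) < 2 || anyNA(nest[1:2])) {
    stop("nest coordinates missing", call. = FALSE)
  }
  d <- sqrt((track$x - nest[1])^2 + (track$y - nest[2])^2)
  out <- phases$fixes
  out$distance <- d
  out$excluded <- if (apply_exclusion) d < exclusion else rep(FALSE, length(d))
  out
}

#' Prenesting distance summary for one bird
#'
#' Overall mean and SD of distance over all prenesting fixes (or of the
#' per-day means, per config), the overall minimum, the days-before-laying
#' index at which the minimum occurs (`day_closest`; ties broken toward the
#' day nearer laying), and the number of distinct tracked prenesting days.
#'
#' @param distances output of [fix_nest_distances()].
#' @param mean_mode `"fixes"` or `"daily_means"`.
#' @return data.frame with one row: `days_prenest`, `mean_dist_m`,
#'   `sd_dist_m`, `min_dist_m`, `day_closest`.
#' @export
summarize_prenesting <- function(distances, mean_mode = c("fixes", "daily_means")) {
  mean_mode <- match.arg(mean_mode)
  pre <- distances[distances$phase == "prenesting", , drop = FALSE]
  if (!nrow(pre)) stop("no prenesting fixes", call. = FALSE)
  if (mean_mode == "fixes") {
    m <- mean(pre$distance)
    s <- stats::sd(pre$distance)
  } else {
    daily <- tapply(pre$distance, pre$day, mean)
    m <- mean(daily)
    s <- stats::sd(daily)
  }
  dmin <- min(pre$distance)
  at_min <- pre$days_before_laying[pre$distance == dmin]
  data.frame(
    days_prenest = length(unique(pre$day)),
    mean_dist_m = m,
    sd_dist_m = if (is.na(s)) 0 else s,
    min_dist_m = dmin,
    day_closest = min(at_min)
  )
}

#' Bin day-closest values into days-before-laying windows
#'
#' @param day_closest integer vector (one per bird), or a data.frame with a
#'   `day_closest` column.
#' @param windows list of inclusive `c(lo, hi)` ranges covering the values.
#' @param bird_id optional ids for error messages.
#' @return data.frame per window: `window`, `lo`, `hi`, `count`,
#'   `proportion`; attribute `mean_day_closest`.
#' @export
bin_day_closest <- function(day_closest,
                            windows = list(c(1L, 5L), c(6L, 15L), c(16L, 45L)),
                            bird_id = NULL) {
  if (is.data.frame(day_closest)) {
    if (is.null(bird_id)) bird_id <- day_closest$band_id %||% day_closest$bird_id
    day_closest <- day_closest$day_closest
  }
  if (is.null(bird_id)) bird_id <- as.character(seq_along(day_closest))
  hit <- vapply(day_closest, function(d) {
    w <- which(vapply(windows, function(r) d >= r[1] && d <= r[2], logical(1)))
    if (!length(w)) NA_integer_ else w[1]
  }, integer(1))
  if (anyNA(hit)) {
    stop("day_closest outside all windows for bird(s): ",
         paste(bird_id[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    window = vapply(windows, function(r) sprintf("%d-%d", r[1], r[2]),
                    character(1)),
    lo = vapply(windows, `[`, integer(1), 1),
    hi = vapply(windows, `[`, integer(1), 2),
    count = vapply(seq_along(windows), function(i) sum(hit == i), integer(1))
  )
  out$proportion <- out$count / length(day_closest)
  attr(out, "mean_day_closest") <- mean(day_closest)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nest membership in the prenesting-range isopleths
#'
#' @param nest numeric `c(x, y)`.
#' @param isopleths named list of `isopleth` objects (names are levels such
#'   as `"50"`, `"95"`, `"99"`).
#' @return data.frame: `level`, `inside`, `area_ha`.
#' @export
nest_range_membership <- function(nest, isopleths) {
  data.frame(
    level = names(isopleths),
    inside = vapply(isopleths, function(iso) contains_point(iso, nest),
                    logical(1)),
    area_ha = vapply(isopleths, function(iso) iso$area_ha, numeric(1)),
    row.names = NULL
  )
}

#' Population membership proportions
#'
#' @param membership data.frame with `bird_id`, `level`, `inside` rows for
#'   every bird and level.
#' @return data.frame per level: `level`, `n`, `n_out`, `pct_out`.
#' @export
membership_proportions <- function(membership) {
  lv <- unique(membership$level)
  do.call(rbind, lapply(lv, function(l) {
    s <- membership[membership$level == l, , drop = FALSE]
    data.frame(level = l, n = nrow(s), n_out = sum(!s$inside),
               pct_out = 100 * mean(!s$inside))
  }))
}

#' Parse a possibly censored distance entry
#'
#' Published tables print left-censored minima such as `"<1"`; these parse to
#' the bound with a censored flag and are excluded from mean recomputations.
#'
#' @param x character vector.
#' @return data.frame: `value`, `censored`.
#' @export
parse_censored <- function(x) {
  x <- trimws(as.character(x))
  cens <- grepl("^<", x)
  val <- as.numeric(sub("^<", "", x))
  data.frame(value = val, censored = cens)
}
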