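#' Reproductive-phase delineation from movement
#'
#' Incubation onset is the first day on which every GPS fix lies within a
#' nest buffer (default 50 m) and that starts a run of at least
#' `min_run` such days; laying is the run of daily nest visits (a daytime fix
#' inside the visit radius while the midnight roost is outside) ending the
#' day before incubation begins; prenesting is the 45 days before laying.
#'
#' @name phenology
NULL

# Days (sorted) on which every fix lies within `radius` of the nest.
all_within_days <- function(track, nest, radius) {
  d <- sqrt((track$x - nest[1])^2 + (track$y - nest[2])^2)
  day <- fix_day(track$timestamp)
  ok <- tapply(d <= radius, day, all)
  sort(as.Date(names(ok)[ok]))
}

#' Detect incubation onset
#'
#' Earliest day on which all fixes lie within `radius` of the nest and that
#' begins a run of at least `min_run` consecutive such days. `min_run = 1`
#' reproduces the literal single-day rule; the default 2 guards against a
#' single low-movement day mimicking incubation. Days with no fixes break
#' runs.
#'
#' @param track a `track`.
#' @param nest numeric `c(x, y)` nest coordinates in meters.
#' @param radius buffer radius in meters.
#' @param min_run consecutive qualifying days required.
#' @return a `Date`, or `NULL` when no qualifying day exists.
#' @export
detect_incubation_onset <- function(track, nest, radius = 50, min_run = 2L) {
  if (!nrow(track)) stop("track is empty", call. = FALSE)
  days <- all_within_days(track, nest, radius)
  if (!length(days)) return(NULL)
  run_start <- days[1]
  run_len <- 1L
  for (i in seq_along(days)) {
    if (i > 1) {
      if (as.integer(days[i] - days[i - 1]) == 1L) {
        run_len <- run_len + 1L
      } else {
        run_start <- days[i]
        run_len <- 1L
      }
    }
    if (run_len >= min_run) return(run_start)
  }
  NULL
}

#' Detect laying onset
#'
#' A laying day shows a daily nest visit: at least one non-midnight fix
#' within `visit_radius` of the nest while the day's midnight roost fix lies
#' outside it (a missing midnight fix leaves the roost condition
#' unconstrained). Laying onset is the first day of the run of consecutive
#' visit days ending the day before `incubation_onset`; if that day shows no
#' visit, the laying signature is absent and onset falls back to
#' `incubation_onset` (logged).
#'
#' @param track a `track`.
#' @param nest numeric `c(x, y)` in meters.
#' @param visit_radius visit radius in meters.
#' @param incubation_onset a `Date`.
#' @return a `Date` (never `NULL`).
#' @export
detect_laying_onset <- function(track, nest, visit_radius = 50,
                                incubation_onset) {
  stopifnot(inherits(incubation_onset, "Date"))
  d <- sqrt((track$x - nest[1])^2 + (track$y - nest[2])^2)
  day <- fix_day(track$timestamp)
  lt <- as.POSIXlt(track$timestamp, tz = "UTC")
  is_mid <- lt$hour == 0L & lt$min == 0L & lt$sec == 0
  days <- sort(unique(day[day < incubation_onset]))
  if (!length(days)) return(incubation_onset)
  visit <- vapply(days, function(dd) {
    i <- day == dd
    daytime_in <- any(!is_mid[i] & d[i] <= visit_radius)
    roost <- which(i & is_mid)
    roost_out <- !length(roost) || all(d[roost] > visit_radius)
    daytime_in && roost_out
  }, logical(1))
  visit_days <- days[visit]
  cur <- incubation_onset - 1L
  if (!cur %in% visit_days) {
    nm_log("laying", track$bird_id[1],
           "no laying visit signature; laying onset set to incubation onset")
    return(incubation_onset)
  }
  while ((cur - 1L) %in% visit_days) cur <- cur - 1L
  cur
}

#' Delineate reproductive phases and index days before laying
#'
#' Resolves laying and incubation onsets (from the nest record when present,
#' otherwise from the movement detectors), then tags every fix as
#' `prenesting` (the half-open window of `prenesting_days` days before laying
#' onset), `laying` (laying to incubation onset), `incubation` (the
#' consecutive all-within run from incubation onset), or `other`.
#' `days_before_laying` indexes prenesting dates 1 (day immediately before
#' laying) through `prenesting_days`.
#'
#' @param track a `track`.
#' @param nest one row of a `nest_attempts` table (or a list with `nest_x`,
#'   `nest_y` and optional `laying_onset`, `incubation_onset`).
#' @param config an [analysis_config()].
#' @return object of class `phase_labels`: list with `bird_id`,
#'   `laying_onset`, `incubation_onset`, `prenesting_start`, and `fixes`
#'   (data.frame `timestamp`, `day`, `phase`, `days_before_laying`).
#' @export
delineate_phases <- function(track, nest, config = analysis_config()) {
  if (is.na(nest$nest_x) || is.na(nest$nest_y)) {
    stop("nest coordinates missing for bird ", track$bird_id[1], call. = FALSE)
  }
  np <- c(nest$nest_x, nest$nest_y)
  incubation_onset <- nest$incubation_onset
  if (is.null(incubation_onset) || is.na(incubation_onset)) {
    incubation_onset <- detect_incubation_onset(
      track, np, radius = config$incubation_radius_m,
      min_run = config$incubation_min_run)
    if (is.null(incubation_onset)) {
      stop("cannot resolve incubation onset for bird ", track$bird_id[1],
           call. = FALSE)
    }
  }
  laying_onset <- nest$laying_onset
  if (is.null(laying_onset) || is.na(laying_onset)) {
    laying_onset <- detect_laying_onset(
      track, np, visit_radius = config$laying_visit_radius_m,
      incubation_onset = incubation_onset)
  }
  prenesting_start <- laying_onset - config$prenesting_days

  day <- fix_day(track$timestamp)
  phase <- rep("other", nrow(track))
  phase[day >= prenesting_start & day < laying_onset] <- "prenesting"
  phase[day >= laying_onset & day < incubation_onset] <- "laying"
  # incubation: consecutive all-within run starting at onset
  aw <- all_within_days(track, np, config$incubation_radius_m)
  inc_end <- incubation_onset
  while ((inc_end + 1L) %in% aw) inc_end <- inc_end + 1L
  phase[day >= incubation_onset & day <= inc_end] <- "incubation"

  dbl <- rep(NA_integer_, nrow(track))
  pre <- phase == "prenesting"
  dbl[pre] <- as.integer(laying_onset - day[pre])
  if (!any(pre)) {
    warning("track for bird ", track$bird_id[1],
            " covers no prenesting day", call. = FALSE)
  }
  structure(list(
    bird_id = track$bird_id[1],
    laying_onset = laying_onset,
    incubation_onset = incubation_onset,
    prenesting_start = prenesting_start,
    fixes = data.frame(timestamp = track$timestamp, day = day, phase = phase,
                       days_before_laying = dbl, stringsAsFactors = FALSE)
  ), class = "phase_labels")
}

#' Export phase labels as a per-day CSV-ready table
#'
#' @param phases a `phase_labels` object.
#' @return data.frame with `bird_id`, `date`, `phase`, `days_before_laying`.
#' @export
phase_table <- function(phases) {
  f <- phases$fixes
  agg <- unique(data.frame(bird_id = phases$bird_id, date = f$day,
                           phase = f$phase,
                           days_before_laying = f$days_before_laying,
                           stringsAsFactors = FALSE))
  agg[order(agg$date), , drop = FALSE]
}
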