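#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults encode the study design the pipeline implements: a 45-day
#' prenesting window, a 50-m all-fixes-within rule for incubation onset, a
#' 10-m GPS-accuracy exclusion for incubation distance summaries, fixed 100-
#' and 500-m nest buffers, subspecies-level mean incubation distances
#' (Rio Grande 70.82 m, Eastern 55.24 m), the 1-5 / 6-15 / 16-45
#' days-before-laying windows, and 50/75/95/99% kernel isopleths.
#'
#' @param prenesting_days days before laying onset that define prenesting.
#' @param incubation_radius_m radius (m) of the all-fixes-within nest buffer
#'   that marks incubation onset.
#' @param gps_exclusion_m fixes closer than this (m) to the nest are dropped
#'   from incubation-period distance summaries (GPS positional error).
#' @param fixed_buffer_radii_m radii (m) of the fixed nest buffers.
#' @param population_incubation_distance_m named vector of population mean
#'   incubation distances (m) per subspecies; used as the radius of the mean
#'   incubation circle buffer.
#' @param day_windows list of inclusive `c(lo, hi)` days-before-laying ranges.
#' @param kernel_levels isopleth probability levels, each in (0, 1).
#' @param schedule `"hourly"` (0600-2000 hourly plus midnight) or
#'   `"two_hour"` (0600-2000 at 2-h increments plus midnight).
#' @param incubation_min_run consecutive all-within days required to call
#'   incubation onset; 1 reproduces the literal single-day rule.
#' @param laying_visit_radius_m nest-visit radius (m) for laying detection;
#'   defaults to the incubation radius.
#' @param intersection_mode `"closed"` counts contained segments as
#'   intersections; `"boundary"` requires boundary contact.
#' @param mean_distance_mode `"fixes"` averages over all prenesting fixes;
#'   `"daily_means"` averages the per-day means.
#' @param contingency_unit `"segments"` or `"fixes"`: the unit counted in the
#'   windowed contingency tables.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(prenesting_days = 45L,
                            incubation_radius_m = 50,
                            gps_exclusion_m = 10,
                            fixed_buffer_radii_m = c(100, 500),
                            population_incubation_distance_m =
                              c(rio_grande = 70.82, eastern = 55.24),
                            day_windows = list(c(1L, 5L), c(6L, 15L), c(16L, 45L)),
                            kernel_levels = c(0.50, 0.75, 0.95, 0.99),
                            schedule = c("hourly", "two_hour"),
                            incubation_min_run = 2L,
                            laying_visit_radius_m = incubation_radius_m,
                            intersection_mode = c("closed", "boundary"),
                            mean_distance_mode = c("fixes", "daily_means"),
                            contingency_unit = c("segments", "fixes")) {
  cfg <- list(
    prenesting_days = as.integer(prenesting_days),
    incubation_radius_m = incubation_radius_m,
    gps_exclusion_m = gps_exclusion_m,
    fixed_buffer_radii_m = fixed_buffer_radii_m,
    population_incubation_distance_m = population_incubation_distance_m,
    day_windows = lapply(day_windows, function(w) as.integer(w)),
    kernel_levels = kernel_levels,
    schedule = match.arg(schedule),
    incubation_min_run = as.integer(incubation_min_run),
    laying_visit_radius_m = laying_visit_radius_m,
    intersection_mode = match.arg(intersection_mode),
    mean_distance_mode = match.arg(mean_distance_mode),
    contingency_unit = match.arg(contingency_unit)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$prenesting_days >= 1,
    cfg$incubation_radius_m > 0,
    cfg$gps_exclusion_m >= 0,
    all(cfg$fixed_buffer_radii_m > 0),
    all(cfg$population_incubation_distance_m > 0),
    all(cfg$kernel_levels > 0 & cfg$kernel_levels < 1),
    cfg$incubation_min_run >= 1,
    cfg$laying_visit_radius_m > 0
  )
  w <- cfg$day_windows
  if (length(w)) {
    covered <- unlist(lapply(w, function(r) seq(r[1], r[2])))
    if (anyDuplicated(covered)) stop("day_windows overlap", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a key=value configuration file
#'
#' Plain-text `key = value` lines (comments with `#`). Scalars are parsed as
#' numbers where possible; comma-separated values become vectors;
#' `day_windows` is given as `lo-hi` ranges separated by commas
#' (e.g. `day_windows = 1-5, 6-15, 16-45`). Unknown keys are an error; every
#' default of [analysis_config()] can be overridden.
#'
#' @param path config file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    args[[key]] <- parse_config_value(key, val)
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(analysis_config, args)
}

parse_config_value <- function(key, val) {
  if (key == "day_windows") {
    parts <- trimws(strsplit(val, ",")[[1]])
    return(lapply(parts, function(p) {
      r <- as.integer(trimws(strsplit(p, "-")[[1]]))
      if (length(r) != 2 || anyNA(r)) stop("bad day window: ", p, call. = FALSE)
      r
    }))
  }
  if (key %in% c("schedule", "intersection_mode", "mean_distance_mode",
                 "contingency_unit")) {
    return(val)
  }
  if (key == "population_incubation_distance_m") {
    parts <- trimws(strsplit(val, ",")[[1]])
    out <- numeric(0)
    for (p in parts) {
      kv <- trimws(strsplit(p, ":")[[1]])
      if (length(kv) != 2) stop("bad subspecies distance: ", p, call. = FALSE)
      out[kv[1]] <- as.numeric(kv[2])
    }
    return(out)
  }
  parts <- trimws(strsplit(val, ",")[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (anyNA(num)) stop("non-numeric value for ", key, ": ", val, call. = FALSE)
  num
}

#' Fix schedule clock hours
#'
#' @param schedule `"hourly"` or `"two_hour"`.
#' @return integer clock hours; midnight (0) is the roost fix.
#' @export
schedule_hours <- function(schedule = c("hourly", "two_hour")) {
  schedule <- match.arg(schedule)
  if (schedule == "hourly") c(0L, 6:20) else c(0L, seq(6L, 20L, by = 2L))
}

# Minimal structured logging: one line per stage with bird context.
nm_log <- function(stage, bird_id = NA, msg) {
  message(sprintf("[%s]%s %s", stage,
                  if (is.na(bird_id)) "" else sprintf(" bird=%s", bird_id),
                  msg))
}
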