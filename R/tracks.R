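#' GPS tracks and nest records
#'
#' A track is an ordered table of GPS fixes for one female: `bird_id`,
#' `timestamp` (POSIXct, study-local clock stored as UTC), planar `x`/`y` in
#' meters, and `is_roost` (the midnight roost fix). Nest attempts carry the
#' nest coordinates, laying/incubation onset dates, and a consumed fate label.
#'
#' @name tracks
NULL

#' Construct a track
#'
#' @param bird_id single identifier.
#' @param timestamp POSIXct vector.
#' @param x,y planar coordinates in meters.
#' @param schedule declared fix schedule (`"hourly"` or `"two_hour"`).
#' @return a `track`: a data.frame sorted by time with a `schedule` attribute.
#' @export
track <- function(bird_id, timestamp, x, y, schedule = "hourly") {
  stopifnot(length(bird_id) == 1, length(timestamp) == length(x),
            length(x) == length(y))
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  if (anyNA(timestamp)) stop("track has unparseable timestamps", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("track coordinates must be finite", call. = FALSE)
  }
  ord <- order(timestamp)
  timestamp <- timestamp[ord]; x <- x[ord]; y <- y[ord]
  if (anyDuplicated(timestamp)) {
    stop("duplicate timestamps in track for bird ", bird_id, call. = FALSE)
  }
  out <- data.frame(
    bird_id = as.character(bird_id),
    timestamp = timestamp,
    x = x, y = y,
    is_roost = as.POSIXlt(timestamp, tz = "UTC")$hour == 0L,
    stringsAsFactors = FALSE
  )
  attr(out, "schedule") <- schedule
  class(out) <- c("track", "data.frame")
  out
}

# Element-wise ISO-8601 parsing: rows fail individually, not collectively.
parse_timestamps <- function(v) {
  v <- as.character(v)
  out <- as.POSIXct(strptime(v, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    na <- is.na(out)
    if (!any(na)) break
    out[na] <- as.POSIXct(strptime(v[na], fmt, tz = "UTC"))
  }
  out
}

#' Calendar day of a fix
#'
#' The midnight roost fix closes the preceding evening: its day is the
#' calendar day before its timestamp's date. All other fixes belong to their
#' timestamp's date.
#'
#' @param timestamp POSIXct vector.
#' @return Date vector.
#' @export
fix_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  d <- as.Date(timestamp, tz = "UTC")
  mid <- lt$hour == 0L & lt$min == 0L & lt$sec == 0
  d[mid] <- d[mid] - 1L
  d
}

#' Read a GPS fix table into per-bird tracks
#'
#' Delimited text with a header. The default column mapping matches the
#' package's own dialect (`bird_id`, `timestamp` ISO-8601, `x_m`, `y_m`);
#' pass `schema` to remap. Malformed rows (unparseable timestamp, non-finite
#' coordinate, duplicate timestamp within a bird) are dropped and reported
#' with line numbers in the `errors` attribute.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical names
#'   (`bird_id`, `timestamp`, `x`, `y`) to file column names.
#' @param sep field delimiter.
#' @param schedule declared schedule attached to each track.
#' @return named list of `track` objects; attribute `errors` is a data.frame
#'   with `line` and `reason` for each rejected row.
#' @export
read_fixes <- function(path,
                       schema = c(bird_id = "bird_id", timestamp = "timestamp",
                                  x = "x_m", y = "y_m"),
                       sep = ",", schedule = "hourly") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols)) {
    stop("fix table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bird <- raw[[schema[["bird_id"]]]]
  ts <- parse_timestamps(raw[[schema[["timestamp"]]]])
  x <- suppressWarnings(as.numeric(raw[[schema[["x"]]]]))
  y <- suppressWarnings(as.numeric(raw[[schema[["y"]]]]))
  line <- seq_len(nrow(raw)) + 1L # header is line 1

  bad_ts <- is.na(ts)
  bad_xy <- !is.finite(x) | !is.finite(y)
  errors <- data.frame(line = integer(0), reason = character(0),
                       stringsAsFactors = FALSE)
  if (any(bad_ts)) {
    errors <- rbind(errors, data.frame(line = line[bad_ts],
                                       reason = "unparseable timestamp"))
  }
  if (any(bad_xy & !bad_ts)) {
    errors <- rbind(errors, data.frame(line = line[bad_xy & !bad_ts],
                                       reason = "non-finite coordinate"))
  }
  keep <- !bad_ts & !bad_xy
  bird <- bird[keep]; ts <- ts[keep]; x <- x[keep]; y <- y[keep]
  line <- line[keep]

  tracks <- list()
  for (b in unique(bird)) {
    i <- which(bird == b)
    i <- i[order(ts[i])]
    dup <- duplicated(ts[i])
    if (any(dup)) {
      errors <- rbind(errors, data.frame(line = line[i][dup],
                                         reason = "duplicate timestamp"))
      i <- i[!dup]
    }
    tracks[[b]] <- track(b, ts[i], x[i], y[i], schedule = schedule)
  }
  if (nrow(errors)) {
    nm_log("read_fixes", msg = sprintf("%d malformed row(s) rejected (lines %s)",
                                       nrow(errors),
                                       paste(utils::head(errors$line, 10),
                                             collapse = ",")))
  }
  attr(tracks, "errors") <- errors
  tracks
}

#' Write tracks back to the fix-table dialect
#'
#' Round-trips with [read_fixes()]: timestamps to the second, coordinates to
#' 1e-6 m.
#'
#' @param tracks list of `track` objects (or a single track).
#' @param path output file path.
#' @export
write_fixes <- function(tracks, path) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  all <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(bird_id = tr$bird_id,
               timestamp = format(tr$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               x_m = sprintf("%.6f", tr$x),
               y_m = sprintf("%.6f", tr$y),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(all, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a nest-attempt table
#'
#' CSV with columns `bird_id`, `attempt`, `nest_x_m`, `nest_y_m`,
#' `laying_onset`, `incubation_onset`, `fate`. Onset dates are ISO dates and
#' may be empty (unknown, to be detected from movement). Attempts are grouped
#' by bird and ordered by laying onset; `attempt_index` is (re)assigned by
#' that order.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return data.frame of class `nest_attempts`.
#' @export
read_nests <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("bird_id", "nest_x_m", "nest_y_m", "laying_onset",
            "incubation_onset", "fate")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("nest table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fate <- as.character(raw$fate)
  bad_fate <- !(fate %in% c("success", "fail", "unknown"))
  if (any(bad_fate)) {
    stop("unknown fate value(s): ",
         paste(unique(fate[bad_fate]), collapse = ", "), call. = FALSE)
  }
  parse_date <- function(v) {
    v <- as.character(v)
    v[!nzchar(v) | is.na(v)] <- NA
    as.Date(v)
  }
  out <- data.frame(
    bird_id = as.character(raw$bird_id),
    nest_x = as.numeric(raw$nest_x_m),
    nest_y = as.numeric(raw$nest_y_m),
    laying_onset = parse_date(raw$laying_onset),
    incubation_onset = parse_date(raw$incubation_onset),
    fate = fate,
    stringsAsFactors = FALSE
  )
  both <- !is.na(out$laying_onset) & !is.na(out$incubation_onset)
  bad <- both & out$incubation_onset < out$laying_onset
  if (any(bad)) {
    stop("incubation onset precedes laying onset for bird(s): ",
         paste(unique(out$bird_id[bad]), collapse = ", "), call. = FALSE)
  }
  out <- out[order(out$bird_id, out$laying_onset), , drop = FALSE]
  out$attempt_index <- stats::ave(seq_len(nrow(out)), out$bird_id,
                                  FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("nest_attempts", "data.frame")
  out
}

#' Write nest attempts in the package dialect
#'
#' @param nests a `nest_attempts` data.frame.
#' @param path output file path.
#' @export
write_nests <- function(nests, path) {
  fmt_date <- function(d) ifelse(is.na(d), "", format(d))
  out <- data.frame(bird_id = nests$bird_id,
                    attempt = nests$attempt_index,
                    nest_x_m = sprintf("%.6f", nests$nest_x),
                    nest_y_m = sprintf("%.6f", nests$nest_y),
                    laying_onset = fmt_date(nests$laying_onset),
                    incubation_onset = fmt_date(nests$incubation_onset),
                    fate = nests$fate,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Schedule coverage report
#'
#' Compares a track against its declared fix schedule day by day. A day is
#' complete when every expected clock hour produced a fix (the midnight fix
#' counts toward the day it closes), partial when some did, and fixes at
#' unexpected hours are tallied separately.
#'
#' @param track a `track`.
#' @param expected integer clock hours expected each day (see
#'   [schedule_hours()]); may be empty.
#' @return data.frame with one row per tracked day: `day`, `n_expected`,
#'   `n_observed`, `n_unexpected`, `status` (`"full"`/`"partial"`);
#'   attribute `proportion_complete` is the share of full days.
#' @export
validate_schedule <- function(track, expected = schedule_hours("hourly")) {
  if (!nrow(track)) stop("track is empty", call. = FALSE)
  expected <- unique(as.integer(expected))
  day <- fix_day(track$timestamp)
  hour <- as.POSIXlt(track$timestamp, tz = "UTC")$hour
  days <- sort(unique(day))
  rep <- do.call(rbind, lapply(days, function(d) {
    h <- hour[day == d]
    data.frame(day = d,
               n_expected = length(expected),
               n_observed = length(intersect(unique(h), expected)),
               n_unexpected = sum(!h %in% expected))
  }))
  rep$status <- ifelse(rep$n_observed == rep$n_expected & rep$n_expected > 0,
                       "full", "partial")
  attr(rep, "proportion_complete") <- mean(rep$status == "full")
  rep
}
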