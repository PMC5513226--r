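#' Nest-associated buffers and segment classification
#'
#' Five individual-specific regions around each nest: a circle with the
#' equivalent radius of the 95% incubation-kernel area, the 75% incubation
#' kernel polygon itself, a circle at the population mean incubation
#' distance, and fixed 100- and 500-m circles. Every hourly prenesting path
#' segment is classified 0/1 against each region.
#'
#' @name buffer_intersection
NULL

#' Equivalent radius of a circle of given area
#'
#' @param area area in square meters.
#' @return radius in meters, `sqrt(area / pi)`.
#' @export
equivalent_radius <- function(area) {
  if (!is.numeric(area) || any(area <= 0)) {
    stop("area must be positive", call. = FALSE)
  }
  sqrt(area / pi)
}

#' Build the nest-associated buffer set
#'
#' @param nest numeric `c(x, y)` in meters.
#' @param incubation_ud optional `ud_grid` fitted to the incubation fixes;
#'   when absent only the fixed-radius and mean-distance circles are built
#'   (logged).
#' @param subspecies name matching `config$population_incubation_distance_m`.
#' @param config an [analysis_config()].
#' @param bird_id identifier for logging.
#' @return a `buffer_set`: list with `nest` and `regions`, each region either
#'   `list(type = "circle", center, r)` or `list(type = "polygon", iso)`.
#' @export
build_buffers <- function(nest, incubation_ud = NULL,
                          subspecies = "rio_grande",
                          config = analysis_config(), bird_id = NA) {
  regions <- list()
  if (!is.null(incubation_ud)) {
    iso95 <- extract_isopleth(incubation_ud, 0.95)
    regions$kernel95_equiv_circle <- list(
      type = "circle", center = nest,
      r = equivalent_radius(iso95$area_ha * 1e4))
    regions$kernel75_polygon <- list(
      type = "polygon", iso = extract_isopleth(incubation_ud, 0.75))
  } else {
    nm_log("buffers", bird_id,
           "no incubation UD; kernel-based regions omitted")
  }
  if (!subspecies %in% names(config$population_incubation_distance_m)) {
    stop("unknown subspecies: ", subspecies, call. = FALSE)
  }
  md <- config$population_incubation_distance_m[[subspecies]]
  regions$mean_incubation_circle <- list(type = "circle", center = nest, r = md)
  for (r in config$fixed_buffer_radii_m) {
    regions[[sprintf("fixed_%dm", as.integer(r))]] <-
      list(type = "circle", center = nest, r = r)
  }
  structure(list(bird_id = bird_id, nest = nest, regions = regions),
            class = "buffer_set")
}

# One segment vs one region under the configured semantics.
segment_hits_region <- function(x1, y1, x2, y2, region, mode = "closed") {
  if (x1 == x2 && y1 == y2) {
    # zero-length: classify by point containment (closed) / boundary contact
    if (region$type == "circle") {
      d <- sqrt((x1 - region$center[1])^2 + (y1 - region$center[2])^2)
      return(if (mode == "closed") d <= region$r else d == region$r)
    }
    inside <- point_in_rings(x1, y1, region$iso$rings)
    return(if (mode == "closed") inside else FALSE)
  }
  if (region$type == "circle") {
    segment_intersects_circle(x1, y1, x2, y2, region$center[1],
                              region$center[2], region$r, mode = mode)
  } else {
    segment_intersects_polygon(x1, y1, x2, y2, region$iso$rings, mode = mode)
  }
}

#' Classify prenesting path segments against the buffer set
#'
#' Segments connect consecutive fixes that are both tagged prenesting; each
#' segment carries the days-before-laying index of its starting fix. A flag
#' of 1 means the closed straight segment touches the closed region
#' (crossing or containment) under the default `"closed"` semantics, or
#' touches the region boundary under `"boundary"`.
#'
#' @param track a `track`.
#' @param phases matching `phase_labels`.
#' @param buffers a `buffer_set`.
#' @param mode `"closed"` or `"boundary"`.
#' @return data.frame of segment records: `bird_id`, `t_start`, `t_end`,
#'   `x1`, `y1`, `x2`, `y2`, `day_before_laying`, one 0/1 column per region.
#' @export
classify_segments <- function(track, phases, buffers,
                              mode = c("closed", "boundary")) {
  mode <- match.arg(mode)
  f <- phases$fixes
  n <- nrow(track)
  if (n < 2) {
    return(empty_segment_records(names(buffers$regions)))
  }
  i <- seq_len(n - 1L)
  both_pre <- f$phase[i] == "prenesting" & f$phase[i + 1L] == "prenesting"
  i <- i[both_pre]
  rec <- data.frame(
    bird_id = rep(track$bird_id[1], length(i)),
    t_start = track$timestamp[i],
    t_end = track$timestamp[i + 1L],
    x1 = track$x[i], y1 = track$y[i],
    x2 = track$x[i + 1L], y2 = track$y[i + 1L],
    day_before_laying = f$days_before_laying[i],
    stringsAsFactors = FALSE
  )
  for (nm in names(buffers$regions)) {
    region <- buffers$regions[[nm]]
    if (region$type == "circle") {
      # vectorised over segments: min/max distance from center to each segment
      dmin <- seg_dmin_vec(region$center[1], region$center[2],
                           rec$x1, rec$y1, rec$x2, rec$y2)
      if (mode == "closed") {
        rec[[nm]] <- as.integer(dmin <= region$r)
      } else {
        dmax <- pmax(sqrt((rec$x1 - region$center[1])^2 +
                            (rec$y1 - region$center[2])^2),
                     sqrt((rec$x2 - region$center[1])^2 +
                            (rec$y2 - region$center[2])^2))
        rec[[nm]] <- as.integer(dmin <= region$r & dmax >= region$r)
      }
    } else {
      rec[[nm]] <- vapply(seq_len(nrow(rec)), function(k) {
        as.integer(segment_hits_region(rec$x1[k], rec$y1[k], rec$x2[k],
                                       rec$y2[k], region, mode = mode))
      }, integer(1))
    }
  }
  rec
}

empty_segment_records <- function(region_names) {
  rec <- data.frame(bird_id = character(0),
                    t_start = as.POSIXct(character(0), tz = "UTC"),
                    t_end = as.POSIXct(character(0), tz = "UTC"),
                    x1 = numeric(0), y1 = numeric(0),
                    x2 = numeric(0), y2 = numeric(0),
                    day_before_laying = integer(0))
  for (nm in region_names) rec[[nm]] <- integer(0)
  rec
}

#' Per-day intersection frequencies
#'
#' For each days-before-laying value and region: the proportion of segments
#' flagged 1, with segment counts. Days with no segments carry `NA`
#' frequency.
#'
#' @param records segment records from [classify_segments()] (rows may pool
#'   several birds).
#' @param regions region column names; default: every 0/1 column present.
#' @param days integer days to report (default 1..45).
#' @return data.frame: `day_before_laying`, `region`, `n_segments`, `n_hits`,
#'   `frequency`.
#' @export
intersection_frequencies <- function(records, regions = NULL,
                                     days = 1:45) {
  if (!nrow(records)) stop("no segment records", call. = FALSE)
  if (is.null(regions)) {
    fixed <- c("bird_id", "t_start", "t_end", "x1", "y1", "x2", "y2",
               "day_before_laying")
    regions <- setdiff(names(records), fixed)
  }
  out <- expand.grid(day_before_laying = days, region = regions,
                     stringsAsFactors = FALSE)
  out$n_segments <- 0L
  out$n_hits <- 0L
  for (r in regions) {
    for (d in days) {
      sel <- records$day_before_laying == d
      k <- out$region == r & out$day_before_laying == d
      out$n_segments[k] <- sum(sel)
      out$n_hits[k] <- sum(records[[r]][sel])
    }
  }
  out$frequency <- ifelse(out$n_segments > 0, out$n_hits / out$n_segments,
                          NA_real_)
  out
}
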