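#' End-to-end pipeline and reporting
#'
#' Drives every stage for a population of females: phase delineation,
#' prenesting dynamic-bridge ranges and nest membership, incubation kernels
#' and nest-associated buffers, per-bird distance summaries, segment
#' classification, and the pooled logistic / odds-ratio inference. Output
#' mirrors the study's reporting surfaces: a per-bird summary table, range
#' membership proportions, day-closest window counts, per-day intersection
#' frequencies, logistic fits, and windowed odds ratios.
#'
#' @name reporting
NULL

RESULTS_SCHEMA_VERSION <- "1"

#' Run the full pipeline
#'
#' @param tracks named list of `track` objects, or a fix-table path.
#' @param nests a `nest_attempts` table, or a nest-table path.
#' @param config an [analysis_config()].
#' @param subspecies population label selecting the mean incubation distance.
#' @param fit_ranges fit the prenesting dynamic bridge and incubation kernel
#'   (the slow stages); when `FALSE`, membership and kernel buffers are
#'   skipped and classification uses the distance/fixed circles only.
#' @param outdir optional directory for the machine-readable results CSVs.
#' @return a results bundle: list with `summary` (per-bird table),
#'   `membership`, `membership_proportions`, `windows` (day-closest bins),
#'   `segments`, `frequencies`, `logistic` (per-region fits), `odds`
#'   (windowed odds ratios), `errors` (per-bird failures), `schema_version`.
#' @export
run_pipeline <- function(tracks, nests, config = analysis_config(),
                         subspecies = "rio_grande", fit_ranges = TRUE,
                         outdir = NULL) {
  if (is.character(tracks)) tracks <- read_fixes(tracks)
  if (is.character(nests)) nests <- read_nests(nests)

  summary_rows <- list()
  membership_rows <- list()
  segment_tables <- list()
  errors <- list()

  for (bird in names(tracks)) {
    res <- tryCatch({
      nest_rows <- nests[nests$bird_id == bird, , drop = FALSE]
      if (!nrow(nest_rows)) stop("no nest record")
      nest <- nest_rows[1, , drop = FALSE]
      np <- c(nest$nest_x, nest$nest_y)
      tr <- tracks[[bird]]

      phases <- delineate_phases(tr, nest, config)
      dists <- fix_nest_distances(tr, np, phases,
                                  exclusion = config$gps_exclusion_m,
                                  apply_exclusion = FALSE)
      summ <- summarize_prenesting(dists, mean_mode = config$mean_distance_mode)
      summ <- cbind(data.frame(band_id = bird, fate = nest$fate,
                               stringsAsFactors = FALSE), summ)

      inc_ud <- NULL
      member <- NULL
      if (fit_ranges) {
        pre <- tr[phases$fixes$phase == "prenesting", , drop = FALSE]
        if (nrow(pre) >= 2) {
          ud <- fit_brownian_bridge(pre, location_error = config$gps_exclusion_m)
          isos <- lapply(c(0.50, 0.95, 0.99), function(l) extract_isopleth(ud, l))
          names(isos) <- c("50", "95", "99")
          member <- nest_range_membership(np, isos)
          member$bird_id <- bird
          summ$in_50 <- ifelse(member$inside[member$level == "50"], "In", "Out")
          summ$area50_ha <- member$area_ha[member$level == "50"]
          summ$in_95 <- ifelse(member$inside[member$level == "95"], "In", "Out")
          summ$area95_ha <- member$area_ha[member$level == "95"]
          summ$in_99 <- ifelse(member$inside[member$level == "99"], "In", "Out")
          summ$area99_ha <- member$area_ha[member$level == "99"]
        }
        inc <- tr[phases$fixes$phase == "incubation", , drop = FALSE]
        if (nrow(inc) >= 5) {
          inc_ud <- tryCatch(fit_fixed_kernel(inc[, c("x", "y")]),
                             error = function(e) NULL)
        }
      }
      buffers <- build_buffers(np, incubation_ud = inc_ud,
                               subspecies = subspecies, config = config,
                               bird_id = bird)
      segs <- classify_segments(tr, phases, buffers,
                                mode = config$intersection_mode)
      list(summary = summ, membership = member, segments = segs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nm_log("pipeline", bird, paste("skipped:", conditionMessage(res)))
      errors[[bird]] <- conditionMessage(res)
      next
    }
    summary_rows[[bird]] <- res$summary
    if (!is.null(res$membership)) membership_rows[[bird]] <- res$membership
    segment_tables[[bird]] <- res$segments
  }

  if (!length(summary_rows)) stop("pipeline produced no birds", call. = FALSE)
  summary <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  membership <- if (length(membership_rows)) {
    do.call(rbind, c(membership_rows, list(make.row.names = FALSE)))
  } else NULL

  # region set may differ across birds (kernel regions need an incubation UD)
  region_union <- unique(unlist(lapply(segment_tables, function(s) {
    setdiff(names(s), c("bird_id", "t_start", "t_end", "x1", "y1", "x2", "y2",
                        "day_before_laying"))
  })))
  segments <- do.call(rbind, c(lapply(segment_tables, function(s) {
    for (r in setdiff(region_union, names(s))) s[[r]] <- NA_integer_
    s
  }), list(make.row.names = FALSE)))

  windows <- bin_day_closest(summary$day_closest, config$day_windows,
                             bird_id = summary$band_id)

  logistic <- list()
  for (r in region_union) {
    ok <- !is.na(segments[[r]])
    logistic[[r]] <- tryCatch(
      fit_intersection_model(segments[ok, , drop = FALSE], r),
      error = function(e) conditionMessage(e))
  }

  odds <- list()
  w <- config$day_windows
  if (length(w) >= 3 && "mean_incubation_circle" %in% region_union) {
    odds$w1_vs_w2 <- tryCatch(
      window_odds_ratio(segments, "mean_incubation_circle", w[[1]], w[[2]]),
      error = function(e) conditionMessage(e))
    odds$w2_vs_w3 <- tryCatch(
      window_odds_ratio(segments, "mean_incubation_circle", w[[2]], w[[3]]),
      error = function(e) conditionMessage(e))
  }

  frequencies <- intersection_frequencies(segments, regions = region_union,
                                          days = 1:config$prenesting_days)

  bundle <- list(summary = summary, membership = membership,
                 membership_proportions =
                   if (!is.null(membership)) membership_proportions(membership)
                 else NULL,
                 windows = windows, segments = segments,
                 frequencies = frequencies, logistic = logistic, odds = odds,
                 errors = errors, schema_version = RESULTS_SCHEMA_VERSION)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  writeLines(paste0("schema_version,", bundle$schema_version),
             file.path(outdir, "VERSION"))
  utils::write.csv(bundle$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$membership)) {
    utils::write.csv(bundle$membership, file.path(outdir, "membership.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$windows, file.path(outdir, "day_closest_windows.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$segments, file.path(outdir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$frequencies, file.path(outdir, "frequencies.csv"),
                   row.names = FALSE)
  lf <- do.call(rbind, lapply(names(bundle$logistic), function(r) {
    f <- bundle$logistic[[r]]
    if (!inherits(f, "logistic_fit")) {
      return(data.frame(region = r, b0 = NA, b1 = NA, se_b0 = NA, se_b1 = NA,
                        p_b1 = NA, n = NA, note = as.character(f)))
    }
    data.frame(region = r, b0 = f$coef[["b0"]], b1 = f$coef[["b1"]],
               se_b0 = f$se[["b0"]], se_b1 = f$se[["b1"]], p_b1 = f$p[["b1"]],
               n = f$n, note = "")
  }))
  if (!is.null(lf)) {
    utils::write.csv(lf, file.path(outdir, "logistic.csv"), row.names = FALSE)
  }
  orf <- do.call(rbind, lapply(names(bundle$odds), function(nm) {
    o <- bundle$odds[[nm]]
    if (!inherits(o, "odds_ratio")) {
      return(data.frame(comparison = nm, a = NA, b = NA, c = NA, d = NA,
                        or = NA, ci_low = NA, ci_high = NA, corrected = NA,
                        note = as.character(o)))
    }
    data.frame(comparison = nm, a = o$counts[["a"]], b = o$counts[["b"]],
               c = o$counts[["c"]], d = o$counts[["d"]], or = o$or,
               ci_low = o$ci_low, ci_high = o$ci_high,
               corrected = o$corrected, note = "")
  }))
  if (!is.null(orf)) {
    utils::write.csv(orf, file.path(outdir, "odds_ratios.csv"),
                     row.names = FALSE)
  }
  invisible(outdir)
}

#' Aggregate a per-bird summary table into the footer row
#'
#' Means and SDs over birds of prenesting days, per-bird mean distance and
#' per-bird minimum distance (censored minima excluded, with a count),
#' percent of nests outside each isopleth level, day-closest window counts
#' and the mean day-closest. Values are unrounded; rounding belongs to
#' presentation.
#'
#' @param summary per-bird table with columns `days_prenest`, `mean_dist_m`,
#'   `min_dist_m`, `day_closest`, optional `min_dist_censored` and
#'   `nest_in_50`/`nest_in_95`/`nest_in_99` (or `in_50`...) columns.
#' @param windows day-closest windows.
#' @return list of aggregates.
#' @export
table_aggregates <- function(summary,
                             windows = list(c(1L, 5L), c(6L, 15L), c(16L, 45L))) {
  stopifnot(nrow(summary) >= 1)
  cens <- summary$min_dist_censored
  if (is.null(cens)) cens <- rep(FALSE, nrow(summary))
  minv <- summary$min_dist_m[!cens]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- list(
    n = nrow(summary),
    mean_days_prenest = mean(summary$days_prenest),
    sd_days_prenest = sd0(summary$days_prenest),
    mean_dist_m = mean(summary$mean_dist_m),
    sd_dist_m = sd0(summary$mean_dist_m),
    mean_min_dist_m = mean(minv),
    sd_min_dist_m = sd0(minv),
    n_censored_excluded = sum(cens)
  )
  for (lv in c("50", "95", "99")) {
    col <- summary[[paste0("nest_in_", lv)]] %||% summary[[paste0("in_", lv)]]
    if (!is.null(col)) {
      out[[paste0("pct_out_", lv)]] <- 100 * mean(col == "Out")
    }
  }
  bins <- bin_day_closest(summary$day_closest, windows,
                          bird_id = summary$band_id)
  out$window_counts <- stats::setNames(bins$count, bins$window)
  out$mean_day_closest <- attr(bins, "mean_day_closest")
  out
}

#' Read a published per-bird prenesting summary table
#'
#' The package ships the published per-bird prenesting movement summaries
#' for the two monitored populations (21 Rio Grande and 23 Eastern wild
#' turkey females) as plain CSV; left-censored minima are stored as the
#' bound with `min_dist_censored = TRUE`.
#'
#' @param which `"rio_grande"` or `"eastern"`, or a file path.
#' @return data.frame in the summary-table schema.
#' @export
read_published_summary <- function(which = c("rio_grande", "eastern")) {
  path <- if (file.exists(which[1])) {
    which[1]
  } else {
    which <- match.arg(which)
    system.file("extdata", paste0(which, "_prenesting_summary.csv"),
                package = "nestmove", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-day intersection frequency panel
#'
#' Relative frequency of buffer interaction by days before laying (axis runs
#' 45 down to 1), one line per region.
#'
#' @param frequencies output of [intersection_frequencies()].
#' @param regions subset of regions to draw (default all present).
#' @return a ggplot object.
#' @export
plot_intersection_frequencies <- function(frequencies, regions = NULL) {
  if (!is.null(regions)) {
    frequencies <- frequencies[frequencies$region %in% regions, , drop = FALSE]
  }
  ggplot2::ggplot(frequencies[!is.na(frequencies$frequency), ],
                  ggplot2::aes(x = day_before_laying, y = frequency,
                               colour = region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Days before laying", y = "Relative frequency",
                  colour = "Buffer") +
    ggplot2::theme_minimal()
}

#' Fitted intersection-probability panel
#'
#' @param fits named list of `logistic_fit` objects.
#' @param days days-before-laying range to draw.
#' @return a ggplot object.
#' @export
plot_probability_curves <- function(fits, days = 1:45) {
  fits <- Filter(function(f) inherits(f, "logistic_fit"), fits)
  df <- do.call(rbind, lapply(names(fits), function(r) {
    data.frame(region = r, day_before_laying = days,
               probability = predict_probability(fits[[r]], days))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = day_before_laying, y = probability,
                                   colour = region)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Days before laying", y = "P(intersection)",
                  colour = "Buffer") +
    ggplot2::theme_minimal()
}
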