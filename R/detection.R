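#' Local growth reductions relative to the regional reference (Criterion 1)
#'
#' Standardizes the difference between a site chronology and the
#' leave-one-out regional chronology over the reference period and flags
#' years falling more than `threshold` SD below it (strictly; a departure
#' of exactly -1.5 SD is not flagged).
#'
#' @param site_chron A `site_chronology`.
#' @param regional_chron A `regional_chronology` built excluding the site.
#' @param threshold SD threshold. Default 1.5.
#' @param ref_period Standardization year range (default 1950-1991).
#' @return Data frame with `year`, `z` (the standardized departure) and
#'   `flag`.
#' @export
local_growth_reductions <- function(site_chron, regional_chron,
                                    threshold = 1.5,
                                    ref_period = c(1950L, 1991L)) {
  common <- intersect(site_chron$years[is.finite(site_chron$index)],
                      regional_chron$years[is.finite(regional_chron$index)])
  if (length(common) == 0L)
    stop("site and regional chronologies do not overlap")
  d <- site_chron$index[match(common, site_chron$years)] -
    regional_chron$index[match(common, regional_chron$years)]
  ref <- common >= ref_period[1] & common <= ref_period[2]
  if (sum(ref) < 5L)
    stop("fewer than 5 overlapping reference years for site '",
         site_chron$site_code, "'")
  sdv <- sd(d[ref])
  if (sdv == 0)
    stop("zero reference-period SD of the site-regional difference for '",
         site_chron$site_code, "'")
  z <- (d - mean(d[ref])) / sdv
  data.frame(year = common, z = z, flag = z < -threshold)
}

#' Cropper values (windowed normalized growth deviations)
#'
#' Standardizes each series value within a moving window (default 5
#' years) centred on the year: `c_t = (x_t - mean(window)) / sd(window)`.
#' Edge years use the window truncated to the series' span; windows with
#' zero SD yield 0.
#'
#' @param mat Year x series matrix of ring-width indices (e.g. the
#'   `series_indices` of a site chronology).
#' @param window Window length in years (odd). Default 5.
#' @return Matrix of Cropper values, same shape as `mat`.
#' @export
cropper_values <- function(mat, window = 5L) {
  mat <- as.matrix(mat)
  half <- window %/% 2L
  out <- mat * NA_real_
  for (j in seq_len(ncol(mat))) {
    sup <- which(is.finite(mat[, j]))
    if (length(sup) == 0L) next
    for (t in sup) {
      win <- max(min(sup), t - half):min(max(sup), t + half)
      win <- win[is.finite(mat[win, j])]
      w <- mat[win, j]
      if (length(w) < 2L) { out[t, j] <- 0; next }
      s <- sd(w)
      out[t, j] <- if (s == 0) 0 else (mat[t, j] - mean(w)) / s
    }
  }
  out
}

#' Negative pointer years (Additional Criterion 1)
#'
#' A year is a negative pointer year when, strictly, more than
#' `proportion` of the series present show a Cropper value below
#' `-threshold` (strictly). With fewer than `min_series` series present
#' the criterion is not evaluable for that year (`evaluable = FALSE`,
#' `pointer = NA`), which is distinct from a definite `FALSE`.
#'
#' @param cropper Matrix of [cropper_values()].
#' @param threshold Cropper threshold. Default 0.5.
#' @param proportion Required proportion of flagged series. Default 0.5.
#' @param min_series Minimum series present. Default 5.
#' @return Data frame with `year`, `n`, `frac`, `pointer`, `evaluable`.
#' @export
pointer_years <- function(cropper, threshold = 0.5, proportion = 0.5,
                          min_series = 5L) {
  years <- as.integer(rownames(cropper))
  n <- rowSums(is.finite(cropper))
  neg <- rowSums(cropper < -threshold, na.rm = TRUE)
  frac <- ifelse(n > 0L, neg / n, NA_real_)
  evaluable <- n >= min_series
  data.frame(year = years, n = n, frac = frac,
             pointer = ifelse(evaluable, frac > proportion, NA),
             evaluable = evaluable)
}

#' Control-species growth reductions (Criterion 3)
#'
#' Standardizes the evergreen-control regional chronology over the
#' reference period (default 1950-2003) and marks years falling more than
#' `threshold` SD below its mean (strictly) as control reductions --
#' evidence that a shared constraint (drought, volcanic or other regional
#' disturbance) rather than a spring frost depressed growth.
#'
#' @param control_chron A `regional_chronology` of the control network.
#' @param threshold SD threshold. Default 1.5.
#' @param ref_period Standardization year range.
#' @return Data frame with `year`, `z` and `reduced`.
#' @export
control_reduction_years <- function(control_chron, threshold = 1.5,
                                    ref_period = c(1950L, 2003L)) {
  years <- control_chron$years[is.finite(control_chron$index)]
  x <- control_chron$index[match(years, control_chron$years)]
  ref <- years >= ref_period[1] & years <= ref_period[2]
  if (sum(ref) < 5L)
    stop("fewer than 5 reference years in the control chronology")
  sdv <- sd(x[ref])
  if (sdv == 0) stop("zero reference-period SD of the control chronology")
  z <- (x - mean(x[ref])) / sdv
  data.frame(year = years, z = z, reduced = z < -threshold)
}

#' Integrate the detection criteria into the confidence scale
#'
#' Candidate events are the site-years passing all three eliminatory
#' gates: a local growth reduction (C1), anomalously low window minimum
#' temperatures (C2), and no documented insect outbreak (C5). Candidates
#' are then assigned one of four confidence levels:
#'
#' * `validated`: control species unaffected (C3), no adverse climate
#'   deviation (C4), at least one additional criterion met (negative
#'   pointer year A1 or high frost-risk index A2), and the year appears in
#'   the documented frost records;
#' * `low`: as above without documentation;
#' * `medium`: an additional criterion met but C3 or C4 failed (the
#'   failure is annotated as a co-driver, e.g. `"EG"` for a control
#'   reduction or `"high PDec"`);
#' * `high`: the growth reduction was not strong enough to register as a
#'   pointer year and the frost-risk index was not high.
#'
#' `require_additional`, `c3_downgrades` and `c4_downgrades` in the
#' configuration relax the lattice; with the downgrades off, failed C3/C4
#' only annotate, reproducing the looser published usage.
#'
#' @param cm Criterion matrix: a data frame with one row per candidate
#'   site-year and columns `region`, `site`, `year`, logical `c1, c2, c3,
#'   c4, c5, a1, a2` (NA = not evaluable), supporting values `c1_z, c2_z,
#'   win_min_1, win_min_2, a1_frac, a2_z` and `c4_notes`.
#' @param documented Named list (region -> years) of documented frost
#'   records.
#' @param require_additional,c3_downgrades,c4_downgrades See
#'   [detection_config()].
#' @return A `frost_event_table` data frame (rows only where C1, C2 and
#'   C5 all hold).
#' @export
integrate_criteria <- function(cm, documented = list(),
                               require_additional = TRUE,
                               c3_downgrades = TRUE,
                               c4_downgrades = TRUE) {
  gate <- vapply(seq_len(nrow(cm)), function(i)
    isTRUE(cm$c1[i]) && isTRUE(cm$c2[i]) && isTRUE(cm$c5[i]), logical(1))
  cand <- cm[gate, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    x <- cand[i, ]
    a <- isTRUE(x$a1) || isTRUE(x$a2)
    c3_ok <- !isFALSE(x$c3)       # NA (not evaluable) cannot contradict
    c4_ok <- !isFALSE(x$c4)
    ok34 <- (c3_ok || !c3_downgrades) && (c4_ok || !c4_downgrades)
    a_req <- if (require_additional) a else TRUE
    docd <- x$year %in% (documented[[x$region]] %||% integer())
    level <-
      if (ok34 && a_req && docd) "validated"
      else if (ok34 && a_req) "low"
      else if (a && !ok34) "medium"
      else "high"
    drivers <- character()
    if (isFALSE(x$c3)) drivers <- c(drivers, "EG")
    if (isFALSE(x$c4) && nzchar(x$c4_notes %||% ""))
      drivers <- c(drivers, x$c4_notes)
    data.frame(region = x$region, site = x$site, year = x$year,
               confidence = level,
               win_min_1 = x$win_min_1 %||% NA_real_,
               win_min_2 = x$win_min_2 %||% NA_real_,
               co_drivers = paste(drivers, collapse = "; "),
               pinpoint_doy = NA_integer_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), site = character(), year = integer(),
               confidence = character(), win_min_1 = numeric(),
               win_min_2 = numeric(), co_drivers = character(),
               pinpoint_doy = integer())
  out$confidence <- factor(out$confidence, levels = confidence_levels())
  out <- out[order(out$region, out$site, out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("frost_event_table", "data.frame")
  out
}

#' @export
print.frost_event_table <- function(x, ...) {
  cat("Reconstructed spring-frost events:", nrow(x), "site-year row(s)\n")
  if (nrow(x)) print(table(confidence = x$confidence))
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Run the full frost-reconstruction pipeline
#'
#' End-to-end orchestration: builds site chronologies for the deciduous
#' target and evergreen control networks, leave-one-out regional
#' references, per-region daily-climate indices, growth-climate
#' screening, evaluates all seven criteria per site-year and integrates
#' them into the event table. For events at low uncertainty or validated,
#' the most likely frost day is pinpointed on the regional composite
#' daily series. Deterministic given its inputs.
#'
#' @param target Named list (site code -> [ring_width_set()]) of the
#'   deciduous network.
#' @param control Named list of the evergreen control network.
#' @param stations Named list (region -> list of two [station_daily()]).
#' @param monthly Named list (region -> list with [monthly_series()]
#'   entries `temp` and `prec`).
#' @param config A [detection_config()].
#' @return An object of class `frost_reconstruction`: list with `events`
#'   (the `frost_event_table`), `criteria` (full criterion matrix),
#'   `chronologies`, `climate` (per-region index tables) and `report`
#'   (skipped site-years with reasons, per-site key variables).
#' @export
reconstruct_events <- function(target, control, stations, monthly, config) {
  stopifnot(inherits(config, "detection_config"))
  skipped <- list()
  note_skip <- function(site, year, reason)
    skipped[[length(skipped) + 1L]] <<-
      data.frame(site = site, year = year, reason = reason)

  for (r in names(config$regions)) {
    unknown <- setdiff(config$regions[[r]]$sites, names(target))
    if (length(unknown))
      stop("configuration references unknown site(s): ",
           paste(unknown, collapse = ", "))
    unknown_c <- setdiff(config$regions[[r]]$control_sites %||% character(),
                         names(control))
    if (length(unknown_c))
      stop("configuration references unknown control site(s): ",
           paste(unknown_c, collapse = ", "))
    unknown_s <- setdiff(config$regions[[r]]$stations,
                         vapply(stations[[r]], attr, "",
                                which = "station_id"))
    if (length(unknown_s))
      stop("configuration references unknown station(s): ",
           paste(unknown_s, collapse = ", "))
  }

  target_chron <- lapply(target, build_site_chronology)
  control_chron <- lapply(control, build_site_chronology)

  all_cm <- list()
  climate_tabs <- list()
  key_vars <- list()
  for (r in names(config$regions)) {
    reg <- config$regions[[r]]
    chrons <- target_chron[reg$sites]
    if (length(chrons) < 3L)
      stop("region '", r, "' needs at least 3 target sites for ",
           "leave-one-out references")
    ctl <- NULL
    if (length(reg$control_sites %||% character()) >= 2L) {
      ctl_reg <- build_regional_chronology(
        control_chron[reg$control_sites], region = r)
      ctl <- control_reduction_years(ctl_reg,
                                     threshold = config$sd_control,
                                     ref_period = config$ref_control)
    }
    clim <- regional_climate(stations[[r]], config)
    climate_tabs[[r]] <- clim

    for (s in reg$sites) {
      loo <- build_regional_chronology(chrons, region = r, exclude = s)
      c1 <- local_growth_reductions(target_chron[[s]], loo,
                                    threshold = config$sd_local,
                                    ref_period = config$ref_local)
      cv <- cropper_values(target_chron[[s]]$series_indices,
                           window = 5L)
      a1 <- pointer_years(cv, threshold = config$cropper_threshold,
                          proportion = config$pointer_prop,
                          min_series = config$min_pointer_series)
      profile <- correlate_growth_climate(target_chron[[s]],
                                          monthly[[r]]$temp,
                                          monthly[[r]]$prec,
                                          period = config$ref_monthly)
      key <- select_key_variables(profile,
                                  fallback = config$fallback_variables[[r]])
      key_vars[[s]] <- key

      years <- intersect(c1$year, clim$year[clim$ok])
      no_clim <- setdiff(c1$year, clim$year[clim$ok])
      for (y in intersect(no_clim, clim$year))
        note_skip(s, y, "insufficient daily-climate coverage")
      if (length(years) == 0L) next
      c4 <- climate_deviation_flags(monthly[[r]]$temp, monthly[[r]]$prec,
                                    key, years,
                                    ref_period = config$ref_monthly,
                                    threshold = config$sd_climate,
                                    two_sided = config$adverse_two_sided)
      ic <- match(years, clim$year)
      ia <- match(years, a1$year)
      i1 <- match(years, c1$year)
      cm <- data.frame(
        region = r, site = s, year = years,
        c1 = c1$flag[i1], c1_z = c1$z[i1],
        c2 = clim$z[ic] < config$z_cold, c2_z = clim$z[ic],
        win_min_1 = clim$win_min_1[ic], win_min_2 = clim$win_min_2[ic],
        c3 = if (is.null(ctl)) NA else !ctl$reduced[match(years, ctl$year)],
        c4 = c4$c4_pass, c4_notes = c4$notes,
        c5 = !(years %in% (config$outbreak_years[[r]] %||% integer())),
        a1 = a1$pointer[ia], a1_frac = a1$frac[ia],
        a2 = clim$high_fr[ic], a2_z = clim$fr_z[ic])
      all_cm[[paste(r, s)]] <- cm
    }
  }
  criteria <- do.call(rbind, all_cm)
  rownames(criteria) <- NULL
  events <- integrate_criteria(criteria,
                               documented = config$documented_frost_years,
                               require_additional = config$require_additional,
                               c3_downgrades = config$c3_downgrades,
                               c4_downgrades = config$c4_downgrades)
  # pinpoint the frost day for the best-supported events
  comps <- list()
  for (i in which(events$confidence %in% c("validated", "low"))) {
    r <- as.character(events$region[i])
    if (is.null(comps[[r]])) comps[[r]] <- composite_daily(stations[[r]])
    comp <- comps[[r]]
    pp <- try(pinpoint_frost_day(comp, events$year[i],
                                 window = config$pinpoint_window),
              silent = TRUE)
    if (!inherits(pp, "try-error") && pp$detected)
      events$pinpoint_doy[i] <- pp$doy
  }
  structure(list(events = events, criteria = criteria,
                 chronologies = list(target = target_chron,
                                     control = control_chron),
                 climate = climate_tabs,
                 report = list(skipped = if (length(skipped))
                   do.call(rbind, skipped) else NULL,
                   key_variables = key_vars)),
            class = "frost_reconstruction")
}

#' @export
print.frost_reconstruction <- function(x, ...) {
  cat("Frost reconstruction over", length(x$climate), "region(s);",
      nrow(x$criteria), "site-years evaluated\n")
  print(x$events)
  invisible(x)
}
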