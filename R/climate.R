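#' Dates of a within-year seasonal window
#'
#' @param year Calendar year.
#' @param window Character `c("mm-dd", "mm-dd")`, inclusive on both ends.
#' @return `Date` vector of every day in the window.
#' @export
window_dates <- function(year, window) {
  seq(as.Date(sprintf("%04d-%s", year, window[1])),
      as.Date(sprintf("%04d-%s", year, window[2])), by = "day")
}

# per-station annual window statistic with coverage bookkeeping
# (dates are matched as integer day counts; matching Date objects
# directly goes through character formatting and is far slower)
station_window_stat <- function(st, years, window, fun) {
  st_days <- as.integer(st$date)
  out <- data.frame(year = years, value = NA_real_, coverage = 0)
  for (k in seq_along(years)) {
    wd <- as.integer(window_dates(years[k], window))
    i <- match(wd, st_days)
    pres <- !is.na(i)
    out$coverage[k] <- mean(pres)
    if (any(pres)) out$value[k] <- fun(st, i[pres])
  }
  out
}

#' Standardized annual window minimum temperatures
#'
#' For each station and year, takes the minimum daily `tmin` within the
#' leaf-unfolding window (default Oct 1 - Nov 15); standardizes those
#' annual minima per station to z-scores using the mean and SD of the
#' reference period; and averages the two stations' z-scores into the
#' regional index used by the cold criterion (re-standardized over the
#' reference years, so the regional index has mean 0 and SD 1 there). A
#' year counts only when
#' every station covers at least `coverage` of the window days -- gappy
#' years carry `ok = FALSE` and no z-score, never a value.
#'
#' @param stations List of two [station_daily()] records.
#' @param window Cold window as `c("mm-dd", "mm-dd")`.
#' @param ref_period Year range used for standardization (default the
#'   1987-2013 common period).
#' @param coverage Minimum fraction of window days present per station.
#' @param years Years to evaluate; defaults to all years any station
#'   touches.
#' @return Data frame with `year`, per-station window minima
#'   (`win_min_1`, `win_min_2`), the regional `z`, and `ok`.
#' @export
annual_window_min_z <- function(stations, window = c("10-01", "11-15"),
                                ref_period = c(1987L, 2013L),
                                coverage = 0.9, years = NULL) {
  stopifnot(length(stations) == 2L)
  if (is.null(years)) years <- station_years(stations)
  per <- lapply(stations, station_window_stat, years = years,
                window = window,
                fun = function(st, i) min(st$tmin[i]))
  zs <- matrix(NA_real_, length(years), 2L)
  for (s in 1:2) {
    usable <- per[[s]]$coverage >= coverage
    ref <- usable & years >= ref_period[1] & years <= ref_period[2]
    if (sum(ref) < 5L)
      stop("fewer than 5 usable reference years for station ",
           attr(stations[[s]], "station_id") %||% s)
    mu <- mean(per[[s]]$value[ref])
    sdv <- sd(per[[s]]$value[ref])
    if (sdv == 0)
      stop("zero reference-period SD of window minima for station ",
           attr(stations[[s]], "station_id") %||% s)
    zs[usable, s] <- (per[[s]]$value[usable] - mu) / sdv
  }
  ok <- per[[1]]$coverage >= coverage & per[[2]]$coverage >= coverage
  # the mean of two unit-variance z-scores has SD < 1, so the composite is
  # standardized once more over the reference years to keep the regional
  # index on the z scale the thresholds assume
  zreg <- ifelse(ok, rowMeans(zs), NA_real_)
  ref_ok <- ok & years >= ref_period[1] & years <= ref_period[2]
  sdr <- sd(zreg[ref_ok])
  if (is.na(sdr) || sdr == 0)
    stop("zero reference-period SD of the regional window-minimum index")
  data.frame(year = years,
             win_min_1 = per[[1]]$value, win_min_2 = per[[2]]$value,
             z = (zreg - mean(zreg[ref_ok])) / sdr,
             ok = ok)
}

station_years <- function(stations) {
  rng <- range(unlist(lapply(stations,
                             function(st) as.integer(format(st$date, "%Y")))))
  seq.int(rng[1], rng[2])
}

#' Frost-risk index from daily temperatures
#'
#' Per station and year, the frost-risk index is the mean temperature in
#' the early-spring warm window (default Sep 15 - Oct 15, before or during
#' leaf unfolding) minus the absolute minimum temperature in the
#' leaf-unfolding window (default Oct 1 - Nov 15):
#' `FR = Tmean[warm] - Tmin[cold]`. Large values mean a warm early spring
#' -- which accelerates leaf flush -- followed by a hard freeze while the
#' new foliage is vulnerable. The regional FR is the mean of the two
#' stations and is standardized over the reference period; years with
#' `FR_z` above `high_z` (strictly) are flagged as high frost risk.
#'
#' Adding a constant to every temperature leaves FR unchanged (the two
#' terms cancel), and lowering any cold-window minimum can only increase
#' it.
#'
#' @param stations List of two [station_daily()] records.
#' @param warm_window,cold_window Windows as `c("mm-dd", "mm-dd")`.
#' @param ref_period Standardization year range.
#' @param coverage Minimum per-station window coverage.
#' @param high_z Threshold on `FR_z` for the high-risk flag. Default 1.5.
#' @param years Years to evaluate.
#' @return Data frame with `year`, `fr` (degrees C), `fr_z`, `high_fr`
#'   and `ok`.
#' @export
frost_risk_index <- function(stations, warm_window = c("09-15", "10-15"),
                             cold_window = c("10-01", "11-15"),
                             ref_period = c(1987L, 2013L),
                             coverage = 0.9, high_z = 1.5, years = NULL) {
  stopifnot(length(stations) == 2L)
  if (is.null(years)) years <- station_years(stations)
  frs <- matrix(NA_real_, length(years), 2L)
  okm <- matrix(FALSE, length(years), 2L)
  for (s in 1:2) {
    warm <- station_window_stat(stations[[s]], years, warm_window,
                                function(st, i) mean(st$tmean[i]))
    cold <- station_window_stat(stations[[s]], years, cold_window,
                                function(st, i) min(st$tmin[i]))
    okm[, s] <- warm$coverage >= coverage & cold$coverage >= coverage
    frs[, s] <- warm$value - cold$value
  }
  ok <- okm[, 1] & okm[, 2]
  fr <- ifelse(ok, rowMeans(frs), NA_real_)
  ref <- ok & years >= ref_period[1] & years <= ref_period[2]
  if (sum(ref) < 5L)
    stop("fewer than 5 usable reference years for the frost-risk index")
  sdv <- sd(fr[ref])
  if (sdv == 0) stop("zero reference-period SD of the frost-risk index")
  fr_z <- (fr - mean(fr[ref])) / sdv
  data.frame(year = years, fr = fr, fr_z = fr_z,
             high_fr = ifelse(ok, fr_z > high_z, NA), ok = ok)
}

#' Composite regional daily series
#'
#' Day-wise mean of `tmin` and `tmean` over the stations reporting that
#' day, used for frost-day pinpointing at the regional scale.
#'
#' @param stations List of [station_daily()] records.
#' @return A [station_daily()] with id `"composite"`.
#' @export
composite_daily <- function(stations) {
  dates <- sort(unique(as.Date(unlist(lapply(stations, `[[`, "date")),
                               origin = "1970-01-01")))
  days <- as.integer(dates)
  tmin <- rowMeans(sapply(stations, function(st)
    st$tmin[match(days, as.integer(st$date))]), na.rm = TRUE)
  tmean <- rowMeans(sapply(stations, function(st)
    st$tmean[match(days, as.integer(st$date))]), na.rm = TRUE)
  keep <- is.finite(tmin) & is.finite(tmean)
  station_daily(dates[keep], tmin[keep], tmean[keep], "composite")
}

#' Pinpoint the most likely frost day within a spring
#'
#' Scans a search window (default Oct 1 - Nov 30, wide enough to capture
#' early-November damage) and computes, for every candidate day `t` whose
#' 10 preceding days are all present,
#' `d(t) = mean(tmean over t-10 .. t-1) - tmin(t)`: warm periods followed
#' by an extreme freeze give large `d`. Returns the day with the largest
#' amplitude; ties break to the earliest day; a non-positive maximum means
#' no frost signature.
#'
#' @param daily A [station_daily()] record (station or regional
#'   composite).
#' @param year Calendar year to scan.
#' @param window Search window as `c("mm-dd", "mm-dd")`.
#' @param lookback Days in the preceding-mean window. Default 10.
#' @return List with `detected` (logical), `doy` (day of year, `NA` when
#'   not detected), `date`, and `amplitude` (degrees C).
#' @export
pinpoint_frost_day <- function(daily, year, window = c("10-01", "11-30"),
                               lookback = 10L) {
  wd <- window_dates(year, window)
  days <- as.integer(daily$date)
  amp <- rep(NA_real_, length(wd))
  for (k in seq_along(wd)) {
    d <- as.integer(wd[k])
    i <- match(d, days)
    if (is.na(i)) next
    prev <- match(d - seq_len(lookback), days)
    if (anyNA(prev)) next
    amp[k] <- mean(daily$tmean[prev]) - daily$tmin[i]
  }
  if (all(is.na(amp)))
    stop("no candidate day in ", year,
         " has a complete ", lookback, "-day look-back window")
  best <- max(amp, na.rm = TRUE)
  if (best <= 0)
    return(list(detected = FALSE, doy = NA_integer_, date = as.Date(NA),
                amplitude = best))
  k <- which(amp == best)[1]   # ties break to the earliest day
  list(detected = TRUE,
       doy = as.integer(format(wd[k], "%j")),
       date = wd[k], amplitude = best)
}

#' Per-year regional climate indices for frost detection
#'
#' Convenience assembly of [annual_window_min_z()] and
#' [frost_risk_index()] for one region under a [detection_config()].
#'
#' @param stations List of two [station_daily()] records.
#' @param config A [detection_config()].
#' @param years Years to evaluate.
#' @return Data frame keyed by year with window minima, regional
#'   window-minimum z, FR, FR z, the high-FR flag and coverage flag.
#' @export
regional_climate <- function(stations, config, years = NULL) {
  wm <- annual_window_min_z(stations, window = config$cold_window,
                            ref_period = config$ref_daily,
                            coverage = config$coverage, years = years)
  fr <- frost_risk_index(stations, warm_window = config$warm_window,
                         cold_window = config$cold_window,
                         ref_period = config$ref_daily,
                         coverage = config$coverage, high_z = config$z_fr,
                         years = wm$year)
  cbind(wm, fr[c("fr", "fr_z", "high_fr")])
}
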