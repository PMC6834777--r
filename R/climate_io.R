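#' Daily station climate record
#'
#' A validated data frame of daily minimum and mean temperature for one
#' meteorological station. Dates must be strictly increasing; missing days
#' are simply absent rows (gap runs are preserved, mirroring how gappy
#' station periods are excluded from analysis rather than infilled).
#'
#' @param date `Date` vector.
#' @param tmin Daily absolute minimum temperature, degrees C.
#' @param tmean Daily mean temperature, degrees C. Must satisfy
#'   `tmin <= tmean` on every record.
#' @param station_id Station identifier.
#' @return A data frame of class `station_daily` with attribute
#'   `station_id`.
#' @export
station_daily <- function(date, tmin, tmean, station_id) {
  if (!inherits(date, "Date")) stop("'date' must be a Date vector")
  n <- length(date)
  if (length(tmin) != n || length(tmean) != n)
    stop("'tmin' and 'tmean' must match 'date' in length")
  if (anyNA(date)) stop("missing or unparseable date")
  if (any(diff(as.integer(date)) <= 0))
    stop("dates must be strictly increasing")
  bad <- which(is.finite(tmin) & is.finite(tmean) & tmin > tmean)
  if (length(bad))
    stop("tmin > tmean on ", format(date[bad[1]]),
         if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)"))
  out <- data.frame(date = date, tmin = as.numeric(tmin),
                    tmean = as.numeric(tmean))
  attr(out, "station_id") <- station_id
  class(out) <- c("station_daily", "data.frame")
  out
}

#' Read a daily climate CSV
#'
#' Expects a header `date,tmin,tmean` with ISO dates. Gaps (absent days)
#' are preserved.
#'
#' @param path CSV file path.
#' @param station_id Station identifier; defaults to the file name.
#' @return A [station_daily()] record.
#' @export
read_daily_climate <- function(path, station_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(station_id))
    station_id <- tools::file_path_sans_ext(basename(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmean")
  if (!all(need %in% names(df)))
    stop("'", path, "' must have columns date,tmin,tmean")
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable date '", df$date[which(is.na(d))[1]], "' in '", path, "'")
  ord <- order(d)
  station_daily(d[ord], df$tmin[ord], df$tmean[ord], station_id)
}

#' Write a daily climate CSV
#' @param st A [station_daily()] record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_climate <- function(st, path) {
  write.csv(data.frame(date = format(st$date), tmin = st$tmin,
                       tmean = st$tmean),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag gaps in a daily record
#'
#' @param st A [station_daily()] record.
#' @return Data frame of gap runs (`from`, `to`, `days`), zero rows when
#'   the record is continuous.
#' @export
climate_gaps <- function(st) {
  dd <- diff(as.integer(st$date))
  i <- which(dd > 1L)
  data.frame(from = st$date[i], to = st$date[i + 1L], days = dd[i] - 1L)
}

#' Monthly climate series
#'
#' One value per (year, month) for a single variable.
#'
#' @param year,month,value Parallel vectors; months in 1..12.
#' @param variable `"temp"` (mean temperature, degrees C) or `"prec"`
#'   (precipitation, mm).
#' @return Data frame of class `monthly_series` with attribute `variable`.
#' @export
monthly_series <- function(year, month, value, variable = c("temp", "prec")) {
  variable <- match.arg(variable)
  month <- as.integer(month)
  if (any(month < 1L | month > 12L)) stop("months must lie in 1..12")
  if (anyDuplicated(paste(year, month)))
    stop("one value per (year, month) required")
  out <- data.frame(year = as.integer(year), month = month,
                    value = as.numeric(value))
  out <- out[order(out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variable") <- variable
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Read a monthly climate CSV (`year,month,value`)
#' @param path CSV file path.
#' @param variable `"temp"` or `"prec"`.
#' @return A [monthly_series()].
#' @export
read_monthly_climate <- function(path, variable = c("temp", "prec")) {
  variable <- match.arg(variable)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "month", "value") %in% names(df)))
    stop("'", path, "' must have columns year,month,value")
  monthly_series(df$year, df$month, df$value, variable)
}

#' Write a monthly climate CSV
#' @param ms A [monthly_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monthly_climate <- function(ms, path) {
  write.csv(as.data.frame(ms)[c("year", "month", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

event_table_columns <- c("region", "site", "year", "confidence",
                         "win_min_1", "win_min_2", "co_drivers",
                         "pinpoint_doy")

#' Write a reconstructed frost-event table as CSV
#'
#' Columns: region, site, year, confidence (`validated`, `low`, `medium`
#' or `high`), the window-minimum temperature recorded at each of the two
#' regional stations, co-driver annotations (semicolon separated, e.g.
#' `"EG"` for a control-species reduction or `"high PDec"` for an adverse
#' climate deviation), and the pinpointed frost day-of-year where computed.
#'
#' @param events A `frost_event_table` (see [integrate_criteria()]), or any
#'   data frame with the same columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  df <- as.data.frame(events)[event_table_columns]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a frost-event table written by [write_event_table()]
#' @param path CSV file path.
#' @return A `frost_event_table` data frame.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(region = "character", site = "character",
                                year = "integer", confidence = "character",
                                win_min_1 = "numeric", win_min_2 = "numeric",
                                co_drivers = "character",
                                pinpoint_doy = "integer"))
  df$confidence <- factor(df$confidence, levels = confidence_levels())
  df$co_drivers[is.na(df$co_drivers)] <- ""
  class(df) <- c("frost_event_table", "data.frame")
  df
}

#' Ordered confidence levels of the reconstruction
#'
#' Ordered from strongest to weakest support: `validated` (all criteria met
#' and the year is in the documented frost records), `low` (uncertainty; all
#' eliminatory and climatic criteria met), `medium`, `high`.
#' @return Character vector of the four levels.
#' @export
confidence_levels <- function() c("validated", "low", "medium", "high")
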