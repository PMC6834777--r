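#' Ring-width collection for one site
#'
#' Container for the per-core annual ring-width series of a single stand.
#' Widths are stored in millimetres in a year-by-series matrix; years follow
#' the Southern Hemisphere dating convention, under which an annual ring is
#' assigned to the calendar year in which radial growth begins. Each series
#' occupies a block of consecutive years; cells outside a series' span are
#' `NA`.
#'
#' @param widths Numeric matrix (years x series) of ring widths in mm, with
#'   column names identifying cores. Values must be non-negative and each
#'   column's non-missing values must form one consecutive block of years.
#' @param years Integer vector of calendar years, one per matrix row.
#' @param site_code Short site identifier.
#' @param species Free species/network tag, e.g. `"target"` (deciduous) or
#'   `"control"` (evergreen conifer).
#' @param precision Measurement precision in mm per series (0.01 or 0.001),
#'   recycled if scalar. Kept so files round-trip at their stated precision.
#' @return An object of class `ring_width_set`.
#' @seealso [read_rwl()], [write_rwl()]
#' @export
ring_width_set <- function(widths, years, site_code,
                           species = "target", precision = 0.01) {
  widths <- as.matrix(widths)
  years <- as.integer(years)
  if (nrow(widths) != length(years))
    stop("'years' must have one entry per row of 'widths'")
  if (is.null(colnames(widths)))
    stop("'widths' must have series identifiers as column names")
  if (any(widths < 0, na.rm = TRUE))
    stop("ring widths must be >= 0")
  if (any(diff(years) != 1L))
    stop("'years' must be consecutive")
  for (j in seq_len(ncol(widths))) {
    idx <- which(!is.na(widths[, j]))
    if (length(idx) == 0L)
      stop("series '", colnames(widths)[j], "' has no data")
    if (any(diff(idx) != 1L))
      stop("series '", colnames(widths)[j],
           "' has internal gaps; years within a series must be consecutive")
  }
  precision <- rep_len(precision, ncol(widths))
  names(precision) <- colnames(widths)
  rownames(widths) <- years
  structure(
    list(site_code = site_code, years = years, widths = widths,
         species = species, precision = precision),
    class = "ring_width_set")
}

#' @export
print.ring_width_set <- function(x, ...) {
  cat("Ring-width set '", x$site_code, "' (", x$species, ")\n", sep = "")
  cat("  ", ncol(x$widths), " series, years ", min(x$years), "-",
      max(x$years), "\n", sep = "")
  invisible(x)
}

#' Number of series in a ring-width set
#' @param rw A [ring_width_set()].
#' @return Integer count of cores.
#' @export
n_series <- function(rw) ncol(rw$widths)

# years actually covered by one series (column name or index)
series_span <- function(rw, series) {
  idx <- which(!is.na(rw$widths[, series]))
  rw$years[idx]
}

#' Read a Tucson/decadal ring-width (RWL) file
#'
#' Parses the decadal format distributed by the ITRDB: each row carries a
#' series identifier, the calendar year of its first value, and up to ten
#' ring widths; a sentinel terminates each series. Both dialects are
#' supported and auto-detected per series from the terminator: `999`
#' (values in 0.01 mm) and `-9999` (values in 0.001 mm). Widths are
#' returned in mm with the sentinel stripped. A leading 3-line ITRDB
#' header block is skipped if present, not interpreted.
#'
#' @param path Path to the file.
#' @param site_code Site identifier; defaults to the file name without
#'   extension.
#' @param species Species/network tag stored on the result.
#' @return A [ring_width_set()].
#' @export
read_rwl <- function(path, site_code = NULL, species = "target") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(site_code))
    site_code <- tools::file_path_sans_ext(basename(path))
  raw <- readLines(path, warn = FALSE)

  ids <- character(); yrs <- integer(); vals <- list()
  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (!nzchar(line)) next
    toks <- strsplit(line, "[ \t]+")[[1]]
    # fixed-width dialect: an 8-character series id runs flush into the
    # 4-digit year (columns 1-8 and 9-12 of the Tucson layout)
    if (length(toks) >= 2L && nchar(toks[1]) == 12L &&
        grepl("^[0-9]{4}$", substr(toks[1], 9L, 12L)))
      toks <- c(substr(toks[1], 1L, 8L), substr(toks[1], 9L, 12L),
                toks[-1])
    yr <- suppressWarnings(as.integer(toks[2]))
    vv <- if (length(toks) >= 3)
      suppressWarnings(as.numeric(toks[-(1:2)])) else NA_real_
    if (length(toks) < 3 || is.na(yr) || anyNA(vv)) {
      if (i <= 3L) next  # ITRDB header line
      stop("malformed row at line ", i, " of '", path, "'")
    }
    ids <- c(ids, toks[1]); yrs <- c(yrs, yr); vals <- c(vals, list(vv))
  }
  if (length(ids) == 0L) stop("no data rows found in '", path, "'")

  series <- list(); precision <- numeric()
  for (id in unique(ids)) {
    rows <- which(ids == id)
    year <- integer(); val <- numeric()
    for (r in rows) {
      ry <- yrs[r] + seq_along(vals[[r]]) - 1L
      if (length(year)) {
        if (any(ry %in% year))
          stop("duplicate year ", min(ry[ry %in% year]),
               " in series '", id, "'")
        if (yrs[r] != max(year) + 1L)
          stop("non-monotone decades in series '", id, "'")
      }
      year <- c(year, ry); val <- c(val, vals[[r]])
    }
    last <- val[length(val)]
    if (identical(last, 999)) {
      prec <- 0.01
    } else if (identical(last, -9999)) {
      prec <- 0.001
    } else {
      warning("series '", id, "' has no terminating sentinel; ",
              "assuming 0.01 mm precision")
      prec <- 0.01
      last <- NA  # nothing to strip
    }
    if (!is.na(last)) { val <- val[-length(val)]; year <- year[-length(year)] }
    if (length(val) == 0L) stop("series '", id, "' has no widths")
    if (any(val < 0)) stop("negative ring width in series '", id, "'")
    if (any(diff(year) != 1L))
      stop("non-monotone decades in series '", id, "'")
    series[[id]] <- list(years = year, widths = val * prec)
    precision[id] <- prec
  }

  all_years <- range(unlist(lapply(series, `[[`, "years")))
  years <- seq.int(all_years[1], all_years[2])
  mat <- matrix(NA_real_, length(years), length(series),
                dimnames = list(years, names(series)))
  for (id in names(series))
    mat[match(series[[id]]$years, years), id] <- series[[id]]$widths
  ring_width_set(mat, years, site_code, species, precision)
}

#' Write a ring-width set as a Tucson/decadal RWL file
#'
#' Inverse of [read_rwl()]: values are written in the per-series file units
#' (0.01 mm with sentinel `999`, or 0.001 mm with sentinel `-9999`), in
#' decade-aligned rows. Reading the result back yields a set identical to
#' the input at the stated precision.
#'
#' @param rw A [ring_width_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rw, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in colnames(rw$widths)) {
    span <- series_span(rw, id)
    prec <- rw$precision[[id]]
    units <- round(rw$widths[match(span, rw$years), id] / prec)
    sentinel <- if (prec == 0.001) -9999 else 999
    units <- c(units, sentinel)
    yr <- span[1]
    pos <- 1L
    while (pos <= length(units)) {
      take <- min(10L - yr %% 10L, length(units) - pos + 1L)
      row_vals <- units[pos:(pos + take - 1L)]
      cat(sprintf("%-8s%4d%s", id, yr,
                  paste0(sprintf("%6d", row_vals), collapse = "")),
          "\n", sep = "", file = con)
      yr <- yr + take
      pos <- pos + take
    }
  }
  invisible(path)
}
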