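# The 15 month-lags screened for growth associations: January through
# December of the ring's calendar year (the season's spring months under
# the Southern Hemisphere convention) plus January-March of the following
# calendar year, the end of the same growing season.
month_lag_table <- function() {
  data.frame(season = c(rep("prev", 12L), rep("curr", 3L)),
             month = c(1:12, 1:3))
}

# monthly value aligned to ring years: season "prev" -> calendar year t,
# season "curr" -> calendar year t + 1
aligned_monthly <- function(ms, years, month, season) {
  yy <- if (season == "curr") years + 1L else years
  ms$value[match(paste(yy, month), paste(ms$year, ms$month))]
}

#' Correlate a site chronology with monthly climate
#'
#' Pearson correlation of the residual chronology against monthly mean
#' temperature and precipitation over the 15-month window from January of
#' the ring's calendar year (the previous growing season) through March of
#' the following calendar year (the end of the current growing season).
#' P-values use the t approximation; no multiple-testing correction is
#' applied, matching standard correlation-function screening.
#'
#' @param chron A `site_chronology`.
#' @param temp,prec [monthly_series()] of mean temperature and
#'   precipitation.
#' @param period Optional year range restricting the analysis.
#' @return Data frame of class `climate_growth_profile` with one row per
#'   (variable, month-lag): `variable`, `season`, `month`, `r`, `p`, `n`.
#' @export
correlate_growth_climate <- function(chron, temp, prec, period = NULL) {
  years <- chron$years[is.finite(chron$index)]
  if (!is.null(period))
    years <- years[years >= period[1] & years <= period[2]]
  g <- chron$index[match(years, chron$years)]
  lags <- month_lag_table()
  out <- do.call(rbind, lapply(c("temp", "prec"), function(v) {
    ms <- if (v == "temp") temp else prec
    cbind(variable = v, lags, r = NA_real_, p = NA_real_, n = 0L)
  }))
  for (i in seq_len(nrow(out))) {
    ms <- if (out$variable[i] == "temp") temp else prec
    cv <- aligned_monthly(ms, years, out$month[i], out$season[i])
    ok <- is.finite(cv) & is.finite(g)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 3L && sd(cv[ok]) > 0 && sd(g[ok]) > 0) {
      r <- cor(g[ok], cv[ok])
      out$r[i] <- r
      df <- sum(ok) - 2L
      tt <- abs(r) * sqrt(df / max(1 - r^2, .Machine$double.eps))
      out$p[i] <- 2 * pt(tt, df, lower.tail = FALSE)
    }
  }
  if (max(out$n) < 20L)
    stop("chronology-climate overlap shorter than 20 years for site '",
         chron$site_code, "'")
  structure(out, class = c("climate_growth_profile", "data.frame"),
            site_code = chron$site_code)
}

#' Select the key climate variables for a site
#'
#' Keeps every (variable, month-lag) whose growth correlation is
#' significant at `p < alpha` (strictly; a p-value exactly at `alpha` is
#' not selected). When nothing is significant, the region's configured
#' default set -- the variables most frequently influencing regional
#' growth -- is returned with attribute `fallback = TRUE`.
#'
#' @param profile A [correlate_growth_climate()] result.
#' @param alpha Significance level. Default 0.01.
#' @param fallback List of entries `list(variable, season, month, sign)`
#'   (the per-region default set from the configuration).
#' @return Data frame with `variable`, `season`, `month`, `sign` (the
#'   direction of the growth association) and, for selected entries, `r`
#'   and `p`; attribute `fallback` records whether the default set was
#'   used.
#' @export
select_key_variables <- function(profile, alpha = 0.01, fallback = NULL) {
  sel <- profile[!is.na(profile$p) & profile$p < alpha, , drop = FALSE]
  if (nrow(sel) > 0L) {
    out <- data.frame(variable = sel$variable, season = sel$season,
                      month = sel$month, sign = sign(sel$r),
                      r = sel$r, p = sel$p)
    attr(out, "fallback") <- FALSE
    return(out)
  }
  if (is.null(fallback) || length(fallback) == 0L)
    stop("no significant climate variable and no fallback set configured",
         " for site '", attr(profile, "site_code"), "'")
  out <- do.call(rbind, lapply(fallback, function(fv)
    data.frame(variable = fv$variable, season = fv$season %||% "prev",
               month = as.integer(fv$month), sign = fv$sign,
               r = NA_real_, p = NA_real_)))
  attr(out, "fallback") <- TRUE
  out
}

#' Adverse climate-deviation flags (Criterion 4)
#'
#' For each key variable, standardizes its aligned yearly values over the
#' reference period and flags a year as adverse when the z-score exceeds
#' the threshold in the direction opposite the growth association (e.g.
#' unusually high December precipitation where the correlation is
#' negative, annotated `"high PDec"`). Criterion 4 passes for a year iff
#' no key variable is adverse. The z-scores make the outcome invariant to
#' affine rescaling of any climate variable.
#'
#' @param temp,prec [monthly_series()] records.
#' @param key Key-variable table from [select_key_variables()].
#' @param years Ring years to annotate.
#' @param ref_period Standardization year range (default 1950-2003).
#' @param threshold Deviation threshold in SD. Default 1.
#' @param two_sided If `TRUE`, deviations beyond the threshold in either
#'   direction are adverse regardless of correlation sign.
#' @return Data frame with `year`, `c4_pass`, and `notes` (semicolon-
#'   joined annotations such as `"high PNov"`).
#' @export
climate_deviation_flags <- function(temp, prec, key, years,
                                    ref_period = c(1950L, 2003L),
                                    threshold = 1, two_sided = FALSE) {
  if (is.null(key) || nrow(key) == 0L)
    stop("key-variable set must be non-empty (possibly the fallback)")
  notes <- vector("list", length(years))
  adverse_any <- rep(FALSE, length(years))
  ref_years <- year_seq(ref_period)
  for (i in seq_len(nrow(key))) {
    ms <- if (key$variable[i] == "temp") temp else prec
    vals <- aligned_monthly(ms, years, key$month[i], key$season[i])
    refv <- aligned_monthly(ms, ref_years, key$month[i], key$season[i])
    refv <- refv[is.finite(refv)]
    if (length(refv) < 5L)
      stop("fewer than 5 reference years for ", key$variable[i],
           " month ", key$month[i])
    sdv <- sd(refv)
    if (sdv == 0)
      stop("zero reference-period SD for ", key$variable[i], " month ",
           key$month[i])
    z <- (vals - mean(refv)) / sdv
    adverse <- if (two_sided) abs(z) > threshold
               else z * -key$sign[i] > threshold
    adverse[is.na(adverse)] <- FALSE
    lab <- paste0(ifelse(z > 0, "high ", "low "),
                  ifelse(key$variable[i] == "prec", "P", "T"),
                  month.abb[key$month[i]])
    for (k in which(adverse)) notes[[k]] <- c(notes[[k]], lab[k])
    adverse_any <- adverse_any | adverse
  }
  data.frame(year = years, c4_pass = !adverse_any,
             notes = vapply(notes, function(x)
               paste(unique(x), collapse = "; "), character(1)))
}
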