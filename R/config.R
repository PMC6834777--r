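#' Detection configuration
#'
#' Holds every tunable of the frost-detection procedure: region membership,
#' reference periods, thresholds, seasonal windows, documented outbreak and
#' frost-record years, and the per-region fallback climate variables used
#' when no monthly variable correlates significantly with growth.
#'
#' Defaults follow the published procedure: local growth reductions are
#' judged over 1950-1991, the control-species and monthly-climate
#' references over 1950-2003, and daily temperatures are standardized over
#' the 1987-2013 common period. All exceedance thresholds are strict
#' inequalities.
#'
#' @param regions Named list, one entry per region, each a list with
#'   character vectors `sites` (deciduous target stands), `control_sites`
#'   (evergreen control stands) and `stations` (two station ids).
#' @param ref_local Year range (length-2) standardizing the site-minus-
#'   regional difference series (Criterion 1).
#' @param ref_control Year range standardizing the control-species regional
#'   chronology (Criterion 3).
#' @param ref_monthly Year range standardizing monthly climate deviations
#'   (Criterion 4).
#' @param ref_daily Year range standardizing the daily-derived annual
#'   indices (Criterion 2 window minima and the frost-risk index).
#' @param sd_local Criterion 1 threshold: flag years more than this many SD
#'   below the leave-one-out regional chronology. Default 1.5.
#' @param z_cold Criterion 2 threshold on the regional window-minimum
#'   z-score. Default -1.5.
#' @param sd_control Criterion 3 threshold on the control chronology
#'   z-score. Default 1.5.
#' @param sd_climate Criterion 4 threshold on monthly climate deviations,
#'   in SD. Default 1.
#' @param cropper_threshold Cropper-value threshold for a series to count
#'   as a negative deviation. Default 0.5.
#' @param pointer_prop Proportion of series that must exceed the Cropper
#'   threshold for a negative pointer year (strict). Default 0.5.
#' @param z_fr Threshold on the frost-risk-index z-score for "high FR"
#'   (strict). Default 1.5.
#' @param cold_window Character `c("mm-dd","mm-dd")`: the leaf-unfolding
#'   window scanned for minimum temperatures. Default Oct 1 - Nov 15.
#' @param warm_window Window for the warm-spell mean in the frost-risk
#'   index. Default Sep 15 - Oct 15.
#' @param pinpoint_window Search window for the frost-day pinpoint.
#'   Default Oct 1 - Nov 30.
#' @param coverage Minimum fraction of window days a station must cover
#'   for a year to be usable. Default 0.9.
#' @param min_pointer_series Minimum series present for the pointer-year
#'   criterion to be evaluable. Default 5.
#' @param adverse_two_sided If `TRUE`, Criterion 4 flags deviations beyond
#'   the threshold in either direction; the default flags only deviations
#'   opposite to the sign of the growth-climate correlation.
#' @param require_additional If `TRUE` (default) the low-uncertainty level
#'   requires at least one of the two additional criteria (pointer year or
#'   high frost risk).
#' @param c3_downgrades,c4_downgrades If `TRUE` (default) a failed control-
#'   species or climate-deviation criterion downgrades a candidate event to
#'   medium uncertainty; if `FALSE` it is only annotated as a co-driver,
#'   reproducing the looser reading in which e.g. a control-species
#'   reduction accompanies a low-uncertainty event.
#' @param outbreak_years Named list (region -> integer years) of documented
#'   or reconstructed insect-outbreak years (Criterion 5 exclusion list).
#' @param documented_frost_years Named list (region -> integer years) of
#'   frost damage documented in agricultural records, used for validation.
#' @param fallback_variables Named list (region -> list of entries
#'   `list(variable, season, month, sign)`) naming the climate variables
#'   most frequently influencing regional growth, used by Criterion 4 when
#'   no variable correlates significantly at a site. `season` is `"prev"`
#'   (calendar year of the ring) or `"curr"` (the following Jan-Mar);
#'   `sign` is the assumed direction of the growth association.
#' @return A validated list of class `detection_config`.
#' @export
detection_config <- function(regions,
                             ref_local = c(1950L, 1991L),
                             ref_control = c(1950L, 2003L),
                             ref_monthly = c(1950L, 2003L),
                             ref_daily = c(1987L, 2013L),
                             sd_local = 1.5,
                             z_cold = -1.5,
                             sd_control = 1.5,
                             sd_climate = 1.0,
                             cropper_threshold = 0.5,
                             pointer_prop = 0.5,
                             z_fr = 1.5,
                             cold_window = c("10-01", "11-15"),
                             warm_window = c("09-15", "10-15"),
                             pinpoint_window = c("10-01", "11-30"),
                             coverage = 0.9,
                             min_pointer_series = 5L,
                             adverse_two_sided = FALSE,
                             require_additional = TRUE,
                             c3_downgrades = TRUE,
                             c4_downgrades = TRUE,
                             outbreak_years = list(),
                             documented_frost_years = list(),
                             fallback_variables = list()) {
  cfg <- list(regions = regions,
              ref_local = as.integer(ref_local),
              ref_control = as.integer(ref_control),
              ref_monthly = as.integer(ref_monthly),
              ref_daily = as.integer(ref_daily),
              sd_local = sd_local, z_cold = z_cold,
              sd_control = sd_control, sd_climate = sd_climate,
              cropper_threshold = cropper_threshold,
              pointer_prop = pointer_prop, z_fr = z_fr,
              cold_window = cold_window, warm_window = warm_window,
              pinpoint_window = pinpoint_window,
              coverage = coverage,
              min_pointer_series = as.integer(min_pointer_series),
              adverse_two_sided = isTRUE(adverse_two_sided),
              require_additional = isTRUE(require_additional),
              c3_downgrades = isTRUE(c3_downgrades),
              c4_downgrades = isTRUE(c4_downgrades),
              outbreak_years = outbreak_years,
              documented_frost_years = documented_frost_years,
              fallback_variables = fallback_variables)
  validate_detection_config(cfg)
}

validate_detection_config <- function(cfg) {
  if (!is.list(cfg$regions) || is.null(names(cfg$regions)) ||
      length(cfg$regions) == 0L)
    stop("'regions' must be a non-empty named list")
  for (r in names(cfg$regions)) {
    reg <- cfg$regions[[r]]
    if (!all(c("sites", "stations") %in% names(reg)))
      stop("region '", r, "' must declare 'sites' and 'stations'")
    if (length(reg$stations) != 2L)
      stop("region '", r, "' must declare exactly 2 stations")
  }
  for (p in c("ref_local", "ref_control", "ref_monthly", "ref_daily")) {
    pr <- cfg[[p]]
    if (length(pr) != 2L || anyNA(pr) || pr[1] > pr[2])
      stop("'", p, "' must be a non-empty year range c(first, last)")
  }
  for (th in c("sd_local", "sd_control", "sd_climate",
               "cropper_threshold", "z_fr"))
    if (!is.numeric(cfg[[th]]) || cfg[[th]] <= 0)
      stop("threshold '", th, "' must be > 0")
  if (!is.numeric(cfg$z_cold) || cfg$z_cold >= 0)
    stop("'z_cold' must be negative")
  if (cfg$pointer_prop <= 0 || cfg$pointer_prop >= 1)
    stop("'pointer_prop' must lie in (0, 1)")
  if (cfg$coverage <= 0 || cfg$coverage > 1)
    stop("'coverage' must lie in (0, 1]")
  for (w in c("cold_window", "warm_window", "pinpoint_window")) {
    win <- cfg[[w]]
    if (length(win) != 2L || !all(grepl("^[0-1][0-9]-[0-3][0-9]$", win)))
      stop("'", w, "' must be two 'mm-dd' strings")
    md <- parse_month_day(win)
    if (md$month[1] < 8L || md$month[2] > 12L ||
        md$month[1] > md$month[2] ||
        (md$month[1] == md$month[2] && md$day[1] > md$day[2]))
      stop("'", w, "' must lie within one austral spring (Aug-Dec)")
  }
  structure(cfg, class = "detection_config")
}

parse_month_day <- function(md) {
  parts <- do.call(rbind, strsplit(md, "-", fixed = TRUE))
  list(month = as.integer(parts[, 1]), day = as.integer(parts[, 2]))
}

#' @export
print.detection_config <- function(x, ...) {
  cat("Frost detection configuration:", length(x$regions), "region(s)\n")
  for (r in names(x$regions))
    cat("  ", r, ": ", length(x$regions[[r]]$sites), " sites, ",
        length(x$regions[[r]]$control_sites %||% character()),
        " control sites\n", sep = "")
  invisible(x)
}

#' Write a detection configuration as YAML
#' @param cfg A [detection_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read and validate a YAML detection configuration
#'
#' Unknown keys are rejected rather than ignored, so a mistyped threshold
#' name cannot silently fall back to its default.
#'
#' @param path YAML file path.
#' @return A [detection_config()].
#' @export
read_detection_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(detection_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$regions)) stop("configuration must declare 'regions'")
  do.call(detection_config, raw)
}
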