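# Shared fixture builders. Everything is generated in code; no data files.

# compact network for fast unit tests (still spans the default reference
# periods 1950-1991 / 1950-2003 / 1987-2013)
small_params <- function(seed = 42L, ...) {
  simulation_params(seed = seed, n_regions = 2L, sites_per_region = 3L,
                    trees_per_site = 6L, cores_per_tree = 1L,
                    control_sites_per_region = 2L,
                    control_trees_per_site = 6L,
                    start_year = 1944L, n_years = 70L, ...)
}

# daily record with full coverage over whole calendar years
make_station <- function(years, tmin_fun, tmean_fun, id = "stx") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.POSIXlt(dates)$yday + 1
  station_daily(dates, tmin_fun(yr, doy, dates), tmean_fun(yr, doy, dates),
                id)
}

# minimal chronology object for functions that only need (code, years,
# index)
fake_chron <- function(site_code, years, index) {
  structure(list(site_code = site_code, years = as.integer(years),
                 index = index, depth = rep(1L, length(years))),
            class = "site_chronology")
}

fake_regional <- function(region, years, index) {
  structure(list(region = region, years = as.integer(years), index = index,
                 n_sites = rep(2L, length(years)), sites = c("a", "b")),
            class = "regional_chronology")
}

# one criterion-matrix row with overridable flags
cm_row <- function(..., region = "R1", site = "s1", year = 1980L) {
  base <- list(region = region, site = site, year = year,
               c1 = TRUE, c1_z = -2, c2 = TRUE, c2_z = -2,
               win_min_1 = -6, win_min_2 = -5.5,
               c3 = TRUE, c4 = TRUE, c4_notes = "",
               c5 = TRUE, a1 = FALSE, a1_frac = 0.2, a2 = FALSE,
               a2_z = 0)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}
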