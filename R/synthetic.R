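#' Parameters of the synthetic tree-ring and climate generator
#'
#' Bundles every knob of the simulated study system: a network of
#' deciduous target stands and evergreen control stands per region, two
#' meteorological stations per region, and a list of injected frost and
#' drought events with known ground truth. Defaults describe a
#' 2-region x 6-site x 15-tree x 80-year network (1934-2013, so the
#' default reference periods of [detection_config()] are covered) with 6
#' frost events (growth reduction 0.4-0.6, cold snap 2.5 SD deep, 8-day
#' warm spell) and 4 regional droughts.
#'
#' Ring widths compose multiplicatively,
#' `width = ageCurve * exp(regional + site + tree) * eventFactor`,
#' with a negative-exponential age curve per core and AR(1) regional, site
#' and tree log-scale signals, so ratio detrending is well defined and
#' widths stay positive. Frost events multiply affected deciduous sites
#' only by `1 - reduction` in the event year; droughts multiply every
#' site of the region in both networks. The control network's regional
#' signal is correlated `control_cor` with the target's.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_regions,sites_per_region,trees_per_site,cores_per_tree Network
#'   dimensions of the deciduous target network.
#' @param control_sites_per_region,control_trees_per_site Control-network
#'   dimensions (cores per tree as the target).
#' @param start_year,n_years Simulated year span (`n_years >= 60` so the
#'   default reference periods fit).
#' @param age_a,age_b,age_c Ranges (min, max) of the per-core
#'   negative-exponential age-curve parameters `a e^(-b t) + c` (mm).
#' @param phi Lag-1 autocorrelation of the log-scale growth signals,
#'   in `[0, 1)`.
#' @param regional_sd,site_sd,tree_sd Stationary SDs of the shared
#'   regional, site-level and tree-level log-scale signals.
#' @param control_cor Correlation between the target and control regional
#'   signals.
#' @param temp_mean,seasonal_amp Annual mean (degrees C) and amplitude of
#'   the seasonal temperature cycle (warmest in mid-January, austral
#'   summer).
#' @param weather_sd,weather_ar SD and AR(1) coefficient of the
#'   regionally shared daily weather anomaly.
#' @param station_sd SD of the station-specific daily anomaly (the two
#'   stations share the weather term, so they are correlated).
#' @param diurnal_range,diurnal_sd Mean and SD of the daily
#'   tmean - tmin offset (floored at 0.5 so `tmin <= tmean` always).
#' @param precip_base,precip_seasonal,precip_shape Monthly precipitation:
#'   gamma draws with seasonal mean `base + seasonal (1 + cos)` peaking in
#'   austral winter, shape `precip_shape`.
#' @param n_frost,n_drought Number of injected events when `events` is not
#'   given explicitly.
#' @param frost_reduction,drought_reduction Ranges of the growth-reduction
#'   fraction, in (0, 1).
#' @param frost_sites Range (min, max) of the number of affected sites
#'   per frost event.
#' @param snap_depth Cold-snap depth: the snap-day minimum is forced to at
#'   least this many SD below the climatology of annual cold-window
#'   minima. Default 2.5.
#' @param snap_length Cold-snap length in days (1-3).
#' @param warm_spell_days,warm_anom Length (days, within Sep 15 - Oct 15)
#'   and amplitude (degrees C) of the pre-frost warm spell.
#' @param warm_spell Set `FALSE` to inject frosts without a preceding warm
#'   spell (frost damage can occur without a warm early spring; such
#'   events exercise the detector's pointer-year route).
#' @param events Optional explicit event list; each entry a list with
#'   `type` (`"frost"`/`"drought"`), `region`, `year`, `sites`,
#'   `reduction` and, for frosts, `snap_depth`, `snap_length`,
#'   `warm_spell_days`, `warm_anom`, `warm_spell`. When `NULL`, events are
#'   drawn at random inside [simulate_network()].
#' @return Validated list of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              n_regions = 2L, sites_per_region = 6L,
                              trees_per_site = 15L, cores_per_tree = 2L,
                              control_sites_per_region = 3L,
                              control_trees_per_site = 12L,
                              start_year = 1934L, n_years = 80L,
                              age_a = c(0.8, 2.0), age_b = c(0.02, 0.06),
                              age_c = c(0.2, 0.6),
                              phi = 0.35, regional_sd = 0.12,
                              site_sd = 0.08, tree_sd = 0.15,
                              control_cor = 0.5,
                              temp_mean = 8, seasonal_amp = 7,
                              weather_sd = 2.5, weather_ar = 0.6,
                              station_sd = 1.0,
                              diurnal_range = 7, diurnal_sd = 1.5,
                              precip_base = 40, precip_seasonal = 50,
                              precip_shape = 4,
                              n_frost = 6L, n_drought = 4L,
                              frost_reduction = c(0.4, 0.6),
                              drought_reduction = c(0.3, 0.5),
                              frost_sites = c(2L, 4L),
                              snap_depth = 2.5, snap_length = 2L,
                              warm_spell_days = 8L, warm_anom = 4,
                              warm_spell = TRUE,
                              events = NULL) {
  p <- as.list(environment())
  if (p$n_years < 60L)
    stop("'n_years' must be >= 60 so the default reference periods fit")
  if (p$phi < 0 || p$phi >= 1) stop("'phi' must lie in [0, 1)")
  for (rr in list(frost_reduction, drought_reduction))
    if (any(rr <= 0 | rr >= 1))
      stop("reduction fractions must lie in (0, 1)")
  if (p$snap_length < 1L || p$snap_length > 3L)
    stop("'snap_length' must be 1-3 days")
  p$seed <- as.integer(seed)
  structure(p, class = "simulation_params")
}

region_name <- function(r) sprintf("R%d", r)
target_site_codes <- function(p, r) sprintf("r%ds%d", r,
                                            seq_len(p$sites_per_region))
control_site_codes <- function(p, r)
  sprintf("r%dc%d", r, seq_len(p$control_sites_per_region))
station_ids <- function(r) sprintf("st%d%s", r, c("a", "b"))

sim_years <- function(p) seq.int(p$start_year, p$start_year + p$n_years - 1L)

# stationary AR(1) path with marginal SD `sdev`
ar1_path <- function(n, sdev, phi) {
  if (sdev <= 0) return(rep(0, n))
  innov <- rnorm(n, 0, sdev * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# draw the injected-event list; assumes the RNG is already seeded
draw_events <- function(p) {
  pool <- lapply(seq_len(p$n_regions), function(r)
    seq.int(p$start_year + 25L, p$start_year + p$n_years - 3L))
  events <- list()
  take_year <- function(r) {
    y <- sample(pool[[r]], 1L)
    pool[[r]] <<- setdiff(pool[[r]], y)
    y
  }
  for (i in seq_len(p$n_frost)) {
    r <- sample.int(p$n_regions, 1L)
    hi <- min(p$frost_sites[2], p$sites_per_region)
    lo <- min(p$frost_sites[1], hi)
    nsite <- sample(seq.int(lo, hi), 1L)
    events[[length(events) + 1L]] <- list(
      type = "frost", region = region_name(r), year = take_year(r),
      sites = sample(target_site_codes(p, r), nsite),
      reduction = runif(1, p$frost_reduction[1], p$frost_reduction[2]),
      snap_depth = p$snap_depth, snap_length = p$snap_length,
      warm_spell_days = p$warm_spell_days, warm_anom = p$warm_anom,
      warm_spell = p$warm_spell)
  }
  for (i in seq_len(p$n_drought)) {
    r <- sample.int(p$n_regions, 1L)
    events[[length(events) + 1L]] <- list(
      type = "drought", region = region_name(r), year = take_year(r),
      sites = target_site_codes(p, r),
      reduction = runif(1, p$drought_reduction[1],
                        p$drought_reduction[2]))
  }
  events[order(vapply(events, `[[`, 0, "year"))]
}

# core daily-temperature engine for one region; RNG must be seeded.
# Returns the two stations plus the first snap day of each injected frost.
sim_region_daily <- function(p, r, events) {
  years <- sim_years(p)
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])),
               by = "day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  seasonal <- p$temp_mean +
    p$seasonal_amp * cos(2 * pi * (doy - 15) / 365.25)
  shared <- if (p$weather_sd > 0)
    ar1_path(n, p$weather_sd, p$weather_ar) else rep(0, n)
  tmean <- tmin <- matrix(0, n, 2L)
  for (s in 1:2) {
    tmean[, s] <- seasonal + shared + rnorm(n, 0, p$station_sd)
    offset <- pmax(0.5, rnorm(n, p$diurnal_range, p$diurnal_sd))
    tmin[, s] <- tmean[, s] - offset
  }
  # climatology of annual cold-window minima from the undisturbed series
  days <- as.integer(dates)
  clim_mu <- clim_sd <- numeric(2L)
  for (s in 1:2) {
    mins <- vapply(years, function(y) {
      i <- match(as.integer(window_dates(y, c("10-01", "11-15"))), days)
      min(tmin[i, s])
    }, 0)
    clim_mu[s] <- mean(mins); clim_sd[s] <- sd(mins)
  }
  frost_events <- Filter(function(e) e$type == "frost" &&
                           e$region == region_name(r), events)
  snaps <- data.frame(year = integer(), snap_doy = integer())
  for (e in frost_events) {
    spell_end <- as.Date(sprintf("%d-09-30", e$year))  # no-spell default
    if (isTRUE(e$warm_spell) && e$warm_spell_days > 0) {
      w0 <- window_dates(e$year, c("09-15", "10-15"))
      starts <- w0[seq_len(length(w0) - e$warm_spell_days + 1L)]
      sp <- starts[sample.int(length(starts), 1L)]
      idx <- match(sp + seq_len(e$warm_spell_days) - 1L, dates)
      tmean[idx, ] <- tmean[idx, ] + e$warm_anom
      tmin[idx, ] <- tmin[idx, ] + e$warm_anom
      spell_end <- sp + e$warm_spell_days - 1L
    }
    cold <- window_dates(e$year, c("10-01", "11-15"))
    cand <- cold[cold > spell_end]
    cand <- cand[seq_len(max(1L, length(cand) - e$snap_length + 1L))]
    s0 <- cand[sample.int(length(cand), 1L)]
    idx <- match(s0 + seq_len(e$snap_length) - 1L, dates)
    idx <- idx[!is.na(idx)]
    for (s in 1:2) {
      # radiative spring frost: clear nights drive the minimum far down
      # while day-time means recover, so only tmin is forced
      target <- clim_mu[s] - e$snap_depth * clim_sd[s]
      tmin[idx, s] <- pmin(tmin[idx, s], target)
      tmean[idx, s] <- pmax(tmean[idx, s], tmin[idx, s] + 0.5)
    }
    snaps <- rbind(snaps, data.frame(
      year = e$year, snap_doy = as.integer(format(s0, "%j"))))
  }
  stations <- lapply(1:2, function(s)
    station_daily(dates, tmin[, s], tmean[, s], station_ids(r)[s]))
  list(stations = stations, snaps = snaps)
}

#' Simulate daily station temperatures for one region
#'
#' Two correlated stations sharing a seasonal cycle and an AR(1) regional
#' weather anomaly. At each injected frost event the series receives a
#' warm spell (elevated temperatures for the configured number of days
#' within Sep 15 - Oct 15) followed by a 1-3 day cold snap whose window
#' minimum is forced at least `snap_depth` SD below the climatology of
#' annual Oct 1 - Nov 15 minima. `tmin <= tmean` holds everywhere.
#' Deterministic given `params$seed`.
#'
#' @param params A [simulation_params()].
#' @param region Region index (1-based).
#' @param events Event list; defaults to none (the full network generator
#'   draws and shares one list across modalities).
#' @return List with `stations` (two [station_daily()]) and `snaps`
#'   (year and first snap day of each injected frost).
#' @export
simulate_daily_temperature <- function(params, region, events = list()) {
  set.seed((params$seed + region * 7919L) %% .Machine$integer.max)
  sim_region_daily(params, region, events)
}

# monthly aggregates consistent with the daily series; precipitation is
# simulated independently (seasonal gamma), halved over the growing
# season in drought years. RNG must be seeded.
sim_region_monthly <- function(p, stations, drought_years) {
  comp <- composite_daily(stations)
  ym <- format(comp$date, "%Y-%m")
  tm <- tapply(comp$tmean, ym, mean)
  yy <- as.integer(substr(names(tm), 1, 4))
  mm <- as.integer(substr(names(tm), 6, 7))
  temp <- monthly_series(yy, mm, as.numeric(tm), "temp")
  mu <- p$precip_base +
    p$precip_seasonal * (1 + cos(2 * pi * (mm - 6.5) / 12))
  prec_vals <- rgamma(length(mu), shape = p$precip_shape,
                      scale = mu / p$precip_shape)
  for (y in drought_years) {
    dry <- (yy == y & mm >= 10L) | (yy == y + 1L & mm <= 3L)
    prec_vals[dry] <- prec_vals[dry] * 0.45
  }
  prec <- monthly_series(yy, mm, prec_vals, "prec")
  list(temp = temp, prec = prec)
}

# ring-width engine for one region (both networks); RNG must be seeded
sim_region_widths <- function(p, r, events) {
  years <- sim_years(p)
  n <- p$n_years
  regional <- ar1_path(n, p$regional_sd, p$phi)
  regional_ctrl <- p$control_cor * regional +
    sqrt(max(0, 1 - p$control_cor^2)) * ar1_path(n, p$regional_sd, p$phi)

  gen_site <- function(code, n_trees, reg_sig) {
    site_sig <- ar1_path(n, p$site_sd, p$phi)
    cols <- list()
    for (tr in seq_len(n_trees)) {
      tree_sig <- ar1_path(n, p$tree_sd, p$phi)
      for (co in seq_len(p$cores_per_tree)) {
        a <- runif(1, p$age_a[1], p$age_a[2])
        b <- runif(1, p$age_b[1], p$age_b[2])
        cc <- runif(1, p$age_c[1], p$age_c[2])
        age <- a * exp(-b * seq_len(n)) + cc
        cols[[sprintf("T%02d%s", tr, letters[co])]] <-
          age * exp(reg_sig + site_sig + tree_sig)
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- years
    mat
  }

  target <- lapply(target_site_codes(p, r), gen_site,
                   n_trees = p$trees_per_site, reg_sig = regional)
  names(target) <- target_site_codes(p, r)
  control <- lapply(control_site_codes(p, r), gen_site,
                    n_trees = p$control_trees_per_site,
                    reg_sig = regional_ctrl)
  names(control) <- control_site_codes(p, r)

  # events are applied after all random draws, so a run with events is
  # pairable against a no-event run under the same seed
  for (e in events) {
    if (e$region != region_name(r)) next
    i <- match(e$year, years)
    if (is.na(i)) next
    fac <- 1 - e$reduction
    if (e$type == "frost") {
      for (s in intersect(e$sites, names(target)))
        target[[s]][i, ] <- target[[s]][i, ] * fac
    } else {
      for (s in names(target)) target[[s]][i, ] <- target[[s]][i, ] * fac
      for (s in names(control)) control[[s]][i, ] <- control[[s]][i, ] * fac
    }
  }
  list(target = lapply(names(target), function(s)
         ring_width_set(target[[s]], years, s, species = "target")),
       control = lapply(names(control), function(s)
         ring_width_set(control[[s]], years, s, species = "control")))
}

#' Simulate the ring-width sets of one region
#'
#' Generates the deciduous target and evergreen control stands of a
#' region under the multiplicative model described in
#' [simulation_params()]. Deterministic given `params$seed`; injected
#' events modify the widths after all random draws, so runs with and
#' without events are exactly paired.
#'
#' @param params A [simulation_params()].
#' @param region Region index.
#' @param events Event list (default none).
#' @return List with named lists `target` and `control` of
#'   [ring_width_set()]s.
#' @export
simulate_ring_widths <- function(params, region, events = list()) {
  set.seed((params$seed + region * 104729L) %% .Machine$integer.max)
  out <- sim_region_widths(params, region, events)
  names(out$target) <- vapply(out$target, `[[`, "", "site_code")
  names(out$control) <- vapply(out$control, `[[`, "", "site_code")
  out
}

#' Simulate a full multi-region study system
#'
#' Draws (or takes) the injected-event list, then generates for every
#' region the daily temperatures of two stations, monthly climate
#' consistent with the daily series, and the ring widths of both
#' networks, together with a ground-truth table of the injected events
#' and a ready-to-use [detection_config()]. All randomness derives from
#' `params$seed`; identical parameters give bit-identical output.
#'
#' The generated configuration lists the injected frost years as
#' documented frost records (the synthetic analogue of orchard damage
#' archives) and uses November temperature (positive) and November
#' precipitation (negative) as each region's fallback key variables.
#'
#' @param params A [simulation_params()].
#' @return Object of class `frost_simulation`: list with `target` and
#'   `control` (named [ring_width_set()] lists across all regions),
#'   `stations` (region -> list of two [station_daily()]), `monthly`
#'   (region -> `temp`/`prec` [monthly_series()]), `truth` (data frame of
#'   injected events incl. realized snap day-of-year), `config`, and
#'   `params`.
#' @export
simulate_network <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed %% .Machine$integer.max)
  events <- params$events %||% draw_events(params)

  target <- list(); control <- list()
  stations <- list(); monthly <- list()
  snaps <- data.frame(region = character(), year = integer(),
                      snap_doy = integer())
  for (r in seq_len(params$n_regions)) {
    rn <- region_name(r)
    day <- sim_region_daily(params, r, events)
    stations[[rn]] <- day$stations
    if (nrow(day$snaps))
      snaps <- rbind(snaps, cbind(region = rn, day$snaps))
    drought_years <- vapply(Filter(function(e)
      e$type == "drought" && e$region == rn, events), `[[`, 0, "year")
    monthly[[rn]] <- sim_region_monthly(params, day$stations,
                                        drought_years)
    w <- sim_region_widths(params, r, events)
    for (rw in w$target) target[[rw$site_code]] <- rw
    for (rw in w$control) control[[rw$site_code]] <- rw
  }

  truth <- do.call(rbind, lapply(events, function(e) data.frame(
    type = e$type, region = e$region, year = e$year,
    sites = paste(e$sites, collapse = ";"),
    reduction = e$reduction,
    snap_depth = if (e$type == "frost") e$snap_depth else NA_real_,
    warm_spell_days = if (e$type == "frost" && isTRUE(e$warm_spell))
      e$warm_spell_days else 0L)))
  if (is.null(truth))
    truth <- data.frame(type = character(), region = character(),
                        year = integer(), sites = character(),
                        reduction = numeric(), snap_depth = numeric(),
                        warm_spell_days = integer())
  truth <- merge(truth, snaps, by = c("region", "year"), all.x = TRUE)
  truth <- truth[order(truth$year), , drop = FALSE]
  rownames(truth) <- NULL

  regions <- setNames(lapply(seq_len(params$n_regions), function(r)
    list(sites = target_site_codes(params, r),
         control_sites = control_site_codes(params, r),
         stations = station_ids(r))),
    region_name(seq_len(params$n_regions)))
  frost_by_region <- lapply(regions, function(x) integer())
  for (e in events)
    if (e$type == "frost")
      frost_by_region[[e$region]] <-
        sort(c(frost_by_region[[e$region]], e$year))
  fallback <- lapply(regions, function(x)
    list(list(variable = "temp", season = "prev", month = 11L, sign = 1),
         list(variable = "prec", season = "prev", month = 11L,
              sign = -1)))
  config <- detection_config(
    regions = regions,
    documented_frost_years = frost_by_region,
    fallback_variables = fallback)

  structure(list(target = target, control = control, stations = stations,
                 monthly = monthly, truth = truth, config = config,
                 params = params, events = events),
            class = "frost_simulation")
}

#' @export
print.frost_simulation <- function(x, ...) {
  cat("Synthetic frost study system:", x$params$n_regions, "region(s),",
      length(x$target), "target sites,", length(x$control),
      "control sites,", x$params$n_years, "years\n")
  cat("Injected events:\n")
  print(x$truth, row.names = FALSE)
  invisible(x)
}

#' Score a reconstruction against the generator's ground truth
#'
#' Compares a [reconstruct_events()] result with the truth table of the
#' [simulate_network()] run that produced its inputs. An injected frost
#' counts as recovered when at least one of its affected site-years is
#' reconstructed at low uncertainty or validated; event rows at those
#' levels that match no injected frost site-year are spurious; droughts
#' are misclassified when any of their region-years reaches better than
#' medium confidence.
#'
#' @param rec A `frost_reconstruction`.
#' @param sim The `frost_simulation` it was run on.
#' @return List with `n_frost`, `frost_recovered`, `n_drought`,
#'   `drought_better_than_medium`, `spurious_low`, and `site_years`
#'   (number of site-years evaluated).
#' @export
score_reconstruction <- function(rec, sim) {
  ev <- rec$events
  good <- ev$confidence %in% c("validated", "low")
  fr <- sim$truth[sim$truth$type == "frost", , drop = FALSE]
  fr_sites <- strsplit(fr$sites, ";", fixed = TRUE)
  recovered <- vapply(seq_len(nrow(fr)), function(i)
    any(good & ev$year == fr$year[i] & ev$site %in% fr_sites[[i]]),
    logical(1))
  dr <- sim$truth[sim$truth$type == "drought", , drop = FALSE]
  drought_bad <- vapply(seq_len(nrow(dr)), function(i)
    any(good & ev$year == dr$year[i] & ev$region == dr$region[i]),
    logical(1))
  is_true_frost <- vapply(seq_len(nrow(ev)), function(j)
    any(ev$year[j] == fr$year &
          vapply(fr_sites, function(s) ev$site[j] %in% s, logical(1))),
    logical(1))
  list(n_frost = nrow(fr), frost_recovered = sum(recovered),
       n_drought = nrow(dr),
       drought_better_than_medium = sum(drought_bad),
       spurious_low = sum(good & !is_true_frost),
       site_years = nrow(rec$criteria))
}
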