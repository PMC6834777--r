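test_that("the generator is deterministic under a fixed seed", {
  p <- small_params(seed = 13L)
  s1 <- simulate_network(p)
  s2 <- simulate_network(p)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$target[["r1s1"]]$widths, s2$target[["r1s1"]]$widths)
  expect_identical(s1$stations$R1[[1]]$tmin, s2$stations$R1[[1]]$tmin)
  expect_identical(s1$monthly$R2$prec$value, s2$monthly$R2$prec$value)

  s3 <- simulate_network(small_params(seed = 14L))
  expect_false(identical(s1$target[["r1s1"]]$widths,
                         s3$target[["r1s1"]]$widths))
})

test_that("with zero noise the daily series is the pure seasonal cycle", {
  p <- small_params(weather_sd = 0, station_sd = 0, diurnal_sd = 0)
  day <- simulate_daily_temperature(p, 1, events = list())
  st <- day$stations[[1]]
  doy <- as.POSIXlt(st$date)$yday + 1
  cycle <- p$temp_mean + p$seasonal_amp * cos(2 * pi * (doy - 15) / 365.25)
  expect_equal(st$tmean, cycle, tolerance = 1e-12)
  expect_equal(st$tmin, cycle - p$diurnal_range, tolerance = 1e-12)
  expect_identical(st$tmean, day$stations[[2]]$tmean)
})

test_that("with zero signal and noise every core is exactly its age
           curve", {
  p <- small_params(regional_sd = 0, site_sd = 0, tree_sd = 0)
  w <- simulate_ring_widths(p, 1, events = list())
  mat <- w$target[["r1s1"]]$widths
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    expect_true(all(x > 0))
    expect_true(all(diff(x) < 0))          # monotone decreasing
    expect_true(all(diff(diff(x)) > -1e-12))  # convex decay
  }
})

test_that("injected events scale widths exactly against a paired
           no-event run", {
  p <- small_params(seed = 21L)
  frost <- list(list(type = "frost", region = "R1", year = 1988L,
                     sites = c("r1s2"), reduction = 0.5, snap_depth = 2.5,
                     snap_length = 2L, warm_spell_days = 8L,
                     warm_anom = 4, warm_spell = TRUE))
  drought <- list(list(type = "drought", region = "R1", year = 1988L,
                       sites = paste0("r1s", 1:3), reduction = 0.3))
  base <- simulate_ring_widths(p, 1, events = list())
  wf <- simulate_ring_widths(p, 1, events = frost)
  wd <- simulate_ring_widths(p, 1, events = drought)
  i <- match(1988L, base$target[["r1s2"]]$years)

  # frost: affected site halves in the event year, all else identical
  expect_equal(wf$target[["r1s2"]]$widths[i, ],
               base$target[["r1s2"]]$widths[i, ] * 0.5,
               tolerance = 1e-12)
  expect_identical(wf$target[["r1s2"]]$widths[-i, ],
                   base$target[["r1s2"]]$widths[-i, ])
  expect_identical(wf$target[["r1s1"]]$widths,
                   base$target[["r1s1"]]$widths)
  expect_identical(wf$control[["r1c1"]]$widths,
                   base$control[["r1c1"]]$widths)

  # drought: both networks reduced in the event year
  expect_equal(wd$target[["r1s1"]]$widths[i, ],
               base$target[["r1s1"]]$widths[i, ] * 0.7,
               tolerance = 1e-12)
  expect_equal(wd$control[["r1c1"]]$widths[i, ],
               base$control[["r1c1"]]$widths[i, ] * 0.7,
               tolerance = 1e-12)
})

test_that("the injected cold snap reaches its promised depth", {
  p <- small_params(seed = 31L)
  mk_frost <- function(depth) list(
    list(type = "frost", region = "R1", year = 1995L,
         sites = "r1s1", reduction = 0.5, snap_depth = depth,
         snap_length = 2L, warm_spell_days = 8L,
         warm_anom = 4, warm_spell = TRUE))
  base <- simulate_daily_temperature(p, 1, events = list())
  withf <- simulate_daily_temperature(p, 1, events = mk_frost(2.5))
  # a 4 SD snap is colder than the expected minimum of ~70 annual
  # window minima, so that year must be the coldest on record; at 2.5 SD
  # only the depth guarantee itself is a sound assertion
  deep <- simulate_daily_temperature(p, 1, events = mk_frost(4))
  yrs <- frostdendro:::sim_years(p)
  for (s in 1:2) {
    win_min <- function(day, y)
      min(day$stations[[s]]$tmin[match(window_dates(y, c("10-01", "11-15")),
                                       day$stations[[s]]$date)])
    mins_base <- vapply(yrs, win_min, 0, day = base)
    # guaranteed postcondition: at least snap_depth SD below climatology
    expect_lte(win_min(withf, 1995L),
               mean(mins_base) - 2.5 * sd(mins_base) + 1e-9)
    mins_deep <- vapply(yrs, win_min, 0, day = deep)
    expect_equal(which.min(mins_deep), which(yrs == 1995L))
    expect_true(all(withf$stations[[s]]$tmin <=
                      withf$stations[[s]]$tmean))
  }
})

test_that("monthly temperature is the exact mean of the month's daily
           composite", {
  sim <- simulate_network(small_params(seed = 41L))
  comp <- composite_daily(sim$stations$R1)
  tm <- sim$monthly$R1$temp
  for (ym in list(c(1950L, 7L), c(1987L, 11L), c(2010L, 1L))) {
    sel <- as.integer(format(comp$date, "%Y")) == ym[1] &
      as.integer(format(comp$date, "%m")) == ym[2]
    expect_equal(tm$value[tm$year == ym[1] & tm$month == ym[2]],
                 mean(comp$tmean[sel]), tolerance = 1e-12)
  }
})

test_that("the truth table enumerates exactly the injected events", {
  sim <- simulate_network(small_params(seed = 51L))
  p <- sim$params
  expect_equal(nrow(sim$truth), p$n_frost + p$n_drought)
  expect_equal(sum(sim$truth$type == "frost"), p$n_frost)
  expect_true(all(!is.na(sim$truth$snap_doy[sim$truth$type == "frost"])))
  expect_true(all(is.na(sim$truth$snap_doy[sim$truth$type == "drought"])))
  # documented frost records in the generated config match the truth
  fr <- sim$truth[sim$truth$type == "frost", ]
  for (r in names(sim$config$documented_frost_years))
    expect_setequal(sim$config$documented_frost_years[[r]],
                    fr$year[fr$region == r])
})

test_that("invalid generator parameters are rejected", {
  expect_error(simulation_params(n_years = 50), ">= 60")
  expect_error(simulation_params(phi = 1), "\\[0, 1\\)")
  expect_error(simulation_params(frost_reduction = c(0.2, 1.2)), "\\(0, 1\\)")
  expect_error(simulation_params(snap_length = 5), "1-3")
})

test_that("with no injected events the detector stays near-silent", {
  sim <- simulate_network(small_params(seed = 61L, events = list()))
  rec <- reconstruct_events(sim$target, sim$control, sim$stations,
                            sim$monthly, sim$config)
  n_low <- sum(rec$events$confidence %in% c("validated", "low"))
  # false-positive control: at most 1 low-uncertainty row per 100
  # site-years
  expect_lte(n_low / nrow(rec$criteria), 1 / 100)
})

test_that("raising the injected reduction never loses detection
           criteria", {
  mk_events <- function(red) list(
    list(type = "frost", region = "R1", year = 1992L,
         sites = c("r1s1", "r1s2"), reduction = red, snap_depth = 2.5,
         snap_length = 2L, warm_spell_days = 8L, warm_anom = 4,
         warm_spell = TRUE))
  crit_count <- function(red) {
    sim <- simulate_network(small_params(seed = 71L,
                                         events = mk_events(red)))
    rec <- reconstruct_events(sim$target, sim$control, sim$stations,
                              sim$monthly, sim$config)
    cm <- rec$criteria
    rows <- cm[cm$year == 1992 & cm$site %in% c("r1s1", "r1s2"), ]
    sum(vapply(c("c1", "c2", "c3", "c4", "c5", "a1", "a2"),
               function(f) sum(vapply(rows[[f]], isTRUE, TRUE)), 0L))
  }
  expect_gte(crit_count(0.55), crit_count(0.25))
})
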