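test_that("local growth reductions standardize against the reference
           and use a strict threshold", {
  ys <- 1950:1970
  # reference 1950-1954 difference values (1, 1, 2, 3, 3): mean 2, SD
  # exactly 1, so threshold arithmetic is exact in floating point
  d <- rep(2, length(ys))
  d[1:5] <- c(1, 1, 2, 3, 3)
  reg <- fake_regional("R", ys, rep(1, length(ys)))
  mk_site <- function(dd) fake_chron("s", ys, 1 + dd)

  d[ys == 1960] <- 2 - 1.5 * 1       # z exactly -1.5: NOT flagged
  d[ys == 1961] <- 0                 # z = -2: flagged
  out <- local_growth_reductions(mk_site(d), reg,
                                 ref_period = c(1950, 1954))
  expect_equal(out$z[out$year == 1961], -2)
  expect_true(out$flag[out$year == 1961])
  expect_equal(out$z[out$year == 1960], -1.5)
  expect_false(out$flag[out$year == 1960])
  expect_false(any(out$flag[!out$year %in% 1961]))

  # site identical to the regional mean: zero SD is an error, not silence
  expect_error(local_growth_reductions(mk_site(rep(2, length(ys))), reg,
                                       ref_period = c(1950, 1960)),
               "zero reference-period SD")
})

test_that("C1 is invariant to adding a constant to every chronology", {
  set.seed(71)
  ys <- 1945:2000
  base <- rnorm(length(ys), 1, 0.08)
  site <- fake_chron("s", ys, base + rnorm(length(ys), 0, 0.1))
  reg <- fake_regional("R", ys, base)
  a <- local_growth_reductions(site, reg)
  site2 <- site; site2$index <- site2$index + 0.37
  reg2 <- reg; reg2$index <- reg2$index + 0.37
  b <- local_growth_reductions(site2, reg2)
  expect_equal(a$z, b$z, tolerance = 1e-10)
  expect_identical(a$flag, b$flag)
})

test_that("Cropper values match an exhaustive brute-force oracle", {
  # hand series, window 5, edges truncated to the series span
  x <- c(1.2, 0.9, 1.1, 0.4, 1.3, 1.0, 0.8, 1.5, 1.1, 0.95)
  m <- matrix(x, dimnames = list(2001:2010, "s"))
  cv <- cropper_values(m, window = 5)
  oracle <- rep(NA_real_, 10)
  for (t in 1:10) {
    win <- max(1, t - 2):min(10, t + 2)
    oracle[t] <- (x[t] - mean(x[win])) / sd(x[win])
  }
  expect_equal(unname(cv[, 1]), oracle, tolerance = 1e-12)

  # constant series: zero-SD convention gives 0, not NaN
  mc <- matrix(1, 10, 1, dimnames = list(2001:2010, "c"))
  expect_equal(unname(cropper_values(mc)[, 1]), rep(0, 10))

  # antisymmetry around zero
  set.seed(3)
  z <- rnorm(20)
  mz <- matrix(z, dimnames = list(1981:2000, "z"))
  mzn <- matrix(-z, dimnames = list(1981:2000, "z"))
  expect_equal(cropper_values(mz), -cropper_values(mzn),
               tolerance = 1e-12)
})

test_that("Cropper values respect series support inside a ragged matrix", {
  m <- matrix(NA_real_, 10, 2, dimnames = list(2001:2010, c("a", "b")))
  m[1:10, 1] <- sin(1:10)
  m[4:10, 2] <- cos(4:10)
  cv <- cropper_values(m, window = 5)
  # series b starts in 2004: its first value uses the 2004-2006 window
  w <- m[4:6, 2]
  expect_equal(cv[4, 2], (m[4, 2] - mean(w)) / sd(w), tolerance = 1e-12)
  expect_true(all(is.na(cv[1:3, 2])))
})

test_that("pointer years require a strict majority of strong negative
           deviations", {
  yrs <- 2001:2003
  mk <- function(n_below, n_total) {
    m <- matrix(0.1, length(yrs), n_total,
                dimnames = list(yrs, paste0("s", seq_len(n_total))))
    m[2, seq_len(n_below)] <- -0.9
    m
  }
  out6 <- pointer_years(mk(6, 10))
  expect_true(out6$pointer[2])            # 6/10 passes
  out5 <- pointer_years(mk(5, 10))
  expect_false(out5$pointer[2])           # 5/10 is not a strict majority
  outall <- pointer_years(mk(10, 10))
  expect_true(outall$pointer[2])
  # a Cropper value exactly at -0.5 does not count as below threshold
  m <- mk(6, 10); m[2, 1:6] <- -0.5
  expect_false(pointer_years(m)$pointer[2])
  # below the minimum sample the year is not evaluable, distinct from FALSE
  out4 <- pointer_years(mk(4, 4))
  expect_true(is.na(out4$pointer[2]))
  expect_false(out4$evaluable[2])
})

test_that("control-species reductions flag strictly below -1.5 SD", {
  set.seed(17)
  ys <- 1950:2003
  x <- rnorm(length(ys), 1, 0.05)
  x[ys == 1991] <- 0.6              # deep regional reduction
  ctl <- fake_regional("R", ys, x)
  out <- control_reduction_years(ctl)
  # oracle: direct standardization over the full reference period
  z_bf <- (x - mean(x)) / sd(x)
  expect_equal(out$z, z_bf, tolerance = 1e-12)
  expect_identical(out$reduced, z_bf < -1.5)
  expect_true(out$reduced[out$year == 1991])
})

test_that("criteria integrate into the published confidence lattice", {
  # eliminatory gates: no row without C1, C2 and C5
  expect_equal(nrow(integrate_criteria(cm_row(c1 = FALSE))), 0L)
  expect_equal(nrow(integrate_criteria(cm_row(c2 = FALSE))), 0L)
  expect_equal(nrow(integrate_criteria(cm_row(c5 = FALSE))), 0L)

  # no additional criterion met: high uncertainty even with C3, C4 fine
  ev <- integrate_criteria(cm_row())
  expect_equal(as.character(ev$confidence), "high")

  # pointer year but adverse December precipitation: medium + annotation
  ev <- integrate_criteria(cm_row(a1 = TRUE, a1_frac = 0.7, c4 = FALSE,
                                  c4_notes = "high PDec"))
  expect_equal(as.character(ev$confidence), "medium")
  expect_equal(ev$co_drivers, "high PDec")

  # all criteria plus documentation: validated
  ev <- integrate_criteria(cm_row(a2 = TRUE, a2_z = 2.2),
                           documented = list(R1 = c(1980L)))
  expect_equal(as.character(ev$confidence), "validated")

  # same without documentation: low
  ev <- integrate_criteria(cm_row(a2 = TRUE, a2_z = 2.2))
  expect_equal(as.character(ev$confidence), "low")

  # control reduction downgrades by default ...
  ev <- integrate_criteria(cm_row(a1 = TRUE, c3 = FALSE))
  expect_equal(as.character(ev$confidence), "medium")
  expect_equal(ev$co_drivers, "EG")
  # ... but only annotates under the looser reading
  ev <- integrate_criteria(cm_row(a1 = TRUE, c3 = FALSE),
                           c3_downgrades = FALSE)
  expect_equal(as.character(ev$confidence), "low")
  expect_equal(ev$co_drivers, "EG")

  # without the additional-criterion requirement, C1-C5 alone give low
  ev <- integrate_criteria(cm_row(), require_additional = FALSE)
  expect_equal(as.character(ev$confidence), "low")

  # a not-evaluable pointer criterion (NA) counts as not met, not as met
  ev <- integrate_criteria(cm_row(a1 = NA))
  expect_equal(as.character(ev$confidence), "high")
})

test_that("switching any criterion from fail to pass never lowers the
           confidence level", {
  rank_of <- function(cm) {
    ev <- integrate_criteria(cm, documented = list(R1 = 1980L))
    if (nrow(ev) == 0L) return(0L)
    match(as.character(ev$confidence),
          rev(confidence_levels()))  # high=1 ... validated=4
  }
  flags <- c("c1", "c2", "c3", "c4", "c5", "a1", "a2")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(combos) <- flags
  for (i in seq_len(nrow(combos))) {
    args <- as.list(combos[i, ])
    base_rank <- rank_of(do.call(cm_row, args))
    for (f in flags[!unlist(combos[i, ])]) {
      args2 <- args; args2[[f]] <- TRUE
      expect_gte(rank_of(do.call(cm_row, args2)), base_rank)
    }
  }
})

test_that("the full pipeline recovers an injected frost and rejects
           drought and outbreak years", {
  ev_list <- list(
    list(type = "frost", region = "R1", year = 1990L,
         sites = c("r1s1", "r1s2"), reduction = 0.5, snap_depth = 3,
         snap_length = 2L, warm_spell_days = 8L, warm_anom = 4,
         warm_spell = TRUE),
    list(type = "frost", region = "R1", year = 1975L,
         sites = c("r1s3"), reduction = 0.5, snap_depth = 3,
         snap_length = 2L, warm_spell_days = 8L, warm_anom = 4,
         warm_spell = TRUE),
    list(type = "drought", region = "R2", year = 1984L,
         sites = paste0("r2s", 1:3), reduction = 0.45))
  sim <- simulate_network(small_params(seed = 4L, events = ev_list))
  cfg <- sim$config
  cfg$outbreak_years <- list(R1 = 1975L, R2 = integer())
  rec <- reconstruct_events(sim$target, sim$control, sim$stations,
                            sim$monthly, cfg)
  ev <- rec$events

  # the severe 1990 frost passes every eliminatory gate and at least one
  # additional criterion at both affected sites
  cm <- rec$criteria
  hit <- cm[cm$year == 1990 & cm$site %in% c("r1s1", "r1s2"), ]
  expect_equal(nrow(hit), 2L)
  expect_true(all(hit$c1 & hit$c2 & hit$c5))
  expect_true(all(hit$a1 | hit$a2))

  # so it surfaces in the event table above the weakest level; only a
  # co-driver annotation (the C3/C4 screens, which by design also react
  # to coincidental climate anomalies) may hold it below low
  got <- ev[ev$year == 1990 & ev$site %in% c("r1s1", "r1s2"), ]
  expect_equal(nrow(got), 2L)
  expect_true(all(got$confidence %in% c("validated", "low", "medium")))
  downgraded <- got$confidence == "medium"
  expect_true(all(nzchar(got$co_drivers[downgraded])))

  # where it reaches low/validated, the pinpointed day falls inside the
  # injected snap (either of its equally cold days)
  snap <- sim$truth$snap_doy[sim$truth$year == 1990]
  best <- got[got$confidence %in% c("validated", "low"), ]
  if (nrow(best))
    expect_true(all(best$pinpoint_doy %in% (snap + 0:1)))

  # the 1975 candidate is suppressed by the outbreak record (Criterion 5)
  expect_false(any(ev$year == 1975 & ev$site == "r1s3"))

  # the drought year never reaches low or validated confidence
  dr <- ev[ev$year == 1984 & ev$region == "R2", ]
  expect_false(any(dr$confidence %in% c("validated", "low")))

  # determinism: a second run is identical
  rec2 <- reconstruct_events(sim$target, sim$control, sim$stations,
                             sim$monthly, cfg)
  expect_identical(rec$events, rec2$events)
})

test_that("unknown sites in the configuration are an error", {
  sim <- simulate_network(small_params(seed = 6L, events = list()))
  cfg <- sim$config
  cfg$regions$R1$sites <- c(cfg$regions$R1$sites, "ghost")
  expect_error(reconstruct_events(sim$target, sim$control, sim$stations,
                                  sim$monthly, cfg),
               "unknown site")
})
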