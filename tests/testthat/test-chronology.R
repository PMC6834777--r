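test_that("constant-width cores yield an index identically 1", {
  years <- 1951:2010
  m <- matrix(1, 60, 4, dimnames = list(years, paste0("c", 1:4)))
  rw <- ring_width_set(m, years, "flat")
  ch <- build_site_chronology(rw)
  expect_equal(ch$index, rep(1, 60), tolerance = 1e-10)
  expect_equal(ch$depth, setNames(rep(4L, 60), years), ignore_attr = TRUE)
})

test_that("a pure negative-exponential series detrends to 1", {
  t <- 1:80
  w <- 2 * exp(-0.05 * t) + 0.5
  # step-1 curve fit alone recovers the generating parameters
  r1 <- frostdendro:::neg_exp_curve(w)$ratio
  expect_lt(max(abs(r1 - 1)), 1e-3)
  # full detrend + prewhiten: index flat at 1
  idx <- detrend_series(w)
  expect_lt(max(abs(idx - 1), na.rm = TRUE), 1e-3)
  expect_lt(sd(idx, na.rm = TRUE), 0.01)
})

test_that("detrending is invariant to rescaling the raw widths", {
  set.seed(101)
  t <- 1:70
  w <- (1.5 * exp(-0.03 * t) + 0.4) * exp(rnorm(70, 0, 0.2))
  i1 <- detrend_series(w)
  # powers of two rescale exactly in floating point: bit-identical index
  expect_identical(detrend_series(w * 2), i1)
  # non-dyadic factors perturb the curve fit at rounding level only
  expect_equal(detrend_series(w * 3.7), i1, tolerance = 1e-8)
})

test_that("site chronology of a single series equals that series' index", {
  set.seed(5)
  years <- 1941:2010
  w <- matrix((2 * exp(-0.04 * (1:70)) + 0.3) * exp(rnorm(70, 0, 0.15)),
              dimnames = list(years, "solo"))
  rw <- ring_width_set(w, years, "one")
  ch <- build_site_chronology(rw)
  expect_equal(ch$index, unname(ch$series_indices[, 1]))
  expect_equal(ch$index, detrend_series(w[, 1]))
})

test_that("short series are skipped with a warning; empty sites error", {
  years <- 1981:2010
  m <- cbind(long = runif(30, 0.5, 1.5),
             short = c(rep(NA, 20), runif(10, 0.5, 1.5)))
  rownames(m) <- years
  rw <- ring_width_set(m, years, "mix")
  expect_warning(ch <- build_site_chronology(rw, min_years = 15),
                 "skipping 1 series")
  expect_equal(colnames(ch$series_indices), "long")
  m2 <- m[, "short", drop = FALSE]
  expect_error(suppressWarnings(
    build_site_chronology(ring_width_set(m2, years, "tiny"))),
    "shorter than")
})

test_that("chronology statistics match brute-force computation", {
  set.seed(33)
  years <- 1961:2000
  m <- exp(matrix(rnorm(200, 0, 0.2), 40, 5)) *
    matrix(rep(runif(5, 0.8, 1.5), each = 40), 40, 5)
  shared <- rnorm(40, 0, 0.25)
  m <- m * exp(shared)          # common signal so rbar > 0
  dimnames(m) <- list(years, paste0("s", 1:5))
  rw <- ring_width_set(m, years, "bf")
  idx <- m  # treat the raw matrix as the index matrix for the oracle
  st <- chronology_stats(rw, indices = idx)

  # rbar: exhaustive loop over the 10 pairs
  prs <- combn(5, 2)
  rbar_bf <- mean(apply(prs, 2, function(p) cor(idx[, p[1]], idx[, p[2]])))
  expect_equal(st$rbar, rbar_bf, tolerance = 1e-12)
  expect_equal(st$rbt, rbar_bf, tolerance = 1e-12)  # same matrix here

  # EPS: Wigley closed form with N = mean sample depth (= 5, complete)
  expect_equal(st$EPS, 5 * rbar_bf / (5 * rbar_bf + 1 - rbar_bf),
               tolerance = 1e-12)
  expect_equal(st$N, 5)

  # MS and AC1: per-series formula loops
  ms_bf <- mean(sapply(1:5, function(j) {
    x <- m[, j]
    mean(2 * abs(diff(x)) / (x[-40] + x[-1]))
  }))
  ac1_bf <- mean(sapply(1:5, function(j) cor(m[-40, j], m[-1, j])))
  expect_equal(st$MS, ms_bf, tolerance = 1e-12)
  expect_equal(st$AC1, ac1_bf, tolerance = 1e-12)
})

test_that("EPS limits, undefined cases, and monotonicity hold", {
  expect_equal(eps_from_rbar(0, 10), 0)
  expect_equal(eps_from_rbar(1, 10), 1)
  expect_true(is.na(eps_from_rbar(NA, 10)))

  # 10 identical series: rbar = 1, EPS = 1
  set.seed(9)
  base <- exp(rnorm(40, 0, 0.2)) + 0.5
  m <- matrix(rep(base, 10), 40, 10,
              dimnames = list(1961:2000, paste0("t", 1:10)))
  st <- chronology_stats(ring_width_set(m, 1961:2000, "same"),
                         indices = m)
  expect_equal(st$rbar, 1)
  expect_equal(st$EPS, 1)

  # fewer than two series: undefined, not zero
  st1 <- chronology_stats(ring_width_set(m[, 1, drop = FALSE],
                                         1961:2000, "one"),
                          indices = m[, 1, drop = FALSE])
  expect_true(is.na(st1$rbar) && is.na(st1$EPS) && is.na(st1$rbt))

  # monotone in N at fixed rbar and in rbar at fixed N
  for (rb in c(0.1, 0.3, 0.6, 0.9)) {
    eps_n <- sapply(c(2, 5, 10, 25, 50), eps_from_rbar, rbar = rb)
    expect_true(all(diff(eps_n) >= 0))
  }
  for (N in c(2, 5, 10, 25)) {
    eps_r <- sapply(c(0.05, 0.2, 0.4, 0.7, 0.95), eps_from_rbar, N = N)
    expect_true(all(diff(eps_r) >= 0))
  }
})

test_that("regional chronology averages sites and honours exclusion", {
  ys <- 1950:1990
  chs <- list(fake_chron("a", ys, rep(0.8, 41)),
              fake_chron("b", ys, rep(1.0, 41)),
              fake_chron("c", ys, rep(1.2, 41)))
  reg <- build_regional_chronology(chs, "R", exclude = "a")
  expect_equal(unique(reg$index), 1.1)

  # perturbing the excluded site leaves the result untouched
  chs2 <- chs
  chs2[[1]]$index <- rnorm(41, 5, 3)
  reg2 <- build_regional_chronology(chs2, "R", exclude = "a")
  expect_identical(reg$index, reg2$index)

  # identical chronologies: the mean is any one of them
  same <- lapply(c("x", "y", "z"), fake_chron, years = ys,
                 index = sin(ys / 3) / 10 + 1)
  expect_equal(build_regional_chronology(same, "R")$index,
               same[[1]]$index)

  expect_error(build_regional_chronology(chs[1], "R"), "at least 2")
  expect_error(build_regional_chronology(chs[1:2], "R", exclude = "a"),
               "at least 2")
})

test_that("regional mean uses only sites present in a year", {
  chs <- list(fake_chron("a", 1950:1980, rep(1, 31)),
              fake_chron("b", 1950:1980, rep(2, 31)),
              fake_chron("c", 1970:1990, rep(3, 21)))
  reg <- build_regional_chronology(chs, "R")
  expect_equal(reg$index[reg$years == 1960], 1.5)
  expect_equal(reg$index[reg$years == 1975], 2)
  expect_equal(reg$index[reg$years == 1985], 3)
})

test_that("PCA separates block-correlated site clusters", {
  set.seed(77)
  ys <- 1900:1991
  sig1 <- rnorm(length(ys)); sig2 <- rnorm(length(ys))
  mk <- function(code, sig) fake_chron(code, ys,
                                       1 + 0.3 * sig + rnorm(length(ys), 0, 0.05))
  chs <- c(lapply(paste0("p", 1:3), mk, sig = sig1),
           lapply(paste0("q", 1:3), mk, sig = sig2))
  out <- pca_regions(chs, period = c(1900, 1991))
  ld <- out$chronology_pca$rotation[, 1:2]
  # the two clusters separate on one of the first two components
  sep <- apply(ld, 2, function(v) all(sign(v[1:3]) == sign(v[1])) &&
                 all(sign(v[4:6]) == sign(v[4])) &&
                 sign(v[1]) != sign(v[4]))
  expect_true(any(sep))

  # near-identical chronologies: PC1 carries ~all variance
  same <- lapply(paste0("s", 1:4), function(cd)
    fake_chron(cd, ys, 1 + 0.3 * sig1 + rnorm(length(ys), 0, 1e-3)))
  p2 <- pca_regions(same)
  expect_gt(summary(p2$chronology_pca)$importance[2, 1], 0.99)

  expect_error(pca_regions(chs, period = c(1900, 1905)), "shorter than")
})
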