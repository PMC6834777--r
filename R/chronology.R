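#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate with biweight weights and a
#' tuning constant of 9 times the median absolute deviation, 10 iterations.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @param C Tuning constant (multiples of the MAD). Default 9.
#' @param iter Number of reweighting iterations.
#' @return The robust mean (`NA` for an empty vector).
#' @export
tukey_biweight_mean <- function(x, C = 9, iter = 10L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- median(x)
  for (i in seq_len(iter)) {
    s <- median(abs(x - m))
    if (s <= 0) return(m)
    u <- (x - m) / (C * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m <- sum(w * x) / sum(w)
  }
  m
}

# Negative-exponential age-trend curve w = a * exp(-b * t) + c with a, b > 0
# and c >= 0, fitted by Levenberg-Marquardt least squares. The series is
# divided by its own mean first, which makes the subsequent index exactly
# invariant to rescaling the raw widths. Falls back to a horizontal
# mean line when the fit fails or the fitted curve is not positive.
neg_exp_curve <- function(w) {
  n <- length(w)
  t <- seq_len(n)
  m <- mean(w)
  if (m <= 0) stop("series mean must be positive for ratio detrending")
  ws <- w / m
  head_m <- mean(ws[seq_len(max(3L, n %/% 10L))])
  tail_m <- mean(ws[seq.int(n - max(3L, n %/% 10L) + 1L, n)])
  c0 <- max(min(ws) * 0.5, 1e-4)
  a0 <- max(head_m - c0, 0.1)
  b0 <- 0.05
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    ws ~ a * exp(-b * t) + c,
    data = list(ws = ws, t = t),
    start = list(a = a0, b = b0, c = c0),
    lower = c(a = 1e-10, b = 1e-10, c = 0),
    upper = c(a = Inf, b = 2, c = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))),
    silent = TRUE)
  curve <- NULL
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    cand <- cf[["a"]] * exp(-cf[["b"]] * t) + cf[["c"]]
    if (cf[["a"]] > 0 && cf[["b"]] > 0 && all(cand > 1e-8) &&
        head_m >= tail_m)
      curve <- cand
  }
  if (is.null(curve)) curve <- rep(1, n)    # horizontal mean-line fallback
  list(ratio = ws / curve, curve = curve * m)
}

# Penalised discrete smoothing-spline curve. lambda is chosen analytically
# so the filter's frequency response is f (default 0.5) at a period of
# `nyrs` years: the second-difference penalty has transfer (2 sin(pi/T))^4,
# hence H(T) = 1 / (1 + lambda (2 sin(pi/T))^4) and
# lambda = ((1-f)/f) / (2 sin(pi/nyrs))^4.
smoothing_spline_curve <- function(y, nyrs = 50, f = 0.5) {
  n <- length(y)
  if (n < 4L) return(rep(mean(y), n))
  lambda <- ((1 - f) / f) / (2 * sin(pi / nyrs))^4
  D <- diff(diag(n), differences = 2L)
  as.numeric(solve(diag(n) + lambda * crossprod(D), y))
}

# AR(p) prewhitening: order selected by AIC (p <= max_order), residuals
# re-centred by adding back the pre-whitening mean so indices stay near 1.
# Leading p values, for which no residual exists, are NA. Constant series
# are returned unchanged.
prewhiten_series <- function(x, max_order = 10L) {
  n <- length(x)
  if (n < 10L || var(x) < 1e-14) return(x)
  ord <- min(max_order, n - 5L, floor(n / 3))
  if (ord < 1L) return(x)
  fit <- try(stats::ar(x, aic = TRUE, order.max = ord,
                       method = "yule-walker"), silent = TRUE)
  if (inherits(fit, "try-error")) return(x)
  if (fit$order == 0L) return(x)
  as.numeric(fit$resid) + mean(x)
}

#' Detrend and prewhiten a single ring-width series
#'
#' Two-step ratio detrending followed by autoregressive prewhitening:
#' (1) divide by a fitted negative-exponential age curve
#' `w = a exp(-b t) + c` (`a, b > 0`; horizontal mean line when the fit
#' fails or is non-decreasing); (2) divide the step-1 ratios by a cubic
#' smoothing spline with a 50% frequency-response cutoff at
#' `spline_length` years; (3) remove the autoregressive structure (order
#' by AIC, at most 10) and re-add the series mean so the residual index is
#' centred near 1.
#'
#' @param w Numeric vector of ring widths (mm), one value per consecutive
#'   year, no gaps.
#' @param spline_length Spline frequency-response cutoff period in years.
#' @param prewhiten Set `FALSE` to stop after the two detrending steps.
#' @return Numeric vector of residual indices (leading values lost to the
#'   AR fit are `NA`).
#' @export
detrend_series <- function(w, spline_length = 50, prewhiten = TRUE) {
  if (any(!is.finite(w))) stop("series must be gap-free")
  r1 <- neg_exp_curve(w)$ratio
  sp <- smoothing_spline_curve(r1, nyrs = spline_length)
  if (any(sp <= 0)) sp <- rep(mean(r1), length(r1))
  r2 <- r1 / sp
  unname(if (prewhiten) prewhiten_series(r2) else r2)
}

#' Build a residual site chronology
#'
#' Detrends and prewhitens every core ([detrend_series()]) and averages
#' the per-series indices across the site with a Tukey biweight robust
#' mean (arithmetic mean where 3 or fewer series are present in a year).
#' Series shorter than `min_years` are skipped with a warning.
#'
#' @param rw A [ring_width_set()].
#' @param spline_length Spline cutoff period in years. Default 50.
#' @param min_years Minimum series length retained. Default 15.
#' @param tree_ids Optional named vector mapping series id to tree id, used
#'   by the between-tree correlation statistic.
#' @return An object of class `site_chronology`: a list with `site_code`,
#'   `years`, `index` (the residual chronology, `NA` where no series has
#'   data), `depth` (series per year), `series_indices` (year x series
#'   index matrix) and `stats` (a [chronology_stats()] row).
#' @export
build_site_chronology <- function(rw, spline_length = 50, min_years = 15L,
                                  tree_ids = NULL) {
  stopifnot(inherits(rw, "ring_width_set"))
  lens <- colSums(!is.na(rw$widths))
  drop <- names(lens)[lens < min_years]
  if (length(drop) == ncol(rw$widths))
    stop("all series of '", rw$site_code, "' are shorter than ",
         min_years, " years")
  if (length(drop))
    warning("site '", rw$site_code, "': skipping ", length(drop),
            " series shorter than ", min_years, " years (",
            paste(drop, collapse = ", "), ")")
  keep <- setdiff(colnames(rw$widths), drop)
  idx <- matrix(NA_real_, nrow(rw$widths), length(keep),
                dimnames = list(rw$years, keep))
  for (id in keep) {
    sup <- which(!is.na(rw$widths[, id]))
    idx[sup, id] <- detrend_series(rw$widths[sup, id], spline_length)
  }
  depth <- rowSums(!is.na(idx))
  index <- rep(NA_real_, length(rw$years))
  for (i in which(depth > 0L)) {
    v <- idx[i, ][is.finite(idx[i, ])]
    index[i] <- if (length(v) > 3L) tukey_biweight_mean(v) else mean(v)
  }
  stats <- chronology_stats(rw, idx, tree_ids = tree_ids)
  structure(list(site_code = rw$site_code, years = rw$years,
                 index = index, depth = depth, series_indices = idx,
                 stats = stats, species = rw$species),
            class = "site_chronology")
}

#' @export
print.site_chronology <- function(x, ...) {
  ok <- which(!is.na(x$index))
  cat("Site chronology '", x$site_code, "': ", ncol(x$series_indices),
      " series, ", x$years[min(ok)], "-", x$years[max(ok)], "\n", sep = "")
  st <- x$stats
  cat(sprintf("  MS %.3f  AC1 %.3f  rbt %s  rbar %s  EPS %s\n", st$MS,
              st$AC1, fmt_or_na(st$rbt), fmt_or_na(st$rbar),
              fmt_or_na(st$EPS)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

# mean pairwise Pearson correlation over columns of a matrix, counting
# only pairs with at least `min_overlap` overlapping years and, when
# `groups` is given, only pairs from different groups (different trees)
mean_pairwise_cor <- function(mat, min_overlap = 20L, groups = NULL) {
  p <- ncol(mat)
  if (p < 2L) return(NA_real_)
  vals <- numeric()
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (!is.null(groups) && groups[i] == groups[j]) next
      ok <- is.finite(mat[, i]) & is.finite(mat[, j])
      if (sum(ok) < min_overlap) next
      if (sd(mat[ok, i]) == 0 || sd(mat[ok, j]) == 0) next
      vals <- c(vals, cor(mat[ok, i], mat[ok, j]))
    }
  }
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

#' Chronology quality statistics
#'
#' Classical dendrochronological descriptors of a site collection:
#' * `MS` -- mean sensitivity of the raw widths, the mean over years of
#'   `2|x_t - x_(t-1)| / (x_t + x_(t-1))`, averaged over series;
#' * `AC1` -- mean lag-1 autocorrelation of the raw width series;
#' * `rbt` -- mean pairwise Pearson correlation of raw widths between
#'   trees (pairs with fewer than `min_overlap` common years skipped);
#' * `rbar` -- mean pairwise correlation among the detrended indices;
#' * `EPS` -- expressed population signal,
#'   `N rbar / (N rbar + 1 - rbar)` with `N` the mean sample depth,
#'   quantifying how closely the finite-sample chronology tracks a
#'   hypothetical infinitely replicated one;
#' * `N` -- mean sample depth over covered years.
#'
#' With fewer than two series, `rbt`, `rbar` and `EPS` are `NA`
#' (undefined), never 0.
#'
#' @param rw A [ring_width_set()].
#' @param indices Year x series matrix of detrended indices (as produced
#'   within [build_site_chronology()]); defaults to detrending `rw`.
#' @param min_overlap Minimum overlapping years per correlation pair.
#' @param tree_ids Optional named map series id -> tree id; same-tree pairs
#'   are excluded from `rbt`.
#' @return One-row data frame with columns `MS`, `AC1`, `rbt`, `rbar`,
#'   `EPS`, `N`.
#' @export
chronology_stats <- function(rw, indices = NULL, min_overlap = 20L,
                             tree_ids = NULL) {
  mat <- rw$widths
  if (is.null(indices)) {
    indices <- mat
    for (id in colnames(mat)) {
      sup <- which(!is.na(mat[, id]))
      indices[sup, id] <- detrend_series(mat[sup, id])
    }
  }
  ms_one <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    mean(2 * abs(diff(x)) / (x[-length(x)] + x[-1L]))
  }
  ac1_one <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3L || sd(x) == 0) return(NA_real_)
    cor(x[-length(x)], x[-1L])
  }
  MS <- mean(apply(mat, 2L, ms_one), na.rm = TRUE)
  AC1 <- mean(apply(mat, 2L, ac1_one), na.rm = TRUE)
  groups <- NULL
  if (!is.null(tree_ids)) groups <- as.character(tree_ids[colnames(mat)])
  rbt <- mean_pairwise_cor(mat, min_overlap, groups)
  rbar <- mean_pairwise_cor(indices, min_overlap, groups = NULL)
  depth <- rowSums(!is.na(indices))
  N <- mean(depth[depth > 0L])
  EPS <- eps_from_rbar(rbar, N)
  data.frame(MS = MS, AC1 = AC1, rbt = rbt, rbar = rbar, EPS = EPS, N = N)
}

#' Expressed population signal from rbar and sample depth
#'
#' `EPS = N rbar / (N rbar + 1 - rbar)`, clamped to `[0, 1]`;
#' non-positive `rbar` yields 0, missing `rbar` yields `NA`.
#'
#' @param rbar Mean inter-series correlation.
#' @param N Mean sample depth.
#' @return EPS in `[0, 1]`.
#' @export
eps_from_rbar <- function(rbar, N) {
  if (is.na(rbar) || is.na(N)) return(NA_real_)
  if (rbar <= 0) return(0)
  min(1, max(0, N * rbar / (N * rbar + 1 - rbar)))
}

#' Build a regional mean chronology
#'
#' Arithmetic mean of site chronology indices, per year, over the sites
#' with data that year, weighting sites equally. When `exclude` is given
#' the named site is omitted entirely, producing the leave-one-out
#' regional reference against which that site's anomalies are judged; the
#' excluded site's data has no influence on the result.
#'
#' @param chronologies Named list of [build_site_chronology()] results (or
#'   a list whose elements carry `site_code`).
#' @param region Region label stored on the result.
#' @param exclude Optional site code to leave out.
#' @return An object of class `regional_chronology` with `region`,
#'   `years`, `index`, `n_sites` (contributing sites per year) and
#'   `sites`.
#' @export
build_regional_chronology <- function(chronologies, region = "region",
                                      exclude = NULL) {
  codes <- vapply(chronologies, function(ch) ch$site_code, character(1))
  names(chronologies) <- codes
  if (!is.null(exclude)) {
    if (!exclude %in% codes)
      stop("excluded site '", exclude, "' is not in the region")
    chronologies <- chronologies[setdiff(codes, exclude)]
  }
  if (length(chronologies) < 2L)
    stop("a regional chronology needs at least 2 contributing sites",
         if (!is.null(exclude)) " after exclusion")
  years <- sort(unique(unlist(lapply(chronologies,
                                     function(ch) ch$years))))
  mat <- matrix(NA_real_, length(years), length(chronologies),
                dimnames = list(years, names(chronologies)))
  for (ch in chronologies)
    mat[match(ch$years, years), ch$site_code] <- ch$index
  n_sites <- rowSums(is.finite(mat))
  index <- ifelse(n_sites > 0L, rowMeans(mat, na.rm = TRUE), NA_real_)
  structure(list(region = region, years = years, index = as.numeric(index),
                 n_sites = n_sites, sites = names(chronologies),
                 excluded = exclude),
            class = "regional_chronology")
}

#' @export
print.regional_chronology <- function(x, ...) {
  cat("Regional chronology '", x$region, "': ", length(x$sites),
      " sites", if (!is.null(x$excluded))
        paste0(" (excluding ", x$excluded, ")"), "\n", sep = "")
  invisible(x)
}

#' Exploratory PCA of site chronologies (and growth-climate profiles)
#'
#' Principal component analysis on the year-by-site matrix of residual
#' chronology indices over their common period, and optionally a second
#' PCA on per-site growth-climate correlation profiles. Used to explore
#' groupings of sites into homogeneous regions; the pipeline never assigns
#' regions automatically -- membership remains a configuration input.
#'
#' @param chronologies Named list of site chronologies.
#' @param profiles Optional site x variable matrix of growth-climate
#'   correlations (e.g. rows of [correlate_growth_climate()] profiles).
#' @param period Optional year range restricting the common period.
#' @param min_years Minimum common-period length. Default 10.
#' @return List with `chronology_pca` (a `prcomp` fit on correlation-scaled
#'   data), `common_period`, and `profile_pca` (or `NULL`).
#' @export
pca_regions <- function(chronologies, profiles = NULL, period = NULL,
                        min_years = 10L) {
  codes <- vapply(chronologies, function(ch) ch$site_code, character(1))
  years <- sort(unique(unlist(lapply(chronologies,
                                     function(ch) ch$years))))
  mat <- matrix(NA_real_, length(years), length(codes),
                dimnames = list(years, codes))
  for (ch in chronologies)
    mat[match(ch$years, years), ch$site_code] <- ch$index
  if (!is.null(period))
    mat <- mat[years >= period[1] & years <= period[2], , drop = FALSE]
  keep <- rowSums(is.finite(mat)) == ncol(mat)
  if (sum(keep) < min_years)
    stop("common period across sites is shorter than ", min_years,
         " years")
  sds <- apply(mat[keep, , drop = FALSE], 2L, sd)
  pca <- prcomp(mat[keep, , drop = FALSE], center = TRUE,
                scale. = all(sds > 0))
  ppca <- NULL
  if (!is.null(profiles)) {
    pm <- as.matrix(profiles)
    ppca <- prcomp(pm, center = TRUE, scale. = all(apply(pm, 2, sd) > 0))
  }
  list(chronology_pca = pca,
       common_period = range(as.integer(rownames(mat)[keep])),
       profile_pca = ppca)
}
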