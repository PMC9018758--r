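# Statistics on cycle tables: lagged amplitude-duration correlations with
# permutation and sign-flip inference, regression de-trending, cycle
# autocorrelations, eigenvalue-sweep regression, the cycle-based amplitude
# spectrum and cycle-frequency variability estimators.

# Extract per-cycle quantity vector and a lag map. Rows of the (channel-
# filtered) cycle table are ordered by epoch and time; cycle i + lag is
# admissible only within the same epoch.
laggedCycleValues <- function(cyc, quantity, lag) {
  v <- cyc[[quantity]]
  n <- nrow(cyc)
  j <- seq_len(n) + lag
  ok <- j >= 1L & j <= n
  out <- rep(NA_real_, n)
  out[ok] <- ifelse(cyc$epoch_id[j[ok]] == cyc$epoch_id[ok], v[j[ok]],
                    NA_real_)
  out
}

cycleSubset <- function(tab, channel, cycleKind) {
  cyc <- if (cycleKind == "half") halfCycles(tab) else fullCycles(tab)
  cyc <- cyc[cyc$channel == channel, , drop = FALSE]
  cyc[order(cyc$trial, cyc$epoch_id, cyc$start_time), , drop = FALSE]
}

#' Lagged correlation between cycle amplitude and duration
#'
#' The instantaneous (lag 0) or lagged Spearman correlation between the
#' amplitude of a cycle and the duration of the cycle shifted by \code{lag}
#' positions within the same oscillatory epoch. Positive lag correlates the
#' current amplitude with a later cycle's duration.
#'
#' Two schemes are supported. \code{"timewise"} (for multi-trial data)
#' correlates across trials separately at each post-onset time point, skips
#' time points with fewer than \code{minTrials} valid trials, and averages
#' the coefficients over time points — this removes the contribution of
#' stimulus-locked time courses. \code{"pooled"} (for single long synthetic
#' realisations without trial structure) correlates across all cycles
#' directly.
#'
#' @param tab a \linkS4class{HalfCycleTable}.
#' @param lag signed integer, in cycles.
#' @param xQuantity,yQuantity cycle columns to correlate (defaults:
#'   amplitude against duration).
#' @param scheme "pooled" or "timewise".
#' @param nSamples time-grid length for the timewise scheme.
#' @param channel channel to analyse.
#' @param cycleKind "half" or "full".
#' @param minTrials minimum valid trials per contributing time point.
#' @param method "spearman" (default) or "pearson".
#' @return one-row data.frame: lag, rho, n_effective (pairs or contributing
#'   time points).
#' @export
cycleLaggedCorrelation <- function(tab, lag = 0L, xQuantity = "amplitude",
                                   yQuantity = "duration",
                                   scheme = c("pooled", "timewise"),
                                   nSamples = NULL, channel = 1L,
                                   cycleKind = c("half", "full"),
                                   minTrials = 2L,
                                   method = c("spearman", "pearson")) {
  scheme <- match.arg(scheme)
  cycleKind <- match.arg(cycleKind)
  method <- match.arg(method)
  cyc <- cycleSubset(tab, channel, cycleKind)
  if (!nrow(cyc)) return(data.frame(lag = lag, rho = NA_real_,
                                    n_effective = 0L))
  x <- cyc[[xQuantity]]
  y <- laggedCycleValues(cyc, yQuantity, lag)
  if (scheme == "pooled") {
    ok <- !is.na(y)
    rho <- if (sum(ok) >= 3L) {
      if (method == "spearman") spearmanRho(x[ok], y[ok])
      else stats::cor(x[ok], y[ok])
    } else NA_real_
    return(data.frame(lag = lag, rho = rho, n_effective = sum(ok)))
  }
  if (is.null(nSamples))
    nSamples <- ceiling(max(cyc$end_time) * samplingRate(tab)) + 1L
  mats <- laggedAssignments(tab, cyc, x, y, nSamples, channel, cycleKind)
  rhos <- timepointCorrelations(mats$x, mats$y, minTrials, method)
  data.frame(lag = lag, rho = mean(rhos, na.rm = TRUE),
             n_effective = sum(!is.na(rhos)))
}

# time x trial matrices of a per-cycle x value and lagged y value.
laggedAssignments <- function(tab, cyc, xvals, yvals, nSamples, channel,
                              cycleKind) {
  asg <- assignCyclesToTimepoints(tab, nSamples, channel, cycleKind)
  cid <- asg$cycle
  # cycle ids index the channel-filtered table in assignCyclesToTimepoints,
  # which uses the original (unsorted) row order; re-map to sorted order.
  orig <- if (cycleKind == "half") halfCycles(tab) else fullCycles(tab)
  orig <- orig[orig$channel == channel, , drop = FALSE]
  key <- paste(orig$trial, orig$epoch_id, orig$start_time)
  sortedKey <- paste(cyc$trial, cyc$epoch_id, cyc$start_time)
  map <- match(key, sortedKey)
  xm <- matrix(NA_real_, nrow(cid), ncol(cid))
  ym <- xm
  valid <- !is.na(cid)
  xm[valid] <- xvals[map[cid[valid]]]
  ym[valid] <- yvals[map[cid[valid]]]
  list(x = xm, y = ym)
}

# Per-time-point across-trial correlations; NA where < minTrials valid.
timepointCorrelations <- function(xm, ym, minTrials, method = "spearman") {
  vapply(seq_len(nrow(xm)), function(t) {
    x <- xm[t, ]; y <- ym[t, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < minTrials) return(NA_real_)
    if (method == "spearman") spearmanRho(x[ok], y[ok])
    else {
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok])
    }
  }, numeric(1))
}

#' Permutation null for the timewise amplitude-duration correlation
#'
#' The order of valid duration values is randomly shuffled across trials,
#' separately for each time point, and the full averaged statistic is
#' recomputed \code{nPerm} times. A Gaussian is fitted to the surrogate
#' statistics by moment matching, and the empirical value is deemed
#' significant when it lies more than \code{sdRule} standard deviations from
#' the surrogate mean (the 3-SD default approximates a two-sided test at
#' p ~ 0.001). Shuffles never mix values across time points.
#'
#' @param tab a \linkS4class{HalfCycleTable} with trial structure.
#' @param lag signed integer lag in cycles.
#' @param nPerm number of permutations (default 1000; below 100 triggers a
#'   warning).
#' @param nSamples time-grid length.
#' @param channel,cycleKind,minTrials as in
#'   \code{\link{cycleLaggedCorrelation}}.
#' @param sdRule significance band half-width in surrogate SDs.
#' @param seed integer seed for the shuffles.
#' @return list: rho, surrogateMean, surrogateSD, significant, surrogates.
#' @export
permutationNull <- function(tab, lag = 0L, nPerm = 1000L, nSamples = NULL,
                            channel = 1L, cycleKind = c("half", "full"),
                            minTrials = 2L, sdRule = 3, seed = NULL) {
  cycleKind <- match.arg(cycleKind)
  if (nPerm < 100L) warning("nPerm < 100 gives an unstable surrogate fit")
  cyc <- cycleSubset(tab, channel, cycleKind)
  if (!nrow(cyc)) stop("empty cycle table")
  x <- cyc$amplitude
  y <- laggedCycleValues(cyc, "duration", lag)
  if (is.null(nSamples))
    nSamples <- ceiling(max(cyc$end_time) * samplingRate(tab)) + 1L
  mats <- laggedAssignments(tab, cyc, x, y, nSamples, channel, cycleKind)
  xm <- mats$x; ym <- mats$y
  # standardized ranks per time point over valid trials
  perTp <- lapply(seq_len(nrow(xm)), function(t) {
    xv <- xm[t, ]; yv <- ym[t, ]
    ok <- which(!is.na(xv) & !is.na(yv))
    n <- length(ok)
    if (n < minTrials) return(NULL)
    zx <- rank(xv[ok]); zy <- rank(yv[ok])
    if (stats::sd(zx) == 0 || stats::sd(zy) == 0) return(NULL)
    zx <- (zx - mean(zx)) / stats::sd(zx)
    zy <- (zy - mean(zy)) / stats::sd(zy)
    list(zx = zx, zy = zy, n = n)
  })
  perTp <- Filter(Negate(is.null), perTp)
  if (!length(perTp)) stop("no time point has >= minTrials valid trials")
  empir <- mean(vapply(perTp, function(p)
    sum(p$zx * p$zy) / (p$n - 1), numeric(1)))
  surr <- withSeed(seed, {
    acc <- matrix(0, nPerm, length(perTp))
    for (j in seq_along(perTp)) {
      p <- perTp[[j]]
      perms <- replicate(nPerm, sample.int(p$n))
      acc[, j] <- as.numeric(crossprod(p$zy[perms] |>
        matrix(nrow = p$n), p$zx)) / (p$n - 1)
    }
    rowMeans(acc)
  })
  mu <- mean(surr); sdv <- stats::sd(surr)
  list(rho = empir, surrogateMean = mu, surrogateSD = sdv,
       significant = abs(empir - mu) > sdRule * sdv, surrogates = surr)
}

#' Exact sign-flip test on per-dataset correlations
#'
#' Enumerates every assignment of signs to the per-dataset correlation
#' values (2^k combinations), forming the exact surrogate distribution of
#' the mean under the null of sign-symmetric values. The empirical mean is
#' compared with the 2.5th/97.5th percentiles, and a two-sided enumeration
#' p-value is returned.
#'
#' @param values numeric vector of per-dataset correlation values
#'   (2 <= length <= 20).
#' @return list: mean, p (two-sided, exact), significant (outside the
#'   2.5-97.5 percentile band), lower, upper.
#' @examples
#' signflipMeanTest(c(0.2, 0.15, 0.3, 0.22, 0.18, 0.25))$p  # = 2/2^6
#' @export
signflipMeanTest <- function(values) {
  k <- length(values)
  if (k < 2L) stop("need at least 2 datasets")
  if (k > 20L) stop("exact enumeration capped at 20 datasets")
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  means <- as.numeric(signs %*% values) / k
  emp <- mean(values)
  pUp <- mean(means >= emp - 1e-15)
  pDn <- mean(means <= emp + 1e-15)
  p <- min(1, 2 * min(pUp, pDn))
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 1)
  list(mean = emp, p = p, significant = emp > q[2L] || emp < q[1L],
       lower = q[1L], upper = q[2L])
}

#' Correlation of regression residuals of amplitude and duration
#'
#' Removes slower dynamics by regressing, separately for amplitude and for
#' duration, the value of the ongoing half-cycle on the values of the
#' previous and next half-cycle (ordinary least squares), then correlating
#' the two residual series. In the timewise scheme the regression and
#' correlation are computed across trials per time point; in the pooled
#' scheme across all interior cycles.
#'
#' @inheritParams cycleLaggedCorrelation
#' @return one-row data.frame: lag (0), rho, n_effective. Degenerate time
#'   points (collinear neighbors, zero residual variance) are skipped.
#' @export
regressionResidualCorrelation <- function(tab, scheme = c("pooled",
                                                          "timewise"),
                                          nSamples = NULL, channel = 1L,
                                          cycleKind = c("half", "full"),
                                          minTrials = 4L) {
  scheme <- match.arg(scheme)
  cycleKind <- match.arg(cycleKind)
  cyc <- cycleSubset(tab, channel, cycleKind)
  if (nrow(cyc) < 3L)
    return(data.frame(lag = 0L, rho = NA_real_, n_effective = 0L))
  residPair <- function(prev, cur, nxt) {
    X <- cbind(1, prev, nxt)
    if (qr(X)$rank < 3L) return(NULL)
    stats::lm.fit(X, cur)$residuals
  }
  aPrev <- laggedCycleValues(cyc, "amplitude", -1L)
  aNext <- laggedCycleValues(cyc, "amplitude", 1L)
  dPrev <- laggedCycleValues(cyc, "duration", -1L)
  dNext <- laggedCycleValues(cyc, "duration", 1L)
  inner <- !is.na(aPrev) & !is.na(aNext)
  if (scheme == "pooled") {
    sel <- which(inner)
    if (length(sel) < 5L)
      return(data.frame(lag = 0L, rho = NA_real_, n_effective = 0L))
    ra <- residPair(aPrev[sel], cyc$amplitude[sel], aNext[sel])
    rd <- residPair(dPrev[sel], cyc$duration[sel], dNext[sel])
    if (is.null(ra) || is.null(rd) || stats::sd(ra) == 0 ||
        stats::sd(rd) == 0)
      return(data.frame(lag = 0L, rho = NA_real_, n_effective = 0L))
    return(data.frame(lag = 0L, rho = spearmanRho(ra, rd),
                      n_effective = length(sel)))
  }
  if (is.null(nSamples))
    nSamples <- ceiling(max(cyc$end_time) * samplingRate(tab)) + 1L
  ampMats <- laggedAssignments(tab, cyc,
                               ifelse(inner, cyc$amplitude, NA_real_),
                               cyc$duration, nSamples, channel, cycleKind)
  # per-cycle matrices for the neighbor values
  nb <- lapply(list(aPrev, aNext, dPrev, dNext), function(v)
    laggedAssignments(tab, cyc, v, v, nSamples, channel, cycleKind)$x)
  rhos <- vapply(seq_len(nrow(ampMats$x)), function(t) {
    cur <- ampMats$x[t, ]; dcur <- ampMats$y[t, ]
    ok <- which(!is.na(cur) & !is.na(nb[[1L]][t, ]) &
                !is.na(nb[[2L]][t, ]) & !is.na(dcur))
    if (length(ok) < minTrials) return(NA_real_)
    ra <- residPair(nb[[1L]][t, ok], cur[ok], nb[[2L]][t, ok])
    rd <- residPair(nb[[3L]][t, ok], dcur[ok], nb[[4L]][t, ok])
    if (is.null(ra) || is.null(rd) || stats::sd(ra) == 0 ||
        stats::sd(rd) == 0) return(NA_real_)
    spearmanRho(ra, rd)
  }, numeric(1))
  data.frame(lag = 0L, rho = mean(rhos, na.rm = TRUE),
             n_effective = sum(!is.na(rhos)))
}

#' Cycle amplitude/duration autocorrelation over lags
#'
#' Lagged Spearman autocorrelation of a per-cycle quantity, with the same
#' pooled/timewise schemes as \code{\link{cycleLaggedCorrelation}}. Epochs
#' too short for a requested lag simply contribute no pairs at that lag.
#'
#' @inheritParams cycleLaggedCorrelation
#' @param quantity "amplitude" or "duration".
#' @param lags integer vector of lags (default -10:10).
#' @return data.frame with one row per lag: lag, rho, n_effective.
#' @export
cycleAutocorrelation <- function(tab, quantity = c("amplitude", "duration"),
                                 lags = -10:10,
                                 scheme = c("pooled", "timewise"),
                                 nSamples = NULL, channel = 1L,
                                 cycleKind = c("half", "full"),
                                 minTrials = 2L) {
  quantity <- match.arg(quantity)
  scheme <- match.arg(scheme)
  cycleKind <- match.arg(cycleKind)
  do.call(rbind, lapply(lags, function(L)
    cycleLaggedCorrelation(tab, L, xQuantity = quantity,
                           yQuantity = quantity, scheme = scheme,
                           nSamples = nSamples, channel = channel,
                           cycleKind = cycleKind, minTrials = minTrials)))
}

#' Least-squares regression of correlations on eigenvalue magnitudes
#'
#' @param x eigenvalue magnitudes (>= 3 values with nonzero variance).
#' @param y per-dataset correlation values.
#' @return list: slope, intercept.
#' @export
eigenSweepRegression <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}

#' Cycle-based amplitude spectrum (CBAS)
#'
#' Converts cycle durations to frequencies, bins them on a grid aligned to
#' the Fourier-spectral gamma peak (offset 0 = peak), and returns the mean
#' amplitude and the incidence count per bin within +-\code{range} Hz of the
#' peak. Empty interior bins are filled by linear interpolation between
#' their occupied neighbors.
#'
#' @param tab a \linkS4class{HalfCycleTable}.
#' @param gammaPeak peak gamma frequency from the Fourier power spectrum of
#'   the same data, Hz.
#' @param binWidth Hz (default 1).
#' @param range half-range around the peak, Hz (default 20).
#' @param channel,cycleKind as elsewhere.
#' @return data.frame: offset_hz, frequency, mean_amplitude, count,
#'   interpolated (logical).
#' @export
cbas <- function(tab, gammaPeak, binWidth = 1, range = 20, channel = 1L,
                 cycleKind = c("half", "full")) {
  cycleKind <- match.arg(cycleKind)
  cyc <- cycleSubset(tab, channel, cycleKind)
  if (!nrow(cyc)) stop("empty cycle table")
  off <- round((cyc$frequency - gammaPeak) / binWidth)
  sel <- abs(off * binWidth) <= range
  off <- off[sel]; amp <- cyc$amplitude[sel]
  grid <- seq(-round(range / binWidth), round(range / binWidth))
  meanAmp <- vapply(grid, function(g) {
    v <- amp[off == g]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  counts <- vapply(grid, function(g) sum(off == g), numeric(1))
  interp <- is.na(meanAmp)
  occ <- which(!is.na(meanAmp))
  if (length(occ) >= 2L) {
    inner <- seq(min(occ), max(occ))
    na <- inner[is.na(meanAmp[inner])]
    if (length(na)) {
      meanAmp[na] <- stats::approx(occ, meanAmp[occ], xout = na)$y
      counts[na] <- stats::approx(occ, counts[occ], xout = na)$y
    }
  }
  data.frame(offset_hz = grid * binWidth,
             frequency = gammaPeak + grid * binWidth,
             mean_amplitude = meanAmp, count = counts,
             interpolated = interp & !is.na(meanAmp))
}

#' Cycle-frequency variability estimators
#'
#' Standard deviation of the gamma-cycle frequency distribution by several
#' estimators: \code{"gaussian_fit"} — SD of a Gaussian fitted to the
#' frequency distribution by maximum likelihood (for a Gaussian this is the
#' sample SD; preferred because cycle durations are quantised at the
#' sampling rate, which turns finely binned histograms into combs that
#' defeat curve fitting); \code{"gaussian_ls"} — SD of a Gaussian
#' least-squares-fitted to the binned frequency histogram with free mean,
#' SD and scale, retained for comparison; \code{"pairs_bessel"} — the variance
#' of each adjacent cycle pair (with Bessel's correction, i.e.
#' \code{(f1 - f2)^2 / 2}), averaged and square-rooted;
#' \code{"triplets_debias"} — the pair-style variance of each middle cycle
#' against the mean of its two neighbors, multiplied by the analytic debias
#' factor 2/3 (the raw triplet statistic overestimates the variance by 3/2
#' on independent cycles), averaged and square-rooted. The pair/triplet
#' estimators are insensitive to slow drift in the mean frequency; the
#' Gaussian fit is not.
#'
#' @param frequencies per-cycle frequencies, Hz (in epoch order; pairs and
#'   triplets use adjacent elements).
#' @param method estimator.
#' @param binWidth histogram bin width for the Gaussian fit, Hz.
#' @return SD estimate in Hz.
#' @export
frequencyVariability <- function(frequencies,
                                 method = c("gaussian_fit", "gaussian_ls",
                                            "pairs_bessel",
                                            "triplets_debias"),
                                 binWidth = 1) {
  method <- match.arg(method)
  f <- frequencies[is.finite(frequencies)]
  if (method == "gaussian_fit") {
    if (length(f) < 2L) stop("need >= 2 cycles for a Gaussian fit")
    return(sqrt(mean((f - mean(f))^2)))   # ML estimate
  }
  if (method == "pairs_bessel") {
    if (length(f) < 2L) stop("need >= 2 cycles for the pair estimator")
    d <- diff(f)
    return(sqrt(mean(d^2 / 2)))
  }
  if (method == "triplets_debias") {
    if (length(f) < 3L) stop("need >= 3 cycles for the triplet estimator")
    n <- length(f)
    mid <- 2:(n - 1L)
    dev <- f[mid] - (f[mid - 1L] + f[mid + 1L]) / 2
    return(sqrt(mean(dev^2) * 2 / 3))
  }
  # gaussian_ls: least squares on binned counts
  if (length(f) < 10L) stop("too few cycles for a histogram fit")
  if (stats::sd(f) == 0) return(0)
  brks <- seq(floor(min(f)) - binWidth / 2, ceiling(max(f)) + binWidth,
              by = binWidth)
  h <- graphics::hist(f, breaks = brks, plot = FALSE)
  xc <- h$mids; yc <- h$counts
  obj <- function(p) {
    mu <- p[1L]; s <- exp(p[2L]); a <- exp(p[3L])
    sum((a * exp(-(xc - mu)^2 / (2 * s^2)) - yc)^2)
  }
  init <- c(mean(f), log(stats::sd(f)), log(max(yc)))
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  exp(opt$par[2L])
}
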