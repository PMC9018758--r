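# Power spectra, time-frequency analysis, the AR(2) analytic spectrum and
# its least-squares fit, high-order AR surrogates, and the phase-plane
# density.

#' Averaged tapered power spectrum
#'
#' Cuts every trial into consecutive non-overlapping epochs of
#' \code{epochLength} seconds, tapers each epoch (Hann by default;
#' rectangular for fitting, where minimal spectral smearing matters),
#' computes periodograms and averages across epochs and trials. Power is a
#' one-sided density: \code{sum(power) * df} equals the signal variance
#' (Parseval) up to taper normalisation.
#'
#' @param rec a \linkS4class{ContinuousRecording} or a numeric matrix of
#'   epochs (columns).
#' @param epochLength epoch length in seconds (sets the Rayleigh resolution
#'   1/epochLength).
#' @param taper "hann" or "rectangular".
#' @param channel channel to analyse when \code{rec} is a recording.
#' @param samplingRate required when \code{rec} is a plain matrix.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' rec <- simulateAR(ar2FromEigen(0.95, 50, 1000), 8000, seed = 2)
#' sp <- powerSpectrum(rec, epochLength = 1, taper = "rectangular")
#' @export
powerSpectrum <- function(rec, epochLength = 1,
                          taper = c("hann", "rectangular"), channel = 1L,
                          samplingRate = NULL) {
  taper <- match.arg(taper)
  if (is(rec, "ContinuousRecording")) {
    fs <- samplingRate(rec)
    epSamp <- round(epochLength * fs)
    s <- samples(rec)
    if (dim(s)[1L] < epSamp) stop("epoch longer than the trial")
    mats <- lapply(seq_len(dim(s)[2L]),
                   function(tr) asEpochMatrix(s[, tr, channel], epSamp))
    em <- do.call(cbind, mats)
  } else {
    if (is.null(samplingRate)) stop("samplingRate required for matrix input")
    fs <- samplingRate
    em <- as.matrix(rec)
    epochLength <- nrow(em) / fs
  }
  pg <- epochPeriodogram(em, fs, taper)
  new("Spectrum", frequencies = pg$frequencies[-1L], power = pg$power[-1L],
      taper = taper, epochLength = epochLength, samplingRate = fs)
}

#' Baseline-normalise a spectrum
#'
#' Relative power change: \code{(stim - base) / base} per frequency.
#'
#' @param stim,base \linkS4class{Spectrum}s on identical frequency grids.
#' @return A dimensionless \linkS4class{Spectrum}.
#' @export
baselineNormalize <- function(stim, base) {
  if (!isTRUE(all.equal(stim@frequencies, base@frequencies)))
    stop("frequency grids differ")
  if (any(base@power <= 0)) stop("baseline power must be positive everywhere")
  new("Spectrum", frequencies = stim@frequencies,
      power = (stim@power - base@power) / base@power,
      taper = stim@taper, epochLength = stim@epochLength,
      samplingRate = stim@samplingRate)
}

#' Time-frequency representation
#'
#' Sliding-window tapered power per frequency, with a window of
#' \code{windowCycles} cycles of each frequency (i.e. +-windowCycles/2
#' around the window center) slid in steps of \code{stepSec}.
#'
#' @param x numeric signal vector.
#' @param samplingRate Hz.
#' @param frequencies Hz vector.
#' @param windowCycles total window length in cycles of each frequency
#'   (default 5, i.e. +-2.5 cycles).
#' @param stepSec slide step in seconds (default 0.001).
#' @param taper "hann" or "rectangular".
#' @return list with \code{time} (s, window centers), \code{frequencies},
#'   and \code{power} (time x frequency matrix).
#' @export
tfr <- function(x, samplingRate, frequencies, windowCycles = 5,
                stepSec = 0.001, taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  n <- length(x)
  step <- max(1L, round(stepSec * samplingRate))
  maxLen <- round(windowCycles / min(frequencies) * samplingRate)
  if (maxLen > n) stop("lowest frequency window does not fit in the trial")
  centers <- seq(ceiling(maxLen / 2), n - ceiling(maxLen / 2), by = step)
  P <- matrix(NA_real_, length(centers), length(frequencies))
  for (fi in seq_along(frequencies)) {
    f <- frequencies[fi]
    L <- round(windowCycles / f * samplingRate)
    w <- if (taper == "hann")
      0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L)) else rep(1, L)
    w <- w / sqrt(sum(w^2))
    carrier <- exp(-2i * pi * f * (0:(L - 1L)) / samplingRate) * w
    half <- floor(L / 2)
    for (ci in seq_along(centers)) {
      i0 <- centers[ci] - half
      if (i0 < 1L || i0 + L - 1L > n) next
      P[ci, fi] <- Mod(sum(x[i0:(i0 + L - 1L)] * carrier))^2
    }
  }
  list(time = (centers - 1L) / samplingRate, frequencies = frequencies,
       power = P)
}

# S(f) evaluated at frequencies in Hz; f is converted to cycles/sample.
ar2SpectrumValues <- function(params, freqHz) {
  f <- freqHz / params@samplingRate
  den <- 1 + params@phi1^2 + params@phi2^2 -
    2 * params@phi1 * (1 - params@phi2) * cos(2 * pi * f) -
    2 * params@phi2 * cos(4 * pi * f)
  if (any(den <= 0)) stop("non-positive spectral denominator (non-stationary?)")
  params@sigmaZ^2 / den
}

#' Analytic AR(2) power spectrum
#'
#' Evaluates
#' \deqn{S(f) = \sigma_z^2 / (1 + \phi_1^2 + \phi_2^2
#'   - 2\phi_1(1-\phi_2)\cos(2\pi f) - 2\phi_2 \cos(4\pi f))}
#' with f in cycles per sample (Hz input is divided by the sampling rate).
#'
#' @param params an \linkS4class{AR2Params}.
#' @param frequencies Hz, below Nyquist.
#' @return A \linkS4class{Spectrum}.
#' @export
ar2Spectrum <- function(params, frequencies) {
  if (any(frequencies < 0) || any(frequencies > params@samplingRate / 2))
    stop("frequencies must lie in [0, Nyquist]")
  new("Spectrum", frequencies = frequencies,
      power = ar2SpectrumValues(params, frequencies),
      taper = "rectangular", epochLength = NA_real_,
      samplingRate = params@samplingRate)
}

#' Fit an AR(2) spectrum to an empirical power spectrum
#'
#' Minimises the squared error between the analytic AR(2) spectrum S(f) and
#' the empirical spectrum over the fit band, using derivative-free
#' Nelder-Mead simplex iterations multi-started from a coarse grid over
#' eigenvalue magnitude and peak frequency. The innovation variance is
#' profiled out analytically by default (the least-squares-optimal
#' \code{sigma_z^2} given the shape is available in closed form), or fitted
#' as a free parameter.
#'
#' @param spectrum a \linkS4class{Spectrum} (rectangular taper recommended
#'   for minimal leakage).
#' @param fitBand two-element Hz range; default the spectral peak +- 20 Hz.
#' @param profileSigma profile the innovation variance analytically
#'   (default) rather than optimising it as a third free parameter.
#' @return An \linkS4class{AR2Model}; non-oscillatory (real-eigenvalue)
#'   degenerate fits are flagged via a warning and carry \code{NA} peak
#'   frequency.
#' @examples
#' sp <- ar2Spectrum(ar2FromEigen(0.99, 50, 2035), seq(20, 90, 0.5))
#' fitAR2(sp)
#' @export
fitAR2 <- function(spectrum, fitBand = NULL, profileSigma = TRUE) {
  fs <- spectrum@samplingRate
  if (is.null(fitBand)) {
    pk <- spectrum@frequencies[which.max(spectrum@power)]
    fitBand <- c(max(pk - 20, min(spectrum@frequencies)),
                 min(pk + 20, max(spectrum@frequencies)))
  }
  sel <- spectrum@frequencies >= fitBand[1L] &
         spectrum@frequencies <= fitBand[2L]
  if (sum(sel) < 4L) stop("fit band contains fewer than 4 spectral bins")
  f <- spectrum@frequencies[sel]
  y <- spectrum@power[sel]
  shape <- function(m, f0) {
    p <- ar2FromEigen(m, f0, fs, sigmaZ = 1)
    ar2SpectrumValues(p, f)
  }
  clampUnit <- function(u) pmin(pmax(u, 1e-8), 1 - 1e-8)
  sse <- function(par) {
    m <- clampUnit(stats::plogis(par[1L]))
    f0 <- fs / 2 * clampUnit(stats::plogis(par[2L]))
    g <- shape(m, f0)
    if (profileSigma) {
      s2 <- sum(y * g) / sum(g^2)
      if (s2 <= 0) return(sum(y^2))
      sum((s2 * g - y)^2)
    } else {
      s2 <- exp(par[3L])
      sum((s2 * g - y)^2)
    }
  }
  grid <- expand.grid(m = c(0.9, 0.95, 0.97, 0.99, 0.995),
                      f0 = seq(max(min(f), 1), max(f),
                               length.out = 5L))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    p0 <- c(stats::qlogis(grid$m[i]), stats::qlogis(2 * grid$f0[i] / fs))
    if (!profileSigma) p0 <- c(p0, log(max(mean(y), 1e-12)))
    opt <- stats::optim(p0, sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  m <- clampUnit(stats::plogis(best$par[1L]))
  f0 <- fs / 2 * clampUnit(stats::plogis(best$par[2L]))
  g <- shape(m, f0)
  s2 <- if (profileSigma) sum(y * g) / sum(g^2) else exp(best$par[3L])
  params <- ar2FromEigen(m, f0, fs, sigmaZ = sqrt(max(s2, 0)))
  # degenerate fits: the complex-pair parameterisation cannot produce real
  # eigenvalues, so degeneracy shows up as |lambda| -> 0 or an essentially
  # flat fitted spectrum over the band
  if (m < 0.5 || max(g) / min(g) < 1.5)
    warning("fit is non-oscillatory (|lambda| -> 0 or flat spectrum)")
  ar2ModelFromParams(params, fitError = best$value)
}

#' Fit a high-order AR surrogate model
#'
#' Least-squares (Yule-Walker) AR(p) fit pooled across all trials; the
#' returned coefficients are generator-ready for \code{\link{simulateAR}},
#' so a surrogate simulation reproduces the data's power spectrum while
#' destroying slower non-stationary structure.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param order AR order (the analyses this supports use 50-100).
#' @param channel channel to fit.
#' @return list with \code{coefficients} (length \code{order}),
#'   \code{sigmaZ}, and \code{order}.
#' @export
fitARp <- function(rec, order = 50L, channel = 1L) {
  s <- samples(rec)
  if (dim(s)[1L] <= 10L * order)
    warning("few samples relative to the AR order; fit may be unstable")
  # pooled Yule-Walker: average autocovariance across trials
  acfs <- lapply(seq_len(dim(s)[2L]), function(tr) {
    stats::acf(s[, tr, channel], lag.max = order, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  })
  g <- Reduce(`+`, acfs) / length(acfs)
  G <- stats::toeplitz(g[seq_len(order)])
  rhs <- g[2:(order + 1L)]
  phi <- solve(G, rhs)
  s2 <- g[1L] - sum(phi * rhs)
  roots <- polyroot(c(1, -phi))
  if (any(1 / Mod(roots) >= 1)) {
    # shrink toward stationarity (rare, ill-conditioned fits)
    shrink <- 0.99 / max(1 / Mod(roots))
    phi <- phi * shrink^(seq_along(phi))
  }
  list(coefficients = as.numeric(phi), sigmaZ = sqrt(max(s2, 0)),
       order = order)
}

#' Phase-plane density of the analytic signal
#'
#' z-scores the real and imaginary components of the analytic signal and
#' returns their joint 2-D histogram. Noise-driven damped oscillators show a
#' single central focus; a constant-amplitude sinusoid shows a ring.
#'
#' @param x numeric signal (high-pass filtered; for field potentials above
#'   ~10 Hz).
#' @param nbins grid size per axis (default 61 over +-3 z).
#' @param zlim half-range in z units.
#' @return list with \code{density} (nbins x nbins, z-scored counts...
#'   normalised to sum 1), \code{breaks}, and \code{centers}.
#' @export
phasePlaneDensity <- function(x, nbins = 61L, zlim = 3) {
  if (stats::sd(x) == 0) stop("degenerate (constant) signal")
  a <- analyticSignal(x)
  re <- as.numeric(scale(Re(a)))
  im <- as.numeric(scale(Im(a)))
  brks <- seq(-zlim, zlim, length.out = nbins + 1L)
  bx <- cut(re, brks, include.lowest = TRUE)
  by <- cut(im, brks, include.lowest = TRUE)
  tab <- table(bx, by)
  list(density = unclass(tab) / sum(tab), breaks = brks,
       centers = (brks[-1L] + brks[-length(brks)]) / 2)
}
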