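#' Generate 1/f^n colored noise
#'
#' Draws Gaussian white noise per trace, Fourier transforms it, multiplies the
#' positive-frequency coefficients by \code{1/f^n}, rebuilds a Hermitian
#' spectrum by concatenating the conjugated, reversed coefficients, and
#' inverse transforms. Because amplitude coefficients are scaled by
#' \code{1/f^n}, the power spectrum falls as \code{1/f^(2n)}. The DC
#' coefficient is set to zero, so every trace has exactly zero mean.
#'
#' @param exponent spectral slope n of the amplitude shaping, in [0, 4];
#'   n = 0 is white noise, n = 1 Brownian-like power (1/f^2).
#' @param nSamples samples per trace (>= 2).
#' @param nTraces number of independent traces (trials).
#' @param samplingRate Hz.
#' @param seed integer seed; the generator is bit-reproducible.
#' @return A \linkS4class{ContinuousRecording} (time x trial x 1).
#' @examples
#' rec <- generateColoredNoise(1, 4096, nTraces = 2, seed = 1)
#' @export
generateColoredNoise <- function(exponent, nSamples, nTraces = 1L,
                                 samplingRate = 1000, seed = NULL) {
  if (!is.finite(exponent) || exponent < 0 || exponent > 4)
    stop("exponent must be finite and in [0, 4]")
  if (nSamples < 2L) stop("nSamples must be >= 2")
  n <- as.integer(nSamples)
  npos <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L
  fpos <- seq_len(npos) * samplingRate / n
  gain <- 1 / fpos^exponent
  out <- withSeed(seed, {
    sapply(seq_len(nTraces), function(i) {
      W <- stats::fft(stats::rnorm(n))
      X <- complex(length.out = n)
      X[1L] <- 0                      # zero-mean by construction
      X[1L + seq_len(npos)] <- W[1L + seq_len(npos)] * gain
      if (n %% 2L == 0L) {
        fny <- samplingRate / 2
        X[n / 2L + 1L] <- Re(W[n / 2L + 1L]) / fny^exponent
      }
      X[n + 1L - seq_len(npos)] <- Conj(X[1L + seq_len(npos)])
      Re(stats::fft(X, inverse = TRUE)) / n
    })
  })
  ContinuousRecording(matrix(out, nrow = n), samplingRate)
}

#' AR(2) coefficients from eigenvalue magnitude and peak frequency
#'
#' For complex-conjugate eigenvalues \code{m exp(+-i 2 pi f0 / fs)} the
#' coefficients are \code{phi1 = 2 m cos(2 pi f0 / fs)} and
#' \code{phi2 = -m^2}. The eigenvalue magnitude m sets the damping (m -> 1 is
#' an ever stronger, narrower-band oscillation); f0 is the rotation frequency
#' of the eigenvalues, which is within a fraction of a Hz of the spectral
#' peak for weak damping.
#'
#' @param magnitude eigenvalue modulus, in (0, 1).
#' @param peakFreq rotation/peak frequency in Hz, below Nyquist.
#' @param samplingRate Hz.
#' @param sigmaZ innovation SD.
#' @return An \linkS4class{AR2Params}.
#' @examples
#' ar2FromEigen(0.987, 50, 2035)
#' @export
ar2FromEigen <- function(magnitude, peakFreq, samplingRate, sigmaZ = 1) {
  if (!is.finite(magnitude) || magnitude <= 0 || magnitude >= 1)
    stop("magnitude must lie in (0, 1): |lambda| >= 1 is non-stationary")
  if (peakFreq <= 0 || peakFreq >= samplingRate / 2)
    stop("peakFreq must lie strictly below the Nyquist frequency")
  AR2Params(phi1 = 2 * magnitude * cos(2 * pi * peakFreq / samplingRate),
            phi2 = -magnitude^2, sigmaZ = sigmaZ,
            samplingRate = samplingRate)
}

#' Eigenvalue summary of AR(2) parameters
#'
#' @param params an \linkS4class{AR2Params}.
#' @param fitError optional SSE to record (used by \code{\link{fitAR2}}).
#' @return An \linkS4class{AR2Model} with eigenvalues, magnitude and the
#'   analytic spectral peak frequency (dense-grid argmax of
#'   \code{\link{ar2Spectrum}} for oscillatory parameters).
#' @export
ar2ModelFromParams <- function(params, fitError = NA_real_) {
  ev <- ar2Eigenvalues(params@phi1, params@phi2)
  oscillatory <- params@phi1^2 + 4 * params@phi2 < 0
  if (oscillatory) {
    fgrid <- seq(0.1, params@samplingRate / 2 - 0.1, length.out = 8192L)
    S <- ar2SpectrumValues(params, fgrid)
    pf <- fgrid[which.max(S)]
  } else pf <- NA_real_
  new("AR2Model", params = params, eigenvalues = ev,
      eigenvalueMagnitude = if (oscillatory) sqrt(-params@phi2)
                            else max(Mod(ev)),
      peakFrequency = pf, fitError = fitError)
}

#' Simulate an autoregressive process
#'
#' Iterates \code{x[t] = sum_k phi_k x[t-k] + eps[t]} with Gaussian
#' innovations, discarding an initial burn-in so the output is (numerically)
#' stationary. Accepts \linkS4class{AR2Params} or a raw coefficient vector of
#' any order.
#'
#' @param params \linkS4class{AR2Params}, or a numeric vector of AR
#'   coefficients (phi_1 ... phi_p).
#' @param nSamples output samples per trace.
#' @param nTraces number of independent traces.
#' @param seed integer seed.
#' @param burnIn samples discarded before the output window; default
#'   \code{ceiling(20 / (1 - maxMod))} where maxMod is the largest eigenvalue
#'   modulus, which exceeds the envelope autocorrelation time.
#' @param sigmaZ innovation SD (ignored when \code{params} is AR2Params).
#' @param samplingRate Hz (ignored when \code{params} is AR2Params).
#' @return A \linkS4class{ContinuousRecording}.
#' @examples
#' rec <- simulateAR(ar2FromEigen(0.95, 50, 1000), 2000, seed = 1)
#' @export
simulateAR <- function(params, nSamples, nTraces = 1L, seed = NULL,
                       burnIn = NULL, sigmaZ = 1, samplingRate = 1000) {
  if (is(params, "AR2Params")) {
    phi <- c(params@phi1, params@phi2)
    sigmaZ <- params@sigmaZ
    samplingRate <- params@samplingRate
  } else phi <- as.numeric(params)
  p <- length(phi)
  if (p) {
    roots <- polyroot(c(1, -phi))          # 1 - phi1 z - ... = 0, z = 1/lambda
    maxMod <- max(1 / Mod(roots))
    if (maxMod >= 1)
      stop("non-stationary AR coefficients (eigenvalue modulus >= 1)")
  } else maxMod <- 0
  if (is.null(burnIn)) burnIn <- ceiling(20 / (1 - maxMod))
  ntot <- as.integer(nSamples + burnIn)
  out <- withSeed(seed, {
    sapply(seq_len(nTraces), function(i) {
      eps <- stats::rnorm(ntot, sd = sigmaZ)
      x <- if (p) as.numeric(stats::filter(eps, phi, method = "recursive"))
           else eps
      x[(burnIn + 1L):ntot]
    })
  })
  ContinuousRecording(matrix(out, nrow = nSamples), samplingRate)
}

#' Simulate a linear stochastic E-I circuit
#'
#' Iterates the two-population linear difference system
#' \code{E[t] = vEE E[t-1] + vEI I[t-1] + epsE[t]},
#' \code{I[t] = vIE E[t-1] + vII I[t-1] + epsI[t]}, with the innovation
#' stream shared between the rows or drawn independently according to
#' \code{weights@noiseShared}. Requires spectral radius of V below one.
#'
#' @param weights an \linkS4class{EIWeights}.
#' @param nSamples output samples.
#' @param seed integer seed.
#' @param samplingRate Hz recorded on the output.
#' @param burnIn discarded initial samples (default scaled by the spectral
#'   radius as in \code{\link{simulateAR}}).
#' @param innovations optional matrix (nSamples + burnIn) x 2 of innovation
#'   values (columns E, I) overriding random generation; used for exact
#'   co-simulation against an AR(2).
#' @return list with numeric vectors \code{E}, \code{I} and the
#'   \code{samplingRate}.
#' @export
simulateEICircuit <- function(weights, nSamples, seed = NULL,
                              samplingRate = 1000, burnIn = NULL,
                              innovations = NULL) {
  V <- eiMatrix(weights)
  rad <- max(Mod(eigen(V, only.values = TRUE)$values))
  if (rad >= 1) stop("spectral radius of V must be < 1")
  if (is.null(burnIn)) burnIn <- ceiling(20 / (1 - rad))
  ntot <- as.integer(nSamples + burnIn)
  if (is.null(innovations)) {
    innovations <- withSeed(seed, {
      if (weights@noiseShared) {
        e <- stats::rnorm(ntot, sd = weights@noiseSD); cbind(e, e)
      } else matrix(stats::rnorm(2L * ntot, sd = weights@noiseSD), ncol = 2L)
    })
  } else {
    if (nrow(innovations) < ntot)
      stop("innovations must have at least nSamples + burnIn rows")
  }
  E <- numeric(ntot); I <- numeric(ntot)
  E[1L] <- innovations[1L, 1L]; I[1L] <- innovations[1L, 2L]
  for (t in 2:ntot) {
    E[t] <- V[1L, 1L] * E[t - 1L] + V[1L, 2L] * I[t - 1L] + innovations[t, 1L]
    I[t] <- V[2L, 1L] * E[t - 1L] + V[2L, 2L] * I[t - 1L] + innovations[t, 2L]
  }
  keep <- (burnIn + 1L):ntot
  list(E = E[keep], I = I[keep], samplingRate = samplingRate)
}

#' Simulate inhomogeneous Poisson spikes modulated by a drive signal
#'
#' Spike times are drawn from an inhomogeneous Poisson process with
#' rate \code{lambda(t) = link(baseRate + gain * e(t))}, where \code{e} is the
#' modulating (e.g. excitatory-population) signal. The identity-rectified
#' link clips negative rates to zero; the exponential link uses
#' \code{baseRate * exp(gain * e(t))}.
#'
#' @param eSignal numeric drive series.
#' @param samplingRate Hz of \code{eSignal}.
#' @param baseRate baseline rate, Hz (>= 0).
#' @param gain modulation depth (Hz per drive unit for the rectified link,
#'   per-unit log-rate for the exponential link).
#' @param link "rectified" or "exponential".
#' @param nUnits number of independent units.
#' @param seed integer seed.
#' @param trial trial index stored on the spikes.
#' @return A \linkS4class{SpikeTrainSet}; times are uniform within their
#'   source sample bin.
#' @export
simulateModulatedSpikes <- function(eSignal, samplingRate, baseRate,
                                    gain = 0, link = c("rectified",
                                                       "exponential"),
                                    nUnits = 1L, seed = NULL, trial = 1L) {
  link <- match.arg(link)
  if (baseRate < 0) stop("baseRate must be >= 0")
  lam <- switch(link,
    rectified = pmax(0, baseRate + gain * eSignal),
    exponential = baseRate * exp(gain * eSignal))
  if (any(!is.finite(lam))) stop("link produced non-finite rates")
  dt <- 1 / samplingRate
  sp <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nUnits), function(u) {
      counts <- stats::rpois(length(lam), lam * dt)
      idx <- rep.int(seq_along(counts), counts)
      if (!length(idx))
        return(data.frame(unit = integer(), trial = integer(),
                          time = numeric()))
      t <- sort((idx - 1L + stats::runif(length(idx))) * dt)
      data.frame(unit = u, trial = as.integer(trial), time = t)
    }))
  })
  SpikeTrainSet(sp, trialDuration = length(eSignal) * dt)
}

#' Mix an oscillation with scaled background noise
#'
#' Adds \code{noise} to \code{oscillation} after rescaling the noise so that
#' \code{SD(noise) / SD(oscillation) = noiseLevel} per trace.
#'
#' @param oscillation,noise \linkS4class{ContinuousRecording}s of identical
#'   geometry and sampling rate.
#' @param noiseLevel dimensionless SD ratio (0 returns the oscillation).
#' @return A \linkS4class{ContinuousRecording}.
#' @export
addNoiseMixture <- function(oscillation, noise, noiseLevel) {
  if (!identical(dim(samples(oscillation)), dim(samples(noise))))
    stop("oscillation and noise must have identical dimensions")
  if (samplingRate(oscillation) != samplingRate(noise))
    stop("sampling rates differ")
  if (noiseLevel < 0) stop("noiseLevel must be >= 0")
  so <- samples(oscillation); sn <- samples(noise)
  out <- so
  for (ch in seq_len(dim(so)[3L])) for (tr in seq_len(dim(so)[2L])) {
    sdo <- stats::sd(so[, tr, ch]); sdn <- stats::sd(sn[, tr, ch])
    scale <- if (noiseLevel == 0 || sdn == 0) 0 else noiseLevel * sdo / sdn
    out[, tr, ch] <- so[, tr, ch] + scale * sn[, tr, ch]
  }
  ContinuousRecording(out, samplingRate(oscillation))
}

#' Generate a synthetic eye-position trace with injected microsaccades
#'
#' Smooth fixation jitter (moving-average-filtered Gaussian noise) in both
#' coordinates, plus smooth ramped displacements ("microsaccades") at the
#' requested times, each in a random direction. Returns the ground truth for
#' scoring a detector.
#'
#' @param nSamples samples.
#' @param samplingRate Hz.
#' @param saccadeTimes onset times, s (events must not overlap).
#' @param amplitudes displacement sizes, degrees (recycled).
#' @param durations event durations, s (recycled).
#' @param noiseSD SD of the jitter position noise, degrees.
#' @param seed integer seed.
#' @return list with \code{x}, \code{y} (degrees), \code{samplingRate} and
#'   \code{truth} (data.frame: onset, offset, amplitude).
#' @export
generateEyeTrace <- function(nSamples, samplingRate, saccadeTimes = numeric(),
                             amplitudes = 0.5, durations = 0.02,
                             noiseSD = 0.01, seed = NULL) {
  k <- length(saccadeTimes)
  amplitudes <- rep_len(amplitudes, max(k, 1L))[seq_len(k)]
  durations <- rep_len(durations, max(k, 1L))[seq_len(k)]
  if (k > 1L) {
    o <- order(saccadeTimes)
    st <- saccadeTimes[o]; du <- durations[o]
    if (any(st[-1L] < (st + du)[-k])) stop("injected events overlap")
  }
  withSeed(seed, {
    smoothJitter <- function() {
      raw <- stats::rnorm(nSamples)
      w <- max(3L, round(0.05 * samplingRate))
      sm <- stats::filter(raw, rep(1 / w, w), sides = 2)
      sm[is.na(sm)] <- 0
      as.numeric(sm) * noiseSD / max(stats::sd(sm, na.rm = TRUE), 1e-12)
    }
    x <- smoothJitter(); y <- smoothJitter()
    truth <- data.frame(onset = numeric(), offset = numeric(),
                        amplitude = numeric())
    for (i in seq_len(k)) {
      i0 <- round(saccadeTimes[i] * samplingRate) + 1L
      len <- max(2L, round(durations[i] * samplingRate))
      i1 <- min(nSamples, i0 + len - 1L)
      theta <- stats::runif(1, 0, 2 * pi)
      ramp <- (1 - cos(pi * seq(0, 1, length.out = i1 - i0 + 1L))) / 2
      dx <- amplitudes[i] * cos(theta); dy <- amplitudes[i] * sin(theta)
      x[i0:i1] <- x[i0:i1] + dx * ramp
      y[i0:i1] <- y[i0:i1] + dy * ramp
      if (i1 < nSamples) {
        x[(i1 + 1L):nSamples] <- x[(i1 + 1L):nSamples] + dx
        y[(i1 + 1L):nSamples] <- y[(i1 + 1L):nSamples] + dy
      }
      truth <- rbind(truth, data.frame(onset = (i0 - 1L) / samplingRate,
                                       offset = (i1 - 1L) / samplingRate,
                                       amplitude = amplitudes[i]))
    }
    list(x = x, y = y, samplingRate = samplingRate, truth = truth)
  })
}
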