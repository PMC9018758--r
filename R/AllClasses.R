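#' @import methods
NULL

#' ContinuousRecording: multi-trial sampled signal
#'
#' Container for a continuous, regularly sampled voltage recording organised
#' as samples x trials x channels, with its sampling rate, physical units and
#' an event table (e.g. stimulus onsets) in seconds relative to trial start.
#'
#' @slot samples numeric array \code{[time, trial, channel]}.
#' @slot samplingRate sampling rate in Hz.
#' @slot events \code{data.frame} with columns \code{trial}, \code{time},
#'   \code{label}; times in seconds, trials 1-based.
#' @slot units character scalar, physical units of the samples.
#'
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(samples = "array", samplingRate = "numeric",
                 events = "data.frame", units = "character"),
  prototype(events = data.frame(trial = integer(), time = numeric(),
                                label = character()),
            units = "a.u."))

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (length(dim(object@samples)) != 3L)
    msg <- c(msg, "samples must be a 3-d array [time, trial, channel]")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!all(c("trial", "time", "label") %in% names(object@events)))
    msg <- c(msg, "events must have columns trial, time, label")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a ContinuousRecording
#'
#' @param samples numeric vector (one trial, one channel), matrix
#'   (time x trial) or 3-d array (time x trial x channel).
#' @param samplingRate sampling rate in Hz.
#' @param events optional event table (columns trial, time, label).
#' @param units physical units of the samples.
#' @return A \linkS4class{ContinuousRecording}.
#' @examples
#' rec <- ContinuousRecording(sin(2 * pi * 50 * (0:999) / 1000), 1000)
#' nSamples(rec)
#' @export
ContinuousRecording <- function(samples, samplingRate,
                                events = NULL, units = "a.u.") {
  if (is.vector(samples)) samples <- array(samples, c(length(samples), 1L, 1L))
  if (is.matrix(samples)) samples <- array(samples, c(dim(samples), 1L))
  if (is.null(events))
    events <- data.frame(trial = integer(), time = numeric(),
                         label = character())
  new("ContinuousRecording", samples = samples,
      samplingRate = as.numeric(samplingRate), events = events, units = units)
}

#' HalfCycleTable: detected oscillation cycles
#'
#' Result of a cycle detector. Holds one row per half-cycle and per full
#' cycle, plus the table of retained oscillatory epochs (maximal runs of
#' contiguous cycles). Times are in seconds from trial start; all intervals
#' are half-open \code{[start, end)}.
#'
#' @slot halfCycles \code{data.frame}: trial, channel, epoch_id, start_time,
#'   end_time, start_value, end_value, amplitude, duration, frequency,
#'   polarity ("trough_peak" or "peak_trough").
#' @slot fullCycles \code{data.frame}: peak-to-peak cycles with amplitude =
#'   |first peak - intervening trough|.
#' @slot epochs \code{data.frame}: epoch_id, trial, channel, start_time,
#'   end_time, n_half_cycles.
#' @slot samplingRate Hz of the source signal.
#' @slot detector character, which detector produced the table.
#'
#' @exportClass HalfCycleTable
setClass("HalfCycleTable",
  representation(halfCycles = "data.frame", fullCycles = "data.frame",
                 epochs = "data.frame", samplingRate = "numeric",
                 detector = "character"))

setValidity("HalfCycleTable", function(object) {
  hc <- object@halfCycles
  msg <- character()
  need <- c("trial", "channel", "epoch_id", "start_time", "end_time",
            "amplitude", "duration", "frequency", "polarity")
  if (!all(need %in% names(hc)))
    msg <- c(msg, paste("halfCycles must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(hc)) {
    if (any(hc$duration <= 0)) msg <- c(msg, "durations must be positive")
    if (any(hc$amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
    if (any(hc$end_time <= hc$start_time))
      msg <- c(msg, "end_time must exceed start_time")
    if (any(!is.finite(hc$frequency))) msg <- c(msg, "frequency must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' AR2Params: coefficients of a second-order autoregressive process
#'
#' The discrete damped harmonic oscillator
#' \code{x[t] = phi1 x[t-1] + phi2 x[t-2] + eps[t]}, with Gaussian innovations
#' of standard deviation \code{sigmaZ}. Stationary iff both roots of
#' \code{lambda^2 - phi1 lambda - phi2} lie inside the unit circle;
#' oscillatory (complex roots) iff \code{phi1^2 + 4 phi2 < 0}.
#'
#' @slot phi1,phi2 AR coefficients (dimensionless).
#' @slot sigmaZ innovation standard deviation (signal units).
#' @slot samplingRate Hz.
#' @exportClass AR2Params
setClass("AR2Params",
  representation(phi1 = "numeric", phi2 = "numeric", sigmaZ = "numeric",
                 samplingRate = "numeric"))

setValidity("AR2Params", function(object) {
  msg <- character()
  if (!all(is.finite(c(object@phi1, object@phi2, object@sigmaZ,
                       object@samplingRate))))
    msg <- c(msg, "all fields must be finite")
  if (length(object@sigmaZ) == 1L && object@sigmaZ < 0)
    msg <- c(msg, "sigmaZ must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname AR2Params-class
#' @param phi1,phi2 AR coefficients.
#' @param sigmaZ innovation SD.
#' @param samplingRate Hz.
#' @export
AR2Params <- function(phi1, phi2, sigmaZ = 1, samplingRate = 2035) {
  new("AR2Params", phi1 = phi1, phi2 = phi2, sigmaZ = sigmaZ,
      samplingRate = samplingRate)
}

#' AR2Model: fitted AR(2) with spectral summary
#'
#' An \linkS4class{AR2Params} bundle plus the eigenvalues of the companion
#' matrix, their magnitude, the implied spectral peak frequency and the
#' sum-of-squares error of a spectral fit (NA when constructed analytically).
#'
#' @slot params \linkS4class{AR2Params}.
#' @slot eigenvalues complex pair, roots of the characteristic polynomial.
#' @slot eigenvalueMagnitude modulus of the (complex) eigenvalues.
#' @slot peakFrequency argmax of the analytic spectrum, Hz.
#' @slot fitError sum of squared residuals over the fitted band.
#' @exportClass AR2Model
setClass("AR2Model",
  representation(params = "AR2Params", eigenvalues = "complex",
                 eigenvalueMagnitude = "numeric", peakFrequency = "numeric",
                 fitError = "numeric"))

setValidity("AR2Model", function(object) {
  p <- object@params
  ev <- sort(Mod(object@eigenvalues))
  ref <- sort(Mod(ar2Eigenvalues(p@phi1, p@phi2)))
  if (max(abs(ev - ref)) > 1e-8)
    return("eigenvalues are not the roots of lambda^2 - phi1 lambda - phi2")
  TRUE
})

#' EIWeights: 2x2 interaction matrix of a linear E-I circuit
#'
#' Weight matrix V of the two-population linear stochastic difference system
#' \code{E[t] = vEE E[t-1] + vEI I[t-1] + epsE[t]},
#' \code{I[t] = vIE E[t-1] + vII I[t-1] + epsI[t]}.
#' Complex eigenvalues (an oscillatory circuit) require \code{vEI * vIE < 0}.
#'
#' @slot vEE,vEI,vIE,vII interaction weights.
#' @slot noiseSD innovation standard deviation.
#' @slot noiseShared logical; if TRUE the same innovation enters both rows.
#' @exportClass EIWeights
setClass("EIWeights",
  representation(vEE = "numeric", vEI = "numeric", vIE = "numeric",
                 vII = "numeric", noiseSD = "numeric",
                 noiseShared = "logical"),
  prototype(noiseSD = 1, noiseShared = TRUE))

#' @rdname EIWeights-class
#' @param vEE,vEI,vIE,vII interaction weights.
#' @param noiseSD innovation SD.
#' @param noiseShared share one innovation stream between E and I rows.
#' @export
EIWeights <- function(vEE, vEI, vIE, vII, noiseSD = 1, noiseShared = TRUE) {
  new("EIWeights", vEE = vEE, vEI = vEI, vIE = vIE, vII = vII,
      noiseSD = noiseSD, noiseShared = noiseShared)
}

#' EICircuit: linear E-I circuit equivalent to an AR(2)
#'
#' @slot weights \linkS4class{EIWeights}.
#' @slot sourceModel the \linkS4class{AR2Model} it was derived from.
#' @slot transformation 2x2 change of basis A mapping the AR state
#'   \code{(x[t], x[t-1])} to \code{(E[t], I[t])}.
#' @exportClass EICircuit
setClass("EICircuit",
  representation(weights = "EIWeights", sourceModel = "AR2Model",
                 transformation = "matrix"))

setValidity("EICircuit", function(object) {
  A <- object@transformation
  if (!all(dim(A) == c(2L, 2L))) return("transformation must be 2x2")
  if (abs(det(A)) < 1e-12) return("transformation is singular")
  V <- eiMatrix(object@weights)
  evV <- sort(Mod(eigen(V, only.values = TRUE)$values))
  evM <- sort(Mod(object@sourceModel@eigenvalues))
  if (max(abs(evV - evM)) > 1e-6)
    return("circuit eigenvalues do not match the source AR(2) eigenvalues")
  TRUE
})

#' SpikeTrainSet: per-unit spike event times
#'
#' @slot spikes \code{data.frame}: unit, trial, time (s, sorted within
#'   unit/trial).
#' @slot unitInfo \code{data.frame}: unit, waveform_peak_to_trough (ms, may be
#'   NA), unit_class.
#' @slot trialDuration numeric, seconds per trial (used for rate computations).
#' @exportClass SpikeTrainSet
setClass("SpikeTrainSet",
  representation(spikes = "data.frame", unitInfo = "data.frame",
                 trialDuration = "numeric"))

setValidity("SpikeTrainSet", function(object) {
  sp <- object@spikes
  if (!all(c("unit", "trial", "time") %in% names(sp)))
    return("spikes must have columns unit, trial, time")
  if (nrow(sp)) {
    o <- order(sp$unit, sp$trial, sp$time)
    key <- order(sp$unit, sp$trial)
    if (is.unsorted(o) && any(unlist(tapply(sp$time,
        interaction(sp$unit, sp$trial, drop = TRUE),
        function(x) is.unsorted(x, strictly = FALSE)))))
      return("spike times must be sorted within each unit/trial")
  }
  TRUE
})

#' @rdname SpikeTrainSet-class
#' @param spikes spike event table (unit, trial, time).
#' @param unitInfo optional per-unit metadata.
#' @param trialDuration trial duration in seconds.
#' @export
SpikeTrainSet <- function(spikes, unitInfo = NULL, trialDuration = NA_real_) {
  if (is.null(unitInfo)) {
    u <- sort(unique(spikes$unit))
    unitInfo <- data.frame(unit = u,
                           waveform_peak_to_trough =
                             rep(NA_real_, length(u)),
                           unit_class = rep("unclassified", length(u)))
  }
  new("SpikeTrainSet", spikes = spikes, unitInfo = unitInfo,
      trialDuration = trialDuration)
}

#' Spectrum: averaged power spectrum
#'
#' @slot frequencies Hz, strictly increasing.
#' @slot power power per frequency (signal units squared per Hz, or
#'   dimensionless after baseline normalisation).
#' @slot taper "hann" or "rectangular".
#' @slot epochLength seconds of the underlying epochs.
#' @slot samplingRate Hz.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(frequencies = "numeric", power = "numeric",
                 taper = "character", epochLength = "numeric",
                 samplingRate = "numeric"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@power))
    msg <- c(msg, "frequencies and power must have equal length")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(msg)) msg else TRUE
})
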