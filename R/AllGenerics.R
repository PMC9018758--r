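#' @include AllClasses.R
NULL

#' Accessors for gammacycle classes
#'
#' Small accessor generics: \code{samples} (sample array), \code{samplingRate}
#' (Hz), \code{events} (event table), \code{nSamples}/\code{nTrials}/
#' \code{nChannels} (dimensions), \code{halfCycles}/\code{fullCycles}/
#' \code{epochs} (cycle tables), \code{spikes} (spike event table).
#'
#' @param object a gammacycle object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("halfCycles", function(object) standardGeneric("halfCycles"))
#' @rdname accessors
#' @export
setGeneric("fullCycles", function(object) standardGeneric("fullCycles"))
#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))

#' @rdname accessors
setMethod("samples", "ContinuousRecording", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "ContinuousRecording",
          function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "HalfCycleTable",
          function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "AR2Params", function(object) object@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "Spectrum", function(object) object@samplingRate)
#' @rdname accessors
setMethod("events", "ContinuousRecording", function(object) object@events)
#' @rdname accessors
setMethod("nSamples", "ContinuousRecording",
          function(object) dim(object@samples)[1L])
#' @rdname accessors
setMethod("nTrials", "ContinuousRecording",
          function(object) dim(object@samples)[2L])
#' @rdname accessors
setMethod("nChannels", "ContinuousRecording",
          function(object) dim(object@samples)[3L])
#' @rdname accessors
setMethod("halfCycles", "HalfCycleTable", function(object) object@halfCycles)
#' @rdname accessors
setMethod("fullCycles", "HalfCycleTable", function(object) object@fullCycles)
#' @rdname accessors
setMethod("epochs", "HalfCycleTable", function(object) object@epochs)
#' @rdname accessors
setMethod("spikes", "SpikeTrainSet", function(object) object@spikes)

#' Extract one trial/channel trace
#'
#' @param object a \linkS4class{ContinuousRecording}.
#' @param trial,channel 1-based indices.
#' @return numeric vector of samples.
#' @export
setGeneric("extractTrace", function(object, trial = 1L, channel = 1L)
  standardGeneric("extractTrace"))

#' @rdname extractTrace
setMethod("extractTrace", "ContinuousRecording", function(object, trial, channel) {
  object@samples[, trial, channel]
})

setMethod("show", "ContinuousRecording", function(object) {
  d <- dim(object@samples)
  cat(sprintf(
    "ContinuousRecording: %d samples x %d trials x %d channels @ %.6g Hz (%s)\n",
    d[1L], d[2L], d[3L], object@samplingRate, object@units))
  cat(sprintf("  duration %.4g s/trial, %d events\n",
              d[1L] / object@samplingRate, nrow(object@events)))
})

setMethod("show", "HalfCycleTable", function(object) {
  cat(sprintf(
    "HalfCycleTable [%s]: %d half-cycles, %d full cycles in %d epochs\n",
    object@detector, nrow(object@halfCycles), nrow(object@fullCycles),
    nrow(object@epochs)))
  if (nrow(object@halfCycles))
    cat(sprintf("  median half-cycle frequency %.2f Hz, median amplitude %.3g\n",
                stats::median(object@halfCycles$frequency),
                stats::median(object@halfCycles$amplitude)))
})

setMethod("show", "AR2Params", function(object) {
  cat(sprintf("AR2Params: phi1 = %.6g, phi2 = %.6g, sigma_z = %.4g @ %.6g Hz\n",
              object@phi1, object@phi2, object@sigmaZ, object@samplingRate))
})

setMethod("show", "AR2Model", function(object) {
  p <- object@params
  cat(sprintf(
    "AR2Model: |lambda| = %.4f, peak %.2f Hz (phi1 = %.4f, phi2 = %.4f)\n",
    object@eigenvalueMagnitude, object@peakFrequency, p@phi1, p@phi2))
  if (is.finite(object@fitError))
    cat(sprintf("  spectral fit SSE = %.4g\n", object@fitError))
})

setMethod("show", "EIWeights", function(object) {
  cat(sprintf("EIWeights: V = [[%.4g, %.4g], [%.4g, %.4g]], noise SD %.3g (%s)\n",
              object@vEE, object@vEI, object@vIE, object@vII, object@noiseSD,
              if (object@noiseShared) "shared" else "independent"))
})

setMethod("show", "EICircuit", function(object) {
  show(object@weights)
  cat(sprintf("  equivalent AR(2): |lambda| = %.4f, peak %.2f Hz\n",
              object@sourceModel@eigenvalueMagnitude,
              object@sourceModel@peakFrequency))
})

setMethod("show", "SpikeTrainSet", function(object) {
  cat(sprintf("SpikeTrainSet: %d spikes, %d units, %d trials\n",
              nrow(object@spikes), length(unique(object@spikes$unit)),
              length(unique(object@spikes$trial))))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins, %.3g-%.4g Hz, %s taper, %.3g s epochs\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies), object@taper, object@epochLength))
})
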