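# The AR(2) <-> linear E-I circuit correspondence.
#
# The AR(2) recursion in companion form is s[t] = C s[t-1] + (eps[t], 0)'
# with s[t] = (x[t], x[t-1])' and C = [[phi1, phi2], [1, 0]]. Any invertible
# A maps it to an equivalent two-variable circuit (E, I)' = A s with
# interaction matrix V = A C A^-1 and innovations A (eps, 0)'. The lag-one
# filter family E[t] = x[t] - cE x[t-1], I[t] = x[t] - cI x[t-1]
# corresponds to A = [[1, -cE], [1, -cI]]; its innovation vector is
# (eps, eps)', i.e. both populations share the same noise stream.

#' Construct the E-I circuit equivalent to an AR(2) model
#'
#' Similarity-transforms the AR(2) companion matrix by the 2x2 matrix
#' induced by the lag-one filters \code{(cE, cI)} (or by an arbitrary
#' invertible \code{transformation}). Eigenvalues are preserved exactly; for
#' complex eigenvalues the off-diagonal interaction weights always have
#' opposite signs (\code{vEI * vIE < 0}), the linear-circuit signature of
#' coupled excitation and inhibition.
#'
#' @param model an \linkS4class{AR2Model} with complex eigenvalues.
#' @param cE,cI lag-one filter coefficients defining the default
#'   transformation (must differ).
#' @param transformation optional explicit invertible 2x2 matrix A
#'   overriding the filter-based default.
#' @return An \linkS4class{EICircuit}.
#' @examples
#' mod <- ar2ModelFromParams(ar2FromEigen(0.987, 50, 2035))
#' ar2ToEI(mod)
#' @export
ar2ToEI <- function(model, cE = 1.1, cI = 0.86, transformation = NULL) {
  p <- model@params
  if (p@phi1^2 + 4 * p@phi2 >= 0)
    stop("AR(2) has real eigenvalues: no oscillatory E-I equivalent")
  A <- if (is.null(transformation))
    matrix(c(1, -cE, 1, -cI), 2L, 2L, byrow = TRUE) else transformation
  if (abs(det(A)) < 1e-12) stop("singular transformation")
  C <- matrix(c(p@phi1, p@phi2, 1, 0), 2L, 2L, byrow = TRUE)
  V <- A %*% C %*% solve(A)
  w <- EIWeights(vEE = V[1L, 1L], vEI = V[1L, 2L], vIE = V[2L, 1L],
                 vII = V[2L, 2L], noiseSD = p@sigmaZ, noiseShared = TRUE)
  new("EICircuit", weights = w, sourceModel = model, transformation = A)
}

#' Recover the AR(2) companion matrix from a circuit
#'
#' Inverse of \code{\link{ar2ToEI}}: returns \code{phi1}, \code{phi2} from
#' \code{A^-1 V A}.
#'
#' @param circuit an \linkS4class{EICircuit}.
#' @return named numeric vector \code{c(phi1, phi2)}.
#' @export
eiToAR2 <- function(circuit) {
  A <- circuit@transformation
  C <- solve(A) %*% eiMatrix(circuit@weights) %*% A
  c(phi1 = C[1L, 1L], phi2 = C[1L, 2L])
}

#' Decompose a scalar signal into E and I components
#'
#' Applies the lag-one filters \code{E[t] = x[t] - cE x[t-1]},
#' \code{I[t] = x[t] - cI x[t-1]} and solves the 2x2 system
#' \code{wE + wI = 1}, \code{wE cE + wI cI = 0} for the reconstruction
#' weights, so that \code{x[t] = wE E[t] + wI I[t]} holds exactly (an
#' algebraic identity, not a fit). For filters bracketing 1 from opposite
#' sides the weights have opposite signs, reproducing an E-I-balance-like
#' composition of the signal.
#'
#' @param x numeric signal.
#' @param cE,cI distinct lag-one filter coefficients.
#' @param samplingRate Hz (stored for phase-lead computation).
#' @return list: cE, cI, wE, wI, E, I (series of length length(x) - 1) and
#'   \code{x} (the reconstructed-equal input, aligned with E/I).
#' @examples
#' d <- decomposeSignal(rnorm(100), 1.1, 0.86, 1000)
#' max(abs(d$x - (d$wE * d$E + d$wI * d$I)))  # 0
#' @export
decomposeSignal <- function(x, cE = 1.1, cI = 0.86, samplingRate = 2035) {
  if (cE == cI) stop("cE and cI must differ (singular decomposition)")
  n <- length(x)
  E <- x[-1L] - cE * x[-n]
  I <- x[-1L] - cI * x[-n]
  W <- solve(matrix(c(1, 1, cE, cI), 2L, 2L, byrow = TRUE), c(1, 0))
  list(cE = cE, cI = cI, wE = W[1L], wI = W[2L], E = E, I = I,
       x = x[-1L], samplingRate = samplingRate)
}

# Segment-averaged cross-spectrum of two series; returns complex values on
# the positive-frequency grid.
crossSpectrum <- function(a, b, fs, epochSamples = NULL) {
  n <- length(a)
  if (is.null(epochSamples)) epochSamples <- min(n, round(fs))
  k <- floor(n / epochSamples)
  ma <- matrix(a[seq_len(k * epochSamples)], epochSamples)
  mb <- matrix(b[seq_len(k * epochSamples)], epochSamples)
  Fa <- stats::mvfft(ma); Fb <- stats::mvfft(mb)
  nf <- floor(epochSamples / 2) + 1L
  cs <- rowMeans(Fa[seq_len(nf), , drop = FALSE] *
                 Conj(Fb[seq_len(nf), , drop = FALSE]))
  list(frequencies = (seq_len(nf) - 1L) * fs / epochSamples, cross = cs)
}

#' Phase lead of E over I at the spectral peak
#'
#' Phase of the cross-spectrum of E against I at \code{peakFreq}, converted
#' to milliseconds (\code{dphi / (2 pi f) * 1000}); positive values mean E
#' leads I. Computed from segment-averaged cross-periodograms; an error is
#' raised when the two series are essentially incoherent at the peak.
#'
#' @param E,I numeric series from the same realisation.
#' @param peakFreq Hz.
#' @param samplingRate Hz.
#' @param epochSeconds cross-spectrum segment length (default 1 s).
#' @return lead in milliseconds.
#' @export
phaseLead <- function(E, I, peakFreq, samplingRate, epochSeconds = 1) {
  cs <- crossSpectrum(E, I, samplingRate,
                      round(epochSeconds * samplingRate))
  i <- which.min(abs(cs$frequencies - peakFreq))
  # coherence check against neighboring-band power
  pa <- crossSpectrum(E, E, samplingRate,
                      round(epochSeconds * samplingRate))$cross[i]
  pb <- crossSpectrum(I, I, samplingRate,
                      round(epochSeconds * samplingRate))$cross[i]
  coh <- Mod(cs$cross[i])^2 / (Re(pa) * Re(pb))
  if (!is.finite(coh) || coh < 0.1)
    stop("negligible coherence between E and I at the peak frequency")
  dphi <- Arg(cs$cross[i])
  dphi / (2 * pi * peakFreq) * 1000
}

#' Analytic phase lead of the lag-one filter pair
#'
#' The filter-transfer-phase difference
#' \code{arg(1 - cE exp(-i w0)) - arg(1 - cI exp(-i w0))} at the angular
#' frequency of the spectral peak, in milliseconds. This is the
#' deterministic prediction that \code{\link{phaseLead}} estimates from a
#' realisation.
#'
#' @param cE,cI filter coefficients.
#' @param peakFreq Hz.
#' @param samplingRate Hz.
#' @return lead in milliseconds (positive: E leads I).
#' @export
analyticFilterLead <- function(cE, cI, peakFreq, samplingRate) {
  w0 <- 2 * pi * peakFreq / samplingRate
  dphi <- Arg(1 - cE * exp(-1i * w0)) - Arg(1 - cI * exp(-1i * w0))
  dphi / (2 * pi * peakFreq) * 1000
}
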