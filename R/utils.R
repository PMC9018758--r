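# Internal numeric helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards; seed = NULL uses (and advances) the global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed)) stop("seed must be a finite integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Analytic signal via the FFT half-spectrum construction: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
analyticSignal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for the analytic transform")
  if (all(x == 0)) stop("all-zero signal has no defined phase")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Unwrap radian phase by removing 2*pi jumps.
unwrapPhase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

# Roots of lambda^2 - phi1*lambda - phi2 (companion-matrix eigenvalues).
ar2Eigenvalues <- function(phi1, phi2) {
  disc <- as.complex(phi1^2 + 4 * phi2)
  (phi1 + c(1, -1) * sqrt(disc)) / 2
}

ar2Stationary <- function(phi1, phi2) {
  all(Mod(ar2Eigenvalues(phi1, phi2)) < 1)
}

# 2x2 interaction matrix of an EIWeights object, rows/cols ordered (E, I).
eiMatrix <- function(w) {
  matrix(c(w@vEE, w@vEI, w@vIE, w@vII), 2L, 2L, byrow = TRUE)
}

# Spearman rho with average ranks for ties; NA-free input expected.
spearmanRho <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# Indices of strict-left / weak-right local maxima (or minima) of x.
localExtrema <- function(x, maxima = TRUE) {
  if (!maxima) x <- -x
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# Mean power spectrum of a matrix of epochs (columns), one-sided grid.
# Returns power such that sum(power) * df ~= variance (Parseval), i.e.
# density per Hz.
epochPeriodogram <- function(epochMat, fs, taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  n <- nrow(epochMat)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
       else rep(1, n)
  U <- sum(w^2)
  X <- stats::mvfft(epochMat * w)
  nf <- floor(n / 2) + 1L
  P <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / (U * fs)
  # fold negative frequencies onto positive ones (one-sided density)
  scale <- rep(2, nf); scale[1L] <- 1
  if (n %% 2L == 0L) scale[nf] <- 1
  p <- rowMeans(P) * scale
  list(frequencies = (seq_len(nf) - 1L) * fs / n, power = p)
}

# Cut a vector into a matrix of consecutive non-overlapping epochs.
asEpochMatrix <- function(x, epochSamples) {
  k <- floor(length(x) / epochSamples)
  if (k < 1L) stop("signal shorter than one epoch")
  matrix(x[seq_len(k * epochSamples)], nrow = epochSamples)
}
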