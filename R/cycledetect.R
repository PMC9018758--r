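# Gamma-cycle detection from the analytic-signal phase, plus the
# band-passed variant with an amplitude criterion and the
# filter-plus-extrema baseline method.

#' Instantaneous phase and amplitude of the analytic signal
#'
#' @param x numeric signal vector.
#' @return list with \code{phase} (wrapped to (-pi, pi]), \code{unwrapped},
#'   and \code{amplitude} (envelope modulus).
#' @examples
#' p <- analyticPhase(cos(2 * pi * 50 * (0:999) / 1000))
#' @export
analyticPhase <- function(x) {
  if (any(!is.finite(x))) stop("signal must be finite")
  a <- analyticSignal(x)
  ph <- Arg(a)
  list(phase = ph, unwrapped = unwrapPhase(ph), amplitude = Mod(a))
}

# Sign changes of the wrapped phase series. The phase of a forward-rotating
# oscillation crosses zero upward near signal peaks and jumps from +pi to
# -pi (a sign change through +-pi) near troughs, so both peak- and
# trough-adjacent events appear as sign changes. Jump magnitude below pi
# means a genuine zero crossing (peak); above pi means a wrap crossing
# (trough).
phaseCrossings <- function(phase) {
  n <- length(phase)
  p0 <- phase[-n]; p1 <- phase[-1L]
  chg <- (p0 < 0 & p1 >= 0) | (p0 >= 0 & p1 < 0)
  idx <- which(chg)
  if (!length(idx))
    return(data.frame(index = integer(), isPeak = logical(),
                      forward = logical()))
  jump <- p1[idx] - p0[idx]
  isZero <- abs(jump) < pi
  # forward rotation: upward through zero, or downward wrap (+pi -> -pi)
  forward <- (isZero & jump > 0) | (!isZero & jump < 0)
  data.frame(index = idx, isPeak = isZero, forward = forward)
}

# Nearest extremum of the correct type for each crossing, searched within
# the half-open interval bounded by the adjacent crossings; ties toward the
# earlier sample. Returns NA when no admissible extremum exists.
nearestExtremum <- function(crossIdx, lowerIdx, upperIdx, extrema) {
  if (!length(extrema)) return(rep(NA_integer_, length(crossIdx)))
  a <- findInterval(lowerIdx, extrema)             # extrema <= lower excluded
  b <- findInterval(upperIdx - 1e-9, extrema)      # extrema < upper included
  j <- findInterval(crossIdx + 0.5, extrema)
  cand1 <- pmin(pmax(j, a + 1L), b)                # left-or-equal candidate
  cand2 <- pmin(pmax(j + 1L, a + 1L), b)           # right candidate
  ok <- b > a
  cand1 <- pmax(cand1, 1L); cand2 <- pmax(cand2, 1L)
  v1 <- extrema[cand1]; v2 <- extrema[cand2]
  ci <- crossIdx + 0.5
  out <- rep(NA_integer_, length(crossIdx))
  nearer <- ifelse(abs(v1 - ci) <= abs(v2 - ci), v1, v2)  # tie -> earlier
  out[ok] <- nearer[ok]
  out
}

emptyCycleTable <- function(fs, detector) {
  cyc <- data.frame(trial = integer(), channel = integer(),
                    epoch_id = integer(), start_time = numeric(),
                    end_time = numeric(), start_value = numeric(),
                    end_value = numeric(), amplitude = numeric(),
                    duration = numeric(), frequency = numeric(),
                    polarity = character())
  new("HalfCycleTable", halfCycles = cyc,
      fullCycles = cyc,
      epochs = data.frame(epoch_id = integer(), trial = integer(),
                          channel = integer(), start_time = numeric(),
                          end_time = numeric(), n_half_cycles = integer()),
      samplingRate = fs, detector = detector)
}

# Build half-cycle / full-cycle / epoch tables from alternating extrema runs.
# runs: list of data.frames with columns index (sample), value, isPeak.
tablesFromRuns <- function(runs, fs, trial, channel, detector,
                           minFullCycles = 2L, epochOffset = 0L) {
  hc <- list(); fc <- list(); ep <- list()
  eid <- epochOffset
  for (run in runs) {
    if (nrow(run) < 2L) next
    npk <- sum(run$isPeak)
    nFull <- max(npk - 1L, 0L)
    if (nFull < minFullCycles) next
    eid <- eid + 1L
    t <- (run$index - 1L) / fs
    v <- run$value
    m <- nrow(run)
    i <- seq_len(m - 1L)
    hc[[length(hc) + 1L]] <- data.frame(
      trial = trial, channel = channel, epoch_id = eid,
      start_time = t[i], end_time = t[i + 1L],
      start_value = v[i], end_value = v[i + 1L],
      amplitude = abs(v[i + 1L] - v[i]),
      duration = t[i + 1L] - t[i],
      frequency = 1 / (2 * (t[i + 1L] - t[i])),
      polarity = ifelse(run$isPeak[i], "peak_trough", "trough_peak"))
    pk <- which(run$isPeak)
    if (length(pk) >= 2L) {
      j <- seq_len(length(pk) - 1L)
      a <- pk[j]; b <- pk[j + 1L]
      fc[[length(fc) + 1L]] <- data.frame(
        trial = trial, channel = channel, epoch_id = eid,
        start_time = t[a], end_time = t[b],
        start_value = v[a], end_value = v[b],
        amplitude = abs(v[a] - v[a + 1L]),   # first peak minus the trough
        duration = t[b] - t[a],
        frequency = 1 / (t[b] - t[a]),
        polarity = "peak_peak")
    }
    ep[[length(ep) + 1L]] <- data.frame(
      epoch_id = eid, trial = trial, channel = channel,
      start_time = t[1L], end_time = t[m], n_half_cycles = m - 1L)
  }
  list(halfCycles = if (length(hc)) do.call(rbind, hc) else NULL,
       fullCycles = if (length(fc)) do.call(rbind, fc) else NULL,
       epochs = if (length(ep)) do.call(rbind, ep) else NULL,
       lastEpoch = eid)
}

bindCycleTables <- function(parts, fs, detector) {
  take <- function(field) {
    xs <- Filter(Negate(is.null), lapply(parts, `[[`, field))
    if (length(xs)) do.call(rbind, xs) else NULL
  }
  empty <- emptyCycleTable(fs, detector)
  hc <- take("halfCycles"); fc <- take("fullCycles"); ep <- take("epochs")
  new("HalfCycleTable",
      halfCycles = if (is.null(hc)) empty@halfCycles else hc,
      fullCycles = if (is.null(fc)) empty@fullCycles else fc,
      epochs = if (is.null(ep)) empty@epochs else ep,
      samplingRate = fs, detector = detector)
}

# Core single-trace detector; returns runs of alternating extrema.
detectRunsPhase <- function(x, fs) {
  ph <- analyticPhase(x)
  cr <- phaseCrossings(ph$phase)
  K <- nrow(cr)
  if (K < 2L) return(list())
  d <- diff(ph$unwrapped)
  negCount <- c(0, cumsum(d <= 0))
  # interval bounds per crossing: previous and next crossing (trace edges
  # for the first/last); velocity must be positive over d[a..b].
  aIdx <- c(1L, cr$index[-K])
  bIdx <- c(cr$index[-1L], length(x) - 1L)
  bad <- (negCount[bIdx + 1L] - negCount[aIdx]) > 0
  # discard the slip crossing and two neighbors on each side
  discard <- logical(K)
  for (off in -2:2) {
    sh <- which(bad) + off
    sh <- sh[sh >= 1L & sh <= K]
    discard[sh] <- TRUE
  }
  keep <- which(!discard)
  if (!length(keep)) return(list())
  # nearest admissible extremum for each retained crossing
  pk <- localExtrema(x, TRUE); tr <- localExtrema(x, FALSE)
  lower <- c(0L, cr$index[-K])[keep]
  upper <- c(cr$index[-1L], length(x) + 1L)[keep]
  ext <- integer(length(keep))
  isP <- cr$isPeak[keep]
  ext[isP] <- nearestExtremum(cr$index[keep][isP], lower[isP], upper[isP], pk)
  ext[!isP] <- nearestExtremum(cr$index[keep][!isP], lower[!isP],
                               upper[!isP], tr)
  ok <- !is.na(ext)
  # split retained crossings into maximal runs of consecutive crossing rank
  # with valid extrema and alternating type
  rank <- keep[ok]; ext <- ext[ok]; isP <- isP[ok]
  if (!length(rank)) return(list())
  newRun <- c(TRUE, diff(rank) != 1L | diff(ext) <= 0L |
                    diff(isP) == 0L)
  runId <- cumsum(newRun)
  lapply(split(seq_along(rank), runId), function(ii) {
    data.frame(index = ext[ii], value = x[ext[ii]], isPeak = isP[ii])
  })
}

#' Detect gamma cycles from the analytic-signal phase
#'
#' The noise-robust detector: (1) all sign changes of the wrapped Hilbert
#' phase are located; (2) a crossing is discarded, together with its two
#' neighboring crossings on each side, whenever the angular velocity of the
#' phase is not positive for all time points between the preceding and the
#' following crossing (a negative phase slip); (3) each surviving
#' negative-to-positive zero crossing is mapped to the nearest local maximum
#' of the signal, each surviving wrap crossing to the nearest local minimum,
#' searched between the adjacent crossings; (4) the alternating peak/trough
#' sequences are cut into half-cycles (amplitude = |peak - trough|, duration
#' = extremum-to-extremum interval, frequency = 1/(2 duration)) and into
#' peak-to-peak full cycles; (5) epochs spanning fewer than
#' \code{minFullCycles} full cycles are dropped. Pure noise legitimately
#' yields an empty table.
#'
#' @param rec a \linkS4class{ContinuousRecording} (broadband or band-passed
#'   per the pipeline configuration).
#' @param minFullCycles minimum full cycles per retained epoch (default 2).
#' @return A \linkS4class{HalfCycleTable}.
#' @examples
#' rec <- simulateAR(ar2FromEigen(0.97, 50, 2035), 20000, seed = 1)
#' tab <- detectCyclesPhase(rec)
#' @export
detectCyclesPhase <- function(rec, minFullCycles = 2L) {
  fs <- samplingRate(rec)
  s <- samples(rec)
  parts <- list(); eid <- 0L
  for (ch in seq_len(dim(s)[3L])) for (tr in seq_len(dim(s)[2L])) {
    runs <- detectRunsPhase(s[, tr, ch], fs)
    res <- tablesFromRuns(runs, fs, tr, ch, "phase", minFullCycles, eid)
    eid <- res$lastEpoch
    parts[[length(parts) + 1L]] <- res
  }
  bindCycleTables(parts, fs, "phase")
}

#' Prestimulus amplitude statistics for the band-passed detector
#'
#' Runs the same cycle-selection procedure on a reference (oscillation-free)
#' recording and returns the mean and SD of the detected half-cycle
#' amplitudes.
#'
#' @param refTable a \linkS4class{HalfCycleTable} from the reference period
#'   (same detector settings as the test data).
#' @return named numeric vector \code{c(mu, sigma)}.
#' @export
prestimAmplitudeStats <- function(refTable) {
  a <- halfCycles(refTable)$amplitude
  if (length(a) < 2L) stop("reference table has fewer than 2 cycles")
  c(mu = mean(a), sigma = stats::sd(a))
}

#' Band-passed cycle detection with an amplitude criterion
#'
#' Band-pass filters the signal (third-order two-pass Butterworth), runs
#' \code{\link{detectCyclesPhase}}, and keeps only cycles whose amplitude A
#' satisfies \code{(A - mu_pre) / sigma_pre > threshold}, where the reference
#' statistics come from running the same procedure on an oscillation-free
#' (pre-stimulus) period. The default threshold 1.63 corresponds to a
#' one-sided test at approximately P < 0.05. Epochs are rebuilt from the
#' surviving contiguous cycles and the minimum-length rule is re-applied.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param band two-element band in Hz.
#' @param prestimStats numeric \code{c(mu, sigma)} from
#'   \code{\link{prestimAmplitudeStats}}.
#' @param threshold amplitude criterion in reference SDs (default 1.63).
#' @param minFullCycles minimum full cycles per retained epoch.
#' @return A \linkS4class{HalfCycleTable}.
#' @export
detectCyclesBandpassed <- function(rec, band, prestimStats,
                                   threshold = 1.63, minFullCycles = 2L) {
  if (prestimStats[2L] <= 0) stop("sigma_pre must be positive")
  filt <- applyFilter(rec, "pass", band, order = 3L, twoPass = TRUE)
  tab <- detectCyclesPhase(filt, minFullCycles = 1L)
  hc <- halfCycles(tab)
  if (!nrow(hc)) return(emptyCycleTable(samplingRate(rec), "bandpassed"))
  keep <- (hc$amplitude - prestimStats[1L]) / prestimStats[2L] > threshold
  rebuildFromMask(tab, keep, "bandpassed", minFullCycles)
}

# Rebuild a HalfCycleTable keeping only masked half-cycles: surviving
# contiguous runs become new epochs; full cycles and the minimum-length rule
# are recomputed.
rebuildFromMask <- function(tab, keep, detector, minFullCycles = 2L) {
  hc <- halfCycles(tab)
  fs <- samplingRate(tab)
  if (!any(keep)) return(emptyCycleTable(fs, detector))
  hc <- hc[order(hc$channel, hc$trial, hc$start_time), ]
  keep <- keep[order(halfCycles(tab)$channel, halfCycles(tab)$trial,
                     halfCycles(tab)$start_time)]
  parts <- list(); eid <- 0L
  for (key in unique(paste(hc$channel, hc$trial))) {
    sel <- paste(hc$channel, hc$trial) == key
    h <- hc[sel, ]; k <- keep[sel]
    if (!any(k)) next
    # contiguity: next half-cycle starts where the previous ended and both
    # survive
    contig <- c(FALSE, h$start_time[-1L] == h$end_time[-nrow(h)] &
                       k[-1L] & k[-nrow(h)])
    runId <- cumsum(!contig)
    runs <- lapply(split(which(k), runId[k]), function(ii) {
      h2 <- h[ii, ]
      firstIsPeak <- h2$polarity[1L] == "peak_trough"
      m <- nrow(h2)
      data.frame(
        index = round(c(h2$start_time, h2$end_time[m]) * fs) + 1L,
        value = c(h2$start_value, h2$end_value[m]),
        isPeak = rep(c(firstIsPeak, !firstIsPeak),
                     length.out = m + 1L))
    })
    res <- tablesFromRuns(runs, fs, h$trial[1L], h$channel[1L], detector,
                          minFullCycles, eid)
    eid <- res$lastEpoch
    parts[[length(parts) + 1L]] <- res
  }
  bindCycleTables(parts, fs, detector)
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric tridiagonal
# eigenproblem; returns n x k matrix of unit-energy tapers.
dpssTapers <- function(n, nw, k) {
  W <- nw / n
  t <- 0:(n - 1L)
  diagv <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  offv <- (1:(n - 1L)) * (n - (1:(n - 1L))) / 2
  M <- diag(diagv)
  M[cbind(1:(n - 1L), 2:n)] <- offv
  M[cbind(2:n, 1:(n - 1L))] <- offv
  e <- eigen(M, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0) v <- -v
    V[, j] <- v
  }
  V
}

# Multitaper sliding-window band power: windows of winSec stepped by
# stepSec, k Slepian tapers, power summed over [band[1], band[2]].
multitaperBandPower <- function(x, fs, band, winSec = 0.1, stepSec = 0.025,
                                k = 5L, nw = 3) {
  L <- round(winSec * fs)
  step <- max(1L, round(stepSec * fs))
  n <- length(x)
  if (L > n) stop("window longer than the trace")
  V <- dpssTapers(L, nw, k)
  freqs <- (0:(L - 1L)) * fs / L
  bandSel <- freqs >= band[1L] & freqs <= band[2L] & freqs <= fs / 2
  starts <- seq(1L, n - L + 1L, by = step)
  pow <- vapply(starts, function(i0) {
    seg <- x[i0:(i0 + L - 1L)]
    X <- stats::mvfft(V * seg)
    mean(colSums(Mod(X[bandSel, , drop = FALSE])^2))
  }, numeric(1))
  data.frame(start = starts, center = starts + (L - 1L) / 2, power = pow)
}

#' Baseline filter-and-extrema cycle detection
#'
#' The comparison method: (1) subtract a 40 ms moving average (a ~20 Hz
#' high-pass); (2) band-pass 5-100 Hz with a third-order two-pass
#' Butterworth; (3) compute a multitaper time-power representation in
#' \code{gammaPeak} +/- 20 Hz (5 Slepian tapers, 100 ms windows, 25 ms
#' steps); (4) define gamma episodes as runs longer than 100 ms whose power
#' exceeds a per-trial threshold (the mean of the time-power series minus
#' its SD by default; set \code{thresholdRule = "mean_plus_sd"} for the
#' stricter variant); (5) within episodes, local extrema of the filtered
#' signal define cycles: amplitude = peak minus subsequent trough, duration
#' = peak-to-next-peak interval.
#'
#' Unlike the phase-based detector this method will happily report "cycles"
#' in non-oscillatory noise, which is precisely the failure mode the
#' phase-based method was designed to avoid.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param gammaPeak center of the gamma band of interest, Hz.
#' @param thresholdRule "mean_minus_sd" (default) or "mean_plus_sd".
#' @param minFullCycles minimum full cycles per retained episode.
#' @return A \linkS4class{HalfCycleTable} (detector = "atallah").
#' @export
detectCyclesAtallah <- function(rec, gammaPeak,
                                thresholdRule = c("mean_minus_sd",
                                                  "mean_plus_sd"),
                                minFullCycles = 2L) {
  thresholdRule <- match.arg(thresholdRule)
  fs <- samplingRate(rec)
  hp <- boxcarHighpass(rec, 0.040)
  bp <- applyFilter(hp, "pass", c(5, min(100, fs / 2 - 1)), order = 3L,
                    twoPass = TRUE)
  band <- c(max(gammaPeak - 20, 1), gammaPeak + 20)
  s <- samples(bp)
  parts <- list(); eid <- 0L
  for (ch in seq_len(dim(s)[3L])) for (tr in seq_len(dim(s)[2L])) {
    x <- s[, tr, ch]
    tp <- multitaperBandPower(x, fs, band)
    thr <- if (thresholdRule == "mean_minus_sd")
      mean(tp$power) - stats::sd(tp$power)
    else mean(tp$power) + stats::sd(tp$power)
    above <- tp$power > thr
    # episodes: merged data coverage of above-threshold windows, kept when
    # the merged segment lasts more than 100 ms
    L <- round(0.1 * fs)
    cov <- logical(length(x))
    for (w in which(above))
      cov[tp$start[w]:min(length(x), tp$start[w] + L - 1L)] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keepRun <- r$values & r$lengths > L
    runs <- list()
    for (ri in which(keepRun)) {
      i0 <- starts[ri]
      i1 <- ends[ri]
      seg <- x[i0:i1]
      pk <- localExtrema(seg, TRUE); tr2 <- localExtrema(seg, FALSE)
      ext <- sort(c(pk, tr2))
      if (length(ext) < 2L) next
      isP <- ext %in% pk
      # enforce alternation: drop the later of two same-type neighbors
      keepE <- rep(TRUE, length(ext))
      last <- 1L
      for (j in seq_along(ext)[-1L]) {
        if (isP[j] == isP[last]) keepE[j] <- FALSE else last <- j
      }
      ext <- ext[keepE]; isP <- isP[keepE]
      runs[[length(runs) + 1L]] <-
        data.frame(index = ext + i0 - 1L, value = seg[ext], isPeak = isP)
    }
    res <- tablesFromRuns(runs, fs, tr, ch, "atallah", minFullCycles, eid)
    eid <- res$lastEpoch
    parts[[length(parts) + 1L]] <- res
  }
  bindCycleTables(parts, fs, "atallah")
}

#' Assign detected cycles to sample time points
#'
#' Each time point falling inside a detected cycle (half-open
#' \code{[start, end)}) carries that cycle's amplitude, duration and id;
#' points outside any cycle are invalid (NA). The result is organised as
#' time x trial matrices suitable for the time-resolved across-trial
#' correlation analyses.
#'
#' @param tab a \linkS4class{HalfCycleTable}.
#' @param nSamples number of time points on the grid (at the table's
#'   sampling rate, starting at time 0).
#' @param channel channel to extract.
#' @param cycleKind "half" or "full".
#' @return list of matrices \code{amplitude}, \code{duration}, \code{cycle}
#'   (global cycle id) and logical \code{valid}, each nSamples x nTrials.
#' @export
assignCyclesToTimepoints <- function(tab, nSamples, channel = 1L,
                                     cycleKind = c("half", "full")) {
  cycleKind <- match.arg(cycleKind)
  cyc <- if (cycleKind == "half") halfCycles(tab) else fullCycles(tab)
  cyc <- cyc[cyc$channel == channel, , drop = FALSE]
  fs <- samplingRate(tab)
  trials <- if (nrow(cyc)) max(cyc$trial) else 1L
  amp <- matrix(NA_real_, nSamples, trials)
  dur <- matrix(NA_real_, nSamples, trials)
  cid <- matrix(NA_integer_, nSamples, trials)
  if (nrow(cyc)) for (i in seq_len(nrow(cyc))) {
    i0 <- floor(cyc$start_time[i] * fs) + 1L
    i1 <- ceiling(cyc$end_time[i] * fs)      # [start, end): end excluded
    i0 <- max(1L, i0); i1 <- min(nSamples, i1)
    if (i1 < i0) next
    tr <- cyc$trial[i]
    amp[i0:i1, tr] <- cyc$amplitude[i]
    dur[i0:i1, tr] <- cyc$duration[i]
    cid[i0:i1, tr] <- i
  }
  list(amplitude = amp, duration = dur, cycle = cid, valid = !is.na(amp))
}
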