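# Filtering, epoch segmentation and eye-movement detection.

# Zero-phase Butterworth with reflect-padding of one transient length so
# onset transients do not masquerade as oscillation cycles.
filtfiltReflect <- function(x, filt, padLen) {
  n <- length(x)
  padLen <- min(n - 1L, padLen)
  xp <- c(2 * x[1L] - x[(padLen + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - padLen)])
  y <- signal::filtfilt(filt, xp)
  y[(padLen + 1L):(padLen + n)]
}

#' Zero-phase Butterworth filtering
#'
#' Applies a Butterworth filter of the stated order to every trial/channel
#' trace. With \code{twoPass = TRUE} (the default) the filter is run forward
#' and backward, giving zero phase distortion and a squared magnitude
#' response. Edges are reflect-padded by one transient length.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param kind "low", "high", "pass" or "stop".
#' @param corners corner frequency (Hz); two ordered values for
#'   "pass"/"stop".
#' @param order filter order (default 3, matching a third-order two-way
#'   Butterworth).
#' @param twoPass forward-backward (zero-phase) application.
#' @return The filtered \linkS4class{ContinuousRecording}.
#' @examples
#' rec <- generateColoredNoise(1, 2048, samplingRate = 1000, seed = 1)
#' filt <- applyFilter(rec, "pass", c(20, 100))
#' @export
applyFilter <- function(rec, kind = c("pass", "low", "high", "stop"),
                        corners, order = 3L, twoPass = TRUE) {
  kind <- match.arg(kind)
  fs <- samplingRate(rec)
  nyq <- fs / 2
  if (any(corners <= 0) || any(corners >= nyq))
    stop("corner frequencies must lie strictly inside (0, Nyquist)")
  if (kind %in% c("pass", "stop")) {
    if (length(corners) != 2L || diff(corners) <= 0)
      stop("band filters need two ordered corner frequencies")
  } else if (length(corners) != 1L) stop("one corner frequency expected")
  filt <- signal::butter(order, corners / nyq, type = kind)
  padLen <- max(3L * order * ceiling(fs / min(corners)), 3L * order)
  s <- samples(rec)
  for (ch in seq_len(dim(s)[3L])) for (tr in seq_len(dim(s)[2L])) {
    x <- s[, tr, ch]
    s[, tr, ch] <- if (twoPass) filtfiltReflect(x, filt, padLen)
                   else as.numeric(signal::filter(filt, x))
  }
  ContinuousRecording(s, fs, events(rec))
}

#' Moving-average (boxcar) high-pass
#'
#' Subtracts a centered moving average from each trace; with the default
#' 40 ms window this amounts to high-pass filtering at roughly 20 Hz. Window
#' tails are truncated at the trace edges so output length equals input
#' length.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param window smoothing window in seconds (default 0.040).
#' @return The high-passed \linkS4class{ContinuousRecording}.
#' @export
boxcarHighpass <- function(rec, window = 0.040) {
  fs <- samplingRate(rec)
  w <- round(window * fs)
  if (w < 2L) stop("window must span at least 2 samples")
  s <- samples(rec)
  if (w > dim(s)[1L]) stop("window longer than the signal")
  half <- floor(w / 2)
  n <- dim(s)[1L]
  for (ch in seq_len(dim(s)[3L])) for (tr in seq_len(dim(s)[2L])) {
    x <- s[, tr, ch]
    s[, tr, ch] <- x - runMeanTruncated(x, half)
  }
  ContinuousRecording(s, fs, events(rec))
}

# Centered running mean over +-half samples with truncated edge windows.
runMeanTruncated <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Cut a task period into non-overlapping fixed-length epochs
#'
#' Epochs are cut backward from the end of the period, stopping before an
#' epoch would include data within \code{exclusionAfterEvent} seconds of the
#' onset event. A period shorter than one epoch yields an empty table, not an
#' error.
#'
#' @param rec optional \linkS4class{ContinuousRecording}; when supplied, the
#'   per-epoch sample matrix is returned alongside the boundary table.
#' @param periodLength length of the analysable period (s), measured from the
#'   onset event.
#' @param epochLength epoch length (s).
#' @param exclusionAfterEvent dead time after the event (s).
#' @param eventTime event (stimulus-onset) time in trial coordinates (s).
#' @param channel channel to extract when \code{rec} is given.
#' @return list with \code{epochs} (data.frame: epoch, start_time, end_time,
#'   ordered by start) and, when \code{rec} is given, \code{data}: a samples
#'   x (epoch * trial) matrix.
#' @examples
#' segmentEpochs(periodLength = 2, epochLength = 0.5,
#'               exclusionAfterEvent = 0.5)$epochs
#' @export
segmentEpochs <- function(rec = NULL, periodLength, epochLength,
                          exclusionAfterEvent = 0, eventTime = 0,
                          channel = 1L) {
  if (epochLength <= 0) stop("epochLength must be positive")
  end <- eventTime + periodLength
  k <- floor((periodLength - exclusionAfterEvent) / epochLength)
  k <- max(k, 0L)
  starts <- if (k > 0) end - (k:1) * epochLength else numeric()
  ep <- data.frame(epoch = seq_len(k), start_time = starts,
                   end_time = starts + epochLength)
  out <- list(epochs = ep)
  if (!is.null(rec) && k > 0) {
    fs <- samplingRate(rec)
    len <- round(epochLength * fs)
    s <- samples(rec)
    cols <- list()
    for (tr in seq_len(dim(s)[2L])) for (i in seq_len(k)) {
      i0 <- round(ep$start_time[i] * fs) + 1L
      cols[[length(cols) + 1L]] <- s[i0:(i0 + len - 1L), tr, channel]
    }
    out$data <- do.call(cbind, cols)
  }
  out
}

#' Detect microsaccades from eye-position traces
#'
#' Positions are smoothed by replacing each value with the mean over itself
#' plus/minus 15 ms; eye speed is the magnitude of the first temporal
#' derivative of the smoothed (x, y); the speed SD is computed per trial; and
#' contiguous runs with speed above \code{threshSD} standard deviations
#' lasting at least \code{minDuration} are returned as saccadic events.
#'
#' @param x,y eye position series (degrees), equal length.
#' @param samplingRate Hz.
#' @param threshSD speed threshold in SDs (default 4).
#' @param minDuration minimum event duration in seconds (default 0.030).
#' @param smoothHalfWidth half-width of the smoothing window, s (default
#'   0.015).
#' @return data.frame: onset, offset (s), duration, peak_speed (deg/s).
#' @export
detectMicrosaccades <- function(x, y, samplingRate, threshSD = 4,
                                minDuration = 0.030,
                                smoothHalfWidth = 0.015) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  half <- round(smoothHalfWidth * samplingRate)
  if (length(x) <= 2L * half + 1L)
    stop("trial shorter than the smoothing window")
  xs <- runMeanTruncated(x, half)
  ys <- runMeanTruncated(y, half)
  vx <- diff(xs) * samplingRate
  vy <- diff(ys) * samplingRate
  speed <- sqrt(vx^2 + vy^2)
  thr <- threshSD * stats::sd(speed)
  above <- speed > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(minDuration * samplingRate)
  if (!any(keep))
    return(data.frame(onset = numeric(), offset = numeric(),
                      duration = numeric(), peak_speed = numeric()))
  data.frame(
    onset = (starts[keep] - 1L) / samplingRate,
    offset = (ends[keep] - 1L) / samplingRate,
    duration = (ends[keep] - starts[keep] + 1L) / samplingRate,
    peak_speed = vapply(which(keep), function(i)
      max(speed[starts[i]:ends[i]]), numeric(1)))
}

#' Anti-aliased integer-factor decimation
#'
#' Low-pass filters (8th order Butterworth, zero-phase, corner at 80% of the
#' new Nyquist) and keeps every q-th sample. Provided as a utility for
#' ingesting high-rate recordings; the synthetic layer generates directly at
#' target rates.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param q integer decimation factor.
#' @return The decimated \linkS4class{ContinuousRecording}.
#' @export
decimateRecording <- function(rec, q) {
  q <- as.integer(q)
  if (q < 2L) stop("q must be an integer >= 2")
  fs <- samplingRate(rec)
  lp <- applyFilter(rec, "low", 0.8 * fs / (2 * q), order = 8L)
  s <- samples(lp)
  idx <- seq(1L, dim(s)[1L], by = q)
  ContinuousRecording(s[idx, , , drop = FALSE], fs / q, events(rec))
}
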