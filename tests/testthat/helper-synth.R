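# Helpers: construct small synthetic cycle tables directly (no detection),
# and shared fixtures.

# A HalfCycleTable with contiguous alternating half-cycles per trial.
# amplitude/duration generators are functions of (trial, cycleIndex).
makeCycleTable <- function(nTrials, cyclesPerTrial, fs = 100,
                           durationFun = function(tr, i) 0.05,
                           amplitudeFun = function(tr, i) 1,
                           seed = NULL) {
  build <- function() {
    rows <- list()
    eid <- 0L
    for (tr in seq_len(nTrials)) {
      eid <- eid + 1L
      t0 <- 0
      for (i in seq_len(cyclesPerTrial)) {
        d <- durationFun(tr, i)
        a <- amplitudeFun(tr, i)
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, channel = 1L, epoch_id = eid,
          start_time = t0, end_time = t0 + d,
          start_value = 0, end_value = a,
          amplitude = a, duration = d, frequency = 1 / (2 * d),
          polarity = if (i %% 2L == 1L) "trough_peak" else "peak_trough")
        t0 <- t0 + d
      }
    }
    hc <- do.call(rbind, rows)
    ep <- do.call(rbind, lapply(split(hc, hc$epoch_id), function(h)
      data.frame(epoch_id = h$epoch_id[1L], trial = h$trial[1L],
                 channel = 1L, start_time = min(h$start_time),
                 end_time = max(h$end_time), n_half_cycles = nrow(h))))
    new("HalfCycleTable", halfCycles = hc, fullCycles = hc[0, ],
        epochs = ep, samplingRate = fs, detector = "synthetic")
  }
  if (!is.null(seed)) set.seed(seed)
  build()
}

# Independent Spearman oracle: rank (average ties) then Pearson by the
# textbook covariance formula, no cor() call.
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  cxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  vx <- sum((rx - mean(rx))^2); vy <- sum((ry - mean(ry))^2)
  cxy / sqrt(vx * vy)
}

# Independent exhaustive sign-flip oracle: iterate bit patterns.
signflipOracle <- function(values) {
  k <- length(values)
  emp <- mean(values)
  means <- numeric(2^k)
  for (code in 0:(2^k - 1)) {
    s <- ifelse(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0, 1, -1)
    means[code + 1L] <- mean(s * values)
  }
  pUp <- mean(means >= emp - 1e-15)
  pDn <- mean(means <= emp + 1e-15)
  min(1, 2 * min(pUp, pDn))
}

# Spearman trend statistic of y over x (used for sweep monotonicity).
trendRho <- function(x, y) suppressWarnings(
  stats::cor(x, y, method = "spearman"))
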