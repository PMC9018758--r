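# Spike-field statistics: per-cycle spike counts/rates, pairwise phase
# consistency, phase-bin firing profiles and waveform classification.

# Map each spike to the (full or half) cycle containing it; half-open
# [start, end). Returns the spike table with cycle row indices (NA when the
# spike falls outside every cycle).
assignSpikesToCycles <- function(sp, cyc) {
  idx <- rep(NA_integer_, nrow(sp))
  for (tr in unique(sp$trial)) {
    ctr <- which(cyc$trial == tr)
    if (!length(ctr)) next
    str <- which(sp$trial == tr)
    o <- order(cyc$start_time[ctr])
    ctr <- ctr[o]
    pos <- findInterval(sp$time[str], cyc$start_time[ctr])
    ok <- pos >= 1L
    ok[ok] <- sp$time[str][ok] < cyc$end_time[ctr[pos[ok]]]
    idx[str[ok]] <- ctr[pos[ok]]
  }
  idx
}

#' Spike phase within a gamma cycle
#'
#' Linear phase interpolation: \code{phase = 2 pi (t - start) / duration},
#' where t is the spike time and the cycle spans \code{[start,
#' start + duration)}.
#'
#' @param spikeTime spike times, s.
#' @param cycleStart cycle start times, s (recycled).
#' @param cycleDuration cycle durations, s (recycled).
#' @return phases in [0, 2 pi).
#' @examples
#' spikePhase(0.015, 0.01, 0.02)  # 3/4 through a 20 ms cycle -> 3 pi / 2
#' @export
spikePhase <- function(spikeTime, cycleStart, cycleDuration) {
  ph <- (spikeTime - cycleStart) / cycleDuration * 2 * pi
  if (any(ph < 0 | ph >= 2 * pi))
    stop("spike outside the cycle interval [start, start + duration)")
  ph
}

#' Pairwise phase consistency, cross-trial variant (PPC1)
#'
#' Average of \code{cos(theta_i - theta_j)} over all spike pairs drawn from
#' different trials, which removes biases from spike count and within-trial
#' history. Computed in closed form from per-trial resultant vectors.
#'
#' @param phases spike phases in radians.
#' @param trials trial index per spike.
#' @return PPC1 value; 1 for identical phases, expectation 0 for uniform
#'   phases. Errors when all spikes share one trial (no valid pairs).
#' @export
ppc1 <- function(phases, trials) {
  z <- exp(1i * phases)
  Sa <- tapply(z, trials, sum)
  na <- tapply(z, trials, length)
  S <- sum(Sa)
  N <- sum(na)
  nPairs <- N^2 - sum(na^2)
  if (nPairs <= 0) stop("all spikes from one trial: no cross-trial pairs")
  (Mod(S)^2 - sum(Mod(Sa)^2)) / nPairs
}

#' Per-cycle spike metrics as a function of cycle frequency
#'
#' Assigns spikes to the cycles containing them; computes, per unit, the
#' spike count in each cycle and the firing rate (count/duration); and bins
#' cycles by frequency. Counts and rates are normalised per unit by the
#' unit's own mean across all its cycles, so units average on a common scale
#' while within-unit frequency dependence is preserved. Spike-field locking
#' per bin is quantified with \code{\link{ppc1}} over the spikes pooled from
#' all cycles of that bin (defined only where the pool has at least
#' \code{minSpikes} spikes). The Spearman correlation of each per-cycle
#' metric with cycle frequency is returned per unit and averaged.
#'
#' @param spikeSet a \linkS4class{SpikeTrainSet} sharing the trial structure
#'   and clock of the cycle table.
#' @param tab a \linkS4class{HalfCycleTable}.
#' @param binWidth frequency bin width, Hz.
#' @param channel,cycleKind as elsewhere (cycles default to full cycles).
#' @param minSpikes PPC defined only for bins with at least this many
#'   spikes (default 50).
#' @return list: \code{byBin} (data.frame: frequency, n_cycles, n_spikes,
#'   count_norm, rate_norm, ppc), \code{correlations} (data.frame: unit,
#'   rho_count, rho_rate), \code{rhoPPC} (Spearman of PPC against bin
#'   frequency across defined bins).
#' @export
perCycleSpikeMetrics <- function(spikeSet, tab, binWidth = 2, channel = 1L,
                                 cycleKind = c("full", "half"),
                                 minSpikes = 50L) {
  cycleKind <- match.arg(cycleKind)
  cyc <- cycleSubset(tab, channel, cycleKind)
  if (!nrow(cyc)) stop("empty cycle table")
  sp <- spikes(spikeSet)
  sp$cycleRow <- assignSpikesToCycles(sp, cyc)
  if (all(is.na(sp$cycleRow))) stop("no overlap between spikes and cycles")
  fbin <- round(cyc$frequency / binWidth) * binWidth
  units <- sort(unique(sp$unit))
  countMat <- matrix(0, nrow(cyc), length(units))
  for (ui in seq_along(units)) {
    rows <- sp$cycleRow[sp$unit == units[ui]]
    rows <- rows[!is.na(rows)]
    if (length(rows)) {
      t <- table(rows)
      countMat[as.integer(names(t)), ui] <- as.numeric(t)
    }
  }
  rateMat <- countMat / cyc$duration
  corrs <- data.frame(unit = units, rho_count = NA_real_,
                      rho_rate = NA_real_)
  for (ui in seq_along(units)) {
    corrs$rho_count[ui] <- spearmanRho(countMat[, ui], cyc$frequency)
    corrs$rho_rate[ui] <- spearmanRho(rateMat[, ui], cyc$frequency)
  }
  normBy <- function(m) {
    mu <- colMeans(m)
    mu[mu == 0] <- NA_real_
    sweep(m, 2L, mu, "/")
  }
  cn <- normBy(countMat); rn <- normBy(rateMat)
  bins <- sort(unique(fbin))
  byBin <- do.call(rbind, lapply(bins, function(b) {
    rows <- which(fbin == b)
    inBin <- which(!is.na(sp$cycleRow) & sp$cycleRow %in% rows)
    ppcVal <- NA_real_
    if (length(inBin) >= minSpikes &&
        length(unique(sp$trial[inBin])) >= 2L) {
      ph <- spikePhase(sp$time[inBin], cyc$start_time[sp$cycleRow[inBin]],
                       cyc$duration[sp$cycleRow[inBin]])
      ppcVal <- ppc1(ph, sp$trial[inBin])
    }
    data.frame(frequency = b, n_cycles = length(rows),
               n_spikes = length(inBin),
               count_norm = mean(cn[rows, , drop = FALSE], na.rm = TRUE),
               rate_norm = mean(rn[rows, , drop = FALSE], na.rm = TRUE),
               ppc = ppcVal)
  }))
  defined <- !is.na(byBin$ppc)
  rhoPPC <- if (sum(defined) >= 3L)
    spearmanRho(byBin$ppc[defined], byBin$frequency[defined]) else NA_real_
  list(byBin = byBin, correlations = corrs, rhoPPC = rhoPPC)
}

#' Firing-rate profile over gamma-phase bins, by cycle-duration class
#'
#' Divides each cycle into \code{nBins} non-overlapping phase bins, splits
#' cycles into short and long classes at the median duration, and computes
#' the firing rate per (class, bin). The preferred bin is the argmax of the
#' overall profile; the short-minus-long rate difference is reported at the
#' preferred and at the non-preferred (argmin) bin.
#'
#' @param spikeSet a \linkS4class{SpikeTrainSet}.
#' @param tab a \linkS4class{HalfCycleTable}.
#' @param nBins phase bins per cycle (default 8).
#' @param channel,cycleKind as elsewhere.
#' @return list: \code{rates} (2 x nBins matrix, rows short/long, Hz),
#'   \code{preferredBin}, \code{nonPreferredBin},
#'   \code{contrastPreferred}, \code{contrastNonPreferred} (short minus
#'   long normalised rate at those bins).
#' @export
phaseBinProfile <- function(spikeSet, tab, nBins = 8L, channel = 1L,
                            cycleKind = c("full", "half")) {
  cycleKind <- match.arg(cycleKind)
  cyc <- cycleSubset(tab, channel, cycleKind)
  sp <- spikes(spikeSet)
  sp$cycleRow <- assignSpikesToCycles(sp, cyc)
  sp <- sp[!is.na(sp$cycleRow), , drop = FALSE]
  med <- stats::median(cyc$duration)
  isShort <- cyc$duration <= med
  if (all(isShort) || !any(isShort)) stop("empty duration class")
  ph <- spikePhase(sp$time, cyc$start_time[sp$cycleRow],
                   cyc$duration[sp$cycleRow])
  bin <- pmin(floor(ph / (2 * pi / nBins)) + 1L, nBins)
  cls <- ifelse(isShort[sp$cycleRow], 1L, 2L)
  counts <- matrix(0, 2L, nBins)
  for (k in seq_len(nrow(sp)))
    counts[cls[k], bin[k]] <- counts[cls[k], bin[k]] + 1
  timePerBin <- c(sum(cyc$duration[isShort]),
                  sum(cyc$duration[!isShort])) / nBins
  rates <- counts / timePerBin
  overall <- colSums(counts) / (sum(timePerBin) * 1)
  pref <- which.max(overall)
  nonPref <- which.min(overall)
  # normalise each class profile by its mean rate so the contrast reflects
  # modulation shape, not overall rate differences between classes
  nr <- rates / rowMeans(rates)
  list(rates = rates, preferredBin = pref, nonPreferredBin = nonPref,
       contrastPreferred = nr[1L, pref] - nr[2L, pref],
       contrastNonPreferred = nr[1L, nonPref] - nr[2L, nonPref])
}

#' Classify a unit by spike-waveform width
#'
#' Threshold on the peak-to-trough duration of the average action-potential
#' waveform: above 0.235 ms is broad-waveform (BW, putative pyramidal),
#' below is narrow-waveform (NW). A value exactly at the threshold is
#' assigned NW with a warning.
#'
#' @param peakToTrough peak-to-trough duration in ms.
#' @param threshold ms (default 0.235).
#' @return "BW" or "NW" (vectorised).
#' @export
classifyWaveform <- function(peakToTrough, threshold = 0.235) {
  if (any(!is.finite(peakToTrough))) stop("peakToTrough must be finite")
  if (any(peakToTrough == threshold))
    warning("value exactly at the classification boundary; assigned NW")
  ifelse(peakToTrough > threshold, "BW", "NW")
}

#' Correlate trough-to-peak firing rate with the next half-cycle duration
#'
#' Computes the firing rate within each trough-to-peak half-cycle and
#' correlates it (Spearman) with the duration of the succeeding
#' peak-to-trough half-cycle. A strong positive value is the signature of
#' models in which a bout of excitation produces a long ensuing cycle.
#'
#' @param spikeSet a \linkS4class{SpikeTrainSet}.
#' @param tab a \linkS4class{HalfCycleTable} with polarity information.
#' @param channel channel to analyse.
#' @return one-row data.frame: rho, n_effective.
#' @export
leadlagRateDuration <- function(spikeSet, tab, channel = 1L) {
  cyc <- cycleSubset(tab, channel, "half")
  if (!nrow(cyc) || !("polarity" %in% names(cyc)))
    stop("no half-cycle polarity information")
  sp <- spikes(spikeSet)
  sp$cycleRow <- assignSpikesToCycles(sp, cyc)
  counts <- numeric(nrow(cyc))
  t <- table(sp$cycleRow[!is.na(sp$cycleRow)])
  counts[as.integer(names(t))] <- as.numeric(t)
  rate <- counts / cyc$duration
  nextDur <- laggedCycleValues(cyc, "duration", 1L)
  sel <- which(cyc$polarity == "trough_peak" & !is.na(nextDur))
  if (length(sel) < 3L)
    return(data.frame(rho = NA_real_, n_effective = length(sel)))
  data.frame(rho = spearmanRho(rate[sel], nextDur[sel]),
             n_effective = length(sel))
}
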