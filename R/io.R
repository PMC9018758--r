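# Plain-text serialisation: a recording is a directory bundle (JSON header
# plus one TSV of samples per channel); cycle tables and spike trains are
# single header-keyed TSV files.

#' Write / read a ContinuousRecording as a text bundle
#'
#' The bundle is a directory containing \code{header.json} (sampling rate,
#' dimensions, units), \code{events.tsv}, and one \code{channel_<k>.tsv} of
#' samples (rows = time, columns = trials, full precision). Round trips are
#' exact to the printed precision (17 significant digits, i.e. lossless for
#' doubles).
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param path bundle directory (created if needed).
#' @return \code{writeRecording}: the path, invisibly. \code{readRecording}:
#'   the recording.
#' @export
writeRecording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(samples(rec))
  header <- list(sampling_rate_hz = samplingRate(rec),
                 n_samples = d[1L], n_trials = d[2L], n_channels = d[3L],
                 units = rec@units)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(events(rec), file.path(path, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (ch in seq_len(d[3L])) {
    m <- samples(rec)[, , ch, drop = FALSE]
    dim(m) <- d[1:2]
    ms <- sprintf("%.17g", m)
    dim(ms) <- d[1:2]
    utils::write.table(ms,
                       file.path(path, sprintf("channel_%d.tsv", ch)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  ev <- utils::read.delim(file.path(path, "events.tsv"),
                          colClasses = c("integer", "numeric", "character"))
  arr <- array(NA_real_, c(header$n_samples, header$n_trials,
                           header$n_channels))
  for (ch in seq_len(header$n_channels)) {
    m <- as.matrix(utils::read.table(
      file.path(path, sprintf("channel_%d.tsv", ch)), sep = "\t"))
    arr[, , ch] <- m
  }
  ContinuousRecording(arr, header$sampling_rate_hz, ev, header$units)
}

#' Write / read a HalfCycleTable as TSV
#'
#' One row per half-cycle; full cycles and epochs in sibling files sharing
#' the stem. Reading is header-keyed, so shuffled column orders are
#' accepted.
#'
#' @param tab a \linkS4class{HalfCycleTable}.
#' @param stem file stem; writes \code{<stem>_half.tsv},
#'   \code{<stem>_full.tsv}, \code{<stem>_epochs.tsv} and
#'   \code{<stem>_meta.json}.
#' @return \code{writeCycles}: stem, invisibly; \code{readCycles}: the
#'   table.
#' @export
writeCycles <- function(tab, stem) {
  wt <- function(df, suffix)
    utils::write.table(df, paste0(stem, suffix), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(halfCycles(tab), "_half.tsv")
  wt(fullCycles(tab), "_full.tsv")
  wt(epochs(tab), "_epochs.tsv")
  jsonlite::write_json(list(sampling_rate_hz = samplingRate(tab),
                            detector = tab@detector),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeCycles
#' @export
readCycles <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  rd <- function(suffix) utils::read.delim(paste0(stem, suffix))
  canon <- function(df, template) df[, names(template), drop = FALSE]
  empty <- emptyCycleTable(meta$sampling_rate_hz, meta$detector)
  hc <- rd("_half.tsv"); fc <- rd("_full.tsv"); ep <- rd("_epochs.tsv")
  new("HalfCycleTable",
      halfCycles = if (nrow(hc)) canon(hc, empty@halfCycles)
                   else empty@halfCycles,
      fullCycles = if (nrow(fc)) canon(fc, empty@fullCycles)
                   else empty@fullCycles,
      epochs = if (nrow(ep)) canon(ep, empty@epochs) else empty@epochs,
      samplingRate = meta$sampling_rate_hz, detector = meta$detector)
}

#' Write / read spike trains as a delimited event list
#'
#' Columns unit, trial, time (seconds). On reading, unsorted times within a
#' unit/trial are rejected with the offending line number.
#'
#' @param spikeSet a \linkS4class{SpikeTrainSet}.
#' @param path TSV file path.
#' @return \code{writeSpikes}: path, invisibly; \code{readSpikes}: the
#'   \linkS4class{SpikeTrainSet}.
#' @export
writeSpikes <- function(spikeSet, path) {
  utils::write.table(spikes(spikeSet), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(path) {
  sp <- utils::read.delim(path)
  if (!all(c("unit", "trial", "time") %in% names(sp)))
    stop("spike file must have columns unit, trial, time")
  sp <- sp[, c("unit", "trial", "time")]
  key <- paste(sp$unit, sp$trial)
  for (k in unique(key)) {
    idx <- which(key == k)
    bad <- which(diff(sp$time[idx]) < 0)
    if (length(bad))
      stop(sprintf("unsorted spike times at line %d of %s",
                   idx[bad[1L] + 1L] + 1L, path))
  }
  SpikeTrainSet(sp)
}
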