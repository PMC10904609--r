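# Plain-text interchange: recordings as a CSV sample matrix plus a JSON
# header, stimulus events as a 3-column TSV, feature sets as CSV with
# metadata columns and f000... feature columns.

#' Write / read stimulus events as TSV
#'
#' Three tab-separated columns: `onset`, `duration`, `condition`.
#'
#' @param timeline a [StimulusTimeline-class].
#' @param path file path.
#' @export
writeEvents <- function(timeline, path) {
  write.table(stimEvents(timeline), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname writeEvents
#' @param totalDuration total run duration (s); default last event end.
#' @param samplingRate Hz.
#' @return `readEvents()` returns a [StimulusTimeline-class].
#' @export
readEvents <- function(path, totalDuration = NULL, samplingRate = 3.9063) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "condition") %in% names(ev)))
    stop("events file needs onset, duration, condition columns")
  if (is.null(totalDuration))
    totalDuration <- max(ev$onset + ev$duration)
  new("StimulusTimeline", events = ev[order(ev$onset), ],
      totalDuration = totalDuration, samplingRate = samplingRate)
}

#' Write / read an optical recording as CSV + JSON header
#'
#' The CSV holds one row per (channel, wavelength) labeled
#' `<channel>_w<nm>`, one column per sample; the JSON sidecar records
#' sampling rate, wavelengths, start time and channel metadata.
#'
#' @param rec an [OpticalRecording-class].
#' @param path CSV path; the header is written alongside as
#'   `<path>.json`.
#' @export
writeRecording <- function(rec, path) {
  wl <- metadata(rec)$wavelengths
  rows <- do.call(rbind, lapply(wl, function(w) {
    m <- intensity(rec, w)
    rownames(m) <- sprintf("%s_w%d", rownames(m), w)
    m
  }))
  write.csv(rows, path)
  hdr <- list(samplingRate = samplingRate(rec), wavelengths = wl,
              startTime = startTime(rec),
              channelIds = rownames(rec),
              distanceCm = rowData(rec)$distanceCm[1])
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname writeRecording
#' @return `readRecording()` returns an [OpticalRecording-class]
#'   (without ground truth).
#' @export
readRecording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  ints <- lapply(hdr$wavelengths, function(w) {
    sub <- m[sprintf("%s_w%d", hdr$channelIds, w), , drop = FALSE]
    rownames(sub) <- hdr$channelIds
    sub
  })
  OpticalRecording(ints, wavelengths = hdr$wavelengths,
                   samplingRate = hdr$samplingRate,
                   channelIds = hdr$channelIds,
                   distance = hdr$distanceCm, startTime = hdr$startTime)
}

#' Write / read a feature set as CSV
#'
#' Metadata columns (`label`, `channel`, `chromophore`, `run`)
#' followed by feature columns `f000 ... f(P-1)`.
#'
#' @param fm a [FingerFeatureSet-class].
#' @param path CSV path.
#' @export
writeFeatures <- function(fm, path) {
  X <- featureValues(fm)
  colnames(X) <- sprintf("f%03d", seq_len(ncol(X)) - 1)
  df <- cbind(as.data.frame(colData(fm)), as.data.frame(X))
  write.csv(df, path, row.names = FALSE)
}

#' @rdname writeFeatures
#' @return `readFeatures()` returns a [FingerFeatureSet-class].
#' @export
readFeatures <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- c("label", "channel", "chromophore", "run")
  if (!all(meta %in% names(df)))
    stop("features file needs columns ", paste(meta, collapse = ", "))
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  X <- t(as.matrix(df[, fcols]))
  colnames(X) <- sprintf("ex%04d", seq_len(ncol(X)))
  rownames(X) <- sprintf("t%03d", seq_len(nrow(X)))
  se <- SummarizedExperiment(assays = list(features = X),
    colData = DataFrame(df[, meta], row.names = colnames(X)))
  new("FingerFeatureSet", se)
}
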