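#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData `rowData<-` colData `colData<-`
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

.FINGERS <- c("thumb", "index", "middle", "ring", "little")

#' Finger-tapping condition labels
#'
#' The five task conditions of the individual finger-tapping paradigm,
#' in canonical order, plus (optionally) the rest condition.
#'
#' @param rest if `TRUE`, append `"rest"`.
#' @return Character vector of condition labels.
#' @examples
#' fingerConditions()
#' @export
fingerConditions <- function(rest = FALSE) {
  if (rest) c(.FINGERS, "rest") else .FINGERS
}

# ---------------------------------------------------------------------------
# StimulusTimeline

#' StimulusTimeline: ordered block-design stimulus events
#'
#' Task blocks (onset, duration, condition) of a block-design run.
#' Rest periods are implicit: anything outside a task block is rest.
#' Validity enforces onset ordering, non-overlap of task blocks,
#' strictly positive durations and a total duration covering the last
#' block.
#'
#' @slot events `data.frame` with columns `onset` (s), `duration` (s),
#'   `condition` (character).
#' @slot totalDuration numeric, seconds.
#' @slot samplingRate numeric, Hz (rate at which the run is sampled).
#' @seealso [buildParadigm()]
#' @export
setClass("StimulusTimeline",
  representation(events = "data.frame", totalDuration = "numeric",
                 samplingRate = "numeric"))

setValidity("StimulusTimeline", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (is.unsorted(ev$onset)) msg <- c(msg, "events must be sorted by onset")
    if (any(ev$duration <= 0)) msg <- c(msg, "event durations must be > 0")
    ends <- ev$onset + ev$duration
    if (nrow(ev) > 1 && any(ev$onset[-1] < ends[-nrow(ev)] - 1e-9))
      msg <- c(msg, "task events must not overlap")
    if (object@totalDuration < max(ends) - 1e-9)
      msg <- c(msg, "totalDuration must cover the last event")
  }
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn StimulusTimeline-class task events as a data.frame.
#' @param x a `StimulusTimeline`.
#' @export
setMethod("stimEvents", "StimulusTimeline", function(x) x@events)

#' @describeIn StimulusTimeline-class total run duration (s).
#' @export
setMethod("totalDuration", "StimulusTimeline", function(x) x@totalDuration)

#' @describeIn StimulusTimeline-class sampling rate (Hz).
#' @export
setMethod("samplingRate", "StimulusTimeline", function(x) x@samplingRate)

setMethod("show", "StimulusTimeline", function(object) {
  ev <- object@events
  cat(sprintf("StimulusTimeline: %d task events over %.1f s @ %.4f Hz\n",
              nrow(ev), object@totalDuration, object@samplingRate))
  if (nrow(ev))
    cat("  conditions:", paste(unique(ev$condition), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SyntheticConfig / GroundTruth

#' SyntheticConfig: parameters of the recording simulator
#'
#' Holds every tunable of [simulateRecording()] and [injectArtifacts()].
#' Construct with [syntheticConfig()] or [syntheticPreset()].
#'
#' @slot nChannels integer, montage channel count.
#' @slot samplingRate numeric, Hz.
#' @slot baselineIntensity numeric, mean detected intensity per channel
#'   (device units).
#' @slot hrf named numeric: `peakDelay`, `undershootDelay`,
#'   `peakDispersion`, `undershootDispersion`, `undershootRatio`.
#' @slot classAmplitude conditions x channels matrix of peak HbO
#'   amplitudes (uM).
#' @slot classPeakShift named numeric, per-condition shift of the
#'   response peak delay (s).
#' @slot hbrRatio numeric, HbR/HbO scaling (negative).
#' @slot eventGainSd numeric, sdlog of the per-event log-normal gain.
#' @slot eventLatencySd numeric, sd of per-event onset-latency jitter (s).
#' @slot noise named numeric: `cardiacAmp`, `cardiacHz`, `respAmp`,
#'   `respHz`, `mayerAmp`, `mayerHz`, `whiteSd` (intensity units).
#' @slot artifact named numeric: `spikeRate` (per min), `spikeAmplitude`,
#'   `shiftRate` (per min), `shiftAmplitude` (intensity units).
#' @slot wavelengths numeric length-2 (nm).
#' @slot dpf numeric length-2, differential pathlength factors.
#' @slot extinction 2x2 matrix, rows = wavelengths, cols = (HbO, HbR),
#'   in 1/(uM*cm).
#' @slot distance numeric, source-detector distance (cm).
#' @slot seed integer, fixes all randomness of the simulator.
#' @export
setClass("SyntheticConfig",
  representation(nChannels = "integer", samplingRate = "numeric",
    baselineIntensity = "numeric", hrf = "numeric",
    classAmplitude = "matrix", classPeakShift = "numeric",
    hbrRatio = "numeric", eventGainSd = "numeric",
    eventLatencySd = "numeric", noise = "numeric", artifact = "numeric",
    wavelengths = "numeric", dpf = "numeric", extinction = "matrix",
    distance = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (!all(is.finite(object@classAmplitude)))
    msg <- c(msg, "classAmplitude must be finite")
  if (ncol(object@classAmplitude) != object@nChannels)
    msg <- c(msg, "classAmplitude must have one column per channel")
  if (!all(is.finite(object@noise)) || any(object@noise < 0))
    msg <- c(msg, "noise amplitudes must be finite and >= 0")
  if (any(object@artifact[c("spikeRate", "shiftRate")] < 0))
    msg <- c(msg, "artifact rates must be >= 0")
  if (any(dim(object@extinction) != c(2L, 2L)))
    msg <- c(msg, "extinction must be 2x2")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d channels @ %.4f Hz, wavelengths %s nm, seed %d\n",
    object@nChannels, object@samplingRate,
    paste(object@wavelengths, collapse = "/"), object@seed))
  cat(sprintf("  conditions: %s\n",
              paste(rownames(object@classAmplitude), collapse = ", ")))
  cat(sprintf("  noise white sd %.2g, artifacts %.2g spikes/min\n",
              object@noise[["whiteSd"]], object@artifact[["spikeRate"]]))
})

#' GroundTruth: the simulator's hidden state
#'
#' Clean (noise- and artifact-free) concentration series, the event
#' labels, and the positions of injected artifacts, kept alongside a
#' simulated [OpticalRecording-class] so recovery can be scored.
#'
#' @slot cleanHbo,cleanHbr channels x samples matrices (uM).
#' @slot events `data.frame` of task events with condition labels.
#' @slot artifacts `data.frame` with columns `channel`, `wavelength`,
#'   `index`, `type` ("spike"/"shift"), `amplitude`.
#' @export
setClass("GroundTruth",
  representation(cleanHbo = "matrix", cleanHbr = "matrix",
                 events = "data.frame", artifacts = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d channels x %d samples, %d events, %d artifacts\n",
              nrow(object@cleanHbo), ncol(object@cleanHbo),
              nrow(object@events), nrow(object@artifacts)))
})

# ---------------------------------------------------------------------------
# OpticalRecording

#' OpticalRecording: dual-wavelength raw intensity time series
#'
#' A `SummarizedExperiment` with one assay per wavelength (named
#' `"w<nm>"`), rows = channels, columns = samples. `rowData` carries the
#' channel id, source-detector distance (cm) and a normalized montage
#' position in `[0, 1]`. Metadata holds the sampling rate, start time
#' and (for simulated data) the [GroundTruth-class].
#'
#' Intensities must be strictly positive (optical density is a log of
#' them) and both wavelengths must be present for every channel.
#'
#' @seealso [simulateRecording()], [opticalDensity()]
#' @export
setClass("OpticalRecording", contains = "SummarizedExperiment")

setValidity("OpticalRecording", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (length(an) != 2 || !all(grepl("^w[0-9]+$", an)))
    msg <- c(msg, "needs exactly two wavelength assays named w<nm>")
  for (a in an)
    if (!all(assay(object, a) > 0))
      msg <- c(msg, sprintf("assay %s has non-positive intensities", a))
  md <- metadata(object)
  if (is.null(md$samplingRate) || md$samplingRate <= 0)
    msg <- c(msg, "metadata samplingRate must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an OpticalRecording
#'
#' @param intensity list of channels x samples matrices, one per
#'   wavelength, in device units (strictly positive).
#' @param wavelengths numeric vector of wavelengths (nm), same length as
#'   `intensity`.
#' @param samplingRate Hz.
#' @param channelIds character vector of channel labels; default
#'   `CH01...`.
#' @param distance source-detector distance, cm.
#' @param startTime time of the first sample (s).
#' @param groundTruth optional [GroundTruth-class].
#' @return An [OpticalRecording-class].
#' @export
OpticalRecording <- function(intensity, wavelengths = c(760, 850),
                             samplingRate = 3.9063, channelIds = NULL,
                             distance = 3, startTime = 0,
                             groundTruth = NULL) {
  stopifnot(is.list(intensity), length(intensity) == length(wavelengths))
  nch <- nrow(intensity[[1]])
  if (is.null(channelIds)) channelIds <- sprintf("CH%02d", seq_len(nch))
  assays <- lapply(intensity, function(m) {
    dimnames(m) <- list(channelIds, NULL)
    m
  })
  names(assays) <- sprintf("w%d", wavelengths)
  rd <- DataFrame(channelId = channelIds,
                  distanceCm = rep(distance, nch),
                  position = if (nch > 1) (seq_len(nch) - 0.5) / nch else 0.5,
                  row.names = channelIds)
  se <- SummarizedExperiment(assays = assays, rowData = rd)
  metadata(se) <- list(samplingRate = samplingRate,
                       wavelengths = wavelengths, startTime = startTime,
                       groundTruth = groundTruth)
  new("OpticalRecording", se)
}

#' @describeIn OpticalRecording-class sampling rate (Hz).
#' @param x an `OpticalRecording`.
#' @export
setMethod("samplingRate", "OpticalRecording",
          function(x) metadata(x)$samplingRate)

#' @describeIn OpticalRecording-class time of first sample (s).
#' @export
setMethod("startTime", "OpticalRecording", function(x) metadata(x)$startTime)

#' @describeIn OpticalRecording-class sample time stamps (s).
#' @export
setMethod("timePoints", "OpticalRecording", function(x)
  metadata(x)$startTime + (seq_len(ncol(x)) - 1) / metadata(x)$samplingRate)

#' @describeIn OpticalRecording-class intensity matrix at one wavelength.
#' @param wavelength wavelength in nm (defaults to the first).
#' @export
setMethod("intensity", "OpticalRecording", function(x, wavelength) {
  if (missing(wavelength)) wavelength <- metadata(x)$wavelengths[1]
  a <- sprintf("w%d", wavelength)
  if (!a %in% assayNames(x))
    stop("no assay for wavelength ", wavelength, " nm")
  assay(x, a)
})

#' @describeIn OpticalRecording-class simulator ground truth or NULL.
#' @export
setMethod("groundTruth", "OpticalRecording",
          function(x) metadata(x)$groundTruth)

setMethod("show", "OpticalRecording", function(object) {
  cat(sprintf(
    "OpticalRecording: %d channels x %d samples @ %.4f Hz (%s nm)\n",
    nrow(object), ncol(object), samplingRate(object),
    paste(metadata(object)$wavelengths, collapse = "/")))
  cat(sprintf("  start %.2f s, duration %.1f s%s\n", startTime(object),
              ncol(object) / samplingRate(object),
              if (!is.null(groundTruth(object))) ", with ground truth" else ""))
})

# ---------------------------------------------------------------------------
# HemodynamicRecording

#' HemodynamicRecording: concentration-change time series
#'
#' A `SummarizedExperiment` with assays `hbo`, `hbr`, `hbt`
#' (channels x samples, uM). The identity `hbt = hbo + hbr` is enforced
#' by validity while the series are on the concentration scale; after
#' per-chromophore z-normalization (which discards the common scale and
#' would make the sum cancel) the metadata flag `normalized` is set and
#' the identity is no longer required.
#'
#' @seealso [mbll()], [preprocessRecording()]
#' @export
setClass("HemodynamicRecording", contains = "SummarizedExperiment")

setValidity("HemodynamicRecording", function(object) {
  msg <- character()
  if (!all(c("hbo", "hbr", "hbt") %in% assayNames(object)))
    msg <- c(msg, "needs assays hbo, hbr, hbt")
  else if (!isTRUE(metadata(object)$normalized)) {
    d <- max(abs(assay(object, "hbt") -
                 (assay(object, "hbo") + assay(object, "hbr"))))
    if (!is.finite(d) || d > 1e-8)
      msg <- c(msg, "hbt must equal hbo + hbr")
  }
  md <- metadata(object)
  if (is.null(md$samplingRate) || md$samplingRate <= 0)
    msg <- c(msg, "metadata samplingRate must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a HemodynamicRecording
#'
#' @param hbo,hbr channels x samples matrices of concentration changes
#'   (uM). `hbt` defaults to their sum.
#' @param hbt total-hemoglobin matrix; supply only for normalized data.
#' @param samplingRate Hz.
#' @param startTime time of first sample (s).
#' @param rejectedChannels character vector of channel ids removed by
#'   quality control.
#' @param normalized set `TRUE` when the series are z-normalized
#'   features rather than concentrations.
#' @return A [HemodynamicRecording-class].
#' @export
HemodynamicRecording <- function(hbo, hbr, hbt = hbo + hbr,
                                 samplingRate = 3.9063, startTime = 0,
                                 rejectedChannels = character(),
                                 normalized = FALSE) {
  stopifnot(all(dim(hbo) == dim(hbr)))
  se <- SummarizedExperiment(assays = list(hbo = hbo, hbr = hbr, hbt = hbt))
  metadata(se) <- list(samplingRate = samplingRate, startTime = startTime,
                       rejectedChannels = rejectedChannels,
                       normalized = normalized)
  new("HemodynamicRecording", se)
}

#' @describeIn HemodynamicRecording-class sampling rate (Hz).
#' @param x a `HemodynamicRecording`.
#' @export
setMethod("samplingRate", "HemodynamicRecording",
          function(x) metadata(x)$samplingRate)

#' @describeIn HemodynamicRecording-class time of first sample (s).
#' @export
setMethod("startTime", "HemodynamicRecording",
          function(x) metadata(x)$startTime)

#' @describeIn HemodynamicRecording-class sample time stamps (s).
#' @export
setMethod("timePoints", "HemodynamicRecording", function(x)
  metadata(x)$startTime + (seq_len(ncol(x)) - 1) / metadata(x)$samplingRate)

#' @describeIn HemodynamicRecording-class oxygenated Hb changes (uM).
#' @export
setMethod("hbo", "HemodynamicRecording", function(x) assay(x, "hbo"))

#' @describeIn HemodynamicRecording-class deoxygenated Hb changes (uM).
#' @export
setMethod("hbr", "HemodynamicRecording", function(x) assay(x, "hbr"))

#' @describeIn HemodynamicRecording-class total Hb changes (uM).
#' @export
setMethod("hbt", "HemodynamicRecording", function(x) assay(x, "hbt"))

#' @describeIn HemodynamicRecording-class ids rejected by QC.
#' @export
setMethod("rejectedChannels", "HemodynamicRecording",
          function(x) metadata(x)$rejectedChannels)

setMethod("show", "HemodynamicRecording", function(object) {
  cat(sprintf("HemodynamicRecording: %d channels x %d samples @ %.4f Hz\n",
              nrow(object), ncol(object), samplingRate(object)))
  rj <- rejectedChannels(object)
  if (length(rj)) cat("  rejected:", paste(rj, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# PreprocessReport

#' PreprocessReport: per-stage log of the preprocessing pipeline
#'
#' @slot channelCV `data.frame`: channel, wavelength, cv (percent).
#' @slot rejected character vector of rejected channel ids.
#' @slot spikeCounts named integer vector, flagged samples per series.
#' @slot settings list of the settings the pipeline ran with.
#' @slot stages character vector, the stage names in execution order.
#' @export
setClass("PreprocessReport",
  representation(channelCV = "data.frame", rejected = "character",
                 spikeCounts = "integer", settings = "list",
                 stages = "character"))

setValidity("PreprocessReport", function(object) {
  if (length(object@rejected) &&
      !all(object@rejected %in% object@channelCV$channel))
    "rejected ids must be a subset of the surveyed channels" else TRUE
})

setMethod("show", "PreprocessReport", function(object) {
  cat(sprintf("PreprocessReport: %d stages, %d channels rejected, %d spikes\n",
              length(object@stages), length(object@rejected),
              sum(object@spikeCounts)))
  cat("  stages:", paste(object@stages, collapse = " -> "), "\n")
})

# ---------------------------------------------------------------------------
# EpochSet

#' EpochSet: stimulus-locked epochs or event averages
#'
#' Columns of `epochs` are fixed-length stimulus-locked segments, one
#' per (channel, chromophore, event) — or one per group after
#' [eventAverage()], in which case `trial` is `NA`.
#'
#' @slot epochs nPoints x nEpochs numeric matrix.
#' @slot info `data.frame` with columns `channel`, `chromophore`,
#'   `condition`, `trial`, `onset`.
#' @slot tGrid numeric, time of each row relative to stimulus onset (s).
#' @export
setClass("EpochSet",
  representation(epochs = "matrix", info = "data.frame", tGrid = "numeric"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (ncol(object@epochs) != nrow(object@info))
    msg <- c(msg, "one info row per epoch required")
  if (nrow(object@epochs) != length(object@tGrid))
    msg <- c(msg, "tGrid must have one entry per sample")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs x %d samples, t in [%.2f, %.2f] s\n",
              ncol(object@epochs), nrow(object@epochs),
              min(object@tGrid), max(object@tGrid)))
})

# ---------------------------------------------------------------------------
# FingerFeatureSet

#' FingerFeatureSet: event-average feature vectors with labels
#'
#' A `SummarizedExperiment` whose single assay `features` is a
#' time-points x examples matrix; each column is one training example
#' (the event average of one channel/chromophore/condition[, run]).
#' `colData` carries `label` (the finger condition), `channel`,
#' `chromophore` and `run`.
#'
#' @seealso [buildFeatureMatrix()], [featureValues()], [exampleLabels()]
#' @export
setClass("FingerFeatureSet", contains = "SummarizedExperiment")

setValidity("FingerFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "needs assay 'features'")
  else if (!all(is.finite(assay(object, "features"))))
    msg <- c(msg, "features must be finite")
  if (!all(c("label", "channel", "chromophore", "run") %in%
           colnames(colData(object))))
    msg <- c(msg, "colData needs label, channel, chromophore, run")
  else if (!all(as.character(colData(object)$label) %in%
                fingerConditions(rest = TRUE)))
    msg <- c(msg, "labels must be finger conditions (or rest)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn FingerFeatureSet-class examples x time-points matrix.
#' @param x a `FingerFeatureSet`.
#' @export
setMethod("featureValues", "FingerFeatureSet",
          function(x) t(assay(x, "features")))

#' @describeIn FingerFeatureSet-class finger label per example.
#' @export
setMethod("exampleLabels", "FingerFeatureSet", function(x)
  factor(as.character(colData(x)$label),
         levels = intersect(fingerConditions(rest = TRUE),
                            unique(as.character(colData(x)$label)))))

setMethod("show", "FingerFeatureSet", function(object) {
  lab <- table(as.character(colData(object)$label))
  cat(sprintf("FingerFeatureSet: %d examples x %d time points\n",
              ncol(object), nrow(object)))
  cat("  classes:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "),
      "\n")
})

# ---------------------------------------------------------------------------
# Evaluation / plans

#' EvaluationReport: confusion matrix and per-class metrics
#'
#' @slot confusion K x K integer matrix; entry (i, j) counts true class
#'   i predicted as class j.
#' @slot perClass `data.frame`: class, precision, recall, f1, support,
#'   zeroDivision.
#' @slot accuracy numeric scalar.
#' @slot macro named numeric: unweighted means of precision/recall/f1.
#' @slot weighted named numeric: support-weighted means.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 accuracy = "numeric", macro = "numeric",
                 weighted = "numeric"))

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: N = %d, accuracy %.3f, macro F1 %.3f\n",
              sum(object@confusion), object@accuracy,
              object@macro[["f1"]]))
  print(object@perClass, row.names = FALSE, digits = 3)
})

#' SplitPlan: train/test partition specification
#'
#' @slot strategy `"stratified-pooled"` (per-class sampling of pooled
#'   examples) or `"by-run"` (whole runs held out).
#' @slot testFraction numeric in (0, 1).
#' @slot seed integer.
#' @seealso [splitFeatures()]
#' @export
setClass("SplitPlan",
  representation(strategy = "character", testFraction = "numeric",
                 seed = "integer"))

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (!object@strategy %in% c("stratified-pooled", "by-run"))
    msg <- c(msg, "unknown strategy")
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must be in (0, 1)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Create a SplitPlan
#'
#' @param strategy `"stratified-pooled"` or `"by-run"`.
#' @param testFraction fraction of examples (or runs) held out.
#' @param seed integer seed for the partition.
#' @return A [SplitPlan-class].
#' @export
splitPlan <- function(strategy = "stratified-pooled", testFraction = 0.2,
                      seed = 1L) {
  new("SplitPlan", strategy = strategy, testFraction = testFraction,
      seed = as.integer(seed))
}

#' TrainingPlan: optimization settings for the deep models
#'
#' Defaults follow the published training recipe: batch size 32, L2
#' penalty, cyclic triangular learning rate in `[1e-5, 1e-2]` for the
#' dense baseline and Hemo-Net, fixed 1e-4 for the recurrent and hybrid
#' models (set `lrSchedule = "fixed"`).
#'
#' @slot batchSize integer.
#' @slot maxEpochs integer.
#' @slot lrSchedule `"cyclic"` or `"fixed"`.
#' @slot lrMin,lrMax cyclic triangular bounds.
#' @slot lr fixed learning rate (used when `lrSchedule = "fixed"`).
#' @slot l2 L2 weight-penalty coefficient.
#' @slot valFraction fraction of training data held out for early
#'   stopping.
#' @slot patience early-stopping patience (epochs).
#' @slot seed integer seed for initialization and shuffling.
#' @export
setClass("TrainingPlan",
  representation(batchSize = "integer", maxEpochs = "integer",
                 lrSchedule = "character", lrMin = "numeric",
                 lrMax = "numeric", lr = "numeric", l2 = "numeric",
                 valFraction = "numeric", patience = "integer",
                 seed = "integer"))

setValidity("TrainingPlan", function(object) {
  msg <- character()
  if (!(object@lrMin > 0 && object@lrMin < object@lrMax))
    msg <- c(msg, "need 0 < lrMin < lrMax")
  if (!object@lrSchedule %in% c("cyclic", "fixed"))
    msg <- c(msg, "lrSchedule must be 'cyclic' or 'fixed'")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Create a TrainingPlan
#'
#' @param batchSize minibatch size.
#' @param maxEpochs maximum training epochs.
#' @param lrSchedule `"cyclic"` (triangular between `lrMin` and `lrMax`)
#'   or `"fixed"` (constant `lr`).
#' @param lrMin,lrMax cyclic learning-rate bounds.
#' @param lr fixed learning rate.
#' @param l2 L2 weight penalty.
#' @param valFraction validation fraction for early stopping (0 turns
#'   early stopping off).
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed.
#' @return A [TrainingPlan-class].
#' @export
trainingPlan <- function(batchSize = 32, maxEpochs = 100,
                         lrSchedule = "cyclic", lrMin = 1e-5, lrMax = 1e-2,
                         lr = 1e-4, l2 = 1e-4, valFraction = 0.15,
                         patience = 20, seed = 1L) {
  new("TrainingPlan", batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), lrSchedule = lrSchedule,
      lrMin = lrMin, lrMax = lrMax, lr = lr, l2 = l2,
      valFraction = valFraction, patience = as.integer(patience),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# FittedDecoder

#' FittedDecoder: a trained classifier under the common contract
#'
#' Every model in the registry (see [decoderNames()]) is returned as a
#' `FittedDecoder`; `predict()` yields hard labels and [predictProb()]
#' class probabilities that are nonnegative and sum to one per row.
#'
#' @slot name registry name of the model family.
#' @slot fit internal fitted state (family-specific list).
#' @slot classes character vector of class labels, fixed at fit time.
#' @slot info list: hyperparameters, CV table, training history, notes.
#' @export
setClass("FittedDecoder",
  representation(name = "character", fit = "list", classes = "character",
                 info = "list"))

setMethod("show", "FittedDecoder", function(object) {
  cat(sprintf("FittedDecoder '%s' over %d classes (%s)\n", object@name,
              length(object@classes), paste(object@classes, collapse = ", ")))
  hp <- object@info$hyperparameters
  if (!is.null(hp))
    cat("  hyperparameters:",
        paste(sprintf("%s=%s", names(hp), unlist(lapply(hp, format))),
              collapse = ", "), "\n")
})
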