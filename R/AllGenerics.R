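#' @useDynLib HemoDecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats approx coef cor fft mad median optim predict quantile
#'   rbinom rnorm rpois runif sd setNames var
#' @importFrom utils head modifyList read.csv read.delim tail write.csv
#'   write.table
NULL

#' Sampling rate accessor
#'
#' Returns the acquisition rate, in Hz, of a recording or timeline.
#'
#' @param x an object with a sampling rate.
#' @return A numeric scalar (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Start time of a recording
#'
#' Time, in seconds, of the first retained sample relative to the
#' experiment clock. Zero for a freshly simulated recording; positive
#' after truncation to the stimulus window.
#'
#' @param x a recording object.
#' @return A numeric scalar (seconds).
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' Sample time stamps
#'
#' @param x a recording object.
#' @return Numeric vector of sample times in seconds on the experiment
#'   clock (`startTime(x) + (0:(n-1)) / samplingRate(x)`).
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' Raw intensity matrix of an optical recording
#'
#' @param x an [OpticalRecording-class].
#' @param wavelength one of the recording's wavelengths (nm); defaults to
#'   the first.
#' @return channels x samples numeric matrix in device units.
#' @export
setGeneric("intensity", function(x, wavelength) standardGeneric("intensity"))

#' Chromophore concentration accessors
#'
#' `hbo()`, `hbr()` and `hbt()` return the per-channel oxygenated,
#' deoxygenated and total hemoglobin concentration change series (uM)
#' of a [HemodynamicRecording-class].
#'
#' @param x a [HemodynamicRecording-class].
#' @return channels x samples numeric matrix (uM).
#' @export
setGeneric("hbo", function(x) standardGeneric("hbo"))

#' @rdname hbo
#' @export
setGeneric("hbr", function(x) standardGeneric("hbr"))

#' @rdname hbo
#' @export
setGeneric("hbt", function(x) standardGeneric("hbt"))

#' Ground truth of a simulated recording
#'
#' @param x an [OpticalRecording-class] produced by [simulateRecording()].
#' @return A [GroundTruth-class] object, or `NULL` for real data.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Channels rejected by quality control
#'
#' @param x a [HemodynamicRecording-class].
#' @return Character vector of rejected channel ids (possibly empty).
#' @export
setGeneric("rejectedChannels", function(x) standardGeneric("rejectedChannels"))

#' Stimulus events of a timeline
#'
#' @param x a [StimulusTimeline-class].
#' @return A `data.frame` with columns `onset`, `duration`, `condition`
#'   (task blocks only; rest is implicit).
#' @export
setGeneric("stimEvents", function(x) standardGeneric("stimEvents"))

#' Total duration of a timeline
#'
#' @param x a [StimulusTimeline-class].
#' @return Numeric scalar, seconds.
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' Feature matrix of a feature set
#'
#' @param x a [FingerFeatureSet-class].
#' @return N x P numeric matrix, one row per training example (the
#'   transpose of the stored time-points x examples assay).
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Class labels of a feature set
#'
#' @param x a [FingerFeatureSet-class].
#' @return Factor of length N with the finger condition of each example.
#' @export
setGeneric("exampleLabels", function(x) standardGeneric("exampleLabels"))

#' Class probability predictions
#'
#' @param object a [FittedDecoder-class].
#' @param newdata N x P numeric matrix of feature vectors.
#' @param ... further arguments passed to methods.
#' @return N x K matrix of class probabilities; rows sum to one.
#' @export
setGeneric("predictProb", function(object, newdata, ...)
  standardGeneric("predictProb"))
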