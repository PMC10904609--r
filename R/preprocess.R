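# Preprocessing pipeline: truncation -> spike interpolation -> CV channel
# rejection -> optical density -> modified Beer-Lambert inversion ->
# band-pass -> TDDR -> normalization.

#' Default extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' acquisition wavelengths, in 1/(uM*cm), compiled from the Gratzer/Cope
#' tabulated spectra as distributed with the Homer analysis suite
#' (values at 760 and 850 nm divided by 1e6 to convert from
#' 1/(M*cm)).
#'
#' @param wavelengths numeric length-2; only `c(760, 850)` is tabulated.
#' @return 2x2 matrix, rows = wavelengths, columns = `HbO`, `HbR`.
#' @export
extinctionDefaults <- function(wavelengths = c(760, 850)) {
  tab <- rbind(`760` = c(HbO = 1486.5865, HbR = 3843.707),
               `850` = c(HbO = 2526.391,  HbR = 1798.643)) / 1e6
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("extinction coefficients tabulated only for 760 and 850 nm")
  tab[key, , drop = FALSE]
}

#' Truncate a recording to its stimulus window
#'
#' Drops samples before `first onset - pad` and after
#' `last onset + last duration + pad`. The default 5 s pad preserves the
#' pre-stimulus margin that epoching later needs.
#'
#' @param rec an [OpticalRecording-class].
#' @param timeline a [StimulusTimeline-class] with at least one task
#'   event.
#' @param pad seconds kept on either side of the stimulus span.
#' @return A truncated [OpticalRecording-class]; its `startTime` records
#'   the experiment-clock time of the new first sample.
#' @export
truncateRecording <- function(rec, timeline, pad = 5) {
  ev <- stimEvents(timeline)
  if (!nrow(ev)) stop("timeline has no task events")
  fs <- samplingRate(rec)
  t <- timePoints(rec)
  lo <- min(ev$onset) - pad
  hi <- max(ev$onset + ev$duration) + pad
  keep <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  if (!length(keep)) stop("truncation window contains no samples")
  wl <- metadata(rec)$wavelengths
  ints <- lapply(wl, function(w) intensity(rec, w)[, keep, drop = FALSE])
  out <- OpticalRecording(ints, wavelengths = wl, samplingRate = fs,
                          channelIds = rownames(rec),
                          distance = rowData(rec)$distanceCm[1],
                          startTime = t[keep[1]],
                          groundTruth = groundTruth(rec))
  rowData(out) <- rowData(rec)
  out
}

#' Interpolate spike artifacts in a series
#'
#' Samples whose robust z-score `|x - median| / (1.4826 * MAD)` exceeds
#' `zThresh` are replaced by linear interpolation between the nearest
#' non-flagged neighbors; flagged endpoints take the nearest valid
#' value.
#'
#' @param x numeric vector (length >= 3).
#' @param zThresh robust z threshold; default 5 flags only gross
#'   excursions.
#' @return list with `series` (repaired vector) and `flagged` (integer
#'   indices of replaced samples).
#' @export
removeSpikes <- function(x, zThresh = 5) {
  if (length(x) < 3) stop("series too short for spike removal")
  med <- median(x)
  s <- mad(x)  # 1.4826 * MAD
  z <- if (s > 0) abs(x - med) / s else ifelse(x == med, 0, Inf)
  bad <- which(z > zThresh)
  if (length(bad) == length(x)) stop("all samples flagged as spikes")
  if (length(bad)) {
    idx <- seq_along(x)
    good <- setdiff(idx, bad)
    x[bad] <- approx(good, x[good], xout = bad, rule = 2)$y
  }
  list(series = x, flagged = bad)
}

#' Coefficient of variation of a series
#'
#' `100 * sd / |mean|` with the population standard deviation
#' (denominator n), the usual optode signal-quality index.
#'
#' @param x numeric vector.
#' @return CV in percent.
#' @export
channelCV <- function(x) {
  m <- mean(x)
  if (m == 0) stop("CV undefined for zero-mean series")
  100 * sqrt(mean((x - m)^2)) / abs(m)
}

#' Reject noisy channels by coefficient of variation
#'
#' A channel is rejected when its raw-intensity CV strictly exceeds
#' `threshold` at either wavelength; survivors keep their original
#' order. Rejection is idempotent.
#'
#' @param rec an [OpticalRecording-class].
#' @param threshold CV threshold in percent (default 7.5). A channel at
#'   exactly the threshold is retained.
#' @return list with `recording` (surviving channels), `rejected`
#'   (character ids) and `cv` (data.frame channel/wavelength/cv).
#' @export
rejectChannels <- function(rec, threshold = 7.5) {
  stopifnot(threshold > 0)
  wl <- metadata(rec)$wavelengths
  cvTab <- do.call(rbind, lapply(wl, function(w) {
    m <- intensity(rec, w)
    data.frame(channel = rownames(m), wavelength = w,
               cv = apply(m, 1, channelCV))
  }))
  bad <- unique(cvTab$channel[cvTab$cv > threshold])
  if (length(bad) == nrow(rec))
    stop("all channels rejected (CV > ", threshold, "%); inspect the data")
  keep <- setdiff(rownames(rec), bad)
  out <- rec[keep, ]
  list(recording = out, rejected = bad, cv = cvTab)
}

#' Optical density change
#'
#' `dOD(t) = -log10(I(t) / I_ref)` per channel and wavelength. By
#' default the reference is the channel's own temporal mean, the usual
#' convention for continuous-wave data; a known DC level can be passed
#' instead (e.g. the simulator's baseline intensity), in which case the
#' Beer-Lambert inversion recovers absolute concentration changes
#' rather than changes about the recording mean.
#'
#' @param rec an [OpticalRecording-class] (strictly positive
#'   intensities).
#' @param reference `"mean"`, or a positive numeric DC intensity.
#' @return list of channels x samples OD matrices, one per wavelength,
#'   named `w760`, `w850`.
#' @export
opticalDensity <- function(rec, reference = "mean") {
  wl <- metadata(rec)$wavelengths
  od <- lapply(wl, function(w) {
    m <- intensity(rec, w)
    if (any(m <= 0)) stop("non-positive intensity")
    ref <- if (identical(reference, "mean")) rowMeans(m) else reference
    if (any(ref <= 0)) stop("reference intensity must be positive")
    -log10(m / ref)
  })
  names(od) <- sprintf("w%d", wl)
  od
}

#' Modified Beer-Lambert inversion
#'
#' Solves, per channel and sample, the 2x2 linear system
#' `dOD_lambda = d * DPF_lambda * (eps_lambda,HbO * dHbO +
#' eps_lambda,HbR * dHbR)` for the concentration changes.
#'
#' @param od list of two channels x samples OD matrices (one per
#'   wavelength, in the order of `extinction` rows).
#' @param dpf differential pathlength factors, length 2.
#' @param extinction 2x2 extinction matrix, 1/(uM*cm); see
#'   [extinctionDefaults()].
#' @param distance source-detector distance, cm.
#' @param samplingRate Hz, recorded in the result.
#' @param startTime seconds, recorded in the result.
#' @return A [HemodynamicRecording-class] (uM).
#' @export
mbll <- function(od, dpf = c(6, 6), extinction = extinctionDefaults(),
                 distance = 3, samplingRate = 3.9063, startTime = 0) {
  stopifnot(length(od) == 2, distance > 0)
  A <- distance * diag(dpf) %*% extinction   # (dOD1, dOD2) = A (HbO, HbR)
  if (abs(det(A)) < 1e-14 * max(abs(A))^2)
    stop("extinction system is singular; cannot separate HbO/HbR")
  Ainv <- solve(A)
  nch <- nrow(od[[1]])
  hboM <- Ainv[1, 1] * od[[1]] + Ainv[1, 2] * od[[2]]
  hbrM <- Ainv[2, 1] * od[[1]] + Ainv[2, 2] * od[[2]]
  rownames(hboM) <- rownames(hbrM) <- rownames(od[[1]])
  HemodynamicRecording(hboM, hbrM, samplingRate = samplingRate,
                       startTime = startTime)
}

#' Forward modified Beer-Lambert composition
#'
#' The inverse of [mbll()]: maps concentration changes to optical
#' density changes. Used by the simulator and by roundtrip tests.
#'
#' @param hboM,hbrM channels x samples matrices (uM).
#' @inheritParams mbll
#' @return list of two OD matrices in wavelength order.
#' @export
mbllForward <- function(hboM, hbrM, dpf = c(6, 6),
                        extinction = extinctionDefaults(), distance = 3) {
  A <- distance * diag(dpf) %*% extinction
  list(A[1, 1] * hboM + A[1, 2] * hbrM,
       A[2, 1] * hboM + A[2, 2] * hbrM)
}

#' Z-normalize a series with a baseline offset
#'
#' `(x - mean) / sd + baselineOffset`: unit variance with the baseline
#' mean moved to a fixed positive value so that downstream event
#' averages sit on a common, sign-safe level.
#'
#' @param x numeric vector with positive variance.
#' @param baselineOffset value the mean is moved to (default 10).
#' @return Normalized vector (mean `baselineOffset`, sd 1).
#' @export
normalizeSeries <- function(x, baselineOffset = 10) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot normalize constant series")
  (x - mean(x)) / s + baselineOffset
}

#' Preprocessing settings
#'
#' @param pad truncation pad, s.
#' @param spikeZ robust z threshold for spike interpolation.
#' @param cvThreshold channel-rejection CV threshold, percent.
#' @param lowHz,highHz band-pass edges, Hz.
#' @param filterOrder Butterworth order per cascade section.
#' @param dpf differential pathlength factors.
#' @param extinction 2x2 extinction matrix, 1/(uM*cm).
#' @param distance source-detector distance, cm.
#' @param baselineOffset normalization offset.
#' @param stages the pipeline stage order; fixed, any permutation is an
#'   error.
#' @return A settings list for [preprocessRecording()].
#' @export
preprocessSettings <- function(pad = 5, spikeZ = 5, cvThreshold = 7.5,
                               lowHz = 0.01, highHz = 0.5, filterOrder = 4,
                               dpf = c(6, 6),
                               extinction = extinctionDefaults(),
                               distance = 3, baselineOffset = 10,
                               stages = .PIPELINE_STAGES) {
  list(pad = pad, spikeZ = spikeZ, cvThreshold = cvThreshold,
       lowHz = lowHz, highHz = highHz, filterOrder = filterOrder,
       dpf = dpf, extinction = extinction, distance = distance,
       baselineOffset = baselineOffset, stages = stages)
}

.PIPELINE_STAGES <- c("truncate", "spikes", "reject", "od", "mbll",
                      "bandpass", "tddr", "normalize")

#' Run the full preprocessing pipeline
#'
#' Applies, in fixed order: truncation to the stimulus window, spike
#' interpolation, CV-based channel rejection, optical-density
#' conversion, modified Beer-Lambert inversion, zero-phase Butterworth
#' band-pass, temporal-derivative distribution repair, and per-channel
#' per-chromophore normalization. The band-pass and repair act on the
#' `hbo` and `hbr` concentration series with `hbt` as their sum; the
#' final z-normalization is applied to each of the three chromophore
#' series independently (they are features from then on, so the
#' additive identity is deliberately given up; the result carries
#' `normalized = TRUE`).
#'
#' @param rec an [OpticalRecording-class].
#' @param timeline the matching [StimulusTimeline-class].
#' @param settings list from [preprocessSettings()].
#' @return list with `recording` (a [HemodynamicRecording-class]) and
#'   `report` (a [PreprocessReport-class]).
#' @examples
#' tl <- buildParadigm(nSessions = 1)
#' cfg <- syntheticPreset("high-snr", nChannels = 4, seed = 1)
#' rec <- simulateRecording(tl, cfg)
#' out <- preprocessRecording(rec, tl)
#' out$report
#' @export
preprocessRecording <- function(rec, timeline,
                                settings = preprocessSettings()) {
  if (!identical(settings$stages, .PIPELINE_STAGES))
    stop("the pipeline stage order is fixed: ",
         paste(.PIPELINE_STAGES, collapse = " -> "))
  fs <- samplingRate(rec)

  rec <- truncateRecording(rec, timeline, pad = settings$pad)

  wl <- metadata(rec)$wavelengths
  spikeCounts <- integer(0)
  ints <- lapply(wl, function(w) {
    m <- intensity(rec, w)
    for (i in seq_len(nrow(m))) {
      fix <- removeSpikes(m[i, ], zThresh = settings$spikeZ)
      m[i, ] <- fix$series
      spikeCounts[[sprintf("%s_w%d", rownames(m)[i], w)]] <<-
        length(fix$flagged)
    }
    m
  })
  rec2 <- OpticalRecording(ints, wavelengths = wl, samplingRate = fs,
                           channelIds = rownames(rec),
                           distance = rowData(rec)$distanceCm[1],
                           startTime = startTime(rec),
                           groundTruth = groundTruth(rec))

  rj <- rejectChannels(rec2, threshold = settings$cvThreshold)
  rec2 <- rj$recording

  od <- opticalDensity(rec2)
  hb <- mbll(od, dpf = settings$dpf, extinction = settings$extinction,
             distance = rowData(rec2)$distanceCm[1], samplingRate = fs,
             startTime = startTime(rec2))

  hboM <- t(bandpassFilter(t(hbo(hb)), fs, lowHz = settings$lowHz,
                           highHz = settings$highHz,
                           order = settings$filterOrder))
  hbrM <- t(bandpassFilter(t(hbr(hb)), fs, lowHz = settings$lowHz,
                           highHz = settings$highHz,
                           order = settings$filterOrder))

  hboM <- t(tddr(t(hboM), fs))
  hbrM <- t(tddr(t(hbrM), fs))
  hbtM <- hboM + hbrM

  hboM <- t(apply(hboM, 1, normalizeSeries,
                  baselineOffset = settings$baselineOffset))
  hbrM <- t(apply(hbrM, 1, normalizeSeries,
                  baselineOffset = settings$baselineOffset))
  hbtM <- t(apply(hbtM, 1, normalizeSeries,
                  baselineOffset = settings$baselineOffset))
  rownames(hboM) <- rownames(hbrM) <- rownames(hbtM) <- rownames(rec2)

  out <- HemodynamicRecording(hboM, hbrM, hbtM, samplingRate = fs,
                              startTime = startTime(rec2),
                              rejectedChannels = rj$rejected,
                              normalized = TRUE)
  report <- new("PreprocessReport", channelCV = rj$cv,
                rejected = rj$rejected, spikeCounts = spikeCounts,
                settings = settings, stages = .PIPELINE_STAGES)
  list(recording = out, report = report)
}
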