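# Block-design paradigm and dual-wavelength recording simulator.
# The generator's defaults reproduce the acquisition this package is
# designed around: 3.9063 Hz continuous-wave recording at 760/850 nm over
# a motor-cortex montage, a 30 s baseline followed by three sessions of
# five finger-tapping trials (10 s rest + 10 s task each) and a 20 s
# terminal rest, 350 s in total.

#' Build a block-design finger-tapping paradigm
#'
#' A baseline rest, then `nSessions` passes over all conditions (each
#' trial = `trialRest` s of rest followed by `trialTask` s of task),
#' then a terminal rest. The default configuration (3 sessions x 5
#' fingers x (10 + 10) s, 30 s baseline, 20 s terminal rest) totals
#' 350 s.
#'
#' @param nSessions number of passes over the condition list.
#' @param conditions character vector of task conditions (non-empty).
#' @param trialRest rest before each task block, s (>= 0).
#' @param trialTask task-block duration, s (> 0).
#' @param baseline initial rest, s (>= 0).
#' @param terminalRest final rest, s (>= 0).
#' @param samplingRate Hz, carried by the timeline.
#' @param shuffle if `TRUE`, the condition order is permuted
#'   independently within each session (seeded by `seed`); the default
#'   keeps the fixed thumb-to-little order.
#' @param seed integer seed used only when `shuffle = TRUE`.
#' @return A [StimulusTimeline-class]; `totalDuration` equals
#'   `baseline + nSessions * length(conditions) * (trialRest +
#'   trialTask) + terminalRest`.
#' @examples
#' tl <- buildParadigm()
#' totalDuration(tl)  # 350
#' @export
buildParadigm <- function(nSessions = 3, conditions = fingerConditions(),
                          trialRest = 10, trialTask = 10, baseline = 30,
                          terminalRest = 20, samplingRate = 3.9063,
                          shuffle = FALSE, seed = 1L) {
  if (length(conditions) < 1) stop("conditions must be non-empty")
  if (any(c(trialRest, baseline, terminalRest) < 0))
    stop("durations must be non-negative")
  if (trialTask <= 0) stop("trialTask must be > 0 (empty trials are invalid)")
  if (nSessions < 1) stop("nSessions must be >= 1")

  onsets <- numeric(0); labels <- character(0)
  t <- baseline
  if (shuffle) {
    rng <- .seededRNG(seed)
    on.exit(rng$restore(), add = TRUE)
  }
  for (s in seq_len(nSessions)) {
    order <- if (shuffle) sample(conditions) else conditions
    for (cond in order) {
      t <- t + trialRest
      onsets <- c(onsets, t)
      labels <- c(labels, cond)
      t <- t + trialTask
    }
  }
  total <- t + terminalRest
  ev <- data.frame(onset = onsets, duration = rep(trialTask, length(onsets)),
                   condition = labels, stringsAsFactors = FALSE)
  new("StimulusTimeline", events = ev, totalDuration = total,
      samplingRate = samplingRate)
}

# Save/restore the global RNG around seeded simulator calls so that the
# simulator is a pure function of its config and does not disturb the
# caller's RNG stream.
.seededRNG <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a positive lobe peaking near
#' `peakDelay` seconds minus a scaled undershoot lobe, normalized to a
#' maximum of one.
#'
#' @param t non-negative, increasing time grid (s).
#' @param peakDelay time-to-peak of the positive lobe, s.
#' @param undershootDelay time-to-trough of the undershoot, s.
#' @param peakDispersion,undershootDispersion gamma dispersions (scale
#'   parameters, s).
#' @param undershootRatio amplitude ratio of undershoot to peak.
#' @return numeric vector, `h(0) = 0`, `max(h) = 1`, late undershoot,
#'   decaying to zero.
#' @examples
#' h <- canonicalHrf(seq(0, 30, by = 0.1))
#' @export
canonicalHrf <- function(t, peakDelay = 6, undershootDelay = 16,
                         peakDispersion = 1, undershootDispersion = 1,
                         undershootRatio = 1 / 6) {
  if (is.unsorted(t, strictly = TRUE)) stop("time grid must be increasing")
  if (any(t < 0)) stop("time grid must be non-negative")
  if (peakDispersion <= 0 || undershootDispersion <= 0 || peakDelay <= 0 ||
      undershootDelay <= 0)
    stop("HRF delays and dispersions must be positive")
  a1 <- peakDelay / peakDispersion
  a2 <- undershootDelay / undershootDispersion
  g <- function(t, a, b) ifelse(t > 0, stats::dgamma(t, shape = a, scale = b), 0)
  h <- g(t, a1, peakDispersion) - undershootRatio * g(t, a2, undershootDispersion)
  m <- max(h)
  if (m <= 0) stop("degenerate HRF parameters")
  h / m
}

.defaultClassAmplitude <- function(conditions, nChannels, base = 1,
                                   gains = NULL, envelopeWidth = 0.35) {
  # Separable amplitude map: a monotone per-finger response gain times a
  # shared spatial sensitivity profile over the montage (strongest over
  # the central optodes, in [0.5, 1]). Keeping the spatial factor common
  # to all fingers reflects optode-coupling heterogeneity while leaving
  # the finger-specific amplitude ratios identical in every channel.
  if (is.null(gains))
    gains <- seq(0.6, 1.4, length.out = length(conditions))
  pos <- if (nChannels > 1) (seq_len(nChannels) - 0.5) / nChannels else 0.5
  profile <- 0.5 + 0.5 * exp(-(pos - 0.5)^2 / (2 * envelopeWidth^2))
  amp <- base * (gains %o% profile)
  rownames(amp) <- conditions
  amp
}

#' Simulator configuration
#'
#' Assembles a [SyntheticConfig-class]. Defaults emulate a clean
#' motor-cortex finger-tapping acquisition: peak HbO responses of order
#' 1 uM with a somatotopy-like spatial envelope and a monotone
#' amplitude gradient plus a small per-finger peak-latency offset
#' (+-0.5 s around the canonical 6 s), HbR at -1/3 of HbO, cardiac
#' (1.1 Hz), respiratory (0.3 Hz) and Mayer-wave (0.1 Hz) oscillations
#' and white noise at a fraction of a percent of the DC intensity.
#'
#' @param nChannels montage channel count.
#' @param conditions task condition labels.
#' @param samplingRate Hz.
#' @param baselineIntensity DC detected intensity (device units).
#' @param hrf named numeric of HRF parameters (see
#'   [canonicalHrf()]): `peakDelay`, `undershootDelay`,
#'   `peakDispersion`, `undershootDispersion`, `undershootRatio`.
#' @param classAmplitude conditions x channels matrix of peak HbO
#'   amplitudes (uM); default somatotopy-like map.
#' @param amplitudeBase scaling of the default amplitude map.
#' @param classPeakShift named per-condition shift of the HRF peak
#'   delay (s).
#' @param hbrRatio HbR/HbO amplitude ratio (negative).
#' @param eventGainSd sdlog of the log-normal per-event gain (trial-to-
#'   trial response variability); 0 disables.
#' @param eventLatencySd sd of the per-event onset latency jitter (s).
#' @param cardiacAmp,cardiacHz,respAmp,respHz,mayerAmp,mayerHz
#'   physiological oscillation amplitudes (intensity units) and
#'   frequencies (Hz). The cardiac component may alias at the default
#'   sampling rate; that is faithful to the acquisition.
#' @param whiteSd white-noise sd (intensity units).
#' @param spikeRate,spikeAmplitude,shiftRate,shiftAmplitude motion
#'   artifact rates (events per minute) and amplitudes (intensity
#'   units), used by [injectArtifacts()].
#' @param wavelengths nm, length 2.
#' @param dpf differential pathlength factors.
#' @param extinction 2x2 extinction matrix 1/(uM*cm).
#' @param distance source-detector distance, cm.
#' @param seed integer; fixes all simulator randomness.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nChannels = 48, conditions = fingerConditions(),
    samplingRate = 3.9063, baselineIntensity = 1,
    hrf = c(peakDelay = 6, undershootDelay = 16, peakDispersion = 1,
            undershootDispersion = 1, undershootRatio = 1 / 6),
    classAmplitude = NULL, amplitudeBase = 1,
    classPeakShift = NULL, hbrRatio = -1 / 3,
    eventGainSd = 0.15, eventLatencySd = 0.3,
    cardiacAmp = 4e-3, cardiacHz = 1.1, respAmp = 2e-3, respHz = 0.3,
    mayerAmp = 2e-3, mayerHz = 0.1, whiteSd = 2e-3,
    spikeRate = 0, spikeAmplitude = 0.05, shiftRate = 0,
    shiftAmplitude = 0.02, wavelengths = c(760, 850), dpf = c(6, 6),
    extinction = extinctionDefaults(), distance = 3, seed = 1L) {
  if (is.null(classAmplitude))
    classAmplitude <- .defaultClassAmplitude(conditions, nChannels,
                                             base = amplitudeBase)
  if (is.null(classPeakShift))
    classPeakShift <- setNames(
      seq(-0.5, 0.5, length.out = nrow(classAmplitude)) *
        (nrow(classAmplitude) > 1), rownames(classAmplitude))
  new("SyntheticConfig", nChannels = as.integer(nChannels),
      samplingRate = samplingRate, baselineIntensity = baselineIntensity,
      hrf = hrf, classAmplitude = classAmplitude,
      classPeakShift = classPeakShift, hbrRatio = hbrRatio,
      eventGainSd = eventGainSd, eventLatencySd = eventLatencySd,
      noise = c(cardiacAmp = cardiacAmp, cardiacHz = cardiacHz,
                respAmp = respAmp, respHz = respHz, mayerAmp = mayerAmp,
                mayerHz = mayerHz, whiteSd = whiteSd),
      artifact = c(spikeRate = spikeRate, spikeAmplitude = spikeAmplitude,
                   shiftRate = shiftRate, shiftAmplitude = shiftAmplitude),
      wavelengths = wavelengths, dpf = dpf, extinction = extinction,
      distance = distance, seed = as.integer(seed))
}

#' Named simulator presets
#'
#' Fixed study conditions used throughout the package's tests and
#' examples:
#' \describe{
#'   \item{`"default"`}{the realistic defaults of [syntheticConfig()].}
#'   \item{`"high-snr"`}{strong distinct class responses, quarter-scale
#'     physiological noise and low trial variability: the
#'     parameter-recovery regime.}
#'   \item{`"mid-snr"`}{reduced response amplitude (x0.6), full
#'     physiological noise, higher trial variability: the regime where
#'     model ranking is examined.}
#'   \item{`"null"`}{identical amplitude map and latency for every
#'     condition: labels carry no information (chance-level control).}
#'   \item{`"artifacts"`}{defaults plus 2 spikes/min and 0.5 baseline
#'     shifts/min.}
#' }
#'
#' @param name preset name.
#' @param nChannels montage size.
#' @param seed integer seed.
#' @param ... further overrides passed to [syntheticConfig()].
#' @return A [SyntheticConfig-class].
#' @export
syntheticPreset <- function(name = c("default", "high-snr", "mid-snr",
                                     "null", "artifacts"),
                            nChannels = 48, seed = 1L, ...) {
  name <- match.arg(name)
  conds <- fingerConditions()
  switch(name,
    "default" = syntheticConfig(nChannels = nChannels, seed = seed, ...),
    "high-snr" = syntheticConfig(nChannels = nChannels, seed = seed,
      amplitudeBase = 1.2, whiteSd = 5e-4, cardiacAmp = 1e-3,
      respAmp = 5e-4, mayerAmp = 5e-4, eventGainSd = 0.05,
      eventLatencySd = 0.1, ...),
    "mid-snr" = syntheticConfig(nChannels = nChannels, seed = seed,
      amplitudeBase = 0.6, whiteSd = 3e-3, eventGainSd = 0.25,
      eventLatencySd = 0.5, ...),
    "null" = syntheticConfig(nChannels = nChannels, seed = seed,
      classAmplitude = matrix(1, length(conds), nChannels,
                              dimnames = list(conds, NULL)),
      classPeakShift = setNames(rep(0, length(conds)), conds), ...),
    "artifacts" = syntheticConfig(nChannels = nChannels, seed = seed,
      spikeRate = 2, shiftRate = 0.5, ...))
}

#' Simulate a dual-wavelength recording
#'
#' Clean concentration responses (condition boxcar convolved with the
#' canonical HRF, scaled so the peak equals the class amplitude, with
#' seeded per-event gain and latency variability), forward
#' Beer-Lambert composition to optical densities, conversion to
#' intensities around the DC level, then physiological sinusoids with
#' seeded random phases and white noise. The same config (including
#' seed) yields bit-identical output.
#'
#' @param timeline a [StimulusTimeline-class]; its sampling rate must
#'   equal the config's.
#' @param cfg a [SyntheticConfig-class].
#' @return An [OpticalRecording-class] whose metadata carries the
#'   [GroundTruth-class].
#' @examples
#' tl <- buildParadigm(nSessions = 1)
#' rec <- simulateRecording(tl, syntheticPreset("high-snr", nChannels = 2))
#' @export
simulateRecording <- function(timeline, cfg) {
  if (abs(samplingRate(timeline) - cfg@samplingRate) > 1e-9)
    stop("timeline and config sampling rates differ")
  ev <- stimEvents(timeline)
  conds <- rownames(cfg@classAmplitude)
  if (nrow(ev) && !all(ev$condition %in% conds))
    stop("timeline conditions missing from classAmplitude map")
  fs <- cfg@samplingRate
  n <- max(1L, round(totalDuration(timeline) * fs))
  nch <- cfg@nChannels
  tgrid <- (seq_len(n) - 1) / fs

  rng <- .seededRNG(cfg@seed)
  on.exit(rng$restore(), add = TRUE)

  hboM <- matrix(0, nch, n)
  if (nrow(ev)) {
    # per-event trial variability, seeded
    gains <- if (cfg@eventGainSd > 0)
      exp(rnorm(nrow(ev), 0, cfg@eventGainSd)) else rep(1, nrow(ev))
    lags <- if (cfg@eventLatencySd > 0)
      rnorm(nrow(ev), 0, cfg@eventLatencySd) else rep(0, nrow(ev))
    hrfGrid <- seq(0, 32, by = 1 / fs)
    for (i in seq_len(nrow(ev))) {
      p <- cfg@hrf
      shift <- cfg@classPeakShift[[ev$condition[i]]] + lags[i]
      h <- canonicalHrf(hrfGrid,
                        peakDelay = max(2, p[["peakDelay"]] + shift),
                        undershootDelay = p[["undershootDelay"]] + shift,
                        peakDispersion = p[["peakDispersion"]],
                        undershootDispersion = p[["undershootDispersion"]],
                        undershootRatio = p[["undershootRatio"]])
      box <- rep(1, max(1L, round(ev$duration[i] * fs)))
      resp <- convolve(box, rev(h), type = "open")
      resp <- resp / max(resp)          # peak amplitude = 1
      k0 <- round(ev$onset[i] * fs) + 1L
      idx <- k0:min(n, k0 + length(resp) - 1L)
      amp <- cfg@classAmplitude[ev$condition[i], ] * gains[i]
      hboM[, idx] <- hboM[, idx] + amp %o% resp[seq_along(idx)]
    }
  }
  hbrM <- cfg@hbrRatio * hboM

  od <- mbllForward(hboM, hbrM, dpf = cfg@dpf, extinction = cfg@extinction,
                    distance = cfg@distance)
  nz <- cfg@noise
  ints <- lapply(od, function(odw) {
    I <- cfg@baselineIntensity * 10^(-odw)
    for (comp in c("cardiac", "resp", "mayer")) {
      a <- nz[[paste0(comp, "Amp")]]; f <- nz[[paste0(comp, "Hz")]]
      if (a > 0) {
        ph <- runif(nch, 0, 2 * pi)
        I <- I + a * sin(outer(ph, 2 * pi * f * tgrid, `+`))
      }
    }
    if (nz[["whiteSd"]] > 0)
      I <- I + matrix(rnorm(nch * n, 0, nz[["whiteSd"]]), nch, n)
    I
  })

  gt <- new("GroundTruth", cleanHbo = hboM, cleanHbr = hbrM, events = ev,
            artifacts = data.frame(channel = character(),
                                   wavelength = numeric(),
                                   index = integer(), type = character(),
                                   amplitude = numeric()))
  OpticalRecording(ints, wavelengths = cfg@wavelengths, samplingRate = fs,
                   distance = cfg@distance, startTime = 0,
                   groundTruth = gt)
}

#' Inject motion artifacts into a recording
#'
#' Adds isolated single-sample spikes and sustained baseline shifts at
#' seeded random positions (Poisson counts at the configured per-minute
#' rates), independently per channel and wavelength. Artifact positions
#' are appended to the recording's [GroundTruth-class].
#'
#' @param rec an [OpticalRecording-class].
#' @param cfg a [SyntheticConfig-class]; uses its `artifact` rates and
#'   amplitudes and `seed + 1` for the artifact stream.
#' @return The recording with artifacts added.
#' @export
injectArtifacts <- function(rec, cfg) {
  art <- cfg@artifact
  if (art[["spikeRate"]] == 0 && art[["shiftRate"]] == 0) return(rec)
  rng <- .seededRNG(cfg@seed + 1L)
  on.exit(rng$restore(), add = TRUE)
  wl <- metadata(rec)$wavelengths
  n <- ncol(rec)
  minutes <- n / samplingRate(rec) / 60
  log <- list()
  ints <- lapply(wl, function(w) {
    m <- intensity(rec, w)
    for (i in seq_len(nrow(m))) {
      nspike <- rpois(1, art[["spikeRate"]] * minutes)
      if (nspike > 0) {
        pos <- sample.int(n, nspike)
        amp <- art[["spikeAmplitude"]] * sample(c(-1, 1), nspike, TRUE)
        m[i, pos] <- m[i, pos] + amp
        log[[length(log) + 1L]] <<- data.frame(channel = rownames(m)[i],
          wavelength = w, index = pos, type = "spike", amplitude = amp)
      }
      nshift <- rpois(1, art[["shiftRate"]] * minutes)
      if (nshift > 0) {
        pos <- sort(sample.int(n - 1L, nshift))
        amp <- art[["shiftAmplitude"]] * sample(c(-1, 1), nshift, TRUE)
        for (j in seq_len(nshift)) m[i, pos[j]:n] <- m[i, pos[j]:n] + amp[j]
        log[[length(log) + 1L]] <<- data.frame(channel = rownames(m)[i],
          wavelength = w, index = pos, type = "shift", amplitude = amp)
      }
    }
    m
  })
  gt <- groundTruth(rec)
  if (!is.null(gt) && length(log))
    gt@artifacts <- rbind(gt@artifacts, do.call(rbind, log))
  OpticalRecording(ints, wavelengths = wl, samplingRate = samplingRate(rec),
                   channelIds = rownames(rec),
                   distance = rowData(rec)$distanceCm[1],
                   startTime = startTime(rec), groundTruth = gt)
}
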