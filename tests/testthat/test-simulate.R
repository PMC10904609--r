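# Block-design paradigm and recording simulator.

test_that("paradigm duration follows the block-design formula", {
  tl <- buildParadigm(nSessions = 2, conditions = c("thumb", "index"),
                      trialRest = 5, trialTask = 5, baseline = 10,
                      terminalRest = 0)
  expect_equal(totalDuration(tl), 50)           # 10 + 2*2*(5+5)
  expect_equal(nrow(stimEvents(tl)), 4)

  # property: exact for random non-negative configurations
  set.seed(11)
  for (i in 1:20) {
    ns <- sample(1:4, 1); nc <- sample(1:5, 1)
    tr <- runif(1, 0, 15); tt <- runif(1, 0.5, 15)
    bl <- runif(1, 0, 40); te <- runif(1, 0, 25)
    tl <- buildParadigm(ns, fingerConditions()[seq_len(nc)], tr, tt, bl, te)
    expect_equal(totalDuration(tl), bl + ns * nc * (tr + tt) + te)
    expect_equal(nrow(stimEvents(tl)), ns * nc)
    ev <- stimEvents(tl)
    expect_false(is.unsorted(ev$onset))
  }
})

test_that("degenerate or negative paradigm arguments are rejected", {
  expect_error(buildParadigm(1, "thumb", 0, 0, 0, 0), "trialTask")
  expect_error(buildParadigm(1, "thumb", -1, 10, 30, 0), "non-negative")
  expect_error(buildParadigm(1, character(), 10, 10, 30, 0), "non-empty")
})

test_that("canonical HRF has the expected shape", {
  t <- seq(0, 32, by = 0.01)
  h <- canonicalHrf(t)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak <- t[which.max(h)]
  expect_gt(peak, 4); expect_lt(peak, 7)
  # late undershoot then decay to zero
  expect_lt(min(h[t > 10]), 0)
  expect_lt(abs(h[length(h)]), 0.01)
  expect_error(canonicalHrf(t, peakDispersion = 0), "positive")
  expect_error(canonicalHrf(rev(t)), "increasing")
})

test_that("simulator is deterministic and respects the null model", {
  tl <- buildParadigm(nSessions = 1)
  cfg <- syntheticPreset("default", nChannels = 3, seed = 9)
  r1 <- simulateRecording(tl, cfg)
  r2 <- simulateRecording(tl, cfg)
  expect_identical(intensity(r1, 760), intensity(r2, 760))
  expect_identical(intensity(r1, 850), intensity(r2, 850))

  # zero amplitudes, zero noise -> constant intensity
  conds <- fingerConditions()
  cfg0 <- syntheticConfig(nChannels = 2, seed = 1,
    classAmplitude = matrix(0, 5, 2, dimnames = list(conds, NULL)),
    cardiacAmp = 0, respAmp = 0, mayerAmp = 0, whiteSd = 0)
  r0 <- simulateRecording(tl, cfg0)
  expect_equal(max(intensity(r0, 760)) - min(intensity(r0, 760)), 0)
})

test_that("white-noise level is recovered from a task-free recording", {
  conds <- fingerConditions()
  tl <- buildParadigm()  # 350 s -> 1367 samples > 1000 per channel
  sigma <- 3e-3
  cfg <- syntheticConfig(nChannels = 4, seed = 21,
    classAmplitude = matrix(0, 5, 4, dimnames = list(conds, NULL)),
    cardiacAmp = 0, respAmp = 0, mayerAmp = 0, whiteSd = sigma)
  rec <- simulateRecording(tl, cfg)
  sds <- apply(intensity(rec, 760), 1, sd)
  expect_true(all(abs(sds - sigma) / sigma < 0.1))
})

test_that("forward-then-inverse Beer-Lambert recovers the injected curve", {
  tl <- buildParadigm()
  cfg <- syntheticConfig(nChannels = 1, seed = 2, whiteSd = 0,
                         cardiacAmp = 0, respAmp = 0, mayerAmp = 0,
                         eventGainSd = 0, eventLatencySd = 0)
  rec <- simulateRecording(tl, cfg)
  od <- opticalDensity(rec, reference = cfg@baselineIntensity)
  hb <- mbll(od, samplingRate = samplingRate(rec))
  gt <- groundTruth(rec)
  scale <- max(abs(gt@cleanHbo))
  expect_lt(max(abs(hbo(hb) - gt@cleanHbo)) / scale, 1e-8)
  expect_lt(max(abs(hbr(hb) - gt@cleanHbr)) / scale, 1e-8)
})

test_that("artifact injection is additive, seeded and rate-faithful", {
  tl <- buildParadigm()
  cfg <- syntheticPreset("default", nChannels = 2, seed = 5)
  rec <- simulateRecording(tl, cfg)
  expect_identical(injectArtifacts(rec, cfg), rec)  # rates 0 -> unchanged

  cfgA <- syntheticConfig(nChannels = 2, seed = 5, spikeRate = 2,
                          shiftRate = 0)  # spikes only: clean additivity
  recA <- injectArtifacts(rec, cfgA)
  art <- groundTruth(recA)@artifacts
  spikes <- art[art$type == "spike", ]
  expect_gt(nrow(spikes), 0)
  # additive contract at logged spike positions (1 spike alone at an index)
  one <- spikes[!duplicated(spikes[c("channel", "wavelength", "index")]) &
                !duplicated(spikes[c("channel", "wavelength", "index")],
                            fromLast = TRUE), ]
  for (i in seq_len(min(5, nrow(one)))) {
    w <- one$wavelength[i]
    delta <- unname(intensity(recA, w)[one$channel[i], one$index[i]] -
                    intensity(rec, w)[one$channel[i], one$index[i]])
    expect_equal(delta, one$amplitude[i], tolerance = 1e-12)
  }
  # counts near the configured rate: 2 spikes/min over ~5.8 min,
  # per channel and wavelength; pooled Poisson mean ~ 47
  minutes <- ncol(rec) / samplingRate(rec) / 60
  lambda <- 2 * minutes * 2 * 2
  expect_gt(nrow(spikes), lambda - 4 * sqrt(lambda))
  expect_lt(nrow(spikes), lambda + 4 * sqrt(lambda))
})

test_that("timeline and recording round-trip through text files", {
  tl <- buildParadigm(nSessions = 1)
  cfg <- syntheticPreset("default", nChannels = 2, seed = 3)
  rec <- simulateRecording(tl, cfg)
  td <- withr::local_tempdir()
  writeEvents(tl, file.path(td, "ev.tsv"))
  tl2 <- readEvents(file.path(td, "ev.tsv"),
                    totalDuration = totalDuration(tl))
  expect_equal(stimEvents(tl2), stimEvents(tl))
  writeRecording(rec, file.path(td, "rec.csv"))
  rec2 <- readRecording(file.path(td, "rec.csv"))
  expect_equal(unname(intensity(rec2, 760)), unname(intensity(rec, 760)),
               tolerance = 1e-12)
  expect_equal(samplingRate(rec2), samplingRate(rec))
})
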