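# Preprocessing stages: truncation, spike interpolation, CV rejection,
# optical density, Beer-Lambert inversion, normalization, pipeline.

test_that("truncation keeps the padded stimulus window", {
  fs <- 3.9063
  n <- round(100 * fs)
  set.seed(1)
  ints <- list(matrix(runif(2 * n, 0.9, 1.1), 2),
               matrix(runif(2 * n, 0.9, 1.1), 2))
  rec <- OpticalRecording(ints, samplingRate = fs)
  ev <- data.frame(onset = c(30, 50), duration = c(10, 10),
                   condition = c("thumb", "index"))
  tl <- new("StimulusTimeline", events = ev, totalDuration = 100,
            samplingRate = fs)
  out <- truncateRecording(rec, tl, pad = 5)
  t <- timePoints(out)
  expect_gte(min(t), 25 - 1e-9)
  expect_lte(max(t), 65 + 1e-9)
  # expected sample count by index arithmetic
  keep <- which(timePoints(rec) >= 25 - 1e-9 & timePoints(rec) <= 65 + 1e-9)
  expect_equal(ncol(out), length(keep))

  full <- new("StimulusTimeline",
              events = data.frame(onset = 0.01, duration = 99.9,
                                  condition = "thumb"),
              totalDuration = 100, samplingRate = fs)
  expect_equal(ncol(truncateRecording(rec, full, pad = 5)), ncol(rec))
  empty <- new("StimulusTimeline",
               events = data.frame(onset = numeric(), duration = numeric(),
                                   condition = character()),
               totalDuration = 100, samplingRate = fs)
  expect_error(truncateRecording(rec, empty), "no task events")
})

test_that("spike interpolation bridges flagged samples linearly", {
  x <- rep(10, 50)
  expect_identical(removeSpikes(x + rnorm(50, 0, 1e-3))$flagged, integer(0))

  xs <- x; xs[20] <- 110
  fix <- removeSpikes(xs)
  expect_equal(fix$flagged, 20L)
  expect_equal(fix$series[20], mean(c(xs[19], xs[21])))

  xa <- x; xa[20:21] <- c(200, 150)   # two adjacent spikes
  fa <- removeSpikes(xa)
  expect_equal(fa$flagged, 20:21)
  # linear bridge between samples 19 and 22
  expect_equal(fa$series[20:21],
               xa[19] + (xa[22] - xa[19]) * (1:2) / 3)

  expect_error(removeSpikes(c(1, 2)), "too short")
})

test_that("coefficient of variation uses population sd in percent", {
  expect_equal(channelCV(rep(5, 10)), 0)
  expect_equal(channelCV(c(90, 110)), 10)   # pop sd 10, mean 100
  expect_error(channelCV(c(-1, 1)), "zero-mean")
})

test_that("channel rejection is strict, order-preserving and idempotent", {
  fs <- 3.9063; n <- 500
  set.seed(4)
  mk <- function(cv) {
    # two-point series with exact population CV = cv (%)
    rep(c(100 - cv, 100 + cv), length.out = n)
  }
  m760 <- rbind(A = mk(1), B = mk(10), C = mk(7.5), D = mk(2))
  m850 <- rbind(A = mk(1), B = mk(1),  C = mk(1),   D = mk(2))
  rec <- OpticalRecording(list(m760, m850), samplingRate = fs,
                          channelIds = c("A", "B", "C", "D"))
  rj <- rejectChannels(rec, threshold = 7.5)
  expect_equal(rj$rejected, "B")          # 10% at 760 nm only
  expect_equal(rownames(rj$recording), c("A", "C", "D"))  # C at 7.5 kept
  rj2 <- rejectChannels(rj$recording, threshold = 7.5)
  expect_equal(rj2$rejected, character(0))

  bad <- OpticalRecording(list(rbind(X = mk(20)), rbind(X = mk(20))),
                          samplingRate = fs, channelIds = "X")
  expect_error(rejectChannels(bad), "all channels")
})

test_that("optical density matches the direct formula", {
  fs <- 3.9063; n <- 400
  const <- matrix(2, 1, n)
  rec <- OpticalRecording(list(const, const), samplingRate = fs)
  od <- opticalDensity(rec)
  expect_equal(max(abs(od$w760)), 0)

  t <- seq_len(n)
  sine <- matrix(1 + 0.1 * sin(2 * pi * t / 50), 1, n)
  rec2 <- OpticalRecording(list(sine, const), samplingRate = fs)
  od2 <- opticalDensity(rec2)
  expect_equal(od2$w760, -log10(sine / rowMeans(sine)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # I = Iref / 10 at one sample -> dOD = 1 there
  ten <- matrix(1, 1, n); ten[1, 7] <- 1 / 10
  rec3 <- OpticalRecording(list(ten, const), samplingRate = fs)
  expect_equal(unname(opticalDensity(rec3, reference = 1)$w760[1, 7]), 1)
})

test_that("Beer-Lambert inversion round-trips random concentration fields", {
  set.seed(8)
  hboM <- matrix(rnorm(600), 4)
  hbrM <- matrix(rnorm(600), 4)
  od <- mbllForward(hboM, hbrM)
  hb <- mbll(od)
  scale <- max(abs(hboM), abs(hbrM))
  expect_lt(max(abs(hbo(hb) - hboM)) / scale, 1e-10)
  expect_lt(max(abs(hbr(hb) - hbrM)) / scale, 1e-10)
  expect_equal(hbt(hb), hbo(hb) + hbr(hb))

  expect_equal(max(abs(hbo(mbll(list(hboM * 0, hbrM * 0))))), 0)
  singular <- matrix(c(1, 2, 2, 4), 2, byrow = TRUE)  # proportional rows
  expect_error(mbll(od, extinction = singular), "singular")
})

test_that("normalization yields mean offset and unit sd", {
  set.seed(2)
  x <- rnorm(500, 3, 7)
  z <- normalizeSeries(x)
  expect_equal(mean(z), 10, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # standard-normal input is close to identity + offset
  u <- rnorm(20000)
  expect_lt(max(abs(normalizeSeries(u) - 10 - u)), 0.05)
  expect_error(normalizeSeries(rep(1, 10)), "constant")
})

test_that("pipeline runs clean data without rejections and logs stages", {
  fx <- fixtureRun()
  expect_equal(length(fx$report@rejected), 0)
  expect_equal(sum(fx$report@spikeCounts), 0)
  expect_equal(fx$report@stages,
               c("truncate", "spikes", "reject", "od", "mbll", "bandpass",
                 "tddr", "normalize"))
  hb <- fx$hb
  # per-series normalization held
  expect_equal(unname(rowMeans(hbo(hb))), rep(10, nrow(hb)),
               tolerance = 1e-6)
  expect_equal(unname(apply(hbo(hb), 1, sd)), rep(1, nrow(hb)),
               tolerance = 1e-6)

  st <- preprocessSettings()
  st$stages <- rev(st$stages)
  expect_error(preprocessRecording(fx$rec, fx$timeline, st), "fixed")
})

test_that("the chromophore identity holds before normalization", {
  fx <- fixtureRun()
  od <- opticalDensity(fx$rec)
  hb <- mbll(od, samplingRate = samplingRate(fx$rec))
  expect_identical(max(abs(hbt(hb) - (hbo(hb) + hbr(hb)))), 0)
})

test_that("a planted high-CV channel is rejected by the pipeline", {
  tl <- buildParadigm(nSessions = 1)
  cfg <- syntheticPreset("default", nChannels = 3, seed = 13)
  rec <- simulateRecording(tl, cfg)
  wl <- metadata(rec)$wavelengths
  ints <- lapply(wl, function(w) intensity(rec, w))
  n <- ncol(ints[[1]])
  # slow multiplicative instability (smooth, so not a spike artifact)
  tmod <- (seq_len(n) - 1) / samplingRate(rec)
  ints[[1]][2, ] <- ints[[1]][2, ] * (1 + 0.2 * sin(2 * pi * 0.05 * tmod))
  bad <- OpticalRecording(ints, samplingRate = samplingRate(rec))
  out <- preprocessRecording(bad, tl)
  expect_equal(out$report@rejected, "CH02")
  expect_false("CH02" %in% rownames(out$recording))
})
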