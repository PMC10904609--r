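# Epoch extraction, event averaging, feature assembly, scaling.

test_that("default epoching yields 77-sample vectors", {
  fx <- fixtureRun()
  ep <- extractEpochs(fx$hb, fx$timeline)
  expect_equal(nrow(ep@epochs), 77)
  expect_equal(length(ep@tGrid), 77)
  expect_equal(ep@tGrid[1], ceiling(-5 * samplingRate(fx$hb)) /
                 samplingRate(fx$hb))
  # 15 events x 4 channels x 3 chromophores
  expect_equal(ncol(ep@epochs), 15 * 4 * 3)
})

test_that("epochs exceeding the recording bounds fail loudly", {
  fx <- fixtureRun()
  expect_error(extractEpochs(fx$hb, fx$timeline, tPre = 300),
               "exceeds recording bounds")
  expect_error(extractEpochs(fx$hb, fx$timeline, tPost = 400,
                             nPoints = NULL),
               "exceeds recording bounds")
})

test_that("event averages are the elementwise trial mean", {
  # hand-built toy epochs: 2 channels x 1 chromophore, 3 trials each
  ep <- new("EpochSet",
    epochs = cbind(c(1, 2, 3, 4), c(3, 2, 1, 0), c(5, 5, 5, 5),
                   c(0, 0, 0, 0), c(2, 4, 6, 8), c(1, 1, 1, 1)),
    info = data.frame(
      channel = rep(c("A", "B"), each = 3),
      chromophore = "hbo",
      condition = rep(c("thumb", "thumb", "index"), 2),
      trial = c(1, 2, 3, 1, 2, 3), onset = 1:6),
    tGrid = (0:3) / 3.9063)
  av <- eventAverage(ep)
  expect_equal(ncol(av@epochs), 4)  # 2 channels x 2 conditions
  i <- which(av@info$channel == "A" & av@info$condition == "thumb")
  expect_equal(av@epochs[, i], c(2, 2, 2, 2))  # mean of trials 1,2
  j <- which(av@info$channel == "B" & av@info$condition == "index")
  expect_equal(av@epochs[, j], c(1, 1, 1, 1))

  # symmetry: v and -v average to zero
  ep2 <- new("EpochSet", epochs = cbind(c(1, -2, 3), c(-1, 2, -3)),
             info = data.frame(channel = "A", chromophore = "hbo",
                               condition = c("ring", "ring"),
                               trial = 1:2, onset = 1:2),
             tGrid = (0:2))
  expect_equal(unname(eventAverage(ep2)@epochs[, 1]), c(0, 0, 0))
})

test_that("feature matrix has the product-count rows and labels", {
  fx <- fixtureRun()
  av <- eventAverage(extractEpochs(fx$hb, fx$timeline))
  fm <- buildFeatureMatrix(av)
  expect_equal(ncol(fm), 4 * 3 * 5)  # channels x chromophores x conditions
  expect_equal(nrow(fm), 77)
  expect_true(all(table(exampleLabels(fm)) == 12))
  X <- featureValues(fm)
  expect_equal(dim(X), c(60, 77))
  expect_true(all(is.finite(X)))

  bad <- av
  bad@info$condition[1] <- "elbow"
  expect_error(buildFeatureMatrix(bad), "unknown condition")
})

test_that("epoch-average commutes with channel permutation", {
  fx <- fixtureRun()
  av <- eventAverage(extractEpochs(fx$hb, fx$timeline))
  perm <- rev(seq_len(nrow(fx$hb)))
  hbP <- fx$hb[perm, ]
  avP <- eventAverage(extractEpochs(hbP, fx$timeline))
  for (ch in rownames(fx$hb)) {
    i <- which(av@info$channel == ch & av@info$chromophore == "hbo" &
               av@info$condition == "middle")
    j <- which(avP@info$channel == ch & avP@info$chromophore == "hbo" &
               avP@info$condition == "middle")
    expect_equal(av@epochs[, i], avP@epochs[, j])
  }
})

test_that("active-condition averages peak inside the task window", {
  fx <- fixtureRun()
  av <- eventAverage(extractEpochs(fx$hb, fx$timeline))
  hboRows <- which(av@info$chromophore == "hbo")
  for (i in hboRows) {
    tPeak <- av@tGrid[which.max(av@epochs[, i])]
    expect_gte(tPeak, 0); expect_lte(tPeak, 15)
  }
})

test_that("standard scaling learns on train only and transfers", {
  set.seed(14)
  train <- matrix(rnorm(200, 5, 3), 20)
  test <- matrix(rnorm(100, 5, 3), 10)
  s <- standardScale(train)
  expect_equal(unname(colMeans(s)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(s, 2, sd)), rep(1, 10), tolerance = 1e-9)
  sc <- fitScaler(train)
  manual <- sweep(sweep(test, 2, colMeans(train)), 2,
                  apply(train, 2, sd), `/`)
  expect_equal(standardScale(train, test), manual)
  expect_equal(applyScaler(sc, test), manual)
  const <- train; const[, 3] <- 7
  expect_error(fitScaler(const), "zero-variance")
})

test_that("feature sets round-trip through CSV", {
  fx <- fixtureRun()
  fm <- buildFeatureMatrix(eventAverage(extractEpochs(fx$hb, fx$timeline)))
  td <- withr::local_tempdir()
  writeFeatures(fm, file.path(td, "f.csv"))
  fm2 <- readFeatures(file.path(td, "f.csv"))
  expect_equal(featureValues(fm2), featureValues(fm), tolerance = 1e-12)
  expect_equal(as.character(exampleLabels(fm2)),
               as.character(exampleLabels(fm)))
})
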