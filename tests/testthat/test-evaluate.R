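# Splitting, confusion counting, classification reports, experiment
# driver plumbing.

test_that("confusion counts and accuracy match a hand-tallied example", {
  yt <- c(0, 0, 1, 1, 2, 2)
  yp <- c(0, 1, 1, 1, 2, 0)
  cm <- confusionCounts(yt, yp)
  expect_equal(unname(cm),
               rbind(c(1, 1, 0), c(0, 2, 0), c(1, 0, 1)))
  rep <- evaluationReport(cm)
  expect_equal(rep@accuracy, 4 / 6)
  # class 0: Tp 1, predicted 2, support 2
  expect_equal(rep@perClass$precision[1], 0.5)
  expect_equal(rep@perClass$recall[1], 0.5)
  expect_equal(sum(cm), 6)
  expect_equal(rowSums(cm), setNames(c(2, 2, 2), c("0", "1", "2")))
  expect_error(confusionCounts(numeric(), numeric()), "empty")
  expect_error(confusionCounts(c(0, 3), c(0, 0), classes = c("0", "1")),
               "outside")
})

test_that("perfect and degenerate predictions give the boundary metrics", {
  perfect <- evaluationReport(confusionCounts(c("a", "b", "a"),
                                              c("a", "b", "a")))
  expect_equal(perfect@accuracy, 1)
  expect_true(all(perfect@perClass$f1 == 1))

  # one class never predicted -> precision 0 with the zero-division flag
  cm <- confusionCounts(c("a", "a", "b", "b"), c("a", "a", "a", "a"))
  r <- evaluationReport(cm)
  bRow <- r@perClass[r@perClass$class == "b", ]
  expect_equal(bRow$precision, 0)
  expect_true(bRow$zeroDivision)
})

test_that("macro equals weighted under balanced support; K=2 is textbook", {
  set.seed(51)
  yt <- rep(c("a", "b", "c"), each = 30)
  yp <- sample(yt)
  r <- evaluationReport(confusionCounts(yt, yp))
  expect_equal(r@macro, r@weighted, tolerance = 1e-12)

  # binary case reduces to the usual precision/recall
  cm2 <- confusionCounts(c(1, 1, 1, 0, 0), c(1, 1, 0, 0, 1))
  r2 <- evaluationReport(cm2)
  # class "1": Tp = 2, Fp = 1, Fn = 1
  cls1 <- r2@perClass[r2@perClass$class == "1", ]
  expect_equal(cls1$precision, 2 / 3)
  expect_equal(cls1$recall, 2 / 3)
})

test_that("splits are stratified, disjoint and reproducible", {
  fx <- fixtureRun()
  av <- eventAverage(extractEpochs(fx$hb, fx$timeline))
  fm <- buildFeatureMatrix(list(r1 = av, r2 = av, r3 = av, r4 = av, r5 = av))
  # 300 examples, 60 per class
  sp <- splitFeatures(fm, splitPlan(testFraction = 0.2, seed = 7))
  expect_equal(ncol(sp$test), 60)
  expect_true(all(table(exampleLabels(sp$test)) == 12))
  expect_equal(ncol(sp$train) + ncol(sp$test), 300)
  sp2 <- splitFeatures(fm, splitPlan(testFraction = 0.2, seed = 7))
  expect_identical(colnames(sp$test), colnames(sp2$test))

  byrun <- splitFeatures(fm, splitPlan("by-run", 0.2, seed = 3))
  expect_length(intersect(unique(colData(byrun$train)$run),
                          unique(colData(byrun$test)$run)), 0)
})

test_that("the experiment driver is seeded and writes its artifacts", {
  td <- withr::local_tempdir()
  ex1 <- runExperiment(preset = "high-snr", nRuns = 2, nChannels = 4,
                       models = c("lda", "rf"), seed = 9,
                       outDir = file.path(td, "a"))
  ex2 <- runExperiment(preset = "high-snr", nRuns = 2, nChannels = 4,
                       models = c("lda", "rf"), seed = 9,
                       outDir = file.path(td, "b"))
  expect_identical(ex1$accuracy, ex2$accuracy)
  for (f in c("accuracy.csv", "features.csv", "report_lda.csv",
              "confusion_rf.csv"))
    expect_identical(readLines(file.path(td, "a", f)),
                     readLines(file.path(td, "b", f)))
  expect_true(all(ex1$accuracy$testAccuracy >= 0 &
                  ex1$accuracy$testAccuracy <= 1))
  rf <- ex1$reports$rf
  expect_equal(sum(rf@confusion), ncol(ex1$features$test))
})
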