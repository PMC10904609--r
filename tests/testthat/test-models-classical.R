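# Discriminant analysis, multinomial regression, tree ensembles and the
# cross-validated grid search.

test_that("LDA scatter matrices match hand arithmetic on a 2-D toy", {
  x <- rbind(c(0, 0), c(2, 0), c(1, 1),
             c(5, 5), c(7, 5), c(6, 6),
             c(0, 6), c(2, 6), c(1, 7))
  y <- rep(c("a", "b", "c"), each = 3)
  m <- fitLda(x, y, solver = "lsqr")
  # hand: class means (1, 1/3), (6, 16/3), (1, 19/3); per-class centered
  # squares are identical across classes by construction
  ctr <- function(block, mu) crossprod(sweep(block, 2, mu))
  SwHand <- ctr(x[1:3, ], c(1, 1/3)) + ctr(x[4:6, ], c(6, 16/3)) +
            ctr(x[7:9, ], c(1, 19/3))
  expect_equal(m@fit$Sw, SwHand)
  mu <- colMeans(x)
  SbHand <- 3 * ((c(1, 1/3) - mu) %o% (c(1, 1/3) - mu)) +
            3 * ((c(6, 16/3) - mu) %o% (c(6, 16/3) - mu)) +
            3 * ((c(1, 19/3) - mu) %o% (c(1, 19/3) - mu))
  expect_equal(m@fit$Sb, SbHand)
  expect_equal(as.character(predict(m, x)), y)  # separable toy
})

test_that("LDA solvers agree and degenerate cases behave", {
  set.seed(3)
  x <- matrix(rnorm(300), 100, 3)
  y <- rep(c("a", "b"), 50)
  x[y == "b", 1] <- x[y == "b", 1] + 4
  p1 <- predictProb(fitLda(x, y, "svd"), x)
  p2 <- predictProb(fitLda(x, y, "lsqr"), x)
  p3 <- predictProb(fitLda(x, y, "eigen"), x)
  expect_equal(p1, p2, tolerance = 1e-6)
  expect_equal(p1, p3, tolerance = 1e-6)
  # auto shrinkage runs and still separates
  ps <- fitLda(x, y, "lsqr", shrinkage = "auto")
  expect_gt(mean(predict(ps, x) == y), 0.95)
  expect_error(fitLda(x, y, "svd", shrinkage = "auto"), "shrinkage")

  # identical class means -> between-class scatter is (numerically) zero
  set.seed(4)
  x0 <- matrix(rnorm(200), 100, 2)
  y0 <- rep(c("a", "b"), each = 50)
  x0[51:100, ] <- x0[1:50, ]           # same points, both classes
  m0 <- fitLda(x0, y0, solver = "lsqr")
  expect_lt(max(abs(m0@fit$Sb)), 1e-9 * max(abs(m0@fit$Sw)))
  expect_lt(max(abs(m0@fit$eigenvalues)), 1e-9)
})

test_that("QDA posteriors follow Bayes' rule and reduce to LDA", {
  set.seed(6)
  # equal covariance, 1-D: QDA boundary is linear, agrees with LDA
  x <- matrix(c(rnorm(150, 0), rnorm(150, 3)), ncol = 1)
  y <- rep(c("a", "b"), each = 150)
  q <- fitQda(x, y)
  l <- fitLda(x, y, "lsqr")
  expect_gt(mean(predict(q, x) == predict(l, x)), 0.97)

  pq <- predictProb(q, x)
  expect_equal(unname(rowSums(pq)), rep(1, 300), tolerance = 1e-9)
  expect_true(all(pq >= 0))

  # a point at one class mean, far from the other -> posterior ~ 1
  far <- fitQda(rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
                      matrix(rnorm(60, 20, 0.5), ncol = 2)),
                rep(c("a", "b"), each = 30))
  expect_gt(predictProb(far, matrix(c(0, 0), 1))[1, "a"], 0.99)

  # heavy regularization approaches pooled-covariance decisions
  set.seed(7)
  xg <- matrix(rnorm(400), 200, 2)
  yg <- rep(c("a", "b"), each = 100)
  xg[yg == "b", ] <- xg[yg == "b", ] + 1.5
  qr <- fitQda(xg, yg, regParam = 1)
  lr <- fitLda(xg, yg, "lsqr")
  expect_gte(mean(predict(qr, xg) == predict(lr, xg)), 0.95)

  # singular class covariance at reg 0 (more dims than samples)
  xs <- matrix(rnorm(5 * 10), 5, 10)
  expect_error(fitQda(rbind(xs, xs + 5), rep(c("a", "b"), each = 5), 0),
               "singular")
})

test_that("MNLR follows the reference-class softmax", {
  # all-zero weights -> uniform probabilities
  m0 <- new("FittedDecoder", name = "mnlr",
            fit = list(W = matrix(0, 4, 2)),
            classes = c("a", "b", "c"), info = list())
  p <- predictProb(m0, matrix(rnorm(15), 5, 3))
  expect_equal(unname(p), matrix(1 / 3, 5, 3), tolerance = 1e-12)

  # separable toy (with margin) reaches training accuracy 1 at C = 20
  set.seed(12)
  x <- matrix(rnorm(240), 120, 2)
  x <- x[abs(rowSums(x)) > 0.4, , drop = FALSE]
  y <- ifelse(rowSums(x) > 0, "a", "b")
  m <- fitMnlr(x, y, penalty = "l2", C = 20)
  expect_equal(mean(predict(m, x) == y), 1)

  # first-order optimality of the penalized objective
  set.seed(13)
  x3 <- matrix(rnorm(300), 100, 3)
  y3 <- sample(c("a", "b", "c"), 100, TRUE)
  m3 <- fitMnlr(x3, y3, penalty = "l2", C = 1)
  W <- m3@fit$W
  Xd <- cbind(1, x3)
  pr <- HemoDecode:::.softmax(cbind(Xd %*% W, 0))
  yi <- as.integer(factor(y3))
  G <- crossprod(Xd, pr[, -3] - HemoDecode:::.oneHot(yi, 3)[, -3]) / 100
  G <- G + (1 / 1) * rbind(0, W[-1, ]) / 100
  expect_lt(sqrt(sum(G^2)), 1e-3)

  # L1 fit runs and sparsifies at strong regularization
  ml1 <- fitMnlr(x3, y3, penalty = "l1", C = 0.01)
  expect_gt(mean(ml1@fit$W[-1, ] == 0), 0.5)
})

test_that("tree ensembles behave on canonical patterns", {
  # pure-class data
  xp <- matrix(c(rep(0, 20), rep(5, 20)), ncol = 1)
  yp <- rep(c("a", "b"), each = 20)
  expect_equal(mean(predict(fitForest(xp, yp, seed = 2), xp) == yp), 1)

  # XOR needs depth >= 2; a forest solves it
  set.seed(15)
  n <- 400
  x <- matrix(runif(2 * n, -1, 1), n, 2)
  y <- ifelse(x[, 1] * x[, 2] > 0, "a", "b")
  tr <- sample(n, 300)
  rf <- fitForest(x[tr, ], y[tr], nEstimators = 100, seed = 3)
  expect_gt(mean(predict(rf, x[-tr, ]) == y[-tr]), 0.9)
  expect_equal(length(rf@info$importance), 2)

  # boosting training loss decreases monotonically
  xb <- fitBoost(x[tr, ], y[tr], nEstimators = 40, maxDepth = 3,
                 learningRate = 0.3, seed = 4)
  loss <- xb@info$evalLog$train_mlogloss
  expect_true(all(diff(loss) < 1e-9))
  pb <- predictProb(xb, x[-tr, ])
  expect_equal(unname(rowSums(pb)), rep(1, 100), tolerance = 1e-6)
})

test_that("grid search is exhaustive, seeded and tie-stable", {
  set.seed(16)
  x <- matrix(rnorm(400), 200, 2)
  y <- rep(c("a", "b"), each = 100)
  x[y == "b", ] <- x[y == "b", ] + 3

  one <- gridSearchCV(fitQda, data.frame(regParam = 0.5), x, y, seed = 1)
  expect_equal(one$best$regParam, 0.5)

  # duplicate-performance cells: first in grid wins
  tie <- gridSearchCV(fitQda, data.frame(regParam = c(0.3, 0.3)), x, y,
                      seed = 1)
  expect_equal(tie$bestIndex, 1L)
  expect_equal(tie$table$cvAccuracy[1], tie$table$cvAccuracy[2])

  # degenerate cell (stump depth) loses to an adequate depth on XOR
  set.seed(17)
  xx <- matrix(runif(600, -1, 1), 300, 2)
  yy <- ifelse(xx[, 1] * xx[, 2] > 0, "a", "b")
  gs <- gridSearchCV(function(x, y, maxDepth)
    fitForest(x, y, nEstimators = 50, maxDepth = maxDepth, seed = 5),
    data.frame(maxDepth = c(1, 6)), xx, yy, seed = 2)
  expect_equal(gs$best$maxDepth, 6)

  expect_error(gridSearchCV(fitQda, data.frame(), x, y), "empty")
  expect_error(gridSearchCV(fitQda, data.frame(regParam = 0), x[1:8, ],
                            y[c(1:4, 101:104)], folds = 5), "at least")
})

test_that("the published hyperparameter grids are exposed verbatim", {
  g <- decoderGrids()
  expect_setequal(g$qda$regParam, c(0.0, 0.1, 0.5, 1.0))
  expect_setequal(unique(g$mnlr$C), c(0.01, 0.1, 1, 10, 20))
  expect_setequal(unique(g$mnlr$penalty), c("l1", "l2"))
  expect_setequal(unique(g$rf$nEstimators), c(50, 100))
  expect_true(all(is.na(g$rf$maxDepth) | g$rf$maxDepth %in% c(5, 10)))
  expect_setequal(unique(g$rf$minSamplesSplit), c(2, 5))
  expect_setequal(unique(g$rf$minSamplesLeaf), c(1, 4))
  expect_setequal(unique(g$xgboost$learningRate), c(0.1, 0.01, 0.001))
  expect_setequal(unique(g$lda$solver), c("svd", "lsqr", "eigen"))
  expect_setequal(unique(g$lda$shrinkage), c("auto", "none"))
})

test_that("discriminant fits agree with independent implementations", {
  skip_if_not_installed("MASS")
  set.seed(18)
  x <- matrix(rnorm(300), 100, 3)
  y <- factor(rep(c("a", "b"), 50))
  x[y == "b", 2] <- x[y == "b", 2] + 2
  ours <- predict(fitLda(x, y, "lsqr"), x)
  theirs <- predict(MASS::lda(x, y), x)$class
  expect_gt(mean(ours == theirs), 0.98)
  oq <- predict(fitQda(x, y), x)
  tq <- predict(MASS::qda(x, y), x)$class
  expect_gt(mean(oq == tq), 0.98)
})

test_that("fitted decoders round-trip through the archive format", {
  set.seed(19)
  x <- matrix(rnorm(120), 60, 2)
  y <- rep(c("a", "b"), 30)
  x[y == "b", 1] <- x[y == "b", 1] + 3
  fit <- fitDecoder(x, y, "lda")
  td <- withr::local_tempdir()
  p <- file.path(td, "m.rds")
  saveDecoder(fit, p)
  back <- loadDecoder(p)
  expect_identical(predictProb(back, x), predictProb(fit, x))
  saveRDS(list(x = 1), p)
  expect_error(loadDecoder(p), "archive")
})
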