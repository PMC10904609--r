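# Network engine: analytic gradients vs finite differences, layer
# shapes, LSTM cell arithmetic, architecture wiring, training loop.

test_that("backpropagation matches finite differences in every layer", {
  mk <- function(...) HemoDecode:::.hdNet(HemoDecode:::.lSeq(list(...)),
                                          "test", 12, 3)
  L <- asNamespace("HemoDecode")
  set.seed(101)
  dense <- mk(L$.lDense(12, 8), L$.lBN(8), L$.lAct("relu"),
              L$.lDense(8, 3))
  expect_lt(gradCheckNet(dense), 1e-4)
  set.seed(102)
  conv <- mk(L$.lInputSeq(), L$.lConv(1, 4, 3), L$.lBN(4),
             L$.lAct("lrelu"), L$.lPool(3), L$.lConv(4, 5, 4, bias = FALSE),
             L$.lGAP(), L$.lDense(5, 3))
  expect_lt(gradCheckNet(conv), 1e-4)
  set.seed(103)
  flat <- mk(L$.lInputSeq(), L$.lConv(1, 3, 5), L$.lAct("tanh"),
             L$.lFlatten(), L$.lDense(36, 3))
  expect_lt(gradCheckNet(flat), 1e-4)
  set.seed(104)
  rec <- mk(L$.lInputSeq(), L$.lLSTM(1, 6, returnSeq = TRUE),
            L$.lLSTM(6, 5, returnSeq = FALSE), L$.lDense(5, 3))
  expect_lt(gradCheckNet(rec), 1e-4)
  set.seed(105)
  bi <- mk(L$.lInputSeq(), L$.lBiLSTM(1, 4, returnSeq = TRUE),
           L$.lBiLSTM(8, 3, returnSeq = FALSE), L$.lDense(6, 3))
  expect_lt(gradCheckNet(bi), 1e-3)
})

test_that("full architectures backpropagate correctly", {
  set.seed(106)
  expect_lt(gradCheckNet(buildHemoNet(12, 3, nFilters = 3)), 1e-4)
  set.seed(107)
  expect_lt(gradCheckNet(buildHybrid(12, 3)), 1e-4)
})

test_that("LSTM step matches hand-computed values in both forms", {
  H <- 2
  w0 <- list(Wx = matrix(0, 1, 4 * H), Wa = matrix(0, H, 4 * H),
             b = rep(0, 4 * H))
  aPrev <- c(0.3, -0.2); cPrev <- c(0.4, 0.1)
  # zero weights: all gates sigmoid(0) = 0.5, candidate tanh(0) = 0
  lit <- lstmStep(0, aPrev, cPrev, w0, form = "literal")
  expect_equal(lit$u, c(0.5, 0.5))
  expect_equal(lit$g, c(0, 0))
  expect_equal(lit$c, 1 / (1 + exp(-0.5 * cPrev)))   # sigma(0.5 c_prev)
  expect_equal(lit$a, 1 / (1 + exp(-0.5 * lit$c)))
  can <- lstmStep(0, aPrev, cPrev, w0, form = "canonical")
  expect_equal(can$c, 0.5 * cPrev)
  expect_equal(can$a, 0.5 * tanh(0.5 * cPrev))

  # scalar step, all weights 1, zero input and biases
  w1 <- list(Wx = matrix(1, 1, 4), Wa = matrix(1, 1, 4), b = 0 * 1:4)
  s <- lstmStep(0, 0.5, 0.25, w1)
  sig <- function(z) 1 / (1 + exp(-z))
  z <- 0.5                      # 1 * aPrev + 1 * 0
  expect_equal(s$u, sig(z)); expect_equal(s$f, sig(z))
  expect_equal(s$o, sig(z)); expect_equal(s$g, tanh(z))
  cNew <- sig(z) * 0.25 + sig(z) * tanh(z)
  expect_equal(s$c, cNew)
  expect_equal(s$a, sig(z) * tanh(cNew))

  # gate range invariant under random weights
  set.seed(21)
  wr <- list(Wx = matrix(rnorm(12), 3, 4), Wa = matrix(rnorm(4), 1, 4),
             b = rnorm(4))
  r <- lstmStep(rnorm(3), 0.1, -0.3, wr)
  expect_true(all(r$u > 0 & r$u < 1 & r$f > 0 & r$f < 1 &
                  r$o > 0 & r$o < 1))
  expect_true(all(abs(r$g) < 1))
  expect_error(lstmStep(rnorm(2), 0.1, -0.3, wr), "dimensions")
})

test_that("baseline network parameter count matches the layer formula", {
  net <- buildBaselineDnn(77, 5)
  widths <- c(77, 1024, 512, 128, 64)
  dense <- sum(widths[-length(widths)] * widths[-1] + widths[-1]) +
           64 * 5 + 5
  bn <- 2 * sum(c(1024, 512, 128, 64))   # gamma + beta per hidden layer
  expect_equal(HemoDecode:::.nnParamCount(net$graph), dense + bn)
})

test_that("inception block widths and lengths follow the design", {
  L <- asNamespace("HemoDecode")
  blk <- inceptionBlock(1, nFilters = 32)
  x <- matrix(rnorm(4 * 77), 77 * 4, 1)
  out <- L$.fwd(blk, L$.tns(x, 77L), training = FALSE)
  expect_equal(ncol(out), 128)          # 4 paths x 32 filters
  expect_equal(nrow(out), 77 * 4)       # same padding preserves length

  # zero input -> zero output (bias-free convolutions, bn identity)
  z <- L$.fwd(blk, L$.tns(x * 0, 77L), training = FALSE)
  expect_equal(max(abs(z)), 0)
})

test_that("probability outputs are simplex-valued for all networks", {
  set.seed(31)
  x <- matrix(rnorm(6 * 77), 6, 77)
  for (b in list(buildBaselineDnn, buildLstm, buildBilstm, buildHybrid,
                 buildHemoNet)) {
    net <- b(77, 5)
    p <- nnPredictProb(net, x)
    expect_equal(dim(p), c(6, 5))
    expect_true(all(is.finite(p)) && all(p >= 0))
    expect_equal(unname(rowSums(p)), rep(1, 6), tolerance = 1e-6)
  }
  # zero input stays finite
  p0 <- nnPredictProb(buildHybrid(77, 5), matrix(0, 3, 77))
  expect_true(all(is.finite(p0)))
  expect_equal(unname(rowSums(p0)), rep(1, 3), tolerance = 1e-6)
})

test_that("the residual connection is live", {
  set.seed(32)
  x <- matrix(rnorm(4 * 77), 4, 77)
  set.seed(33); with_res <- buildHemoNet(77, 5, residual = TRUE)
  set.seed(33); without <- buildHemoNet(77, 5, residual = FALSE)
  a <- nnForward(with_res, x)
  b <- nnForward(without, x)
  expect_gt(max(abs(a - b)), 1e-8)
})

test_that("an untrained network predicts at chance on balanced labels", {
  set.seed(34)
  net <- buildHemoNet(77, 5)
  x <- matrix(rnorm(500 * 77), 500, 77)
  y <- rep(fingerConditions(), each = 100)
  acc <- mean(fingerConditions()[max.col(nnPredictProb(net, x))] == y)
  expect_gt(acc, 0.1); expect_lt(acc, 0.3)
})

test_that("training reduces loss, stops early and is seed-deterministic", {
  toy <- toyBumpData(n = 120, P = 24, noise = 0.4, seed = 3)
  xs <- standardScale(toy$x)
  L <- asNamespace("HemoDecode")
  set.seed(41)
  net <- L$.hdNet(L$.lSeq(list(L$.lDense(24, 16), L$.lBN(16),
                               L$.lAct("relu"), L$.lDense(16, 5))),
                  "test", 24, 5)
  plan <- trainingPlan(maxEpochs = 20, seed = 5, valFraction = 0.2,
                       patience = 50, lrSchedule = "fixed", lr = 5e-3)
  fit <- trainDeep(net, xs, toy$y, plan)
  h <- fit$history
  # median loss over the last 5 epochs below the first 5
  expect_lt(median(tail(h$loss, 5)), median(head(h$loss, 5)))

  # same seed, same data -> identical weights
  set.seed(41)
  net2 <- L$.hdNet(L$.lSeq(list(L$.lDense(24, 16), L$.lBN(16),
                                L$.lAct("relu"), L$.lDense(16, 5))),
                   "test", 24, 5)
  fit2 <- trainDeep(net2, xs, toy$y, plan)
  w1 <- L$.nnCopyParams(net$graph)
  w2 <- L$.nnCopyParams(net2$graph)
  expect_identical(w1, w2)

  # divergence is reported, not silently swallowed
  set.seed(42)
  net3 <- L$.hdNet(L$.lSeq(list(L$.lDense(24, 8), L$.lAct("relu"),
                                L$.lDense(8, 5))), "test", 24, 5)
  expect_error(
    trainDeep(net3, xs * 1e6, toy$y,
              trainingPlan(maxEpochs = 5, lrSchedule = "fixed", lr = 1e300,
                           valFraction = 0, seed = 1)),
    "diverged")
})

test_that("training-plan bounds are validated", {
  expect_error(trainingPlan(lrMin = 0.1, lrMax = 0.01), "lrMin")
  expect_error(trainingPlan(lrSchedule = "warm"), "lrSchedule")
})
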