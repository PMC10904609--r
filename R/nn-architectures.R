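# The five deep classifiers: a dense baseline, an LSTM stack, a
# bidirectional LSTM stack, a CNN/LSTM hybrid, and the inception-style
# convolutional network ("Hemo-Net") built from three multi-kernel
# inception blocks with a residual connection.

#' One LSTM cell step
#'
#' A single forward step of the LSTM recurrence, exposed for
#' inspection. The canonical form keeps the cell state as a plain
#' convex-gated sum, `c_t = theta_f * c_{t-1} + theta_u * g_t`, with
#' activation `a_t = theta_o * tanh(c_t)`. The `"literal"` form instead
#' wraps both the cell-state update and the output in a sigmoid
#' (`c_t = sigma(theta_u * g_t + theta_f * c_{t-1})`,
#' `a_t = sigma(theta_o * c_t)`), reproducing a nonstandard published
#' variant of the update equations for comparison.
#'
#' @param x input vector at time t (length d).
#' @param aPrev previous activation (length H).
#' @param cPrev previous cell state (length H).
#' @param weights list with `Wx` (d x 4H), `Wa` (H x 4H), `b` (4H);
#'   gate column order update, forget, output, candidate.
#' @param form `"canonical"` (default) or `"literal"`.
#' @return list with `a` (activation), `c` (cell state), and the gate
#'   outputs `u`, `f`, `o` and candidate `g`.
#' @export
lstmStep <- function(x, aPrev, cPrev, weights,
                     form = c("canonical", "literal")) {
  form <- match.arg(form)
  H <- length(aPrev)
  if (length(cPrev) != H) stop("aPrev and cPrev dimensions disagree")
  if (nrow(weights$Wx) != length(x) || ncol(weights$Wx) != 4 * H ||
      nrow(weights$Wa) != H || ncol(weights$Wa) != 4 * H ||
      length(weights$b) != 4 * H)
    stop("weight dimensions disagree with the state size")
  z <- drop(x %*% weights$Wx + aPrev %*% weights$Wa) + weights$b
  sig <- function(v) 1 / (1 + exp(-v))
  u <- sig(z[seq_len(H)])
  f <- sig(z[H + seq_len(H)])
  o <- sig(z[2 * H + seq_len(H)])
  g <- tanh(z[3 * H + seq_len(H)])
  if (form == "canonical") {
    cNew <- f * cPrev + u * g
    a <- o * tanh(cNew)
  } else {
    cNew <- sig(u * g + f * cPrev)
    a <- sig(o * cNew)
  }
  list(a = a, c = cNew, u = u, f = f, o = o, g = g)
}

.hdNet <- function(graph, arch, inputLen, nClasses) {
  structure(list(graph = graph, arch = arch, inputLen = inputLen,
                 nClasses = nClasses), class = "hdNet")
}

#' @export
print.hdNet <- function(x, ...) {
  cat(sprintf("hdNet '%s': input length %d -> %d classes, %d parameters\n",
              x$arch, x$inputLen, x$nClasses, .nnParamCount(x$graph)))
  invisible(x)
}

#' Dense baseline network
#'
#' Five fully connected hidden layers of 1024, 512, 128 and 64 units
#' and a 5-way output, each hidden linear layer followed by batch
#' normalization and ReLU. The input is the flat feature vector.
#'
#' @param inputLen feature-vector length (default 77).
#' @param nClasses number of classes.
#' @return An `hdNet` network specification.
#' @export
buildBaselineDnn <- function(inputLen = 77, nClasses = 5) {
  if (inputLen < 1) stop("invalid input length")
  widths <- c(1024, 512, 128, 64)
  nodes <- list()
  nin <- inputLen
  for (w in widths) {
    nodes <- c(nodes, list(.lDense(nin, w), .lBN(w), .lAct("relu")))
    nin <- w
  }
  nodes <- c(nodes, list(.lDense(nin, nClasses)))
  .hdNet(.lSeq(nodes), "dnn", inputLen, nClasses)
}

#' LSTM network
#'
#' Two stacked LSTM layers of 50 units (the second returning its final
#' state), then dense layers of 50 and 20 units with ReLU, batch
#' normalization after each, and a 5-way softmax output.
#'
#' @inheritParams buildBaselineDnn
#' @return An `hdNet`.
#' @export
buildLstm <- function(inputLen = 77, nClasses = 5) {
  if (inputLen < 1) stop("invalid input length")
  g <- .lSeq(list(
    .lInputSeq(),
    .lLSTM(1, 50, returnSeq = TRUE), .lBN(50),
    .lLSTM(50, 50, returnSeq = FALSE), .lBN(50),
    .lDense(50, 50), .lBN(50), .lAct("relu"),
    .lDense(50, 20), .lBN(20), .lAct("relu"),
    .lDense(20, nClasses)))
  .hdNet(g, "lstm", inputLen, nClasses)
}

#' Bidirectional LSTM network
#'
#' Three bidirectional LSTM layers of 50, 50 and 20 units (the last
#' returning final states), batch normalization after each, a dense
#' layer of 20 units with ReLU, and a 5-way softmax output.
#'
#' @inheritParams buildBaselineDnn
#' @return An `hdNet`.
#' @export
buildBilstm <- function(inputLen = 77, nClasses = 5) {
  if (inputLen < 1) stop("invalid input length")
  g <- .lSeq(list(
    .lInputSeq(),
    .lBiLSTM(1, 50, returnSeq = TRUE), .lBN(100),
    .lBiLSTM(100, 50, returnSeq = TRUE), .lBN(100),
    .lBiLSTM(100, 20, returnSeq = FALSE), .lBN(40),
    .lDense(40, 20), .lBN(20), .lAct("relu"),
    .lDense(20, nClasses)))
  .hdNet(g, "bilstm", inputLen, nClasses)
}

#' CNN/LSTM hybrid network
#'
#' Two parallel heads over the input sequence: a convolutional head
#' (three 1-D convolutions with 64, 64 and 32 filters, kernel sizes 3,
#' 5 and 3, same padding, Leaky ReLU and batch normalization, then a
#' dense layer of 32 units) and a recurrent head (three stacked LSTM
#' layers of 64, 64 and 32 units, then a dense layer of 32 units with
#' Leaky ReLU). Their outputs are concatenated and passed through two
#' dense layers of 32 units with batch normalization and Leaky ReLU to
#' a 5-way softmax output.
#'
#' @inheritParams buildBaselineDnn
#' @return An `hdNet`.
#' @export
buildHybrid <- function(inputLen = 77, nClasses = 5) {
  if (inputLen < 1) stop("invalid input length")
  cnnHead <- .lSeq(list(
    .lConv(1, 64, 3), .lBN(64), .lAct("lrelu"),
    .lConv(64, 64, 5), .lBN(64), .lAct("lrelu"),
    .lConv(64, 32, 3), .lBN(32), .lAct("lrelu"),
    .lFlatten(),
    .lDense(inputLen * 32, 32), .lBN(32), .lAct("lrelu")))
  lstmHead <- .lSeq(list(
    .lLSTM(1, 64, returnSeq = TRUE), .lBN(64),
    .lLSTM(64, 64, returnSeq = TRUE), .lBN(64),
    .lLSTM(64, 32, returnSeq = FALSE), .lBN(32),
    .lDense(32, 32), .lAct("lrelu"), .lBN(32)))
  g <- .lSeq(list(
    .lInputSeq(),
    .lPar(list(cnnHead, lstmHead)),
    .lDense(64, 32), .lBN(32), .lAct("lrelu"),
    .lDense(32, 32), .lBN(32), .lAct("lrelu"),
    .lDense(32, nClasses)))
  .hdNet(g, "hybrid", inputLen, nClasses)
}

#' Inception block for 1-D time series
#'
#' A bottleneck 1x1 convolution feeding three parallel convolutions
#' with kernel lengths 10, 20 and 40, alongside a max-pool(3) +
#' bottleneck path; the four branches are concatenated (output
#' channels = 4 x `nFilters`), batch-normalized and passed through
#' ReLU. Same padding everywhere, so the temporal length is preserved.
#' Convolutions are bias-free (the batch normalization absorbs any
#' offset), so a zero input yields a zero pre-activation output.
#'
#' @param cin input channel count.
#' @param nFilters filters per branch (default 32).
#' @param kernels the three kernel lengths.
#' @param bottleneck bottleneck width (default 32).
#' @return An engine node; compose with [buildHemoNet()] or use
#'   directly via the internal forward.
#' @export
inceptionBlock <- function(cin, nFilters = 32, kernels = c(10, 20, 40),
                           bottleneck = 32) {
  stopifnot(length(kernels) == 3)
  convIn <- if (cin > 1) bottleneck else cin
  inner <- .lPar(lapply(kernels, function(k)
    .lConv(convIn, nFilters, k, bias = FALSE)))
  mainPath <- if (cin > 1)
    .lSeq(list(.lConv(cin, bottleneck, 1, bias = FALSE), inner))
  else .lSeq(list(inner))
  poolPath <- .lSeq(list(.lPool(3), .lConv(cin, nFilters, 1, bias = FALSE)))
  .lSeq(list(.lPar(list(mainPath, poolPath)),
             .lBN(4 * nFilters), .lAct("relu")))
}

#' Build the inception-style decoder network ("Hemo-Net")
#'
#' Three inception blocks (see [inceptionBlock()]) with a residual
#' connection from the input to the output of the final block through
#' a linear 1x1-convolution projection with batch normalization,
#' followed by global average pooling over time and a dense softmax
#' classifier.
#'
#' @param inputLen input sequence length (default 77).
#' @param nClasses number of classes (>= 2).
#' @param nFilters filters per inception branch.
#' @param residual include the residual connection (default TRUE).
#' @return An `hdNet`.
#' @export
buildHemoNet <- function(inputLen = 77, nClasses = 5, nFilters = 32,
                         residual = TRUE) {
  if (nClasses < 2) stop("need at least two classes")
  width <- 4 * nFilters
  blocks <- .lSeq(list(
    inceptionBlock(1, nFilters),
    inceptionBlock(width, nFilters),
    inceptionBlock(width, nFilters)))
  trunk <- if (residual) {
    proj <- .lSeq(list(.lConv(1, width, 1, bias = FALSE), .lBN(width)))
    .lSeq(list(.lRes(blocks, proj), .lAct("relu")))
  } else blocks
  g <- .lSeq(list(.lInputSeq(), trunk, .lGAP(), .lDense(width, nClasses)))
  .hdNet(g, "hemonet", inputLen, nClasses)
}

#' Forward pass through a network
#'
#' @param net an `hdNet`.
#' @param x N x P feature matrix.
#' @param training use batch statistics (TRUE) or running statistics
#'   (FALSE) in batch normalization.
#' @param chunk rows per inference block (eval mode); bounds the
#'   working memory of the convolution buffers.
#' @return N x K logit matrix.
#' @export
nnForward <- function(net, x, training = FALSE, chunk = 256L) {
  x <- as.matrix(x)
  if (ncol(x) != net$inputLen)
    stop("input length ", ncol(x), " != network input length ", net$inputLen)
  if (training || nrow(x) <= chunk) {
    out <- .fwd(net$graph, x, training)
    if (!training) .nnClearCaches(net$graph)
    return(out)
  }
  starts <- seq(1L, nrow(x), by = chunk)
  out <- do.call(rbind, lapply(starts, function(s0)
    .fwd(net$graph, x[s0:min(nrow(x), s0 + chunk - 1L), , drop = FALSE],
         FALSE)))
  .nnClearCaches(net$graph)
  out
}

#' Class probabilities from a network
#'
#' @inheritParams nnForward
#' @return N x K probability matrix (rows sum to one).
#' @export
nnPredictProb <- function(net, x) .softmax(nnForward(net, x, training = FALSE))

#' Train a deep network
#'
#' Minimizes the multi-class cross-entropy with Adam, an L2 weight
#' penalty and either a cyclic triangular learning rate (period four
#' epochs) or a fixed rate, with optional early stopping on validation
#' loss (best weights restored). Fully deterministic given the plan's
#' seed.
#'
#' @param net an `hdNet` (modified in place; also returned).
#' @param x N x P feature matrix (standard-scaled).
#' @param y factor of class labels, levels matching the network width.
#' @param plan a [TrainingPlan-class].
#' @return list with `net`, `history` (per-epoch data.frame: epoch,
#'   loss, accuracy, valLoss, valAccuracy, lr) and `classes`.
#' @export
trainDeep <- function(net, x, y, plan = trainingPlan()) {
  x <- as.matrix(x); y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K != net$nClasses) stop("label count != network output width")
  rng <- .seededRNG(plan@seed)
  on.exit(rng$restore(), add = TRUE)

  n <- nrow(x)
  if (plan@valFraction > 0 && n >= 20) {
    vIdx <- sort(unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, max(1, round(length(ix) * plan@valFraction))))))
  } else vIdx <- integer(0)
  tIdx <- setdiff(seq_len(n), vIdx)
  xt <- x[tIdx, , drop = FALSE]; yt <- y[tIdx]
  xv <- x[vIdx, , drop = FALSE]; yv <- y[vIdx]

  params <- .nnParams(net$graph)
  state <- .adamInit(params)
  nb <- max(1L, floor(nrow(xt) / plan@batchSize))
  stepsize <- max(1L, 4L * nb)  # half-cycle = four epochs
  iter <- 0L
  hist <- list()
  bestVal <- Inf; bestParams <- NULL; wait <- 0L

  for (ep in seq_len(plan@maxEpochs)) {
    ord <- sample(nrow(xt))
    epLoss <- 0; epAcc <- 0; epN <- 0
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1L) * plan@batchSize + 1L):
                  min(nrow(xt), bi * plan@batchSize)]
      if (bi == nb) rows <- ord[((bi - 1L) * plan@batchSize + 1L):nrow(xt)]
      if (length(rows) < 2) next
      iter <- iter + 1L
      lr <- if (plan@lrSchedule == "cyclic") {
        cyc <- abs(iter / stepsize - 2 * floor(iter / (2 * stepsize)) - 1)
        plan@lrMin + (plan@lrMax - plan@lrMin) * max(0, 1 - cyc)
      } else plan@lr
      xb <- xt[rows, , drop = FALSE]
      logits <- .fwd(net$graph, xb, training = TRUE)
      p <- .softmax(logits)
      yb <- .oneHot(yt[rows], K)
      loss <- -mean(log(pmax(rowSums(p * yb), 1e-12)))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      epLoss <- epLoss + loss * length(rows)
      epAcc <- epAcc + sum(max.col(p, "first") == as.integer(yt[rows]))
      epN <- epN + length(rows)
      .nnZeroGradsP(params)
      .bwd(net$graph, (p - yb) / length(rows))
      state <- .adamStep(params, state, lr, plan@l2, iter)
    }
    rec <- data.frame(epoch = ep, loss = epLoss / epN, accuracy = epAcc / epN,
                      valLoss = NA_real_, valAccuracy = NA_real_, lr = lr)
    if (length(vIdx)) {
      lv <- .fwd(net$graph, xv, training = FALSE)
      pv <- .softmax(lv)
      yvh <- .oneHot(yv, K)
      rec$valLoss <- -mean(log(pmax(rowSums(pv * yvh), 1e-12)))
      rec$valAccuracy <- mean(max.col(pv, "first") == as.integer(yv))
      if (rec$valLoss < bestVal - 1e-6) {
        bestVal <- rec$valLoss; bestParams <- .nnCopyParams(net$graph)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist[[ep]] <- rec
    if (length(vIdx) && wait >= plan@patience) break
  }
  if (!is.null(bestParams)) .nnRestoreParams(net$graph, bestParams)
  .nnClearCaches(net$graph)
  list(net = net, history = do.call(rbind, hist),
       classes = levels(y))
}
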