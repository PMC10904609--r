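# Single entry point to the ten-model suite: five classical classifiers
# and five deep networks under one fit/predict contract.

.CLASSICAL <- c("lda", "qda", "mnlr", "rf", "xgboost")
.DEEP <- c("dnn", "lstm", "bilstm", "hybrid", "hemonet")

#' Names of the available decoder families
#'
#' @return Character vector: `lda`, `qda`, `mnlr`, `rf`, `xgboost`,
#'   `dnn`, `lstm`, `bilstm`, `hybrid`, `hemonet`.
#' @export
decoderNames <- function() c(.CLASSICAL, .DEEP)

#' Default training plan for a deep model family
#'
#' The dense baseline and the inception network train with the cyclic
#' triangular learning rate in `[1e-5, 1e-2]`; the recurrent and
#' hybrid models with a fixed rate of `1e-4`. Batch size 32 and an L2
#' weight penalty throughout.
#'
#' @param model one of the deep family names.
#' @param maxEpochs epoch budget.
#' @param seed integer seed.
#' @return A [TrainingPlan-class].
#' @export
defaultPlan <- function(model, maxEpochs = 60, seed = 1L) {
  if (model %in% c("dnn", "hemonet"))
    trainingPlan(lrSchedule = "cyclic", maxEpochs = maxEpochs, seed = seed)
  else
    trainingPlan(lrSchedule = "fixed", lr = 1e-4, maxEpochs = maxEpochs,
                 seed = seed)
}

#' Fit a decoder by registry name
#'
#' Uniform front end to the model suite. Classical families accept
#' their hyperparameters directly (or `tune = TRUE` for the published
#' 5-fold cross-validated grid search); deep families are built for
#' the input length and trained with `plan`.
#'
#' @param x N x P feature matrix (standard-scale it first; see
#'   [standardScale()]).
#' @param y class labels.
#' @param model a name from [decoderNames()].
#' @param seed integer seed (fold assignment, tree ensembles, network
#'   initialization).
#' @param tune if `TRUE` (classical families), grid-search the
#'   published hyperparameter grid with 5-fold stratified CV first.
#' @param plan [TrainingPlan-class] for deep families; default
#'   [defaultPlan()].
#' @param ... family-specific hyperparameters (see [fitLda()],
#'   [fitQda()], [fitMnlr()], [fitForest()], [fitBoost()]).
#' @return A [FittedDecoder-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 6), 100)
#' x[1:50, 1] <- x[1:50, 1] + 3
#' y <- rep(c("thumb", "index"), each = 50)
#' m <- fitDecoder(x, y, "lda")
#' table(predict(m, x), y)
#' @export
fitDecoder <- function(x, y, model = "hemonet", seed = 1L, tune = FALSE,
                       plan = NULL, ...) {
  model <- match.arg(model, decoderNames())
  x <- as.matrix(x)
  if (model %in% .CLASSICAL) {
    extra <- list(...)
    if (tune) {
      fitFun <- switch(model, lda = fitLda, qda = fitQda, mnlr = fitMnlr,
                       rf = function(...) fitForest(..., seed = seed),
                       xgboost = function(...) fitBoost(..., seed = seed))
      gs <- gridSearchCV(fitFun, decoderGrids()[[model]], x, y,
                         folds = 5, seed = seed)
      extra <- gs$best
      fit <- do.call(fitFun, c(list(x, y), extra))
      fit@info$cvTable <- gs$table
      return(fit)
    }
    return(switch(model,
      lda = do.call(fitLda, c(list(x, y), extra)),
      qda = do.call(fitQda, c(list(x, y), extra)),
      mnlr = do.call(fitMnlr, c(list(x, y), extra)),
      rf = do.call(fitForest, c(list(x, y, seed = seed), extra)),
      xgboost = do.call(fitBoost, c(list(x, y, seed = seed), extra))))
  }
  yf <- droplevels(as.factor(y))
  if (is.null(plan)) plan <- defaultPlan(model, seed = seed)
  rng <- .seededRNG(seed)
  net <- switch(model,
    dnn = buildBaselineDnn(ncol(x), nlevels(yf)),
    lstm = buildLstm(ncol(x), nlevels(yf)),
    bilstm = buildBilstm(ncol(x), nlevels(yf)),
    hybrid = buildHybrid(ncol(x), nlevels(yf)),
    hemonet = buildHemoNet(ncol(x), nlevels(yf)))
  rng$restore()
  tr <- trainDeep(net, x, yf, plan)
  new("FittedDecoder", name = model,
      fit = list(net = tr$net),
      classes = levels(yf),
      info = list(hyperparameters = list(
                    lrSchedule = plan@lrSchedule, batchSize = plan@batchSize,
                    l2 = plan@l2, maxEpochs = plan@maxEpochs),
                  history = tr$history))
}

#' @describeIn predictProb class-probability predictions for every
#'   decoder family.
#' @export
setMethod("predictProb", "FittedDecoder", function(object, newdata, ...) {
  x <- as.matrix(newdata)
  p <- switch(object@name,
    lda = .softmax(x %*% object@fit$Wk +
                   matrix(object@fit$b, nrow(x), length(object@fit$b),
                          byrow = TRUE)),
    qda = .softmax(.qdaLogPost(object, x)),
    mnlr = {
      K <- length(object@classes)
      .softmax(cbind(cbind(1, x) %*% object@fit$W, 0))
    },
    rf = {
      df <- as.data.frame(x)
      colnames(df) <- object@fit$featureNames
      pr <- predict(object@fit$ranger, data = df,
                    num.threads = 1)$predictions
      pr[, object@classes, drop = FALSE]
    },
    xgboost = {
      pr <- predict(object@fit$booster, xgboost::xgb.DMatrix(x))
      if (is.null(dim(pr)))
        pr <- matrix(pr, ncol = length(object@classes), byrow = TRUE)
      unname(pr)
    },
    nnPredictProb(object@fit$net, x))
  colnames(p) <- object@classes
  p
})

#' Predict hard labels from a fitted decoder
#'
#' @param object a [FittedDecoder-class].
#' @param newdata N x P feature matrix.
#' @param ... ignored.
#' @return Factor of predicted class labels (ties broken toward the
#'   first class).
#' @export
setMethod("predict", "FittedDecoder", function(object, newdata, ...) {
  p <- predictProb(object, newdata)
  factor(object@classes[max.col(p, "first")], levels = object@classes)
})

#' Save / load a fitted decoder
#'
#' Serializes a [FittedDecoder-class] together with a format version
#' and the package version, so archives remain identifiable.
#'
#' @param object a [FittedDecoder-class].
#' @param path file path (`.rds`).
#' @export
saveDecoder <- function(object, path) {
  stopifnot(is(object, "FittedDecoder"))
  saveRDS(list(format = 1L,
               package = as.character(utils::packageVersion("HemoDecode")),
               decoder = object), path)
}

#' @rdname saveDecoder
#' @return `loadDecoder()` returns the [FittedDecoder-class].
#' @export
loadDecoder <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$decoder) ||
      !is(obj$decoder, "FittedDecoder"))
    stop("not a decoder archive")
  obj$decoder
}
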