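# Data splitting, evaluation metrics and the end-to-end experiment
# driver. Accuracy is the indicator-mean over samples; per-class
# precision Tp / (Tp + Fp) and recall Tp / (Tp + Fn) come from the
# confusion matrix, F1 is their harmonic mean.

#' Split a feature set into train and test
#'
#' `"stratified-pooled"` samples the test fraction within each class
#' (proportions preserved to within one example); `"by-run"` holds out
#' whole runs so no run contributes to both splits. Deterministic
#' under the plan's seed.
#'
#' @param fm a [FingerFeatureSet-class].
#' @param plan a [SplitPlan-class].
#' @return list with `train` and `test` (both `FingerFeatureSet`).
#' @export
splitFeatures <- function(fm, plan = splitPlan()) {
  rng <- .seededRNG(plan@seed)
  on.exit(rng$restore(), add = TRUE)
  cd <- colData(fm)
  y <- as.character(cd$label)
  n <- ncol(fm)
  if (plan@strategy == "stratified-pooled") {
    testIdx <- sort(unlist(lapply(split(seq_len(n), y), function(ix) {
      k <- round(length(ix) * plan@testFraction)
      if (k < 1 || k >= length(ix))
        stop("class too small for the requested test fraction")
      sample(ix, k)
    })))
  } else {
    runs <- unique(cd$run)
    k <- max(1, round(length(runs) * plan@testFraction))
    if (k >= length(runs)) stop("not enough runs to hold out")
    testRuns <- sample(runs, k)
    testIdx <- which(cd$run %in% testRuns)
  }
  out <- list(train = fm[, setdiff(seq_len(n), testIdx)],
              test = fm[, testIdx])
  missing <- setdiff(unique(y), as.character(colData(out$test)$label))
  if (length(missing))
    stop("class ", paste(missing, collapse = ", "), " absent from test split")
  out
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class
#' `j`.
#'
#' @param yTrue,yPred label vectors of equal, positive length; factors
#'   share levels, otherwise labels must be covered by `classes`.
#' @param classes class label order; default the union of levels.
#' @return K x K integer matrix with dimnames `true` x `predicted`.
#' @export
confusionCounts <- function(yTrue, yPred, classes = NULL) {
  if (!length(yTrue)) stop("empty input")
  if (length(yTrue) != length(yPred)) stop("label lengths differ")
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (is.null(classes)) classes <- sort(unique(c(yTrue, yPred)))
  if (!all(yTrue %in% classes) || !all(yPred %in% classes))
    stop("labels outside the class set")
  tab <- table(factor(yTrue, levels = classes),
               factor(yPred, levels = classes))
  m <- matrix(as.integer(tab), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Classification report from a confusion matrix
#'
#' Per-class precision, recall and F1 (harmonic mean), support, the
#' overall accuracy, and macro (unweighted) and support-weighted
#' averages. A division by zero (class never predicted, or absent)
#' yields 0 with the `zeroDivision` flag set.
#'
#' @param confusion K x K count matrix from [confusionCounts()].
#' @return An [EvaluationReport-class].
#' @examples
#' cm <- confusionCounts(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0))
#' evaluationReport(cm)
#' @export
evaluationReport <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  K <- nrow(confusion)
  classes <- rownames(confusion) %||% as.character(seq_len(K))
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  zero <- predicted == 0 | support == 0 | (prec + rec) == 0
  perClass <- data.frame(class = classes, precision = prec, recall = rec,
                         f1 = f1, support = as.integer(support),
                         zeroDivision = zero, row.names = NULL)
  N <- sum(confusion)
  acc <- sum(tp) / N
  macro <- c(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
  w <- support / N
  weighted <- c(precision = sum(w * prec), recall = sum(w * rec),
                f1 = sum(w * f1))
  new("EvaluationReport", confusion = confusion, perClass = perClass,
      accuracy = acc, macro = macro, weighted = weighted)
}

#' Table-style classification report
#'
#' @param report an [EvaluationReport-class].
#' @return data.frame with per-class rows plus `accuracy`,
#'   `macro avg` and `weighted avg` rows (precision, recall, f1,
#'   support), mirroring the common report layout.
#' @export
reportTable <- function(report) {
  pc <- report@perClass
  N <- sum(pc$support)
  rbind(
    data.frame(row = pc$class, precision = pc$precision,
               recall = pc$recall, f1 = pc$f1, support = pc$support),
    data.frame(row = "accuracy", precision = NA, recall = NA,
               f1 = report@accuracy, support = N),
    data.frame(row = "macro avg", precision = report@macro[["precision"]],
               recall = report@macro[["recall"]], f1 = report@macro[["f1"]],
               support = N),
    data.frame(row = "weighted avg",
               precision = report@weighted[["precision"]],
               recall = report@weighted[["recall"]],
               f1 = report@weighted[["f1"]], support = N))
}

#' Run a full synthetic decoding experiment
#'
#' End to end: simulate `nRuns` block-design recordings, preprocess
#' each through the full pipeline, extract event averages, assemble
#' and split the feature matrix, standard-scale with train statistics,
#' fit the requested decoders and evaluate on the held-out split.
#' Fully seeded and deterministic. If `outDir` is given, writes
#' `features.csv`, per-model classification reports and confusion
#' matrices, and an `accuracy.csv` summary.
#'
#' @param preset simulator preset name (see [syntheticPreset()]).
#' @param nRuns number of independent simulated runs (participants).
#' @param nChannels montage size per run.
#' @param models decoder names to fit (default all ten).
#' @param split a [SplitPlan-class].
#' @param plans named list of [TrainingPlan-class] overrides per deep
#'   model (default [defaultPlan()]).
#' @param epochsDeep epoch budget for deep models when no plan is
#'   given.
#' @param chromophores which chromophores become feature rows; the
#'   default uses the oxygenated and deoxygenated series (the total-Hb
#'   series is computed and available but not a default feature).
#' @param shuffleConditions randomize the condition order within each
#'   session, independently per run. With the fixed thumb-to-little
#'   order, condition is confounded with block position through
#'   hemodynamic response overlap, and even amplitude-identical
#'   classes remain decodable.
#' @param permuteLabels permute the finger labels across examples
#'   (seeded from `seed`) before splitting: the chance-level control
#'   (see [permuteLabels()]).
#' @param seed master integer seed; run r uses `seed + r`.
#' @param outDir optional output directory.
#' @param settings preprocessing settings.
#' @return list with `features` (the split), `fits`, `reports`
#'   (per-model [EvaluationReport-class]), and `accuracy` (data.frame
#'   model / trainAccuracy / testAccuracy).
#' @export
runExperiment <- function(preset = "default", nRuns = 4, nChannels = 16,
                          models = decoderNames(), split = splitPlan(),
                          plans = list(), epochsDeep = 30,
                          chromophores = c("hbo", "hbr"),
                          shuffleConditions = FALSE,
                          permuteLabels = FALSE,
                          seed = 1L, outDir = NULL,
                          settings = preprocessSettings()) {
  models <- match.arg(models, decoderNames(), several.ok = TRUE)
  avgs <- list()
  for (r in seq_len(nRuns)) {
    tl <- buildParadigm(shuffle = shuffleConditions, seed = seed + r)
    cfg <- syntheticPreset(preset, nChannels = nChannels,
                           seed = seed + r)
    rec <- simulateRecording(tl, cfg)
    rec <- injectArtifacts(rec, cfg)
    hb <- preprocessRecording(rec, tl, settings)$recording
    ep <- extractEpochs(hb, tl, chromophores = chromophores)
    avgs[[sprintf("run%02d", r)]] <- eventAverage(ep)
  }
  fm <- buildFeatureMatrix(avgs)
  if (permuteLabels) fm <- HemoDecode::permuteLabels(fm, seed = seed)
  parts <- splitFeatures(fm, split)
  xtr <- featureValues(parts$train); ytr <- exampleLabels(parts$train)
  xte <- featureValues(parts$test); yte <- exampleLabels(parts$test)
  scaler <- fitScaler(xtr)
  xtr <- applyScaler(scaler, xtr); xte <- applyScaler(scaler, xte)

  fits <- list(); reports <- list(); acc <- list()
  for (m in models) {
    plan <- plans[[m]]
    if (is.null(plan) && m %in% .DEEP)
      plan <- defaultPlan(m, maxEpochs = epochsDeep, seed = seed)
    fit <- fitDecoder(xtr, ytr, model = m, seed = seed, plan = plan)
    predTr <- predict(fit, xtr)
    predTe <- predict(fit, xte)
    cm <- confusionCounts(yte, predTe, classes = levels(yte))
    rep <- evaluationReport(cm)
    fits[[m]] <- fit
    reports[[m]] <- rep
    acc[[m]] <- data.frame(model = m,
                           trainAccuracy = mean(predTr == ytr),
                           testAccuracy = rep@accuracy)
  }
  accTab <- do.call(rbind, acc)
  rownames(accTab) <- NULL

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatures(fm, file.path(outDir, "features.csv"))
    write.csv(accTab, file.path(outDir, "accuracy.csv"), row.names = FALSE)
    for (m in models) {
      write.csv(reportTable(reports[[m]]),
                file.path(outDir, sprintf("report_%s.csv", m)),
                row.names = FALSE)
      write.csv(reports[[m]]@confusion,
                file.path(outDir, sprintf("confusion_%s.csv", m)))
    }
  }
  list(features = parts, scaler = scaler, fits = fits, reports = reports,
       accuracy = accTab)
}
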