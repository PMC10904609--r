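# Stimulus-locked epoching, event averaging and feature-matrix assembly.
# The published dimensionality is honored exactly: an epoch spanning 5 s
# before onset to 15 s after is stored as 77 samples at 3.9063 Hz, so each
# training example is a 1 x 77 vector from one channel and chromophore.

#' Extract stimulus-locked epochs
#'
#' One fixed-length epoch per task event, channel and chromophore,
#' starting at sample index `ceiling(-tPre * fs)` relative to the
#' stimulus onset sample. The default `nPoints = 77` matches the
#' feature dimensionality used downstream (20 s of data at 3.9063 Hz,
#' rounded to the published length); pass `nPoints = NULL` to derive
#' the length as `floor((tPre + tPost) * fs)`.
#'
#' @param hb a [HemodynamicRecording-class].
#' @param timeline the matching [StimulusTimeline-class].
#' @param tPre seconds of pre-onset history (default 5).
#' @param tPost seconds after onset, covering task and post-task
#'   (default 15).
#' @param nPoints epoch length in samples, or `NULL` to derive it.
#' @param chromophores which assays to epoch.
#' @return An [EpochSet-class]; epochs are ordered by onset within
#'   channel and chromophore.
#' @export
extractEpochs <- function(hb, timeline, tPre = 5, tPost = 15, nPoints = 77,
                          chromophores = c("hbo", "hbr", "hbt")) {
  ev <- stimEvents(timeline)
  if (!nrow(ev)) stop("timeline has no task events")
  fs <- samplingRate(hb)
  if (is.null(nPoints)) nPoints <- floor((tPre + tPost) * fs)
  k0 <- ceiling(-tPre * fs)
  n <- ncol(hb)
  onsetIdx <- round((ev$onset - startTime(hb)) * fs) + 1L
  lo <- onsetIdx + k0
  hi <- lo + nPoints - 1L
  badIdx <- which(lo < 1L | hi > n)
  if (length(badIdx))
    stop(sprintf("epoch for event %d (%s at %.1f s) exceeds recording bounds",
                 badIdx[1], ev$condition[badIdx[1]], ev$onset[badIdx[1]]))
  tGrid <- (k0 + seq_len(nPoints) - 1) / fs

  mats <- lapply(chromophores, function(a) assay(hb, a))
  names(mats) <- chromophores
  channels <- rownames(hb)
  cols <- list(); info <- list()
  for (ch in seq_along(channels)) {
    for (cr in chromophores) {
      m <- mats[[cr]]
      for (e in seq_len(nrow(ev))) {
        cols[[length(cols) + 1L]] <- m[ch, lo[e]:hi[e]]
        info[[length(info) + 1L]] <- data.frame(
          channel = channels[ch], chromophore = cr,
          condition = ev$condition[e], trial = e, onset = ev$onset[e],
          stringsAsFactors = FALSE)
      }
    }
  }
  new("EpochSet", epochs = do.call(cbind, cols),
      info = do.call(rbind, info), tGrid = tGrid)
}

#' Average epochs within groups
#'
#' Elementwise mean across trials within each
#' (channel, chromophore, condition) group: the channel-specific
#' event-related average.
#'
#' @param epochs an [EpochSet-class] from [extractEpochs()].
#' @return An [EpochSet-class] with one column per group (`trial` is
#'   `NA`).
#' @export
eventAverage <- function(epochs) {
  info <- epochs@info
  key <- interaction(info$channel, info$chromophore, info$condition,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(info)), key)
  if (any(lengths(groups) == 0)) stop("empty epoch group")
  avg <- vapply(groups, function(ix)
    rowMeans(epochs@epochs[, ix, drop = FALSE]),
    numeric(nrow(epochs@epochs)))
  ginfo <- do.call(rbind, lapply(groups, function(ix) {
    r <- info[ix[1], , drop = FALSE]
    r$trial <- NA_integer_; r$onset <- NA_real_
    r
  }))
  rownames(ginfo) <- NULL
  new("EpochSet", epochs = avg, info = ginfo, tGrid = epochs@tGrid)
}

#' Assemble the labeled feature matrix
#'
#' One training example per event-average vector, labeled with its
#' condition: the `N x P` design of the multi-class decoding problem
#' (each row the oxygenation time course of a single channel and
#' chromophore).
#'
#' @param averages an [EpochSet-class] of event averages (or raw
#'   epochs), or a list of them, one per run; list names (or position)
#'   become the `run` annotation.
#' @param chromophores which chromophores to keep as examples; default
#'   all present.
#' @return A [FingerFeatureSet-class].
#' @export
buildFeatureMatrix <- function(averages, chromophores = NULL) {
  if (!is.list(averages)) averages <- list(run1 = averages)
  if (is.null(names(averages)))
    names(averages) <- sprintf("run%d", seq_along(averages))
  P <- nrow(averages[[1]]@epochs)
  feats <- list(); cd <- list()
  for (rn in names(averages)) {
    ep <- averages[[rn]]
    if (nrow(ep@epochs) != P) stop("mixed epoch lengths across runs")
    keep <- if (is.null(chromophores)) seq_len(nrow(ep@info))
            else which(ep@info$chromophore %in% chromophores)
    bad <- setdiff(unique(ep@info$condition[keep]),
                   fingerConditions(rest = TRUE))
    if (length(bad))
      stop("unknown condition label: ", paste(bad, collapse = ", "))
    feats[[rn]] <- ep@epochs[, keep, drop = FALSE]
    cd[[rn]] <- data.frame(label = ep@info$condition[keep],
                           channel = ep@info$channel[keep],
                           chromophore = ep@info$chromophore[keep],
                           run = rn, stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, feats)
  info <- do.call(rbind, cd)
  colnames(X) <- sprintf("ex%04d", seq_len(ncol(X)))
  rownames(X) <- sprintf("t%03d", seq_len(P))
  se <- SummarizedExperiment(assays = list(features = X),
                             colData = DataFrame(info,
                                                 row.names = colnames(X)))
  new("FingerFeatureSet", se)
}

#' Concatenate feature sets
#'
#' @param ... [FingerFeatureSet-class] objects with identical feature
#'   length.
#' @return A single [FingerFeatureSet-class].
#' @export
bindFeatureSets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is(parts[[1]], "FingerFeatureSet"))
    parts <- parts[[1]]
  X <- do.call(cbind, lapply(parts, function(p) assay(p, "features")))
  cd <- do.call(rbind, lapply(parts, function(p) as.data.frame(colData(p))))
  colnames(X) <- sprintf("ex%04d", seq_len(ncol(X)))
  rownames(cd) <- colnames(X)
  se <- SummarizedExperiment(assays = list(features = X),
                             colData = DataFrame(cd))
  new("FingerFeatureSet", se)
}

#' Fit a column-wise standard scaler
#'
#' Learns per-feature mean and standard deviation on the training
#' matrix only; apply to any split with [applyScaler()]. Scaling
#' statistics must never be computed on held-out data.
#'
#' @param x N x P training feature matrix.
#' @return list with `mean` and `sd` (length P), class `"hdScaler"`.
#' @export
fitScaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(!is.finite(s)) || any(s == 0))
    stop("zero-variance training column; cannot standard-scale")
  structure(list(mean = mu, sd = s), class = "hdScaler")
}

#' Apply a fitted standard scaler
#'
#' @param scaler from [fitScaler()].
#' @param x N x P matrix to transform.
#' @return Scaled matrix `(x - mean_train) / sd_train`.
#' @export
applyScaler <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, `/`)
}

#' Standard scaling with train-only statistics
#'
#' Convenience wrapper: fit on `train`, transform `x`.
#'
#' @param train N x P training matrix (statistics source).
#' @param x matrix to transform; defaults to `train`.
#' @return Scaled matrix.
#' @export
standardScale <- function(train, x = train) {
  applyScaler(fitScaler(train), x)
}

#' Permute the labels of a feature set
#'
#' Randomly reassigns the finger labels across examples (seeded),
#' preserving class counts: the canonical chance-level control, since
#' permutation destroys every label-feature dependence, including
#' design confounds (block-position signatures from hemodynamic
#' overlap) and split leakage through correlated rows.
#'
#' @param fm a [FingerFeatureSet-class].
#' @param seed integer seed.
#' @return The feature set with permuted labels.
#' @export
permuteLabels <- function(fm, seed = 1L) {
  rng <- .seededRNG(seed)
  on.exit(rng$restore(), add = TRUE)
  cd <- colData(fm)
  cd$label <- sample(cd$label)
  colData(fm) <- cd
  fm
}
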