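# Classical classifiers under the common fit/predict contract.
# Discriminant analysis and multinomial logistic regression are
# implemented from their defining equations (scatter matrices and the
# generalized eigenproblem for LDA; per-class Gaussian densities with
# Bayes' rule for QDA; reference-class softmax for MNLR); the tree
# ensembles delegate to ranger and xgboost behind the same surface.

#' Hyperparameter grids of the classifier suite
#'
#' The exact search grids used with 5-fold cross-validation for each
#' classical model family.
#'
#' @return Named list of data.frames, one per family (`lda`, `qda`,
#'   `mnlr`, `rf`, `xgboost`), each row one grid cell in search order.
#' @export
decoderGrids <- function() {
  list(
    lda = expand.grid(solver = c("svd", "lsqr", "eigen"),
                      shrinkage = c("auto", "none"),
                      stringsAsFactors = FALSE),
    qda = data.frame(regParam = c(0.0, 0.1, 0.5, 1.0)),
    mnlr = expand.grid(penalty = c("l1", "l2"),
                       C = c(0.01, 0.1, 1, 10, 20),
                       stringsAsFactors = FALSE),
    rf = expand.grid(nEstimators = c(50, 100),
                     maxDepth = c(NA, 5, 10),
                     minSamplesSplit = c(2, 5),
                     minSamplesLeaf = c(1, 4)),
    xgboost = expand.grid(nEstimators = c(50, 100),
                          maxDepth = c(NA, 5, 10),
                          learningRate = c(0.1, 0.01, 0.001)))
}

.asClassMatrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("features must be finite")
  x
}

.asLabels <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least two classes")
  y
}

# ---------------------------------------------------------------------------
# LDA

#' Fit linear discriminant analysis
#'
#' Computes the within-class scatter `S_W = sum_k sum_{x in k}
#' (x - mu_k)(x - mu_k)^T` and between-class scatter `S_B = sum_k n_k
#' (mu_k - mu)(mu_k - mu)^T`, solves the generalized eigenproblem
#' `S_W^{-1} S_B v = lambda v` for the discriminant projections, and
#' classifies with the pooled-covariance Gaussian discriminant scores.
#'
#' @param x N x P feature matrix.
#' @param y class labels (factor or character).
#' @param solver `"svd"` (whitening via singular value decomposition;
#'   no shrinkage support), `"lsqr"` (solves linear systems) or
#'   `"eigen"` (explicit eigendecomposition). All agree numerically on
#'   well-conditioned problems.
#' @param shrinkage `"none"`, `"auto"` (Ledoit-Wolf shrinkage of the
#'   pooled covariance) or a numeric in `[0, 1]`.
#' @return A [FittedDecoder-class] (name `"lda"`). Its `fit` holds
#'   `Sw`, `Sb`, the eigenpairs (`eigenvalues`, `projections`), class
#'   means and priors.
#' @export
fitLda <- function(x, y, solver = c("svd", "lsqr", "eigen"),
                   shrinkage = "none") {
  solver <- match.arg(solver)
  x <- .asClassMatrix(x); y <- .asLabels(y)
  if (any(table(y) < 2)) stop("every class needs >= 2 samples")
  if (solver == "svd" && !identical(shrinkage, "none"))
    stop("shrinkage is not supported with the svd solver")
  K <- nlevels(y); P <- ncol(x); N <- nrow(x)
  mu <- colMeans(x)
  mus <- do.call(rbind, lapply(levels(y), function(k)
    colMeans(x[y == k, , drop = FALSE])))
  rownames(mus) <- levels(y)
  nk <- as.numeric(table(y))
  Sw <- matrix(0, P, P)
  for (i in seq_len(K)) {
    xc <- sweep(x[y == levels(y)[i], , drop = FALSE], 2, mus[i, ])
    Sw <- Sw + crossprod(xc)
  }
  Sb <- matrix(0, P, P)
  for (i in seq_len(K)) {
    d <- mus[i, ] - mu
    Sb <- Sb + nk[i] * (d %o% d)
  }
  # pooled covariance, optionally shrunk toward a scaled identity
  Sigma <- Sw / (N - K)
  alpha <- if (identical(shrinkage, "auto")) .ledoitWolf(x, y)
           else if (is.numeric(shrinkage)) shrinkage else 0
  if (alpha > 0)
    Sigma <- (1 - alpha) * Sigma + alpha * (sum(diag(Sigma)) / P) * diag(P)

  SigInv <- switch(solver,
    svd = {
      s <- svd(Sigma)
      pos <- s$d > max(s$d) * 1e-10
      if (!any(pos)) stop("singular within-class covariance")
      s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    },
    lsqr = tryCatch(solve(Sigma), error = function(e)
      stop("singular within-class scatter; use shrinkage or svd solver")),
    eigen = {
      e <- eigen(Sigma, symmetric = TRUE)
      pos <- e$values > max(e$values) * 1e-10
      if (!any(pos)) stop("singular within-class covariance")
      e$vectors[, pos, drop = FALSE] %*%
        (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    })
  # generalized eigenproblem for the discriminant projections
  ev <- eigen(SigInv %*% Sb)
  ord <- order(Re(ev$values), decreasing = TRUE)
  M <- min(K - 1, P)
  proj <- Re(ev$vectors[, ord[seq_len(M)], drop = FALSE])
  lambda <- Re(ev$values[ord[seq_len(M)]])

  priors <- nk / N
  # linear discriminant scores: x' SigInv mu_k - mu_k' SigInv mu_k / 2 + log pi_k
  Wk <- SigInv %*% t(mus)
  b <- -0.5 * colSums(t(mus) * Wk) + log(priors)
  new("FittedDecoder", name = "lda",
      fit = list(Wk = Wk, b = b, Sw = Sw, Sb = Sb, Sigma = Sigma,
                 means = mus, priors = priors, eigenvalues = lambda,
                 projections = proj),
      classes = levels(y),
      info = list(hyperparameters = list(solver = solver,
                                         shrinkage = shrinkage)))
}

# Ledoit-Wolf shrinkage intensity on within-class centered data
.ledoitWolf <- function(x, y) {
  xc <- x
  for (k in levels(y)) {
    ix <- y == k
    xc[ix, ] <- sweep(x[ix, , drop = FALSE], 2,
                      colMeans(x[ix, , drop = FALSE]))
  }
  n <- nrow(xc); p <- ncol(xc)
  S <- crossprod(xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2) / p
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    b2 <- b2 + sum((xi %o% xi - S)^2)
  }
  b2 <- b2 / (n^2 * p)
  max(0, min(1, min(b2, d2) / d2))
}

# ---------------------------------------------------------------------------
# QDA

#' Fit quadratic discriminant analysis
#'
#' Models each class with its own multivariate Gaussian density
#' `f_k(x) = (2 pi)^{-z/2} |Sigma_k|^{-1/2} exp(-(x - mu_k)'
#' Sigma_k^{-1} (x - mu_k) / 2)` and predicts by Bayes' rule,
#' `P(Y = k | x) = pi_k f_k(x) / sum_l pi_l f_l(x)`. The class
#' covariances are regularized as `(1 - r) Sigma_k + r I`.
#'
#' @param x N x P feature matrix.
#' @param y class labels.
#' @param regParam covariance regularization `r` in `[0, 1]`.
#' @return A [FittedDecoder-class] (name `"qda"`).
#' @export
fitQda <- function(x, y, regParam = 0) {
  x <- .asClassMatrix(x); y <- .asLabels(y)
  P <- ncol(x)
  fits <- lapply(levels(y), function(k) {
    xk <- x[y == k, , drop = FALSE]
    if (nrow(xk) < 2) stop("class ", k, " has < 2 samples")
    muk <- colMeans(xk)
    Sk <- crossprod(sweep(xk, 2, muk)) / (nrow(xk) - 1)
    Sk <- (1 - regParam) * Sk + regParam * diag(P)
    ch <- tryCatch(chol(Sk), error = function(e)
      stop("singular class covariance for '", k,
           "' at regParam = ", regParam))
    list(mu = muk, chol = ch, logdet = 2 * sum(log(diag(ch))),
         prior = nrow(xk))
  })
  priors <- vapply(fits, `[[`, numeric(1), "prior")
  priors <- priors / sum(priors)
  for (i in seq_along(fits)) fits[[i]]$prior <- priors[i]
  new("FittedDecoder", name = "qda",
      fit = list(classFits = fits),
      classes = levels(y),
      info = list(hyperparameters = list(regParam = regParam)))
}

.qdaLogPost <- function(model, x) {
  x <- .asClassMatrix(x)
  fits <- model@fit$classFits
  z <- ncol(x)
  ll <- vapply(fits, function(f) {
    xc <- sweep(x, 2, f$mu)
    q <- colSums(backsolve(f$chol, t(xc), transpose = TRUE)^2)
    -0.5 * (z * log(2 * pi) + f$logdet + q) + log(f$prior)
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  ll
}

# ---------------------------------------------------------------------------
# MNLR

#' Fit multinomial logistic regression
#'
#' Reference-class softmax: separate weight vectors `W_k` for the
#' first `K - 1` classes with the last class as reference, class
#' probabilities `exp(W_k' x) / (1 + sum_{k < K} exp(W_k' x))`.
#' The penalized negative log-likelihood (L2, or L1 via proximal
#' gradient) is minimized to first-order tolerance `tol`; the
#' intercept is never penalized. `C` is the inverse regularization
#' strength, as in the common implementations.
#'
#' @param x N x P feature matrix.
#' @param y class labels.
#' @param penalty `"l1"` or `"l2"`.
#' @param C inverse regularization strength (> 0).
#' @param maxIter iteration budget.
#' @param tol first-order tolerance on the (sub)gradient norm.
#' @return A [FittedDecoder-class] (name `"mnlr"`); `info$converged`
#'   reports whether `tol` was reached.
#' @export
fitMnlr <- function(x, y, penalty = c("l2", "l1"), C = 20,
                    maxIter = 500, tol = 1e-4) {
  penalty <- match.arg(penalty)
  x <- .asClassMatrix(x); y <- .asLabels(y)
  K <- nlevels(y); P <- ncol(x); N <- nrow(x)
  Xd <- cbind(1, x)  # intercept first
  yi <- as.integer(y)
  lam <- 1 / C
  mask <- c(0, rep(1, P))  # intercept unpenalized

  probFull <- function(W) {
    # W: (P+1) x (K-1); reference class K has zero weights
    eta <- cbind(Xd %*% W, 0)
    .softmax(eta)
  }
  grad <- function(W) {
    pr <- probFull(W)
    G <- crossprod(Xd, pr[, -K, drop = FALSE] -
                   .oneHot(yi, K)[, -K, drop = FALSE]) / N
    G
  }
  nll <- function(W) {
    pr <- probFull(W)
    -mean(log(pmax(pr[cbind(seq_len(N), yi)], 1e-300)))
  }

  W <- matrix(0, P + 1, K - 1)
  converged <- FALSE
  if (penalty == "l2") {
    obj <- function(w) {
      W <- matrix(w, P + 1)
      nll(W) + 0.5 * lam * sum((mask * W)^2) / N
    }
    gr <- function(w) {
      W <- matrix(w, P + 1)
      as.vector(grad(W) + lam * (mask * W) / N)
    }
    opt <- optim(as.vector(W), obj, gr, method = "L-BFGS-B",
                 control = list(maxit = maxIter, factr = 1e4))
    W <- matrix(opt$par, P + 1)
    converged <- sqrt(sum(gr(opt$par)^2)) < tol
  } else {
    # FISTA with backtracking for the L1 penalty
    L <- max(1e-3, norm(Xd, "F")^2 / (4 * N))
    Z <- W; tk <- 1
    fprev <- Inf
    for (it in seq_len(maxIter)) {
      G <- grad(Z)
      Wnew <- Z - G / L
      thr <- lam / (L * N)
      Wnew[-1, ] <- sign(Wnew[-1, ]) * pmax(abs(Wnew[-1, ]) - thr, 0)
      tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Z <- Wnew + ((tk - 1) / tnew) * (Wnew - W)
      W <- Wnew; tk <- tnew
      f <- nll(W) + lam * sum(abs(mask * W)) / N
      if (abs(fprev - f) < tol * 1e-3) { converged <- TRUE; break }
      fprev <- f
    }
  }
  if (!converged)
    warning("mnlr did not reach tolerance ", tol, " within ", maxIter,
            " iterations")
  new("FittedDecoder", name = "mnlr",
      fit = list(W = W),
      classes = levels(y),
      info = list(hyperparameters = list(penalty = penalty, C = C),
                  converged = converged))
}

# ---------------------------------------------------------------------------
# Tree ensembles

#' Fit a random forest decoder
#'
#' Bagged decision trees with feature randomness (via `ranger`),
#' exposed under the common decoder contract with the published grid
#' semantics: number of trees, maximum depth (`NA` = unlimited),
#' minimum samples to split a node and minimum samples per leaf.
#'
#' @param x N x P feature matrix.
#' @param y class labels.
#' @param nEstimators number of trees.
#' @param maxDepth maximum tree depth (`NA` for unlimited).
#' @param minSamplesSplit minimum node size to attempt a split.
#' @param minSamplesLeaf minimum terminal node size.
#' @param seed integer seed.
#' @return A [FittedDecoder-class] (name `"rf"`) with
#'   `info$importance` holding impurity feature importances.
#' @export
fitForest <- function(x, y, nEstimators = 100, maxDepth = NA,
                      minSamplesSplit = 2, minSamplesLeaf = 1, seed = 1L) {
  x <- .asClassMatrix(x); y <- .asLabels(y)
  df <- data.frame(.y = y, x)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = nEstimators,
    max.depth = if (is.na(maxDepth)) 0 else maxDepth,
    min.node.size = minSamplesSplit,
    min.bucket = minSamplesLeaf,
    probability = TRUE, importance = "impurity",
    num.threads = 1, seed = as.integer(seed))
  new("FittedDecoder", name = "rf",
      fit = list(ranger = fit, featureNames = colnames(df)[-1]),
      classes = levels(y),
      info = list(hyperparameters = list(nEstimators = nEstimators,
                    maxDepth = maxDepth, minSamplesSplit = minSamplesSplit,
                    minSamplesLeaf = minSamplesLeaf),
                  importance = fit$variable.importance))
}

#' Fit a gradient-boosted tree decoder
#'
#' Gradient boosting of decision trees minimizing the multi-class
#' cross-entropy `L(Y_t, Y_p) = -sum_i sum_k y_ik log p_ik` (one-hot
#' true labels), via `xgboost`.
#'
#' @inheritParams fitForest
#' @param learningRate boosting shrinkage (eta).
#' @return A [FittedDecoder-class] (name `"xgboost"`);
#'   `info$evalLog` holds the per-round training loss.
#' @export
fitBoost <- function(x, y, nEstimators = 100, maxDepth = NA,
                     learningRate = 0.1, seed = 1L) {
  x <- .asClassMatrix(x); y <- .asLabels(y)
  K <- nlevels(y)
  set.seed(as.integer(seed))
  params <- list(objective = "multi:softprob", num_class = K,
                 eta = learningRate, nthread = 1,
                 eval_metric = "mlogloss")
  if (is.na(maxDepth)) {
    params$max_depth <- 0
    params$tree_method <- "hist"
    params$grow_policy <- "lossguide"
  } else params$max_depth <- maxDepth
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nEstimators,
                            evals = list(train = dtrain), verbose = 0)
  new("FittedDecoder", name = "xgboost",
      fit = list(booster = fit),
      classes = levels(y),
      info = list(hyperparameters = list(nEstimators = nEstimators,
                    maxDepth = maxDepth, learningRate = learningRate),
                  evalLog = as.data.frame(fit$evaluation_log)))
}

# ---------------------------------------------------------------------------
# Cross-validated grid search

#' Stratified k-fold cross-validated grid search
#'
#' Exhaustive search over a hyperparameter grid: mean validation
#' accuracy over stratified folds per cell, ties broken by
#' first-in-grid order. Folds are seeded and identical across cells.
#'
#' @param fitFun function `(x, y, ...)` returning a
#'   [FittedDecoder-class]; called with one grid row's parameters.
#' @param grid data.frame, one row per cell (see [decoderGrids()]).
#' @param x N x P feature matrix.
#' @param y class labels.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `best` (the winning row as a list), `bestIndex`,
#'   and `table` (the grid with a `cvAccuracy` column).
#' @export
gridSearchCV <- function(fitFun, grid, x, y, folds = 5, seed = 1L) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  x <- .asClassMatrix(x); y <- .asLabels(y)
  if (any(table(y) < folds))
    stop("every class needs at least ", folds, " members for ", folds,
         "-fold stratified CV")
  rng <- .seededRNG(seed)
  on.exit(rng$restore(), add = TRUE)
  foldId <- integer(length(y))
  for (k in levels(y)) {
    ix <- which(y == k)
    foldId[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  acc <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pars <- as.list(grid[g, , drop = FALSE])
    pars <- lapply(pars, function(v) if (is.factor(v)) as.character(v) else v)
    ok <- TRUE; correct <- 0
    for (f in seq_len(folds)) {
      tr <- foldId != f
      fit <- tryCatch(do.call(fitFun, c(list(x[tr, , drop = FALSE], y[tr]),
                                        pars)),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    if (ok) acc[g] <- correct / length(y)
  }
  if (all(is.na(acc))) stop("no grid cell could be fitted")
  best <- which.max(acc)  # first maximum wins ties
  tab <- cbind(grid, cvAccuracy = acc)
  pars <- as.list(grid[best, , drop = FALSE])
  pars <- lapply(pars, function(v) if (is.factor(v)) as.character(v) else v)
  list(best = pars, bestIndex = best, table = tab)
}
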