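# Minimal reverse-mode neural-network engine for 1-D time-series
# classification. Layers are environments holding parameters, gradients
# and forward caches; containers (sequential, parallel-concat, residual)
# compose them into the architectures this package ships. Sequence
# tensors are stored as (time * batch) x channels matrices, time-fastest
# within each batch element, with the time length in attribute "nt".
# All matrix work goes through BLAS; gradients are hand-derived and
# checked against finite differences in the test suite.

# The temporal length of the sequence tensor currently flowing through
# the graph. Same padding everywhere means nt is constant within one
# forward/backward pass, so it lives in engine state rather than as a
# matrix attribute (attribute writes would copy every tensor).
.ntState <- new.env(parent = emptyenv())
.ntState$nt <- NULL
.tns <- function(x, nt) { .ntState$nt <- nt; x }
.nt <- function(x) .ntState$nt

# fast column-wise broadcast (x is column-major; v recycled per column)
.addC <- function(x, v) x + rep(v, each = nrow(x))
.mulC <- function(x, v) x * rep(v, each = nrow(x))

.heInit <- function(nin, nout, gain = 2)
  matrix(rnorm(nin * nout, 0, sqrt(gain / nin)), nin, nout)

.glorotInit <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -l, l), nin, nout)
}

# --- layer constructors ----------------------------------------------------

.lDense <- function(nin, nout, init = "he") {
  e <- new.env(parent = emptyenv())
  e$kind <- "dense"
  e$W <- if (init == "he") .heInit(nin, nout) else .glorotInit(nin, nout)
  e$b <- rep(0, nout)
  e
}

.lBN <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$kind <- "bn"; e$gamma <- rep(1, C); e$beta <- rep(0, C)
  e$rmean <- rep(0, C); e$rvar <- rep(1, C)
  e$momentum <- momentum; e$eps <- eps
  e
}

.lAct <- function(type = c("relu", "lrelu", "tanh", "sigmoid")) {
  e <- new.env(parent = emptyenv())
  e$kind <- "act"; e$type <- match.arg(type); e$alpha <- 0.01
  e
}

.lConv <- function(cin, cout, k, bias = TRUE) {
  e <- new.env(parent = emptyenv())
  e$kind <- "conv"; e$k <- k; e$cin <- cin; e$cout <- cout
  e$W <- .heInit(cin * k, cout)
  e$b <- if (bias) rep(0, cout) else NULL
  e
}

.lPool <- function(k = 3) {
  e <- new.env(parent = emptyenv()); e$kind <- "pool"; e$k <- k; e
}

.lGAP <- function() { e <- new.env(parent = emptyenv()); e$kind <- "gap"; e }

.lFlatten <- function() {
  e <- new.env(parent = emptyenv()); e$kind <- "flatten"; e
}

.lInputSeq <- function() {
  e <- new.env(parent = emptyenv()); e$kind <- "inputseq"; e
}

.lLSTM <- function(cin, H, returnSeq = TRUE, reverse = FALSE) {
  e <- new.env(parent = emptyenv())
  e$kind <- "lstm"; e$H <- H; e$cin <- cin
  e$returnSeq <- returnSeq; e$reverse <- reverse
  e$Wx <- .glorotInit(cin, 4 * H)
  e$Wa <- .glorotInit(H, 4 * H)
  e$b <- c(rep(0, H), rep(1, H), rep(0, 2 * H))  # forget-gate bias 1
  e
}

.lBiLSTM <- function(cin, H, returnSeq = TRUE) {
  e <- new.env(parent = emptyenv())
  e$kind <- "bilstm"
  e$fwd <- .lLSTM(cin, H, returnSeq, reverse = FALSE)
  e$bwd <- .lLSTM(cin, H, returnSeq, reverse = TRUE)
  e
}

.lSeq <- function(nodes) {
  e <- new.env(parent = emptyenv()); e$kind <- "seq"; e$nodes <- nodes; e
}

.lPar <- function(branches) {
  e <- new.env(parent = emptyenv())
  e$kind <- "par"; e$branches <- branches; e
}

.lRes <- function(body, shortcut) {
  e <- new.env(parent = emptyenv())
  e$kind <- "res"; e$body <- body; e$shortcut <- shortcut; e
}

# --- sequence indexing helpers --------------------------------------------

.seqBase <- function(nt, batch, k) {
  # row index in a (nt + k - 1)-padded per-batch layout for output (b, t)
  rep((0:(batch - 1)) * (nt + k - 1L), each = nt) + rep(seq_len(nt), batch)
}

.timeRows <- function(nt, batch, t) (0:(batch - 1)) * nt + t

# --- forward ---------------------------------------------------------------

.fwd <- function(node, x, training = FALSE) {
  force(x)  # the producer's .tns() must run before .nt() reads the state
  switch(node$kind,
    seq = {
      for (nd in node$nodes) x <- .fwd(nd, x, training)
      x
    },
    par = {
      outs <- lapply(node$branches, .fwd, x = x, training = training)
      node$widths <- vapply(outs, ncol, 1L)
      .tns(do.call(cbind, outs), .nt(outs[[1]]))
    },
    res = {
      b <- .fwd(node$body, x, training)
      s <- .fwd(node$shortcut, x, training)
      .tns(b + s, .nt(b))
    },
    inputseq = {
      # (batch, P) -> sequence tensor with one channel
      node$batch <- nrow(x)
      .tns(matrix(as.vector(t(x)), ncol = 1), ncol(x))
    },
    dense = {
      node$x <- x
      out <- x %*% node$W
      if (!is.null(node$b)) out <- .addC(out, node$b)
      .tns(out, .nt(x))
    },
    bn = {
      if (training) {
        r <- .bnFwdTrainC(x, node$gamma, node$beta, node$eps)
        node$rmean <- (1 - node$momentum) * node$rmean + node$momentum * r$mu
        node$rvar <- (1 - node$momentum) * node$rvar + node$momentum * r$var
        node$xhat <- r$xhat
        node$invstd <- 1 / sqrt(r$var + node$eps)
        node$training <- TRUE
        return(.tns(r$out, .nt(x)))
      }
      invstd <- 1 / sqrt(node$rvar + node$eps)
      xhat <- .colCenterScaleC(x, node$rmean, invstd)
      node$xhat <- xhat; node$invstd <- invstd; node$training <- FALSE
      .tns(.colScaleShiftC(xhat, node$gamma, node$beta), .nt(x))
    },
    act = {
      out <- switch(node$type,
        relu = .reluFwdC(x, 0),
        lrelu = .reluFwdC(x, node$alpha),
        tanh = tanh(x),
        sigmoid = 1 / (1 + exp(-x)))
      node$x <- x; node$out <- out
      .tns(out, .nt(x))
    },
    conv = {
      nt <- .nt(x); batch <- nrow(x) / nt
      left <- (node$k - 1L) %/% 2L
      node$x <- x; node$left <- left
      node$nt <- nt; node$batch <- batch
      out <- .convFwdC(x, node$W, nt, batch, node$k, left)
      if (!is.null(node$b)) out <- .addC(out, node$b)
      .tns(out, nt)
    },
    pool = {
      nt <- .nt(x); batch <- nrow(x) / nt
      left <- (node$k - 1L) %/% 2L
      r <- .poolFwdC(x, nt, batch, node$k, left)
      node$arg <- r$arg; node$left <- left
      node$nt <- nt; node$batch <- batch
      .tns(r$out, nt)
    },
    gap = {
      nt <- .nt(x); batch <- nrow(x) / nt
      node$nt <- nt; node$batch <- batch
      grp <- rep(seq_len(batch), each = nt)
      rowsum(x, grp) / nt
    },
    flatten = {
      nt <- .nt(x); batch <- nrow(x) / nt; C <- ncol(x)
      node$nt <- nt; node$batch <- batch; node$C <- C
      arr <- array(as.vector(x), c(nt, batch, C))
      t(matrix(aperm(arr, c(1, 3, 2)), nt * C, batch))
    },
    lstm = .fwdLSTM(node, x, training),
    bilstm = {
      f <- .fwd(node$fwd, x, training)
      b <- .fwd(node$bwd, x, training)
      .tns(cbind(f, b), .nt(f))
    },
    stop("unknown node kind ", node$kind))
}

.revSeq <- function(x, nt, batch) {
  idx <- rep((0:(batch - 1)) * nt, each = nt) + rep(nt:1, batch)
  .tns(x[idx, , drop = FALSE], nt)
}

.fwdLSTM <- function(node, x, training) {
  nt <- .nt(x); batch <- nrow(x) / nt
  H <- node$H
  if (node$reverse) x <- .revSeq(x, nt, batch)
  a <- matrix(0, batch, H); cst <- matrix(0, batch, H)
  cache <- vector("list", nt)
  outSeq <- if (node$returnSeq) matrix(0, nt * batch, H) else NULL
  for (t in seq_len(nt)) {
    rows <- .timeRows(nt, batch, t)
    xt <- x[rows, , drop = FALSE]
    Z <- .addC(xt %*% node$Wx + a %*% node$Wa, node$b)
    u <- 1 / (1 + exp(-Z[, seq_len(H), drop = FALSE]))
    f <- 1 / (1 + exp(-Z[, H + seq_len(H), drop = FALSE]))
    o <- 1 / (1 + exp(-Z[, 2 * H + seq_len(H), drop = FALSE]))
    g <- tanh(Z[, 3 * H + seq_len(H), drop = FALSE])
    cPrev <- cst
    cst <- f * cPrev + u * g
    tc <- tanh(cst)
    aPrev <- a
    a <- o * tc
    cache[[t]] <- list(xt = xt, aPrev = aPrev, cPrev = cPrev, u = u, f = f,
                       o = o, g = g, tc = tc)
    if (node$returnSeq) outSeq[rows, ] <- a
  }
  node$cache <- cache; node$nt <- nt; node$batch <- batch
  if (node$returnSeq) {
    out <- .tns(outSeq, nt)
    if (node$reverse) out <- .revSeq(out, nt, batch)
    out
  } else a
}

# --- backward --------------------------------------------------------------

.accGrad <- function(node, name, g) {
  gn <- paste0("g", name)
  node[[gn]] <- if (is.null(node[[gn]])) g else node[[gn]] + g
}

.bwd <- function(node, dout) {
  force(dout)
  switch(node$kind,
    seq = {
      for (nd in rev(node$nodes)) dout <- .bwd(nd, dout)
      dout
    },
    par = {
      off <- 0L; dx <- NULL
      for (i in seq_along(node$branches)) {
        w <- node$widths[i]
        di <- .bwd(node$branches[[i]],
                   .tns(dout[, off + seq_len(w), drop = FALSE], .nt(dout)))
        dx <- if (is.null(dx)) di else dx + di
        off <- off + w
      }
      .tns(dx, .nt(dout))
    },
    res = {
      db <- .bwd(node$body, dout)
      ds <- .bwd(node$shortcut, dout)
      .tns(db + ds, .nt(dout))
    },
    inputseq = {
      # gradient w.r.t. the raw input is not propagated further
      NULL
    },
    dense = {
      .accGrad(node, "W", crossprod(node$x, dout))
      if (!is.null(node$b)) .accGrad(node, "b", colSums(dout))
      .tns(dout %*% t(node$W), .nt(dout))
    },
    bn = {
      xhat <- node$xhat
      if (isTRUE(node$training)) {
        r <- .bnBwdTrainC(dout, xhat, node$gamma, node$invstd)
        .accGrad(node, "gamma", r$dgamma)
        .accGrad(node, "beta", r$dbeta)
        return(.tns(r$dx, .nt(dout)))
      }
      .accGrad(node, "gamma", colSums(dout * xhat))
      .accGrad(node, "beta", colSums(dout))
      dx <- .mulC(.mulC(dout, node$gamma), node$invstd)
      .tns(dx, .nt(dout))
    },
    act = {
      dx <- switch(node$type,
        relu = .reluBwdC(node$x, dout, 0),
        lrelu = .reluBwdC(node$x, dout, node$alpha),
        tanh = dout * (1 - node$out^2),
        sigmoid = dout * node$out * (1 - node$out))
      .tns(dx, .nt(dout))
    },
    conv = {
      if (!is.null(node$b)) .accGrad(node, "b", colSums(dout))
      r <- .convBwdC(node$x, node$W, dout, node$nt, node$batch, node$k,
                     node$left)
      .accGrad(node, "W", r$dW)
      node$x <- NULL
      .tns(r$dx, node$nt)
    },
    pool = {
      .tns(.poolBwdC(node$arg, dout, node$nt, node$batch, node$k,
                     node$left), node$nt)
    },
    gap = {
      nt <- node$nt
      .tns(dout[rep(seq_len(node$batch), each = nt), , drop = FALSE] / nt, nt)
    },
    flatten = {
      nt <- node$nt; batch <- node$batch; C <- node$C
      arr <- array(as.vector(t(dout)), c(nt, C, batch))
      .tns(matrix(aperm(arr, c(1, 3, 2)), nt * batch, C), nt)
    },
    lstm = .bwdLSTM(node, dout),
    bilstm = {
      Hf <- node$fwd$H
      df <- .bwd(node$fwd, .sliceCols(dout, seq_len(Hf)))
      db <- .bwd(node$bwd, .sliceCols(dout, Hf + seq_len(node$bwd$H)))
      .tns(df + db, .nt(df))
    },
    stop("unknown node kind ", node$kind))
}

.sliceCols <- function(x, j) .tns(x[, j, drop = FALSE], .nt(x))

.bwdLSTM <- function(node, dout) {
  nt <- node$nt; batch <- node$batch; H <- node$H
  if (node$returnSeq && node$reverse) dout <- .revSeq(dout, nt, batch)
  dx <- matrix(0, nt * batch, node$cin)
  da <- matrix(0, batch, H); dc <- matrix(0, batch, H)
  dWx <- matrix(0, nrow(node$Wx), 4 * H)
  dWa <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H)
  for (t in nt:1) {
    cc <- node$cache[[t]]
    rows <- .timeRows(nt, batch, t)
    if (node$returnSeq) da <- da + dout[rows, , drop = FALSE]
    else if (t == nt) da <- da + dout
    doGate <- da * cc$tc
    dcT <- dc + da * cc$o * (1 - cc$tc^2)
    du <- dcT * cc$g
    dg <- dcT * cc$u
    df <- dcT * cc$cPrev
    dc <- dcT * cc$f
    dZ <- cbind(du * cc$u * (1 - cc$u),
                df * cc$f * (1 - cc$f),
                doGate * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$xt, dZ)
    dWa <- dWa + crossprod(cc$aPrev, dZ)
    db <- db + colSums(dZ)
    dx[rows, ] <- dZ %*% t(node$Wx)
    da <- dZ %*% t(node$Wa)
  }
  .accGrad(node, "Wx", dWx); .accGrad(node, "Wa", dWa); .accGrad(node, "b", db)
  node$cache <- NULL
  dxT <- .tns(dx, nt)
  if (node$reverse) dxT <- .revSeq(dxT, nt, batch)
  dxT
}

# --- parameter walking, Adam, misc -----------------------------------------

.PARAM_NAMES <- c("W", "b", "gamma", "beta", "Wx", "Wa")

.walkNodes <- function(node, acc = list()) {
  acc[[length(acc) + 1L]] <- node
  kids <- switch(node$kind,
    seq = node$nodes, par = node$branches,
    res = list(node$body, node$shortcut),
    bilstm = list(node$fwd, node$bwd), list())
  for (k in kids) acc <- .walkNodes(k, acc)
  acc
}

.nnParams <- function(graph) {
  out <- list()
  for (nd in .walkNodes(graph)) {
    for (p in .PARAM_NAMES)
      if (!is.null(nd[[p]]) && nd$kind != "act")
        out[[length(out) + 1L]] <- list(node = nd, name = p)
  }
  out
}

.nnZeroGrads <- function(graph) {
  for (nd in .walkNodes(graph))
    for (p in .PARAM_NAMES) nd[[paste0("g", p)]] <- NULL
  invisible(NULL)
}

# fast variant over a precomputed parameter list (hot path)
.nnZeroGradsP <- function(params) {
  for (p in params) p$node[[paste0("g", p$name)]] <- NULL
  invisible(NULL)
}

# drop forward caches so large activation tensors are not retained on
# the fitted object
.nnClearCaches <- function(graph) {
  for (nd in .walkNodes(graph))
    for (f in c("x", "xhat", "out", "arg", "cache", "col"))
      nd[[f]] <- NULL
  invisible(NULL)
}

#' @keywords internal
.nnParamCount <- function(graph) {
  sum(vapply(.nnParams(graph), function(p)
    length(p$node[[p$name]]), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adam state (first/second moments) lives beside each parameter in its
# node environment under m<name>/v<name>.
.adamInit <- function(params) {
  for (p in params) {
    z <- p$node[[p$name]] * 0
    p$node[[paste0("m", p$name)]] <- z
    p$node[[paste0("v", p$name)]] <- z
  }
  invisible(params)
}

.adamStep <- function(params, state, lr, l2, iter,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 / (1 - beta1^iter)
  c2 <- 1 / (1 - beta2^iter)
  for (p in params) {
    nd <- p$node; nm <- p$name
    g <- nd[[paste0("g", nm)]]
    if (is.null(g)) next
    w <- nd[[nm]]
    # L2 penalty on weight matrices only (not biases / batch-norm)
    if (l2 > 0 && nm %in% c("W", "Wx", "Wa")) g <- g + l2 * w
    m <- beta1 * nd[[paste0("m", nm)]] + (1 - beta1) * g
    v <- beta2 * nd[[paste0("v", nm)]] + (1 - beta2) * g * g
    nd[[paste0("m", nm)]] <- m
    nd[[paste0("v", nm)]] <- v
    nd[[nm]] <- w - lr * (m * c1) / (sqrt(v * c2) + eps)
  }
  invisible(state)
}

# snapshot/restore of the full inference state: parameters plus the
# batch-norm running statistics (restoring weights without their
# matching statistics would corrupt eval-mode predictions)
.STATE_NAMES <- c(.PARAM_NAMES, "rmean", "rvar")

.nnCopyParams <- function(graph) {
  out <- list()
  for (nd in .walkNodes(graph))
    for (p in .STATE_NAMES)
      if (!is.null(nd[[p]]) && nd$kind != "act")
        out[[length(out) + 1L]] <- nd[[p]]
  out
}

.nnRestoreParams <- function(graph, saved) {
  i <- 0L
  for (nd in .walkNodes(graph))
    for (p in .STATE_NAMES)
      if (!is.null(nd[[p]]) && nd$kind != "act") {
        i <- i + 1L
        nd[[p]] <- saved[[i]]
      }
  invisible(NULL)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.oneHot <- function(y, K) {
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}
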