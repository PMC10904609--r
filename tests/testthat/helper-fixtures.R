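# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a small clean high-SNR run, preprocessed, with its timeline
fixtureRun <- function() {
  if (is.null(.fixtures$run)) {
    tl <- buildParadigm()
    cfg <- syntheticPreset("high-snr", nChannels = 4, seed = 42)
    rec <- simulateRecording(tl, cfg)
    out <- preprocessRecording(rec, tl)
    .fixtures$run <- list(timeline = tl, cfg = cfg, rec = rec,
                          hb = out$recording, report = out$report)
  }
  .fixtures$run
}

# deterministic multi-class toy: five time-shifted bump templates
toyBumpData <- function(n = 200, P = 40, noise = 0.5, seed = 1) {
  set.seed(seed)
  y <- factor(sample(fingerConditions(), n, TRUE),
              levels = fingerConditions())
  tpl <- sapply(1:5, function(k) dnorm(seq_len(P), mean = 8 + 5 * k, sd = 4))
  x <- t(sapply(as.integer(y), function(k)
    tpl[, k] * 10 + rnorm(P, 0, noise)))
  list(x = x, y = y)
}

# finite-difference gradient check of a network against the engine's
# backward pass; returns the worst relative error over sampled entries
gradCheckNet <- function(net, n = 5, P = 12, K = 3, eps = 1e-4,
                         perParam = 3) {
  set.seed(42)
  x <- matrix(rnorm(n * P), n, P)
  y <- factor(sample(letters[seq_len(K)], n, TRUE),
              levels = letters[seq_len(K)])
  oneHot <- HemoDecode:::.oneHot(y, K)
  lossAt <- function() {
    p <- HemoDecode:::.softmax(HemoDecode:::.fwd(net$graph, x,
                                                 training = TRUE))
    -mean(log(pmax(rowSums(p * oneHot), 1e-12)))
  }
  p <- HemoDecode:::.softmax(HemoDecode:::.fwd(net$graph, x,
                                               training = TRUE))
  HemoDecode:::.nnZeroGrads(net$graph)
  HemoDecode:::.bwd(net$graph, (p - oneHot) / n)
  worst <- 0
  for (pp in HemoDecode:::.nnParams(net$graph)) {
    w <- pp$node[[pp$name]]
    g <- as.vector(pp$node[[paste0("g", pp$name)]])
    for (i in sample(length(w), min(perParam, length(w)))) {
      orig <- w[i]
      pp$node[[pp$name]][i] <- orig + eps; lp <- lossAt()
      pp$node[[pp$name]][i] <- orig - eps; lm <- lossAt()
      pp$node[[pp$name]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) /
                            max(1e-5, abs(num), abs(g[i])))
    }
  }
  worst
}
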