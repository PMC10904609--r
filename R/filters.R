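# IIR filtering plumbing. Filter design is delegated to signal::butter;
# the forward pass, steady-state initial conditions and the odd-reflection
# padded forward-backward (zero-phase) application are implemented here so
# that edge transients stay at machine-precision level (a DC input through
# the band-pass must come out numerically zero, which naive forward-backward
# filtering does not deliver).

# Direct-form II transposed filter over the columns of a matrix, with
# initial conditions zi (length n-1) scaled per column.
.lfilter <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  ns <- nrow(x); nc <- ncol(x)
  y <- matrix(0, ns, nc)
  z <- if (is.null(zi)) matrix(0, n - 1, nc) else as.matrix(zi)
  for (t in seq_len(ns)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2)
      z[seq_len(n - 2), ] <- b[2:(n - 1)] %o% xt + z[2:(n - 1), , drop = FALSE] -
        a[2:(n - 1)] %o% yt
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  list(y = y, z = z)
}

# Steady-state initial conditions for a step input of height one
# (scipy.signal.lfilter_zi).
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  # companion matrix of a, transposed
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(A)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# Zero-phase filtering with odd-reflection padding and steady-state
# initial conditions (scipy.signal.filtfilt defaults). x: vector or
# samples x channels matrix.
.filtfilt <- function(b, a, x, padlen = 3 * (max(length(a), length(b)) - 1)) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  ns <- nrow(x)
  if (padlen >= ns)
    stop("series too short for the requested filter padding")
  if (padlen > 0) {
    pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[padlen + 1 - seq_len(padlen) + 1, , drop = FALSE]
    post <- 2 * matrix(x[ns, ], padlen, ncol(x), byrow = TRUE) -
      x[ns - seq_len(padlen), , drop = FALSE]
    ext <- rbind(pre, x, post)
  } else ext <- x
  zi <- .lfilterZi(b, a)
  f1 <- .lfilter(b, a, ext, zi = zi %o% ext[1, ])
  rev1 <- f1$y[rev(seq_len(nrow(f1$y))), , drop = FALSE]
  f2 <- .lfilter(b, a, rev1, zi = zi %o% rev1[1, ])
  y <- f2$y[rev(seq_len(nrow(f2$y))), , drop = FALSE]
  if (padlen > 0) y <- y[padlen + seq_len(ns), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes slow drift and fast physiological oscillations from a
#' hemodynamic series: an order-`order` Butterworth high-pass at
#' `lowHz` cascaded with an order-`order` low-pass at `highHz`, each
#' applied forward and backward (zero phase). Defaults follow standard
#' fNIRS practice: pass band 0.01-0.5 Hz, which keeps the hemodynamic
#' response and the task frequencies while suppressing baseline drift
#' and the cardiac pulsation.
#'
#' @param x numeric vector, or samples x channels matrix (each column
#'   filtered independently).
#' @param samplingRate sampling rate, Hz.
#' @param lowHz,highHz pass-band edges, Hz; must satisfy
#'   `0 < lowHz < highHz < samplingRate / 2`.
#' @param order Butterworth order of each cascade section.
#' @return Filtered series, same shape and length as the input.
#' @examples
#' fs <- 3.9063
#' t <- (0:4000) / fs
#' x <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 1.2 * t) + 5
#' y <- bandpassFilter(x, fs)
#' @export
bandpassFilter <- function(x, samplingRate, lowHz = 0.01, highHz = 0.5,
                           order = 4) {
  if (!(lowHz > 0 && lowHz < highHz && highHz < samplingRate / 2))
    stop("need 0 < lowHz < highHz < samplingRate/2")
  hp <- signal::butter(order, lowHz * 2 / samplingRate, type = "high")
  lp <- signal::butter(order, highHz * 2 / samplingRate, type = "low")
  y <- .filtfilt(hp$b, hp$a, x)
  .filtfilt(lp$b, lp$a, y)
}

#' Temporal-derivative distribution repair (TDDR)
#'
#' Motion-artifact correction by iteratively reweighted robust
#' estimation on the temporal derivative (Fishburn et al., 2019,
#' NeuroImage 184:171-179). The series is split at 0.5 Hz; the
#' derivative of the low-frequency part is centered by a Tukey-biweight
#' robust mean (tuning constant 4.685), down-weighted where outlying,
#' re-integrated, and recombined with the untouched high-frequency
#' part. Spikes and baseline shifts produce extreme derivatives and are
#' suppressed; ordinary hemodynamics are nearly untouched. Note the
#' robust mean of the derivative is removed, so a global linear trend
#' does not survive the repair (run it after high-pass filtering).
#'
#' @param x numeric vector, or samples x channels matrix (each column
#'   repaired independently).
#' @param samplingRate sampling rate, Hz.
#' @return Repaired series, same shape as the input.
#' @references Fishburn, Ludlum, Vaidya & Medvedev (2019). Temporal
#'   Derivative Distribution Repair (TDDR): a motion correction method
#'   for fNIRS. NeuroImage 184, 171-179.
#' @export
tddr <- function(x, samplingRate) {
  if (!all(is.finite(x))) stop("tddr requires finite input")
  if (!is.null(dim(x)))
    return(apply(x, 2, tddr, samplingRate = samplingRate))
  if (length(x) < 3) stop("series too short for tddr")
  sigMean <- mean(x)
  x <- x - sigMean
  fc <- 0.5 * 2 / samplingRate
  if (fc < 1) {
    bw <- signal::butter(3, fc, type = "low")
    low <- .filtfilt(bw$b, bw$a, x, padlen = 0)
  } else low <- x
  high <- x - low

  tune <- 4.685
  D <- sqrt(.Machine$double.eps)
  deriv <- diff(low)
  w <- rep(1, length(deriv))
  mu <- Inf
  for (i in seq_len(50)) {
    mu0 <- mu
    mu <- sum(w * deriv) / sum(w)
    dev <- abs(deriv - mu)
    sigma <- 1.4826 * median(dev)
    if (sigma == 0) break
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (r < 1))^2
    if (abs(mu - mu0) < D * max(abs(mu), abs(mu0))) break
  }
  newDeriv <- w * (deriv - mu)
  lowCorr <- cumsum(c(0, newDeriv))
  lowCorr <- lowCorr - mean(lowCorr)
  lowCorr + high + sigMean
}
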