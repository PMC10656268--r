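# Internal signal-processing primitives shared across modules.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal of a real vector; its modulus is the
#' instantaneous envelope and its argument the instantaneous phase.
#'
#' @param x numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# One-sided periodogram with density scaling (power / Hz); demeans first.
# Returns frequencies (excluding DC) and linear power density.
periodogramPSD <- function(x, fs, demean = TRUE) {
  n <- length(x)
  if (demean) x <- x - mean(x)
  X <- stats::fft(x)
  nf <- floor(n / 2)
  p <- (2 / (fs * n)) * Mod(X[2:(nf + 1L)])^2
  if (n %% 2 == 0) p[nf] <- p[nf] / 2  # Nyquist bin is not doubled
  list(frequency = (1:nf) * fs / n, power = p)
}

# Welch average periodogram: Hann taper, segment length windowS seconds,
# consecutive segments overlap by overlapS seconds.  Density scaling so a
# white-noise input of variance v gives ~ v / (fs/2) per Hz.
welchPSD <- function(x, fs, windowS = 4, overlapS = 0.25) {
  L <- round(windowS * fs)
  if (L < 2) stop("window too short", call. = FALSE)
  if (length(x) < L) {
    warning("segment shorter than one window; zero-padding a single window")
    x <- c(x - mean(x), numeric(L - length(x)))
  }
  step <- max(1L, L - round(overlapS * fs))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- hannWindow(L)
  U <- sum(w^2)
  nf <- floor(L / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- Mod(stats::fft(seg)[2:(nf + 1L)])^2
    acc <- acc + X
  }
  p <- (2 / (fs * U)) * acc / length(starts)
  if (L %% 2 == 0) p[nf] <- p[nf] / 2
  list(frequency = (1:nf) * fs / L, power = p)
}

hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Tapered-cosine (Tukey) window; taper = total fraction of the window
# spent in the raised-cosine ramps (taper/2 on each side).
tukeyWindow <- function(n, taper = 0.25) {
  if (taper <= 0) return(rep(1, n))
  if (taper >= 1) return(hannWindow(n))
  u <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- u < taper / 2
  hi <- u > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / taper - 1)))
  w
}

# Sine-taper multitaper PSD (K orthogonal sine tapers; the K = 2*NW - 1
# convention mirrors a time-bandwidth product NW).  Density scaling.
multitaperPSD <- function(x, fs, nw = 4) {
  n <- length(x)
  k <- max(1L, 2L * nw - 1L)
  x <- x - mean(x)
  nf <- floor(n / 2)
  acc <- numeric(nf)
  idx <- 1:n
  for (j in 1:k) {
    taper <- sqrt(2 / (n + 1)) * sin(pi * j * idx / (n + 1))
    X <- Mod(stats::fft(x * taper)[2:(nf + 1L)])^2
    acc <- acc + X
  }
  p <- (2 / fs) * acc / k
  if (n %% 2 == 0) p[nf] <- p[nf] / 2
  list(frequency = (1:nf) * fs / n, power = p)
}

# Zero-phase Butterworth band-pass; order is the design-prototype order
# (filtfilt doubles the effective order).
butterBandpass <- function(x, fs, low, high, order = 3) {
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  }
  b <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

butterLowpass <- function(x, fs, cutoff, order = 3) {
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    stop("invalid cutoff: need 0 < cutoff < fs/2", call. = FALSE)
  }
  b <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(b, x))
}

butterNotch <- function(x, fs, notch, halfWidth = 1, order = 2) {
  b <- signal::butter(order, c(notch - halfWidth, notch + halfWidth) / (fs / 2),
                      type = "stop")
  as.numeric(signal::filtfilt(b, x))
}

# Union of possibly overlapping [start, end) intervals, sorted.
mergeIntervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outS <- numeric(); outE <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outS <- c(outS, ms); outE <- c(outE, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start_s = c(outS, ms), end_s = c(outE, me))
}

# Maximal runs where a logical vector is TRUE; returns sample indices.
logicalRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Centered moving average with edge shrinkage.
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  # fill edges with partial-window means
  half <- width %/% 2
  n <- length(x)
  for (i in which(is.na(y))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    y[i] <- mean(x[lo:hi])
  }
  as.numeric(y)
}

# von Mises sampler (Best & Fisher 1979); mu in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}
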