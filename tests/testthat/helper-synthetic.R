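# Shared fixtures, all generated in code.

# Constant-envelope cosine burst centered at tPeakS (exact threshold
# crossing times, unlike a tapered event).
injectBurst <- function(x, fs, tPeakS, freqHz, durMs, amp) {
  n <- round(durMs / 1000 * fs)
  i0 <- round(tPeakS * fs) - n %/% 2 + 1L
  idx <- i0:(i0 + n - 1L)
  x[idx] <- x[idx] + amp * cos(2 * pi * freqHz * (0:(n - 1)) / fs)
  x
}

# Add tapered synthetic events (the generator's waveform) at given peak
# times; returns the signal.
addEvents <- function(x, fs, kind, peaksS, freqHz, durMs, amp,
                      regime = "chronic") {
  durMs <- rep(durMs, length.out = length(peaksS))
  for (i in seq_along(peaksS)) {
    ev <- synthEvent(eventSpec(kind, freqHz, durMs[i], amp, peaksS[i],
                               regime = regime), fs)
    i0 <- round((peaksS[i] - ev$peakS) * fs) + 1L
    idx <- i0:(i0 + length(ev$wave) - 1L)
    keep <- idx >= 1 & idx <= length(x)
    x[idx[keep]] <- x[idx[keep]] + ev$wave[keep]
  }
  x
}

# One-to-one nearest matching of detected peaks to truth peaks.
matchPeaks <- function(detPeaksS, truthPeaksS, tolS = 0.075) {
  vapply(truthPeaksS, function(t) {
    if (!length(detPeaksS)) return(NA_integer_)
    j <- which.min(abs(detPeaksS - t))
    if (abs(detPeaksS[j] - t) < tolS) j else NA_integer_
  }, integer(1))
}

circMeanDeg <- function(deg) {
  th <- deg * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}

# Brute-force pair enumeration oracle (inclusive window, ms).
brutePairCount <- function(leadPeaks, trailPeaks, winMs) {
  dt <- outer(leadPeaks, trailPeaks, function(a, b) (b - a) * 1000)
  sum(dt >= winMs[1] & dt <= winMs[2])
}
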