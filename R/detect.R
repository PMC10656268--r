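# Oscillation event detectors: hippocampal ripples (NonREM, quiet wake,
# anesthesia), cortical spindles and delta waves.  All detectors threshold
# the instantaneous envelope (modulus of the analytic signal) of the
# band-passed trace, which stabilizes duration estimates relative to
# thresholding the raw rectified trace.

#' Regime detection defaults
#'
#' Returns the per-regime ripple detection configuration: band, SD
#' multiplier, offset, minimum duration, closeness (merge) threshold and
#' boundary fraction.  Chronic: 100-300 Hz, 20 ms minimum, 20 ms
#' closeness; acute: 90-200 Hz, 50 ms minimum, 80 ms closeness.  Both use
#' a 5 SD multiplier; the chronic threshold adds a 5 uV offset to reduce
#' false positives.
#'
#' @param regime `"chronic"` or `"acute"`.
#' @return list of class `"DetectionConfig"`.
#' @export
detectionConfig <- function(regime = c("chronic", "acute")) {
  regime <- match.arg(regime)
  cfg <- if (regime == "chronic") {
    list(band = c(100, 300), sdMultiplier = 5, offsetUv = 5,
         minDurationMs = 20, closenessMs = 20, boundaryFraction = 0.5)
  } else {
    list(band = c(90, 200), sdMultiplier = 5, offsetUv = 0,
         minDurationMs = 50, closenessMs = 80, boundaryFraction = 0.5)
  }
  cfg$regime <- regime
  structure(cfg, class = "DetectionConfig")
}

#' Study-day ripple detection threshold
#'
#' Computes, per trial period, the standard deviation of the concatenated
#' band-passed NonREM signal times `sdMultiplier`; averages the per-period
#' values into a single study-day threshold; and adds `offsetUv`.  Only
#' periods contributing more than `minNremS` seconds of NonREM qualify.
#'
#' @param periods list of numeric vectors: the band-passed concatenated
#'   NonREM signal of each pre-/post-trial sleep period.
#' @param fs sampling rate, Hz.
#' @param sdMultiplier SD multiplier (default 5).
#' @param offsetUv additive offset in uV (default 5).
#' @param minNremS minimum NonREM seconds a period must contribute
#'   (default 180 s, i.e. 3 min).
#' @return detection threshold in uV.
#' @examples
#' # two periods with sample SDs 10 and 12 uV -> (5*10 + 5*12)/2 + 5 = 60
#' @export
rippleThreshold <- function(periods, fs, sdMultiplier = 5, offsetUv = 5,
                            minNremS = 180) {
  keep <- vapply(periods, function(p) length(p) > minNremS * fs, logical(1))
  if (!any(keep)) {
    stop("no trial period contributes more than ", minNremS,
         " s of NonREM; no threshold can be computed", call. = FALSE)
  }
  sds <- vapply(periods[keep], stats::sd, numeric(1))
  mean(sds * sdMultiplier) + offsetUv
}

emptyEvents <- function() {
  data.frame(kind = character(), context = character(),
             channel_role = character(), start_s = numeric(),
             peak_s = numeric(), end_s = numeric(), duration_ms = numeric(),
             amplitude_uv = numeric(), mean_freq_hz = numeric(),
             length_class = character(), stringsAsFactors = FALSE)
}

eventsFromRuns <- function(runs, env, filtered, fs, kind, context,
                           channelRole, lengthClass = FALSE) {
  if (!nrow(runs)) return(emptyEvents())
  out <- emptyEvents()
  for (i in seq_len(nrow(runs))) {
    i0 <- runs$start[i]; i1 <- runs$end[i]
    pk <- i0 + which.max(env[i0:i1]) - 1L
    tr <- filtered[i0:i1]
    dur <- (i1 - i0 + 1L) / fs * 1000
    out[nrow(out) + 1L, ] <- list(
      kind, context, channelRole, (i0 - 1L) / fs, (pk - 1L) / fs, i1 / fs,
      dur, max(env[i0:i1]), eventMeanFrequency(tr, fs),
      if (lengthClass) (if (dur <= 100) "SHORT" else "LONG") else "NA")
  }
  out
}

mergeCloseRuns <- function(runs, gapSamples) {
  if (nrow(runs) < 2L) return(runs)
  keepS <- runs$start[1]; keepE <- runs$end[1]
  outS <- integer(); outE <- integer()
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - keepE - 1L < gapSamples) {
      keepE <- runs$end[i]
    } else {
      outS <- c(outS, keepS); outE <- c(outE, keepE)
      keepS <- runs$start[i]; keepE <- runs$end[i]
    }
  }
  data.frame(start = c(outS, keepS), end = c(outE, keepE))
}

extendToBoundary <- function(runs, env, bthr) {
  n <- length(env)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    while (s > 1L && env[s - 1L] >= bthr) s <- s - 1L
    e <- runs$end[i]
    while (e < n && env[e + 1L] >= bthr) e <- e + 1L
    runs$start[i] <- s; runs$end[i] <- e
  }
  runs
}

dropMasked <- function(events, mask) {
  if (is.null(mask) || !nrow(mask) || !nrow(events)) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    !any(events$start_s[i] < mask$end_s & events$end_s[i] > mask$start_s)
  }, logical(1))
  events[keep, , drop = FALSE]
}

#' Detect hippocampal ripples in a band-passed trace
#'
#' Candidates are contiguous runs where the envelope of the band-passed
#' signal stays above `threshold` for at least `minDurationMs`.  Runs
#' closer than `closenessMs` are merged into a single event, and event
#' boundaries are then extended outward to the crossings of
#' `boundaryFraction * threshold`.  The event peak is the envelope
#' maximum; ripples are classed `SHORT` (<= 100 ms) or `LONG` (> 100 ms)
#' by their measured duration.  Events overlapping blanked intervals are
#' discarded.
#'
#' @param filtered band-passed (and artifact-blanked) channel, uV.
#'   Chronic: 100-300 Hz over concatenated NonREM bouts; acute: 90-200 Hz
#'   over NonREM-like epochs.
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold, uV (see [rippleThreshold()]).
#' @param minDurationMs minimum suprathreshold duration (chronic 20,
#'   acute 50).
#' @param closenessMs events closer than this are merged (chronic 20,
#'   acute 80).
#' @param boundaryFraction boundary extension threshold as a fraction of
#'   `threshold` (default 0.5).
#' @param mask optional data.frame (`start_s`, `end_s`) of blanked
#'   intervals.
#' @param context event context label (default `"NREM"`).
#' @param channelRole channel role label (default `"HPC"`).
#' @param band optional detection band `c(low, high)`; when provided, the
#'   trace is probed and a warning is raised if less than half of its
#'   power lies in the band (input looks unfiltered).
#' @return data.frame of events (`kind, context, channel_role, start_s,
#'   peak_s, end_s, duration_ms, amplitude_uv, mean_freq_hz,
#'   length_class`).
#' @export
detectRipples <- function(filtered, fs, threshold, minDurationMs = 20,
                          closenessMs = 20, boundaryFraction = 0.5,
                          mask = NULL, context = "NREM",
                          channelRole = "HPC", band = NULL) {
  if (!is.null(band)) {
    probe <- periodogramPSD(filtered, fs)
    inband <- probe$frequency >= band[1] & probe$frequency <= band[2]
    frac <- sum(probe$power[inband]) / sum(probe$power)
    if (is.finite(frac) && frac < 0.5) {
      warning("less than half of the signal power lies in the detection ",
              "band; input may be unfiltered")
    }
  }
  env <- Mod(analyticSignal(filtered))
  runs <- logicalRuns(env > threshold)
  if (nrow(runs)) {
    runs <- runs[(runs$end - runs$start + 1L) >= round(minDurationMs / 1000 * fs), ,
                 drop = FALSE]
  }
  if (!nrow(runs)) return(emptyEvents())
  runs <- mergeCloseRuns(runs, round(closenessMs / 1000 * fs))
  runs <- extendToBoundary(runs, env, boundaryFraction * threshold)
  ev <- eventsFromRuns(runs, env, filtered, fs, "RIPPLE", context,
                       channelRole, lengthClass = TRUE)
  dropMasked(ev, mask)
}

#' Detect ripples during quiet wakefulness
#'
#' Runs [detectRipples()] restricted to wake-labeled bouts, then vetoes
#' candidate events during movement (accelerometer resultant above
#' threshold), locomotion theta (5-10 Hz power above threshold) or
#' high-amplitude artifacts.
#'
#' @param filtered band-passed full-length HPC channel, uV.
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold, uV.
#' @param wakeBouts data.frame (`start_s`, `end_s`) of wake intervals.
#' @param acc optional 3-column matrix of accelerometer channels at `fs`;
#'   when missing, detection proceeds with a warning and no movement veto.
#' @param accThreshold movement veto threshold on the resultant magnitude;
#'   default mean + 2 SD of `accBaseline` (or of the whole resultant).
#' @param accBaseline optional accelerometer resultant from sleep periods
#'   used to calibrate `accThreshold`.
#' @param thetaPower optional data.frame (`start_s`, `end_s`, `power`) of
#'   windowed 5-10 Hz theta power; events whose peak falls in a window
#'   with `power > thetaThreshold` are vetoed.
#' @param thetaThreshold theta veto threshold; default 2x the median of
#'   `thetaPower$power`.
#' @param artifactAmplitudeUv events with envelope amplitude above this
#'   are vetoed as artifacts (default `10 * threshold`).
#' @param config a [detectionConfig()] supplying the duration/merge
#'   parameters (default chronic).
#' @return event data.frame with `context = "QUIET_WAKE"`.
#' @export
detectQuietWakeRipples <- function(filtered, fs, threshold, wakeBouts,
                                   acc = NULL, accThreshold = NULL,
                                   accBaseline = NULL, thetaPower = NULL,
                                   thetaThreshold = NULL,
                                   artifactAmplitudeUv = 10 * threshold,
                                   config = detectionConfig("chronic")) {
  res <- NULL
  if (is.null(acc)) {
    warning("no accelerometer channels supplied; movement veto disabled")
  } else {
    res <- sqrt(rowSums(acc^2))
    if (is.null(accThreshold)) {
      base <- if (is.null(accBaseline)) res else accBaseline
      accThreshold <- mean(base) + 2 * stats::sd(base)
    }
  }
  if (!is.null(thetaPower) && is.null(thetaThreshold)) {
    thetaThreshold <- 2 * stats::median(thetaPower$power)
  }
  out <- emptyEvents()
  for (i in seq_len(nrow(wakeBouts))) {
    i0 <- round(wakeBouts$start_s[i] * fs) + 1L
    i1 <- min(length(filtered), round(wakeBouts$end_s[i] * fs))
    if (i1 - i0 < round(config$minDurationMs / 1000 * fs)) next
    ev <- detectRipples(filtered[i0:i1], fs, threshold,
                        config$minDurationMs, config$closenessMs,
                        config$boundaryFraction, context = "QUIET_WAKE")
    if (!nrow(ev)) next
    shift <- (i0 - 1L) / fs
    ev$start_s <- ev$start_s + shift
    ev$peak_s <- ev$peak_s + shift
    ev$end_s <- ev$end_s + shift
    out <- rbind(out, ev)
  }
  if (!nrow(out)) return(out)
  keep <- rep(TRUE, nrow(out))
  for (j in seq_len(nrow(out))) {
    w0 <- round(out$start_s[j] * fs) + 1L
    w1 <- min(round(out$end_s[j] * fs), length(filtered))
    if (!is.null(res) && mean(res[w0:w1]) > accThreshold) keep[j] <- FALSE
    if (keep[j] && !is.null(thetaPower)) {
      hit <- thetaPower$power[out$peak_s[j] >= thetaPower$start_s &
                                out$peak_s[j] < thetaPower$end_s]
      if (length(hit) && any(hit > thetaThreshold)) keep[j] <- FALSE
    }
    if (keep[j] && out$amplitude_uv[j] > artifactAmplitudeUv) keep[j] <- FALSE
  }
  out[keep, , drop = FALSE]
}

#' Detect cortical sleep spindles
#'
#' The envelope of the 9-20 Hz band-passed trace, smoothed over
#' `smoothMs`, must exceed `lowMult` envelope SDs for 0.4-3.0 s and exceed
#' `highMult` SDs at least once.  Start/end are the low-threshold
#' crossings; runs separated by less than `mergeGapMs` are merged before
#' the duration test.
#'
#' @param filtered 9-20 Hz band-passed PFC channel (concatenated NonREM),
#'   uV.
#' @param fs sampling rate, Hz.
#' @param lowMult low threshold in envelope SDs (default 2.5).
#' @param highMult high threshold in envelope SDs (default 5).
#' @param minDurS,maxDurS admissible duration range, s (0.4-3.0).
#' @param mergeGapMs merge gap, ms (default 100).
#' @param smoothMs envelope smoothing window, ms (default 100).
#' @param mask optional blanked intervals to exclude.
#' @return event data.frame (`kind = "SPINDLE"`).
#' @export
detectSpindles <- function(filtered, fs, lowMult = 2.5, highMult = 5,
                           minDurS = 0.4, maxDurS = 3.0, mergeGapMs = 100,
                           smoothMs = 100, mask = NULL) {
  env <- movingAverage(Mod(analyticSignal(filtered)),
                       round(smoothMs / 1000 * fs))
  sdE <- stats::sd(env)
  lowThr <- lowMult * sdE
  highThr <- highMult * sdE
  runs <- logicalRuns(env > lowThr)
  if (!nrow(runs)) return(emptyEvents())
  runs <- mergeCloseRuns(runs, round(mergeGapMs / 1000 * fs))
  dur <- (runs$end - runs$start + 1L) / fs
  hasHigh <- vapply(seq_len(nrow(runs)), function(i) {
    max(env[runs$start[i]:runs$end[i]]) >= highThr
  }, logical(1))
  runs <- runs[dur >= minDurS & dur <= maxDurS & hasHigh, , drop = FALSE]
  ev <- eventsFromRuns(runs, env, filtered, fs, "SPINDLE", "NREM", "PFC")
  dropMasked(ev, mask)
}

#' Detect cortical delta waves
#'
#' Scans the 1-6 Hz band-passed trace for upward zero-crossing segments
#' whose positive peak exceeds `peakMult` SDs of the filtered signal and
#' is followed, within the wave (before the next upward crossing), by a
#' trough below `-troughMult` SDs.  Start/end are the flanking upward
#' zero-crossings; the wave duration must lie within
#' `[minDurMs, maxDurMs]`.  The event peak is the positive-peak time.
#'
#' @param filtered 1-6 Hz band-passed PFC channel (concatenated NonREM),
#'   uV.
#' @param fs sampling rate, Hz.
#' @param peakMult positive-peak threshold in filtered-signal SDs
#'   (default 2).
#' @param troughMult trough threshold in SDs (default 1.5).
#' @param minDurMs,maxDurMs admissible wave duration, ms (100-1000).
#' @param mask optional blanked intervals to exclude.
#' @return event data.frame (`kind = "DELTA"`).
#' @export
detectDeltaWaves <- function(filtered, fs, peakMult = 2, troughMult = 1.5,
                             minDurMs = 100, maxDurMs = 1000, mask = NULL) {
  sdF <- stats::sd(filtered)
  up <- which(filtered[-length(filtered)] <= 0 & filtered[-1L] > 0) + 1L
  if (length(up) < 2L) return(emptyEvents())
  out <- emptyEvents()
  for (i in seq_len(length(up) - 1L)) {
    i0 <- up[i]; i1 <- up[i + 1L] - 1L
    durMs <- (i1 - i0 + 1L) / fs * 1000
    if (durMs < minDurMs || durMs > maxDurMs) next
    seg <- filtered[i0:i1]
    pkRel <- which.max(seg)
    if (seg[pkRel] <= peakMult * sdF) next
    if (min(seg[pkRel:length(seg)]) >= -troughMult * sdF) next
    pk <- i0 + pkRel - 1L
    out[nrow(out) + 1L, ] <- list(
      "DELTA", "NREM", "PFC", (i0 - 1L) / fs, (pk - 1L) / fs, i1 / fs,
      durMs, seg[pkRel], eventMeanFrequency(seg, fs), "NA")
  }
  dropMasked(out, mask)
}
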