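# Ground-truthed synthetic LFP generator.
#
# Every downstream stage (preprocessing, state scoring, event detection,
# coupling, spectral parameterization) is exercised against recordings
# produced here, where event times, amplitudes, state labels, aperiodic
# parameters and slow-oscillation phases are known exactly.

RIPPLE_BAND_CHRONIC <- c(100, 300)
RIPPLE_BAND_ACUTE <- c(90, 200)
SPINDLE_BAND <- c(9, 20)
DELTA_BAND <- c(1, 6)
SO_BAND <- c(0.5, 4)

#' Specification of one synthetic oscillation event
#'
#' @param kind `"ripple"`, `"spindle"` or `"delta"`.
#' @param centerFrequencyHz carrier frequency in Hz.  Must lie in the
#'   detection band of the kind: ripples 100-300 Hz (chronic regime) or
#'   90-200 Hz (acute), spindles 9-20 Hz, delta waves 1-6 Hz.
#' @param durationMs event duration in ms.
#' @param amplitudeUv envelope peak in microvolts.
#' @param time either a time in seconds for the envelope peak, or a state
#'   label (e.g. `"NREM"`) meaning "place at a random time within that
#'   state".
#' @param channelRole `"HPC"` or `"PFC"`.
#' @param regime `"chronic"` or `"acute"` (controls the admissible ripple
#'   band).
#' @return a list of class `"EventSpec"`.
#' @export
eventSpec <- function(kind = c("ripple", "spindle", "delta"),
                      centerFrequencyHz, durationMs, amplitudeUv,
                      time, channelRole = c("HPC", "PFC"),
                      regime = c("chronic", "acute")) {
  kind <- match.arg(kind)
  channelRole <- match.arg(channelRole)
  regime <- match.arg(regime)
  band <- switch(kind,
    ripple = if (regime == "chronic") RIPPLE_BAND_CHRONIC else RIPPLE_BAND_ACUTE,
    spindle = SPINDLE_BAND,
    delta = DELTA_BAND)
  if (centerFrequencyHz < band[1] || centerFrequencyHz > band[2]) {
    stop(sprintf("%s frequency %g Hz outside admissible band [%g, %g] Hz",
                 kind, centerFrequencyHz, band[1], band[2]), call. = FALSE)
  }
  if (durationMs <= 0) stop("durationMs must be positive", call. = FALSE)
  if (amplitudeUv <= 0) stop("amplitudeUv must be positive", call. = FALSE)
  structure(list(kind = kind, centerFrequencyHz = centerFrequencyHz,
                 durationMs = durationMs, amplitudeUv = amplitudeUv,
                 time = time, channelRole = channelRole, regime = regime),
            class = "EventSpec")
}

defaultEventParams <- function(kind, regime = "chronic") {
  switch(kind,
    ripple = list(centerFrequencyHz = if (regime == "chronic") 150 else 120,
                  durationMs = 60, amplitudeUv = 100),
    spindle = list(centerFrequencyHz = 14, durationMs = 800, amplitudeUv = 80),
    delta = list(centerFrequencyHz = 2.5, durationMs = 400, amplitudeUv = 300),
    stop("unknown kind: ", kind))
}

#' Simulation configuration
#'
#' Collects everything [generateRecording()] needs: recording geometry,
#' aperiodic background parameters, the state schedule, explicit event
#' specifications, cross-region coupling requests, slow-oscillation phase
#' targeting, artifact injection, and the RNG seed.
#'
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param aperiodicExponent spectral exponent chi of the 1/f^chi background.
#' @param aperiodicOffset log10 power density (uV^2/Hz) at 1 Hz.
#' @param stateSchedule data.frame with columns `state`, `duration` (s);
#'   durations must sum to `duration`.  Chronic states are
#'   WAKE/NREM/INTERMEDIATE/REM; acute states NREM_LIKE/REM_LIKE.
#' @param eventSpecs list of [eventSpec()] objects.
#' @param couplingSpecs list of lists with elements `lead`, `trail`
#'   (event kinds), `lagMs`, `jitterMs`, `count`: `count` lead events are
#'   placed in NREM and each trailing event peak follows its lead peak by
#'   `lagMs` + U(-jitterMs, jitterMs).
#' @param phaseSpec optional list `soFrequencyHz`, `targetPhaseDeg` in
#'   \[0, 360), `concentration` (von Mises kappa), `count`,
#'   and optionally `rippleAmplitudeUv`, `soAmplitudeUv`: a coherent slow
#'   oscillation is placed on PFC during NREM and `count` ripples are
#'   injected on HPC at slow-oscillation phases drawn around the target
#'   (phase 0 deg = slow-oscillation peak).
#' @param artifactSpec optional list `count`, `amplitudeUv`, `durationS`:
#'   high-amplitude square excursions added to both LFP channels.
#' @param epochS hypnogram epoch length in seconds (1 chronic, 10 acute).
#' @param regime `"chronic"` or `"acute"`.
#' @param soAmplitudeUv slow-oscillation amplitude added on PFC during
#'   NREM segments.
#' @param thetaAmplitudeUv theta amplitude added on HPC during REM
#'   segments.
#' @param channels channel roles to synthesize.
#' @param seed integer RNG seed; all draws come from one stream.
#' @return a list of class `"SimConfig"`.
#' @export
simConfig <- function(duration, fs,
                      aperiodicExponent = 1.5, aperiodicOffset = 2.5,
                      stateSchedule = data.frame(state = "NREM",
                                                 duration = duration),
                      eventSpecs = list(), couplingSpecs = list(),
                      phaseSpec = NULL, artifactSpec = NULL,
                      epochS = if (regime == "chronic") 1 else 10,
                      regime = c("chronic", "acute"),
                      soAmplitudeUv = 150, thetaAmplitudeUv = 60,
                      channels = c("HPC", "PFC", "ACC_X", "ACC_Y", "ACC_Z"),
                      seed = 1L) {
  regime <- match.arg(regime)
  if (duration <= 0 || fs <= 0) {
    stop("duration and fs must be positive", call. = FALSE)
  }
  if (abs(sum(stateSchedule$duration) - duration) > 1e-9) {
    stop("state schedule durations must sum to the recording duration",
         call. = FALSE)
  }
  if (!is.null(phaseSpec)) {
    if (phaseSpec$targetPhaseDeg < 0 || phaseSpec$targetPhaseDeg >= 360) {
      stop("targetPhaseDeg must lie in [0, 360)", call. = FALSE)
    }
  }
  structure(list(duration = duration, fs = fs,
                 aperiodicExponent = aperiodicExponent,
                 aperiodicOffset = aperiodicOffset,
                 stateSchedule = stateSchedule, eventSpecs = eventSpecs,
                 couplingSpecs = couplingSpecs, phaseSpec = phaseSpec,
                 artifactSpec = artifactSpec, epochS = epochS,
                 regime = regime, soAmplitudeUv = soAmplitudeUv,
                 thetaAmplitudeUv = thetaAmplitudeUv,
                 channels = channels, seed = as.integer(seed)),
            class = "SimConfig")
}

# Core spectral-shaping synthesis using the current RNG stream.
# Target one-sided PSD: P(f) = 10^offset / f^exponent, optionally times
# 10^g(f) for Gaussian peaks (list of c(center, height, width); width is
# twice the Gaussian sd, matching the aperiodic-fit convention).
backgroundCore <- function(n, fs, exponent, offset, peaks = NULL) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  logP <- offset - exponent * log10(f)
  if (!is.null(peaks)) {
    for (pk in peaks) {
      logP <- logP + pk[2] * exp(-(f - pk[1])^2 / (2 * (pk[3] / 2)^2))
    }
  }
  P <- 10^logP
  X <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) *
    sqrt(P * fs * n / 4)
  if (n %% 2 == 0) {
    # Nyquist coefficient must be real
    X[nf] <- stats::rnorm(1) * sqrt(P[nf] * fs * n / 2)
    full <- c(0 + 0i, X, Conj(rev(X[-nf])))
  } else {
    full <- c(0 + 0i, X, Conj(rev(X)))
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Generate aperiodic (1/f^chi) background noise
#'
#' Synthesizes a zero-mean signal whose one-sided power spectral density is
#' `10^offset / f^exponent` (uV^2/Hz), by shaping white Gaussian Fourier
#' coefficients bin-by-bin and inverse transforming.  The log10-log10
#' periodogram therefore has slope `-exponent` and intercept `offset` in
#' expectation at every frequency.
#'
#' @param duration seconds; `duration * fs` must be at least 2 samples.
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent chi (0 = white noise).
#' @param offset log10 power density at 1 Hz.
#' @param seed optional integer; when given, seeds the RNG so the output is
#'   fully reproducible.
#' @param peaks optional list of `c(centerHz, height, widthHz)` Gaussian
#'   bumps added to the log10 spectrum (width = 2 Gaussian sd), used to
#'   emulate oscillatory peaks riding on the aperiodic component.
#' @return numeric vector of `round(duration * fs)` samples (uV).
#' @examples
#' x <- generateBackground(10, 500, exponent = 1, offset = 2, seed = 1)
#' @export
generateBackground <- function(duration, fs, exponent, offset, seed = NULL,
                               peaks = NULL) {
  if (duration <= 0 || fs <= 0) {
    stop("duration and fs must be positive", call. = FALSE)
  }
  n <- round(duration * fs)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  backgroundCore(n, fs, exponent, offset, peaks)
}

#' Synthesize one oscillation event waveform
#'
#' The waveform is a sinusoid at the spec's center frequency under a
#' smooth unimodal envelope peaking at the event midpoint.  The default
#' envelope is a tapered cosine (Tukey) window with a flat central plateau,
#' so that threshold-crossing durations measured by the detectors agree
#' with the nominal event duration; a Hann envelope is also available.
#'
#' @param spec an [eventSpec()].
#' @param fs sampling rate, Hz; must exceed twice the carrier frequency.
#' @param envelope `"tukey"` (default) or `"hann"`.
#' @param taper taper fraction for the Tukey envelope.
#' @return list with `wave` (numeric vector), `peakS` (offset of the
#'   envelope peak from waveform start, s), and `durationS`.
#' @export
synthEvent <- function(spec, fs, envelope = c("tukey", "hann"),
                       taper = 0.25) {
  envelope <- match.arg(envelope)
  if (spec$centerFrequencyHz >= fs / 2) {
    stop("center frequency must be below the Nyquist frequency",
         call. = FALSE)
  }
  n <- max(2L, round(spec$durationMs / 1000 * fs))
  env <- if (envelope == "tukey") tukeyWindow(n, taper) else hannWindow(n)
  tc <- (n - 1) / 2 / fs
  t <- (0:(n - 1)) / fs
  carrier <- if (spec$kind == "delta") {
    # one positive lobe then a trough: canonical cortical delta shape
    sin(2 * pi * spec$centerFrequencyHz * t)
  } else {
    cos(2 * pi * spec$centerFrequencyHz * (t - tc))
  }
  list(wave = spec$amplitudeUv * env * carrier, peakS = tc,
       durationS = (n - 1) / fs)
}

# Sample k peak times uniformly within intervals, keeping a minimum
# separation from previously accepted times and a half-duration margin
# from the interval edges.  Returns numeric vector (may be shorter than k
# if placement fails repeatedly).
samplePeakTimes <- function(intervals, k, halfDurS, minSepS = 0.25,
                            existing = numeric(), maxTries = 2000L) {
  lo <- intervals$start_s + halfDurS
  hi <- intervals$end_s - halfDurS
  ok <- hi > lo
  lo <- lo[ok]; hi <- hi[ok]
  if (!length(lo)) return(numeric())
  len <- hi - lo
  out <- numeric()
  tries <- 0L
  while (length(out) < k && tries < maxTries) {
    tries <- tries + 1L
    seg <- sample.int(length(lo), 1L, prob = len)
    t <- stats::runif(1, lo[seg], hi[seg])
    if (!length(existing) || min(abs(existing - t)) >= minSepS) {
      out <- c(out, t)
      existing <- c(existing, t)
    }
  }
  out
}

rampedSegmentAdd <- function(x, fs, startS, endS, wave) {
  i0 <- max(1L, round(startS * fs) + 1L)
  i1 <- min(length(x), round(endS * fs))
  if (i1 <= i0) return(x)
  n <- i1 - i0 + 1L
  ramp <- rep(1, n)
  nr <- min(n %/% 2, round(0.25 * fs))
  if (nr > 1) {
    up <- 0.5 * (1 - cos(pi * (1:nr) / nr))
    ramp[1:nr] <- up
    ramp[(n - nr + 1L):n] <- rev(up)
  }
  x[i0:i1] <- x[i0:i1] + wave[1:n] * ramp
  x
}

#' Generate a full synthetic recording with ground truth
#'
#' Builds a multi-channel [SignalBundle-class] according to a
#' [simConfig()]: 1/f^chi backgrounds on the LFP channels, state-dependent
#' rhythms (slow oscillation on PFC during NonREM, theta on HPC during
#' REM), embedded oscillation events, cross-region coupled event pairs at
#' controlled lags, ripples locked to a slow-oscillation phase,
#' high-amplitude artifacts, and accelerometer channels whose variance is
#' elevated only during wake and artifact segments.
#'
#' @param config a [simConfig()].
#' @return list with elements `bundle` (the [SignalBundle-class]) and
#'   `truth`, a list with `events` (data.frame sorted by start time:
#'   `id, kind, channel_role, start_s, peak_s, end_s, amplitude_uv,
#'   frequency_hz`), `hypnogram` ([Hypnogram-class]), `aperiodic`
#'   (`c(offset, exponent)`), `coupledTuples` (list of event-id vectors),
#'   `eventPhases` (data.frame `event_id, phase_deg`) and `artifacts`
#'   (data.frame of injected artifact intervals).
#' @export
generateRecording <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  roles <- config$channels
  sched <- config$stateSchedule
  sched$end_s <- cumsum(sched$duration)
  sched$start_s <- sched$end_s - sched$duration

  lfp <- list()
  for (r in intersect(c("HPC", "PFC"), roles)) {
    lfp[[r]] <- backgroundCore(n, fs, config$aperiodicExponent,
                               config$aperiodicOffset)
  }

  thetaFreq <- if (config$regime == "chronic") 7 else 4.5
  soFreq <- if (!is.null(config$phaseSpec)) config$phaseSpec$soFrequencyHz else 1
  soAmp <- if (!is.null(config$phaseSpec) &&
               !is.null(config$phaseSpec$soAmplitudeUv)) {
    config$phaseSpec$soAmplitudeUv
  } else config$soAmplitudeUv

  # State-dependent rhythms.  With a phase spec the NREM slow oscillation
  # is one globally coherent cosine so event phases are exact.
  for (i in seq_len(nrow(sched))) {
    st <- sched$state[i]
    s0 <- sched$start_s[i]; s1 <- sched$end_s[i]
    ns <- round((s1 - s0) * fs) + 1L
    tt <- (0:(ns - 1)) / fs
    if (st %in% c("REM", "REM_LIKE") && "HPC" %in% names(lfp)) {
      w <- config$thetaAmplitudeUv *
        cos(2 * pi * thetaFreq * tt + stats::runif(1, 0, 2 * pi))
      lfp$HPC <- rampedSegmentAdd(lfp$HPC, fs, s0, s1, w)
    }
    if (st %in% c("NREM", "NREM_LIKE") && "PFC" %in% names(lfp)) {
      phase0 <- if (!is.null(config$phaseSpec)) {
        2 * pi * soFreq * s0   # continue the global cosine cos(2 pi f t)
      } else stats::runif(1, 0, 2 * pi)
      w <- soAmp * cos(2 * pi * soFreq * tt + phase0)
      lfp$PFC <- rampedSegmentAdd(lfp$PFC, fs, s0, s1, w)
    }
  }

  events <- data.frame(kind = character(), channel_role = character(),
                       start_s = numeric(), peak_s = numeric(),
                       end_s = numeric(), amplitude_uv = numeric(),
                       frequency_hz = numeric())
  coupledTuples <- list()
  eventPhases <- data.frame(event_id = integer(), phase_deg = numeric())

  addEvent <- function(spec, peakTimeS) {
    ev <- synthEvent(spec, fs)
    startS <- peakTimeS - ev$peakS
    i0 <- round(startS * fs) + 1L
    idx <- i0:(i0 + length(ev$wave) - 1L)
    keep <- idx >= 1L & idx <= n
    if (!any(keep)) return(invisible(NULL))
    ch <- spec$channelRole
    lfp[[ch]][idx[keep]] <<- lfp[[ch]][idx[keep]] + ev$wave[keep]
    events[nrow(events) + 1L, ] <<- list(spec$kind, ch, startS,
                                         startS + ev$peakS,
                                         startS + ev$durationS,
                                         spec$amplitudeUv,
                                         spec$centerFrequencyHz)
    nrow(events)
  }

  stateIv <- function(state) {
    data.frame(start_s = sched$start_s[sched$state == state],
               end_s = sched$end_s[sched$state == state])
  }

  # Explicit event specs
  explicitTimes <- data.frame(kind = character(), t = numeric())
  for (spec in config$eventSpecs) {
    halfDur <- spec$durationMs / 2000
    if (is.character(spec$time)) {
      iv <- stateIv(spec$time)
      if (!nrow(iv)) {
        warning("no '", spec$time, "' segments to place a ", spec$kind,
                " event in; skipped")
        next
      }
      same <- events$peak_s[events$kind == spec$kind &
                              events$channel_role == spec$channelRole]
      t <- samplePeakTimes(iv, 1L, halfDur, existing = same)
      if (!length(t)) {
        warning("could not place a ", spec$kind, " event; skipped")
        next
      }
    } else {
      t <- spec$time
      if (any(explicitTimes$kind == spec$kind & explicitTimes$t == t)) {
        warning("overlapping identical-kind events requested at identical ",
                "times; both recorded in the ground truth")
      }
      explicitTimes[nrow(explicitTimes) + 1L, ] <- list(spec$kind, t)
    }
    addEvent(spec, t)
  }

  # Coupled pairs: lead placed in NREM, trail at lead peak + lag + jitter
  nremState <- if (config$regime == "chronic") "NREM" else "NREM_LIKE"
  for (cs in config$couplingSpecs) {
    iv <- stateIv(nremState)
    leadPar <- defaultEventParams(cs$lead, config$regime)
    trailPar <- defaultEventParams(cs$trail, config$regime)
    if (!is.null(cs$amplitudeUv)) {
      leadPar$amplitudeUv <- trailPar$amplitudeUv <- cs$amplitudeUv
    }
    pad <- (leadPar$durationMs + trailPar$durationMs) / 2000 +
      (cs$lagMs + cs$jitterMs) / 1000
    same <- events$peak_s[events$kind == cs$lead]
    leads <- samplePeakTimes(iv, cs$count, pad,
                             minSepS = 2 * pad + 0.25, existing = same)
    roleFor <- function(kind) if (kind == "ripple") "HPC" else "PFC"
    for (tl in leads) {
      lag <- (cs$lagMs + stats::runif(1, -cs$jitterMs, cs$jitterMs)) / 1000
      leadSpec <- eventSpec(cs$lead, leadPar$centerFrequencyHz,
                            leadPar$durationMs, leadPar$amplitudeUv,
                            time = tl, channelRole = roleFor(cs$lead),
                            regime = config$regime)
      trailSpec <- eventSpec(cs$trail, trailPar$centerFrequencyHz,
                             trailPar$durationMs, trailPar$amplitudeUv,
                             time = tl + lag,
                             channelRole = roleFor(cs$trail),
                             regime = config$regime)
      i1 <- addEvent(leadSpec, tl)
      i2 <- addEvent(trailSpec, tl + lag)
      if (!is.null(i1) && !is.null(i2)) {
        coupledTuples[[length(coupledTuples) + 1L]] <- c(i1, i2)
      }
    }
  }

  # Phase-locked ripples on the coherent NREM slow oscillation
  if (!is.null(config$phaseSpec)) {
    ps <- config$phaseSpec
    rp <- defaultEventParams("ripple", config$regime)
    if (!is.null(ps$rippleAmplitudeUv)) rp$amplitudeUv <- ps$rippleAmplitudeUv
    if (!is.null(ps$rippleDurationMs)) rp$durationMs <- ps$rippleDurationMs
    iv <- stateIv(nremState)
    halfDur <- rp$durationMs / 2000
    phases <- rvonmises(ps$count, ps$targetPhaseDeg * pi / 180,
                        ps$concentration)
    # phase convention: 0 deg at the slow-oscillation peak, so for
    # so(t) = A cos(2 pi f t) the instantaneous phase is (2 pi f t) mod 2pi
    placed <- numeric()
    cyc0 <- ceiling(iv$start_s * soFreq)
    cyc1 <- floor(iv$end_s * soFreq) - 1L
    for (ph in phases) {
      ok <- which(cyc1 >= cyc0)
      if (!length(ok)) next
      t <- NA_real_
      for (try in 1:50) {
        seg <- ok[sample.int(length(ok), 1L)]
        k <- sample(cyc0[seg]:cyc1[seg], 1L)
        tc <- (k + ph / (2 * pi)) / soFreq
        if (tc - halfDur < iv$start_s[seg] || tc + halfDur > iv$end_s[seg]) next
        if (length(placed) && min(abs(placed - tc)) < 2 * halfDur) next
        t <- tc
        break
      }
      if (is.na(t)) next
      spec <- eventSpec("ripple", rp$centerFrequencyHz, rp$durationMs,
                        rp$amplitudeUv, time = t, channelRole = "HPC",
                        regime = config$regime)
      id <- addEvent(spec, t)
      if (!is.null(id)) {
        placed <- c(placed, t)
        eventPhases[nrow(eventPhases) + 1L, ] <-
          list(id, (ph * 180 / pi) %% 360)
      }
    }
  }

  # Artifacts: square excursions on both LFP channels
  artifacts <- data.frame(start_s = numeric(), end_s = numeric())
  if (!is.null(config$artifactSpec)) {
    as_ <- config$artifactSpec
    t0 <- sort(stats::runif(as_$count, 0,
                            max(config$duration - as_$durationS, 0)))
    for (t in t0) {
      i0 <- round(t * fs) + 1L
      i1 <- min(n, i0 + round(as_$durationS * fs))
      for (r in names(lfp)) lfp[[r]][i0:i1] <- lfp[[r]][i0:i1] + as_$amplitudeUv
      artifacts[nrow(artifacts) + 1L, ] <- list(t, t + as_$durationS)
    }
  }

  # Accelerometer: quiet during sleep, high variance in wake + artifacts
  acc <- NULL
  accRoles <- intersect(c("ACC_X", "ACC_Y", "ACC_Z"), roles)
  if (length(accRoles)) {
    accSd <- rep(0.02, n)
    for (i in seq_len(nrow(sched))) {
      if (sched$state[i] == "WAKE") {
        i0 <- round(sched$start_s[i] * fs) + 1L
        i1 <- min(n, round(sched$end_s[i] * fs))
        accSd[i0:i1] <- 0.3
      }
    }
    if (nrow(artifacts)) {
      for (j in seq_len(nrow(artifacts))) {
        i0 <- round(artifacts$start_s[j] * fs) + 1L
        i1 <- min(n, round(artifacts$end_s[j] * fs))
        accSd[i0:i1] <- 0.5
      }
    }
    acc <- sapply(accRoles, function(r) stats::rnorm(n, 0, accSd))
  }

  mat <- matrix(0, nrow = n, ncol = length(roles),
                dimnames = list(NULL, roles))
  for (r in names(lfp)) mat[, r] <- lfp[[r]]
  if (!is.null(acc)) mat[, accRoles] <- acc

  nEp <- floor(config$duration / config$epochS)
  epState <- sched$state[findInterval(((seq_len(nEp)) - 0.5) * config$epochS,
                                      c(0, sched$end_s),
                                      rightmost.closed = TRUE)]
  hyp <- hypnogram(epState, config$epochS)

  o <- order(events$start_s)
  rankOf <- match(seq_len(nrow(events)), o)
  events <- events[o, , drop = FALSE]
  events$id <- seq_len(nrow(events))
  rownames(events) <- NULL
  events <- events[, c("id", "kind", "channel_role", "start_s", "peak_s",
                       "end_s", "amplitude_uv", "frequency_hz")]
  coupledTuples <- lapply(coupledTuples, function(tp) rankOf[tp])
  if (nrow(eventPhases)) eventPhases$event_id <- rankOf[eventPhases$event_id]

  bundle <- signalBundle(mat, fs, roles,
                         sessionMeta = list(regime = config$regime,
                                            seed = config$seed))
  list(bundle = bundle,
       truth = list(events = events, hypnogram = hyp,
                    aperiodic = c(offset = config$aperiodicOffset,
                                  exponent = config$aperiodicExponent),
                    coupledTuples = coupledTuples,
                    eventPhases = eventPhases, artifacts = artifacts))
}
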