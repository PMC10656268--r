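# Preprocessing: anti-aliased decimation, zero-phase band-pass filtering,
# and artifact blanking for the chronic (natural sleep) and acute
# (anesthetized) recording regimes.

#' Anti-aliased downsampling of a recording
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass to every
#' channel and then decimates by an integer factor.  Regime defaults
#' follow the recording pipelines this package targets: chronic 30 kHz ->
#' 2.5 kHz with a 1.25 kHz cutoff, acute 30 kHz -> 600 Hz with a 300 Hz
#' cutoff, both 3rd order.
#'
#' @param bundle a [SignalBundle-class].
#' @param targetFs target sampling rate, Hz; the ratio `fs / targetFs`
#'   must be an integer.
#' @param cutoff low-pass cutoff, Hz (default `targetFs / 2`); must be
#'   below the input Nyquist frequency.
#' @param order Butterworth prototype order (default 3).
#' @return a [SignalBundle-class] at `targetFs`.
#' @export
downsampleSignal <- function(bundle, targetFs, cutoff = targetFs / 2,
                             order = 3) {
  fs <- samplingRate(bundle)
  if (cutoff >= fs / 2) {
    stop("cutoff must be below the input Nyquist frequency", call. = FALSE)
  }
  fac <- fs / targetFs
  if (abs(fac - round(fac)) > 1e-9) {
    stop("fs / targetFs must be an integer decimation factor", call. = FALSE)
  }
  fac <- round(fac)
  keep <- seq(1L, nrow(bundle@samples), by = fac)
  out <- apply(bundle@samples, 2, function(x) {
    butterLowpass(x, fs, cutoff, order)[keep]
  })
  signalBundle(out, targetFs, bundle@channelRoles, bundle@sessionMeta)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward filtering, so band-centered transients keep their peak
#' time (zero group delay).  `order` is the prototype order; the effective
#' attenuation order is doubled by the two passes.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; `0 < low < high < fs/2`.
#' @param order prototype order (default 3).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpassFilter <- function(x, fs, low, high, order = 3) {
  butterBandpass(x, fs, low, high, order)
}

#' Amplitude-threshold artifact blanking (chronic regime)
#'
#' Samples whose absolute value exceeds `ampThreshold` are replaced by the
#' mean of the below-threshold samples of the bout; when `buildup > 0` the
#' build-up window preceding each artifact is blanked as well.  Apply
#' after band-pass filtering so filter transients at the replacement
#' discontinuities never enter the detection band.
#'
#' @param x numeric vector, one NonREM bout (already band-passed).
#' @param fs sampling rate, Hz.
#' @param ampThreshold amplitude threshold, uV.  Default 8 robust SDs
#'   (1.4826 MAD) of the bout, which is insensitive to the artifacts
#'   themselves.
#' @param buildup seconds blanked before each artifact (default 1).
#' @return list with `signal` (blanked vector), `mask` (data.frame
#'   `start_s`, `end_s` of disjoint sorted blanked intervals) and
#'   `replacement` (the substituted value).
#' @export
blankArtifactsChronic <- function(x, fs, ampThreshold = NULL, buildup = 1) {
  if (!length(x)) stop("empty bout", call. = FALSE)
  if (is.null(ampThreshold)) ampThreshold <- 8 * stats::mad(x)
  if (ampThreshold <= 0) stop("ampThreshold must be positive", call. = FALSE)
  above <- abs(x) > ampThreshold
  clean <- x[!above]
  repl <- if (length(clean)) mean(clean) else 0
  if (!any(above)) {
    return(list(signal = x,
                mask = data.frame(start_s = numeric(), end_s = numeric()),
                replacement = repl))
  }
  runs <- logicalRuns(above)
  startS <- pmax(0, (runs$start - 1L) / fs - buildup)
  endS <- runs$end / fs
  mask <- mergeIntervals(startS, endS)
  for (i in seq_len(nrow(mask))) {
    i0 <- round(mask$start_s[i] * fs) + 1L
    i1 <- min(length(x), round(mask$end_s[i] * fs))
    x[i0:i1] <- repl
  }
  list(signal = x, mask = mask, replacement = repl)
}

#' Summed-amplitude artifact blanking (acute regime)
#'
#' Discards the unstable head of the recording, flags artifacts where the
#' sum of absolute values of the two unfiltered LFP channels exceeds a
#' threshold, and replaces `[artifact - buildup, artifact + washout]` with
#' the artifact-free mean on every supplied channel.  Band-pass the ripple
#' detection channels *before* calling this, so blanking discontinuities
#' cannot create spurious high-frequency events; pass those filtered
#' channels via `alsoBlank`.
#'
#' @param hpc,pfc unfiltered LFP channels (equal length), uV.
#' @param fs sampling rate, Hz.
#' @param threshold artifact threshold on `abs(hpc) + abs(pfc)`; default
#'   `median + 8 * mad` of that sum.
#' @param buildup seconds blanked before each artifact sample (default 0.5).
#' @param washout seconds blanked after (default 3.5).
#' @param discardHead seconds removed from the start (default 900).
#' @param alsoBlank optional named list of extra channels (e.g. the
#'   ripple-band filtered traces) to trim and blank with the same mask.
#' @return list with `hpc`, `pfc`, `alsoBlank` (all trimmed and blanked),
#'   and `mask` (data.frame of blanked intervals, seconds relative to the
#'   trimmed recording).
#' @export
blankArtifactsAcute <- function(hpc, pfc, fs, threshold = NULL,
                                buildup = 0.5, washout = 3.5,
                                discardHead = 900, alsoBlank = list()) {
  stopifnot(length(hpc) == length(pfc))
  drop <- round(discardHead * fs)
  if (drop >= length(hpc)) {
    stop("discardHead covers the whole recording; nothing left",
         call. = FALSE)
  }
  if (drop > 0) {
    hpc <- hpc[-seq_len(drop)]
    pfc <- pfc[-seq_len(drop)]
    alsoBlank <- lapply(alsoBlank, function(x) x[-seq_len(drop)])
  }
  s <- abs(hpc) + abs(pfc)
  if (is.null(threshold)) threshold <- stats::median(s) + 8 * stats::mad(s)
  bad <- s > threshold
  if (!any(bad)) {
    return(list(hpc = hpc, pfc = pfc, alsoBlank = alsoBlank,
                mask = data.frame(start_s = numeric(), end_s = numeric())))
  }
  tBad <- (which(bad) - 1L) / fs
  mask <- mergeIntervals(pmax(0, tBad - buildup), tBad + 1 / fs + washout)
  mask$end_s <- pmin(mask$end_s, length(hpc) / fs)
  blank1 <- function(x) {
    good <- rep(TRUE, length(x))
    for (i in seq_len(nrow(mask))) {
      i0 <- round(mask$start_s[i] * fs) + 1L
      i1 <- min(length(x), round(mask$end_s[i] * fs))
      good[i0:i1] <- FALSE
    }
    repl <- if (any(good)) mean(x[good]) else 0
    x[!good] <- repl
    x
  }
  list(hpc = blank1(hpc), pfc = blank1(pfc),
       alsoBlank = lapply(alsoBlank, blank1), mask = mask)
}
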