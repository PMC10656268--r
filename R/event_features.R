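# Per-event characteristics and session-level count bookkeeping.

#' Event amplitude from the filtered trace
#'
#' The amplitude of an event is the maximum of the instantaneous envelope
#' (modulus of the analytic signal) of its band-passed trace.
#'
#' @param trace numeric vector: the event's trace, band-passed in its
#'   detection band, uV.
#' @return amplitude in uV.
#' @export
eventAmplitude <- function(trace) {
  if (!length(trace)) stop("empty trace", call. = FALSE)
  max(Mod(analyticSignal(trace)))
}

#' Power-weighted mean frequency of an event trace
#'
#' The first spectral moment of the trace's power spectral density divided
#' by the zeroth moment (the trace is demeaned first).
#'
#' @param trace numeric vector, band-passed event trace.
#' @param fs sampling rate, Hz.
#' @return mean frequency in Hz, or `NA` for a zero-power trace.
#' @export
eventMeanFrequency <- function(trace, fs) {
  if (length(trace) < 2L) return(NA_real_)
  ps <- periodogramPSD(trace, fs)
  tot <- sum(ps$power)
  if (tot <= 0) return(NA_real_)
  sum(ps$frequency * ps$power) / tot
}

#' Bin event counts over trial-period bins and normalize
#'
#' Assigns each event to a bin by its peak time, counts per bin and kind,
#' normalizes each kind's counts by their mean over the bins of the
#' normalization scope (so normalized counts average 1), and computes a
#' rate per NonREM minute when a hypnogram is given.  The canonical
#' schedule has 8 bins: bins 1-4 the four 45-min inter-trial rests, bins
#' 5-8 the 45-min divisions of the 3-h post-trial rest.
#'
#' @param events event data.frame with `kind` and `peak_s`.
#' @param schedule data.frame with columns `bin`, `start_s`, `end_s`
#'   (half-open intervals).
#' @param hyp optional [Hypnogram-class] for NonREM-minute rates.
#' @param nremStates state labels counted as NonREM
#'   (default `c("NREM", "NREM_LIKE")`).
#' @return data.frame `kind, bin, count, normalized, rate_per_nrem_min`.
#'   Events outside the schedule are excluded with a warning; a kind with
#'   all-zero counts gets normalized counts 0 and is flagged via
#'   `attr(, "zeroKinds")`.
#' @examples
#' ev <- data.frame(kind = "RIPPLE",
#'                  peak_s = c(rep(1, 10), rep(11, 20), rep(21, 30)))
#' sched <- data.frame(bin = 1:3, start_s = c(0, 10, 20),
#'                     end_s = c(10, 20, 30))
#' binAndNormalize(ev, sched)$normalized  # 0.5, 1.0, 1.5
#' @export
binAndNormalize <- function(events, schedule, hyp = NULL,
                            nremStates = c("NREM", "NREM_LIKE")) {
  bin <- rep(NA_integer_, nrow(events))
  for (i in seq_len(nrow(schedule))) {
    hit <- events$peak_s >= schedule$start_s[i] &
      events$peak_s < schedule$end_s[i]
    bin[hit] <- schedule$bin[i]
  }
  if (anyNA(bin) && nrow(events)) {
    warning(sum(is.na(bin)), " event(s) outside the trial-period schedule; ",
            "excluded")
  }
  events <- events[!is.na(bin), , drop = FALSE]
  bin <- bin[!is.na(bin)]
  kinds <- sort(unique(events$kind))
  if (!length(kinds)) kinds <- "RIPPLE"
  nremMin <- vapply(seq_len(nrow(schedule)), function(i) {
    if (is.null(hyp)) return(NA_real_)
    ep <- epochSeconds(hyp)
    t0 <- (seq_len(nEpochs(hyp)) - 1L) * ep
    sum(states(hyp) %in% nremStates &
          t0 >= schedule$start_s[i] & t0 < schedule$end_s[i]) * ep / 60
  }, numeric(1))
  out <- do.call(rbind, lapply(kinds, function(k) {
    cnt <- vapply(schedule$bin, function(b) {
      sum(events$kind == k & bin == b)
    }, numeric(1))
    norm <- if (mean(cnt) > 0) cnt / mean(cnt) else rep(0, length(cnt))
    data.frame(kind = k, bin = schedule$bin, count = cnt,
               normalized = norm,
               rate_per_nrem_min = ifelse(nremMin > 0, cnt / nremMin,
                                          NA_real_))
  }))
  rownames(out) <- NULL
  zero <- kinds[vapply(kinds, function(k) {
    sum(out$count[out$kind == k]) == 0
  }, logical(1))]
  attr(out, "zeroKinds") <- zero
  out
}
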