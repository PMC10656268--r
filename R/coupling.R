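# Hippocampal-cortical coupling: delta/spindle/ripple sequences,
# ripple-spindle co-occurrence, fraction of ripples in sequences, and
# slow-oscillation phase locking.

#' Inter-event interval windows for sequence detection
#'
#' Peak-to-peak windows (ms, both ends inclusive) defining the sequence
#' motifs: delta-spindle 100-1300 ms, delta-ripple 50-400 ms,
#' ripple-spindle 2-1000 ms.
#'
#' @return named list of `c(min, max)` windows in ms.
#' @export
couplingWindows <- function() {
  list(D_S = c(100, 1300), D_R = c(50, 400), R_S = c(2, 1000))
}

ensureIds <- function(events) {
  if (is.null(events$id)) events$id <- seq_len(nrow(events))
  events
}

rippleClassOf <- function(lead, trail, i, j) {
  if (!is.null(lead$length_class) && any(lead$kind == "RIPPLE")) {
    lead$length_class[i]
  } else if (!is.null(trail$length_class) && any(trail$kind == "RIPPLE")) {
    trail$length_class[j]
  } else NA_character_
}

#' Detect ordered event pairs within an inter-peak window
#'
#' Emits one coupling record per ordered pair `(a, b)` with
#' `b.peak - a.peak` inside `[windowMs[1], windowMs[2]]` (inclusive).
#' All qualifying pairs are counted: one event may join several records.
#'
#' @param lead,trail event data.frames (need `peak_s`; `id` added if
#'   missing; `length_class` carried for ripples).
#' @param windowMs `c(min, max)` window in ms; see [couplingWindows()].
#' @param type sequence-type label for the records (e.g. `"D_S"`).
#' @return data.frame `sequence_type, lead_id, trail_id, interval_ms,
#'   ripple_class`.
#' @export
detectPairs <- function(lead, trail, windowMs, type = "PAIR") {
  if (windowMs[1] > windowMs[2]) {
    stop("window minimum exceeds maximum", call. = FALSE)
  }
  lead <- ensureIds(lead); trail <- ensureIds(trail)
  out <- data.frame(sequence_type = character(), lead_id = integer(),
                    trail_id = integer(), interval_ms = numeric(),
                    ripple_class = character(), stringsAsFactors = FALSE)
  if (!nrow(lead) || !nrow(trail)) return(out)
  for (i in seq_len(nrow(lead))) {
    dt <- (trail$peak_s - lead$peak_s[i]) * 1000
    hit <- which(dt >= windowMs[1] & dt <= windowMs[2])
    for (j in hit) {
      out[nrow(out) + 1L, ] <- list(type, lead$id[i], trail$id[j], dt[j],
                                    rippleClassOf(lead, trail, i, j))
    }
  }
  out
}

#' Detect delta-ripple-spindle triplets
#'
#' One `D_R_S` record per (delta, ripple, spindle) combination in which
#' the ripple trails a delta in a `D_R` record and leads a spindle in an
#' `R_S` record.
#'
#' @param dr `D_R` records from [detectPairs()].
#' @param rs `R_S` records from [detectPairs()].
#' @return data.frame `sequence_type, delta_id, ripple_id, spindle_id,
#'   interval_dr_ms, interval_rs_ms, ripple_class`.
#' @export
detectTriplets <- function(dr, rs) {
  out <- data.frame(sequence_type = character(), delta_id = integer(),
                    ripple_id = integer(), spindle_id = integer(),
                    interval_dr_ms = numeric(), interval_rs_ms = numeric(),
                    ripple_class = character(), stringsAsFactors = FALSE)
  if (!nrow(dr) || !nrow(rs)) return(out)
  for (i in seq_len(nrow(dr))) {
    hit <- which(rs$lead_id == dr$trail_id[i])
    for (j in hit) {
      out[nrow(out) + 1L, ] <- list("D_R_S", dr$lead_id[i], dr$trail_id[i],
                                    rs$trail_id[j], dr$interval_ms[i],
                                    rs$interval_ms[j],
                                    rs$ripple_class[j] %||% dr$ripple_class[i])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Ripple-spindle co-occurrence
#'
#' A ripple and a spindle co-occur when (1) the ripple starts and ends
#' within the spindle's duration, or (2) either event's start or end lies
#' inside the other's interval.  Because several ripples can share a
#' spindle, both directional counts are reported.
#'
#' @param ripples,spindles event data.frames with `start_s`, `end_s`
#'   (`id` added if missing).
#' @return list with `pairs` (data.frame `sequence_type = "SwR",
#'   ripple_id, spindle_id, ripple_class`), `nRipplesWithSpindles` and
#'   `nSpindlesWithRipples`.
#' @export
detectCooccurrence <- function(ripples, spindles) {
  ripples <- ensureIds(ripples); spindles <- ensureIds(spindles)
  pairs <- data.frame(sequence_type = character(), ripple_id = integer(),
                      spindle_id = integer(), ripple_class = character(),
                      stringsAsFactors = FALSE)
  inside <- function(t, lo, hi) t >= lo & t <= hi
  for (i in seq_len(nrow(ripples))) {
    r0 <- ripples$start_s[i]; r1 <- ripples$end_s[i]
    for (j in seq_len(nrow(spindles))) {
      s0 <- spindles$start_s[j]; s1 <- spindles$end_s[j]
      co <- (inside(r0, s0, s1) && inside(r1, s0, s1)) ||
        inside(r0, s0, s1) || inside(r1, s0, s1) ||
        inside(s0, r0, r1) || inside(s1, r0, r1)
      if (co) {
        pairs[nrow(pairs) + 1L, ] <- list(
          "SwR", ripples$id[i], spindles$id[j],
          if (is.null(ripples$length_class)) NA_character_
          else ripples$length_class[i])
      }
    }
  }
  list(pairs = pairs,
       nRipplesWithSpindles = length(unique(pairs$ripple_id)),
       nSpindlesWithRipples = length(unique(pairs$spindle_id)))
}

#' Detect delta-spindle-with-ripple conjunctions
#'
#' One `D_SwR` record per spindle that trails a delta in a `D_S` record
#' and hosts at least one co-occurring ripple.
#'
#' @param ds `D_S` records from [detectPairs()].
#' @param swr co-occurrence pairs from [detectCooccurrence()] (`$pairs`).
#' @return data.frame `sequence_type, spindle_id, delta_ids, ripple_ids,
#'   ripple_class` (ids comma-collapsed; class is the collapsed set of
#'   co-occurring ripple classes).
#' @export
detectDSwR <- function(ds, swr) {
  out <- data.frame(sequence_type = character(), spindle_id = integer(),
                    delta_ids = character(), ripple_ids = character(),
                    ripple_class = character(), stringsAsFactors = FALSE)
  if (!nrow(ds) || !nrow(swr)) return(out)
  spindleIds <- intersect(unique(ds$trail_id), unique(swr$spindle_id))
  for (sId in spindleIds) {
    dIds <- ds$lead_id[ds$trail_id == sId]
    rSel <- swr$spindle_id == sId
    out[nrow(out) + 1L, ] <- list(
      "D_SwR", sId, paste(sort(dIds), collapse = ","),
      paste(sort(swr$ripple_id[rSel]), collapse = ","),
      paste(sort(unique(stats::na.omit(swr$ripple_class[rSel]))),
            collapse = ","))
  }
  out
}

#' Fraction of ripples that take part in sequences
#'
#' A ripple is "in sequence" when it is a member of at least one `D_R`,
#' `D_R_S`, `R_S`, `SwR` or `D_SwR` record (set membership, so
#' multiplicity does not inflate the fractions).  Reported per ripple
#' length class, together with per-sequence-type fractions over the
#' coupled ripples.
#'
#' @param ripples ripple event data.frame (`id` added if missing,
#'   `length_class`).
#' @param records named list of record data.frames, e.g.
#'   `list(D_R = ..., R_S = ..., D_R_S = ..., SwR = ...)`.
#' @return list with `byClass` (data.frame `length_class, n,
#'   fraction_alone, fraction_in_sequence`) and `byType` (data.frame
#'   `sequence_type, length_class, fraction_of_coupled`).
#' @export
fractionInSequences <- function(ripples, records) {
  ripples <- ensureIds(ripples)
  idsOf <- function(rec) {
    if (is.null(rec) || !nrow(rec)) return(integer())
    cols <- intersect(c("ripple_id", "ripple_ids"), names(rec))
    if ("ripple_id" %in% cols) return(rec$ripple_id)
    if ("ripple_ids" %in% cols) {
      return(as.integer(unlist(strsplit(rec$ripple_ids, ","))))
    }
    # detectPairs output: the ripple is lead in R_S, trail in D_R
    if (all(rec$sequence_type == "R_S")) rec$lead_id else rec$trail_id
  }
  typeIds <- lapply(records, idsOf)
  inSeq <- unique(unlist(typeIds))
  classes <- if (is.null(ripples$length_class)) "NA" else
    sort(unique(ripples$length_class))
  byClass <- do.call(rbind, lapply(classes, function(cl) {
    sel <- if (is.null(ripples$length_class)) rep(TRUE, nrow(ripples))
    else ripples$length_class == cl
    ids <- ripples$id[sel]
    n <- length(ids)
    fin <- if (n) mean(ids %in% inSeq) else 0
    data.frame(length_class = cl, n = n,
               fraction_alone = if (n) 1 - fin else 1,
               fraction_in_sequence = fin)
  }))
  byType <- do.call(rbind, lapply(names(typeIds), function(tp) {
    do.call(rbind, lapply(classes, function(cl) {
      sel <- if (is.null(ripples$length_class)) rep(TRUE, nrow(ripples))
      else ripples$length_class == cl
      coupled <- intersect(ripples$id[sel], inSeq)
      frac <- if (length(coupled)) {
        mean(coupled %in% typeIds[[tp]])
      } else NA_real_
      data.frame(sequence_type = tp, length_class = cl,
                 fraction_of_coupled = frac)
    }))
  }))
  list(byClass = byClass, byType = byType)
}

#' Slow-oscillation phase at event peaks
#'
#' Band-passes the PFC channel to 0.5-4 Hz (zero-phase, 3rd order) and
#' reads the analytic-signal phase at each event peak, mapped to
#' \[0, 360) with the convention that the filtered-signal positive peak is
#' 0 degrees and the trough 180 degrees.
#'
#' @param pfc PFC channel, uV.
#' @param fs sampling rate, Hz.
#' @param peaksS event peak times, s.
#' @param band slow-oscillation band (default `c(0.5, 4)`).
#' @param order filter prototype order (default 3).
#' @return data.frame `event_id, phase_deg` (one row per in-range peak;
#'   out-of-range peaks are excluded with a warning).
#' @export
soPhaseAtEvents <- function(pfc, fs, peaksS, band = c(0.5, 4), order = 3) {
  so <- butterBandpass(pfc, fs, band[1], band[2], order)
  phase <- (Arg(analyticSignal(so)) * 180 / pi) %% 360
  idx <- round(peaksS * fs) + 1L
  ok <- idx >= 1L & idx <= length(pfc)
  if (any(!ok)) {
    warning(sum(!ok), " event peak(s) outside the signal; excluded")
  }
  data.frame(event_id = which(ok), phase_deg = phase[idx[ok]])
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of phases is uniformly distributed on the
#' circle; significance indicates phase locking.  Returns the circular
#' mean direction, the mean resultant length R in \[0, 1\], and the
#' Rayleigh p-value (Zar's finite-sample approximation).
#'
#' @param phasesDeg numeric vector of phases in degrees (n >= 5), or the
#'   data.frame from [soPhaseAtEvents()].
#' @return list `meanDirectionDeg`, `R`, `p`, `n`.
#' @export
phaseLockingTest <- function(phasesDeg) {
  if (is.data.frame(phasesDeg)) phasesDeg <- phasesDeg$phase_deg
  n <- length(phasesDeg)
  if (n < 5L) stop("need at least 5 phase samples", call. = FALSE)
  th <- phasesDeg * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) * 180 / pi) %% 360
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(meanDirectionDeg = mu, R = R, p = min(1, p), n = n)
}
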