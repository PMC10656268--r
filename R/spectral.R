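# Power spectra and aperiodic (1/f) parameterization.  The aperiodic
# exponent flattens with shifts toward excitation, so the offset/exponent
# pair serves as an excitation/inhibition proxy.

#' Welch power spectral density with notch
#'
#' Averaged Hann-tapered periodogram: 4-s windows with 0.25-s overlap by
#' default, 0.25 Hz grid up to `fmax`, 50 Hz line noise removed by a
#' zero-phase notch.  Output is log10 power density.
#'
#' @param x numeric vector (one channel), uV.
#' @param fs sampling rate, Hz.
#' @param windowS window length, s (default 4; sets the 0.25 Hz grid).
#' @param overlapS window overlap, s (default 0.25).
#' @param notchHz line-noise frequency to notch out, or `NULL` (default
#'   50).
#' @param fmax upper frequency of the reported grid (default 100 Hz).
#' @return list of class `"SpectralEstimate"`: `frequency` (Hz, strictly
#'   increasing), `log10_power`, and `meta`.  A segment shorter than one
#'   window is zero-padded into a single window with a warning.
#' @export
computePSD <- function(x, fs, windowS = 4, overlapS = 0.25, notchHz = 50,
                       fmax = 100) {
  if (!is.null(notchHz) && notchHz < fs / 2) {
    x <- butterNotch(x, fs, notchHz)
  }
  w <- welchPSD(x, fs, windowS, overlapS)
  keep <- w$frequency <= fmax
  structure(list(frequency = w$frequency[keep],
                 log10_power = log10(pmax(w$power[keep], 1e-300)),
                 meta = list(windowS = windowS, overlapS = overlapS,
                             taper = "hann", notchHz = notchHz, fs = fs)),
            class = "SpectralEstimate")
}

#' @export
print.SpectralEstimate <- function(x, ...) {
  cat(sprintf("SpectralEstimate: %d bins, %.2f-%.2f Hz (step %.2g Hz)\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              stats::median(diff(x$frequency))))
  invisible(x)
}

gaussianPeak <- function(f, center, height, width) {
  height * exp(-(f - center)^2 / (2 * (width / 2)^2))
}

robustLinearFit <- function(logf, y) {
  fit <- stats::lm.fit(cbind(1, logf), y)
  resid <- y - fit$fitted.values
  resid[resid < 0] <- 0
  th <- stats::quantile(resid, 0.025)
  keep <- resid <= th
  if (sum(keep) >= 2) fit <- stats::lm.fit(cbind(1, logf[keep]), y[keep])
  fit$coefficients
}

#' Parameterize a spectrum into aperiodic and oscillatory components
#'
#' Iterative spectral parameterization of a log10-power spectrum:
#' (i) a robust linear fit of log10 power against log10 frequency gives
#' the initial aperiodic component; (ii) residual peaks are fitted as
#' Gaussians (center, height, width = 2 sd), largest first, while the
#' residual height reaches `minPeakHeight` and at most `maxPeaks` times,
#' with widths constrained to `peakWidthLimits`; (iii) the aperiodic
#' component is refit on the peak-subtracted spectrum.  The model has no
#' knee: the aperiodic component is a straight line in log-log
#' coordinates, `log10 P = offset - exponent * log10 f`.
#'
#' @param spec a `"SpectralEstimate"` from [computePSD()], or any list
#'   with `frequency` and `log10_power`.
#' @param fitRange frequency range fitted, Hz (default `c(1, 100)`).
#' @param peakWidthLimits Gaussian width limits, Hz (default `c(1, 8)`).
#' @param minPeakHeight minimum residual height (log10-power units) for a
#'   peak to be fitted (default 0.05).
#' @param peakThreshold relative detection threshold in SDs of the
#'   flattened (residual) spectrum (default 2); a peak must clear both
#'   this and `minPeakHeight`, so estimation noise in the spectrum is not
#'   fitted as oscillations.
#' @param maxPeaks maximum number of peaks (default 6).
#' @param exclude frequency band excluded from the fit, guarding the
#'   notch (default `c(45, 55)`; `NULL` to disable).
#' @return list of class `"AperiodicFit"`: `offset` (log10 power at
#'   log10 f = 0), `exponent` (slope is `-exponent`), `peaks` (data.frame
#'   `center_hz, height, width_hz`), `fitRange`, `r_squared`.
#' @export
fitAperiodic <- function(spec, fitRange = c(1, 100),
                         peakWidthLimits = c(1, 8), minPeakHeight = 0.05,
                         peakThreshold = 2, maxPeaks = 6,
                         exclude = c(45, 55)) {
  f <- spec$frequency
  y <- spec$log10_power
  if (any(!is.finite(y))) stop("non-finite power values", call. = FALSE)
  sel <- f >= fitRange[1] & f <= fitRange[2] & f > 0
  if (!is.null(exclude)) sel <- sel & !(f >= exclude[1] & f <= exclude[2])
  f <- f[sel]; y <- y[sel]
  if (length(f) < 4) stop("fit range holds too few bins", call. = FALSE)
  logf <- log10(f)

  co <- robustLinearFit(logf, y)
  resid <- y - (co[1] + co[2] * logf)

  peaks <- data.frame(center_hz = numeric(), height = numeric(),
                      width_hz = numeric())
  sdLim <- peakWidthLimits / 2
  for (k in seq_len(maxPeaks)) {
    i <- which.max(resid)
    h0 <- resid[i]
    if (h0 < max(minPeakHeight, peakThreshold * stats::sd(resid))) break
    c0 <- f[i]
    # width guess from the half-height extent around the maximum
    half <- h0 / 2
    lo <- i; while (lo > 1 && resid[lo - 1] > half) lo <- lo - 1
    hi <- i; while (hi < length(f) && resid[hi + 1] > half) hi <- hi + 1
    sd0 <- max(sdLim[1], min(sdLim[2], (f[hi] - f[lo]) / 2.355))
    obj <- function(p) {
      sum((resid - gaussianPeak(f, p[1], p[2], 2 * p[3]))^2)
    }
    opt <- stats::optim(c(c0, h0, sd0), obj, method = "L-BFGS-B",
                        lower = c(max(fitRange[1], c0 - 2 * sd0), 0, sdLim[1]),
                        upper = c(min(fitRange[2], c0 + 2 * sd0),
                                  1.5 * h0 + 0.5, sdLim[2]))
    g <- gaussianPeak(f, opt$par[1], opt$par[2], 2 * opt$par[3])
    resid <- resid - g
    if (opt$par[2] >= minPeakHeight) {
      peaks[nrow(peaks) + 1L, ] <- c(opt$par[1], opt$par[2], 2 * opt$par[3])
    }
  }

  peakModel <- numeric(length(f))
  for (i in seq_len(nrow(peaks))) {
    peakModel <- peakModel + gaussianPeak(f, peaks$center_hz[i],
                                          peaks$height[i],
                                          peaks$width_hz[i])
  }
  co2 <- stats::lm.fit(cbind(1, logf), y - peakModel)$coefficients
  model <- co2[1] + co2[2] * logf + peakModel
  r2 <- 1 - sum((y - model)^2) / max(sum((y - mean(y))^2), 1e-300)
  structure(list(offset = unname(co2[1]), exponent = unname(-co2[2]),
                 peaks = peaks, fitRange = fitRange, r_squared = r2),
            class = "AperiodicFit")
}

#' @export
print.AperiodicFit <- function(x, ...) {
  cat(sprintf("AperiodicFit: offset %.3f, exponent %.3f (R^2 %.3f)\n",
              x$offset, x$exponent, x$r_squared))
  if (nrow(x$peaks)) {
    for (i in seq_len(nrow(x$peaks))) {
      cat(sprintf("  peak %d: %.2f Hz, height %.3f, width %.2f Hz\n", i,
                  x$peaks$center_hz[i], x$peaks$height[i],
                  x$peaks$width_hz[i]))
    }
  } else cat("  no oscillatory peaks\n")
  invisible(x)
}

#' Event-triggered power spectra
#'
#' For each event, extracts a window (default 4 s) centered on the event
#' peak on each LFP region's channel and computes its Hann periodogram on
#' the 0.25 Hz grid; spectra are averaged (in linear power) within event
#' class (SHORT/LONG ripples) and reported as log10 power, alongside a
#' baseline of randomly selected NonREM windows of the same length.
#'
#' @param bundle a [SignalBundle-class].
#' @param events event data.frame (`peak_s`, `length_class`); may be
#'   empty for a baseline-only output.
#' @param nremIntervals data.frame (`start_s`, `end_s`) of NonREM
#'   intervals for baseline sampling.
#' @param nBaseline number of baseline windows (default 50).
#' @param windowS window length, s (default 4).
#' @param seed RNG seed for the baseline selection.
#' @param notchHz notch frequency passed to the PSD (default 50).
#' @return data.frame `region, class, frequency_hz, log10_power`.  Events
#'   too close to the recording edge are excluded with a warning.
#' @export
eventTriggeredSpectra <- function(bundle, events, nremIntervals,
                                  nBaseline = 50, windowS = 4, seed = 1L,
                                  notchHz = 50) {
  fs <- samplingRate(bundle)
  n <- nSamples(bundle)
  half <- round(windowS / 2 * fs)
  regions <- intersect(c("HPC", "PFC"), channelRoles(bundle))
  winPSD <- function(x) {
    if (!is.null(notchHz) && notchHz < fs / 2) x <- butterNotch(x, fs, notchHz)
    w <- welchPSD(x, fs, windowS, 0)
    w
  }
  classesOf <- function(ev) {
    if (!nrow(ev)) return(character())
    if (is.null(ev$length_class)) "ALL" else unique(ev$length_class)
  }
  out <- NULL
  if (nrow(events)) {
    ctr <- round(events$peak_s * fs) + 1L
    ok <- ctr - half >= 1L & ctr + half - 1L <= n
    if (any(!ok)) {
      warning(sum(!ok), " event(s) too close to the recording edge; excluded")
    }
    events <- events[ok, , drop = FALSE]; ctr <- ctr[ok]
    for (cl in classesOf(events)) {
      sel <- if (cl == "ALL") rep(TRUE, nrow(events))
      else events$length_class == cl
      for (rg in regions) {
        ch <- channelData(bundle, rg)
        acc <- NULL
        for (c0 in ctr[sel]) {
          w <- winPSD(ch[(c0 - half):(c0 + half - 1L)])
          acc <- if (is.null(acc)) w$power else acc + w$power
        }
        if (is.null(acc)) next
        keep <- w$frequency <= 100
        out <- rbind(out, data.frame(region = rg, class = cl,
                                     frequency_hz = w$frequency[keep],
                                     log10_power = log10(acc[keep] / sum(sel))))
      }
    }
  }
  # baseline windows
  set.seed(seed)
  iv <- nremIntervals[nremIntervals$end_s - nremIntervals$start_s >= windowS, ,
                      drop = FALSE]
  if (nrow(iv)) {
    len <- iv$end_s - iv$start_s - windowS
    for (rg in regions) {
      ch <- channelData(bundle, rg)
      acc <- NULL
      for (b in seq_len(nBaseline)) {
        seg <- sample.int(nrow(iv), 1L, prob = len + 1e-9)
        t0 <- stats::runif(1, iv$start_s[seg],
                           iv$end_s[seg] - windowS)
        i0 <- round(t0 * fs) + 1L
        w <- winPSD(ch[i0:(i0 + 2L * half - 1L)])
        acc <- if (is.null(acc)) w$power else acc + w$power
      }
      keep <- w$frequency <= 100
      out <- rbind(out, data.frame(region = rg, class = "BASELINE",
                                   frequency_hz = w$frequency[keep],
                                   log10_power = log10(acc[keep] / nBaseline)))
    }
  }
  out
}
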