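# Sleep architecture statistics and the automatic NonREM-like/REM-like
# classifier for anesthetized recordings.

SLEEP_STATES <- c("NREM", "INTERMEDIATE", "REM", "NREM_LIKE", "REM_LIKE")

#' Sleep architecture summary
#'
#' Computes total sleep time, per-state percentages, bouts (maximal runs
#' of one state), state transitions, and time-binned state percentages
#' from a hypnogram.  Bout-duration statistics consider only bouts longer
#' than `minBout` (default 4 s); the bout table reports all bouts with an
#' `included` flag.  Percentages in a partial final bin are normalized by
#' that bin's own duration.
#'
#' @param hyp a [Hypnogram-class].
#' @param minBout bouts must be strictly longer than this (s) to enter the
#'   duration statistics.
#' @param binWidth width of the time bins (s), default 2700 (45 min).
#' @return list of class `"ArchitectureSummary"`: `tst` (s),
#'   `pctState` (percent of TST per sleep state; all zero with
#'   `noSleep = TRUE` when TST is 0), `bouts` (data.frame `state,
#'   start_s, duration_s, included`), `transitions` (data.frame `from,
#'   to, count`), `binnedPct` (data.frame `bin, state, pct`).
#' @examples
#' h <- hypnogram(c(rep("NREM", 10), rep("REM", 5), rep("NREM", 3)))
#' sleepArchitecture(h)$transitions
#' @export
sleepArchitecture <- function(hyp, minBout = 4, binWidth = 2700) {
  st <- states(hyp)
  ep <- epochSeconds(hyp)
  if (!length(st)) {
    return(structure(list(tst = 0, pctState = numeric(), noSleep = TRUE,
                          bouts = data.frame(), transitions = data.frame(),
                          binnedPct = data.frame()),
                     class = "ArchitectureSummary"))
  }
  r <- rle(st)
  ends <- cumsum(r$lengths) * ep
  starts <- ends - r$lengths * ep
  bouts <- data.frame(state = r$values, start_s = starts,
                      duration_s = r$lengths * ep)
  bouts$included <- bouts$duration_s > minBout

  sleepHere <- intersect(unique(st), SLEEP_STATES)
  tst <- sum(bouts$duration_s[bouts$state %in% SLEEP_STATES])
  noSleep <- tst <= 0
  pct <- vapply(sleepHere, function(s) {
    if (noSleep) 0 else
      100 * sum(bouts$duration_s[bouts$state == s]) / tst
  }, numeric(1))

  transitions <- if (length(r$values) > 1L) {
    tt <- table(from = r$values[-length(r$values)], to = r$values[-1L])
    d <- as.data.frame(tt, stringsAsFactors = FALSE)
    names(d) <- c("from", "to", "count")
    d[d$count > 0, , drop = FALSE]
  } else data.frame(from = character(), to = character(), count = integer())

  total <- length(st) * ep
  nbin <- ceiling(total / binWidth)
  binned <- do.call(rbind, lapply(seq_len(nbin), function(b) {
    if (!length(sleepHere)) return(NULL)
    lo <- (b - 1) * binWidth
    hi <- min(b * binWidth, total)
    epIdx <- seq.int(floor(lo / ep) + 1L, ceiling(hi / ep))
    stB <- st[epIdx]
    sleepT <- sum(stB %in% SLEEP_STATES) * ep
    data.frame(bin = b, state = sleepHere,
               pct = vapply(sleepHere, function(s) {
                 if (sleepT <= 0) 0 else 100 * sum(stB == s) * ep / sleepT
               }, numeric(1)), row.names = NULL)
  }))
  if (is.null(binned)) {
    binned <- data.frame(bin = integer(), state = character(),
                         pct = numeric())
  }

  structure(list(tst = tst, pctState = pct, noSleep = noSleep,
                 bouts = bouts, transitions = transitions,
                 binnedPct = binned),
            class = "ArchitectureSummary")
}

#' @export
print.ArchitectureSummary <- function(x, ...) {
  cat(sprintf("Sleep architecture: TST = %.1f s\n", x$tst))
  if (length(x$pctState)) {
    for (s in names(x$pctState)) {
      cat(sprintf("  %-13s %6.2f %% of TST\n", s, x$pctState[[s]]))
    }
  }
  cat(sprintf("  %d bouts (%d longer than threshold), %d transition types\n",
              nrow(x$bouts), sum(x$bouts$included), nrow(x$transitions)))
  invisible(x)
}

#' Per-epoch spectral features for state classification
#'
#' For each full epoch and each LFP region (HPC and PFC), estimates the
#' multitaper power spectrum (sine tapers, time-bandwidth 4, i.e. 7
#' tapers) on a 0.5 Hz grid and sums it over the canonical bands:
#' slow oscillation 0.1-1 Hz, delta 1-3 Hz, theta 3-6 Hz, low beta
#' 10-20 Hz, low gamma 30-45 Hz, high gamma 55-80 Hz, ripple 90-300 Hz
#' (capped at Nyquist).  Adds the theta/slow-oscillation power ratio and
#' the epoch's maximum absolute amplitude.
#'
#' @param bundle a [SignalBundle-class] with HPC and/or PFC channels.
#' @param epochS epoch length, seconds (default 10).
#' @param nw multitaper time-bandwidth product (default 4).
#' @return data.frame, one row per epoch: `epoch`, then per region
#'   `<region>_so_power`, `_delta_power`, `_theta_power`, `_low_beta`,
#'   `_low_gamma`, `_high_gamma`, `_ripple_power`, `_theta_so_ratio`,
#'   `_amplitude`.  The epoch length is kept in `attr(, "epochS")`.
#' @export
epochFeatures <- function(bundle, epochS = 10, nw = 4) {
  fs <- samplingRate(bundle)
  n <- nSamples(bundle)
  L <- round(epochS * fs)
  nEp <- floor(n / L)
  if (nEp < 1) stop("epoch longer than the recording", call. = FALSE)
  bands <- list(so_power = c(0.1, 1), delta_power = c(1, 3),
                theta_power = c(3, 6), low_beta = c(10, 20),
                low_gamma = c(30, 45), high_gamma = c(55, 80),
                ripple_power = c(90, 300))
  regions <- intersect(c("HPC", "PFC"), channelRoles(bundle))
  if (!length(regions)) stop("no LFP channels in bundle", call. = FALSE)
  rows <- vector("list", nEp)
  for (e in seq_len(nEp)) {
    idx <- ((e - 1L) * L + 1L):(e * L)
    row <- list(epoch = e)
    for (rg in regions) {
      x <- channelData(bundle, rg)[idx]
      ps <- multitaperPSD(x, fs, nw = nw)
      # rebin to a 0.5 Hz grid by averaging
      grid <- floor(ps$frequency / 0.5)
      p05 <- tapply(ps$power, grid, mean)
      f05 <- (as.numeric(names(p05)) + 0.5) * 0.5  # bin centers
      for (b in names(bands)) {
        lo <- bands[[b]][1]; hi <- min(bands[[b]][2], fs / 2)
        sel <- f05 >= lo & f05 <= hi
        row[[paste0(tolower(rg), "_", b)]] <- sum(p05[sel]) * 0.5
      }
      sp <- row[[paste0(tolower(rg), "_so_power")]]
      row[[paste0(tolower(rg), "_theta_so_ratio")]] <-
        if (sp > 0) row[[paste0(tolower(rg), "_theta_power")]] / sp else NA_real_
      row[[paste0(tolower(rg), "_amplitude")]] <- max(abs(x))
    }
    rows[[e]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  attr(out, "epochS") <- epochS
  out
}

#' Flag artifact epochs by amplitude outlier detection
#'
#' An epoch is flagged when its amplitude (maximum over regions) deviates
#' from the median by more than 3 scaled MADs.  When the MAD is zero
#' (e.g. identical amplitudes) no epoch is flagged.
#'
#' @param features output of [epochFeatures()].
#' @param nmad outlier cut in scaled-MAD units (default 3).
#' @return logical vector, one flag per epoch.
#' @export
flagArtifactEpochs <- function(features, nmad = 3) {
  if (nrow(features) < 3L) stop("need at least 3 epochs", call. = FALSE)
  ampCols <- grep("_amplitude$", names(features), value = TRUE)
  amp <- do.call(pmax, features[ampCols])
  m <- stats::median(amp)
  s <- stats::mad(amp)
  if (s == 0) return(rep(FALSE, length(amp)))
  abs(amp - m) > nmad * s
}

#' Classify NonREM-like vs REM-like epochs (anesthesia)
#'
#' Standardizes the epoch features, projects them on the first two
#' principal components, partitions the PC1-PC2 plane with 2-means
#' (10 restarts), and labels the cluster with the higher mean PC1 as
#' `NREM_LIKE`, the other as `REM_LIKE`.  The PC1 sign is first fixed so
#' the summed slow-oscillation power loading is positive, which makes the
#' "higher PC1 = NonREM-like" rule orientation-stable.  Artifact epochs
#' are labeled `ARTIFACT` and excluded from the fit.
#'
#' @param features output of [epochFeatures()].
#' @param seed RNG seed for the k-means restarts.
#' @param artifactFlags optional logical vector; default
#'   [flagArtifactEpochs()] when there are at least 3 epochs.
#' @return a [Hypnogram-class] with states over
#'   `NREM_LIKE`/`REM_LIKE`/`ARTIFACT` and the features' epoch length.
#' @export
classifySleepLike <- function(features, seed = 1L, artifactFlags = NULL) {
  if (is.null(artifactFlags)) {
    artifactFlags <- if (nrow(features) >= 3L) {
      flagArtifactEpochs(features)
    } else rep(FALSE, nrow(features))
  }
  use <- !artifactFlags
  if (sum(use) < 2L) stop("need at least 2 non-artifact epochs", call. = FALSE)
  X <- as.matrix(features[use, setdiff(names(features), "epoch")])
  X[!is.finite(X)] <- 0
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  soLoad <- sum(pc$rotation[grep("_so_power$", rownames(pc$rotation)), 1])
  if (soLoad < 0) scores[, 1] <- -scores[, 1]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = 2L, nstart = 10L)
  nremCluster <- which.max(tapply(scores[, 1], km$cluster, mean))
  lab <- ifelse(km$cluster == nremCluster, "NREM_LIKE", "REM_LIKE")
  out <- rep("ARTIFACT", nrow(features))
  out[use] <- lab
  epochS <- attr(features, "epochS")
  hypnogram(out, if (is.null(epochS)) 10 else epochS)
}
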