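#' @import methods
NULL

VALID_ROLES <- c("HPC", "PFC", "ACC_X", "ACC_Y", "ACC_Z")
CHRONIC_STATES <- c("WAKE", "NREM", "INTERMEDIATE", "REM")
ACUTE_STATES <- c("NREM_LIKE", "REM_LIKE", "ARTIFACT")

#' Multi-channel continuous recording
#'
#' `SignalBundle` holds a multi-channel extracellular recording: a samples
#' matrix (rows = time, columns = channels, microvolts for LFP channels),
#' the sampling rate in Hz, one role label per channel (`"HPC"`, `"PFC"`,
#' `"ACC_X"`, `"ACC_Y"`, `"ACC_Z"`) and free-form session metadata
#' (animal id, treatment, condition, trial-period labels).  All time
#' intervals used throughout the package are half-open `[start, end)`
#' seconds from the start of the recording.
#'
#' @slot samples numeric matrix, one column per channel, LFP in microvolts.
#' @slot fs sampling rate, Hz.
#' @slot channelRoles character vector, one role per column.
#' @slot sessionMeta named list of session metadata.
#'
#' @seealso [signalBundle()] for the constructor, [channelData()],
#'   [samplingRate()], [channelRoles()], [durationSeconds()].
#' @export
setClass("SignalBundle",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelRoles = "character",
    sessionMeta = "list"
  )
)

setValidity("SignalBundle", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (ncol(object@samples) != length(object@channelRoles)) {
    msg <- c(msg, "one channel role is required per column of samples")
  }
  bad <- setdiff(object@channelRoles, VALID_ROLES)
  if (length(bad)) {
    msg <- c(msg, paste0("unknown channel roles: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(object@channelRoles)) {
    msg <- c(msg, "channel roles must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SignalBundle
#'
#' @param samples numeric matrix (rows = samples, cols = channels) or a
#'   single numeric vector for a one-channel bundle.  LFP channels are in
#'   microvolts; accelerometer channels in g.
#' @param fs sampling rate in Hz.
#' @param channelRoles character vector of channel roles, from
#'   `c("HPC", "PFC", "ACC_X", "ACC_Y", "ACC_Z")`.
#' @param sessionMeta optional named list (animal id, treatment, condition,
#'   trial-period labels).
#' @return A [SignalBundle-class] object.
#' @examples
#' sb <- signalBundle(matrix(rnorm(2000), ncol = 2), fs = 1000,
#'                    channelRoles = c("HPC", "PFC"))
#' durationSeconds(sb)
#' @export
signalBundle <- function(samples, fs, channelRoles, sessionMeta = list()) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  storage.mode(samples) <- "double"
  colnames(samples) <- channelRoles
  new("SignalBundle", samples = samples, fs = fs,
      channelRoles = channelRoles, sessionMeta = sessionMeta)
}

#' @describeIn signalBundle sampling rate in Hz.
#' @param x a `SignalBundle` (or `Hypnogram` where noted).
#' @export
samplingRate <- function(x) x@fs

#' @describeIn signalBundle channel role labels.
#' @export
channelRoles <- function(x) x@channelRoles

#' @describeIn signalBundle number of samples per channel.
#' @export
nSamples <- function(x) nrow(x@samples)

#' @describeIn signalBundle recording duration in seconds.
#' @export
durationSeconds <- function(x) nrow(x@samples) / x@fs

#' @describeIn signalBundle extract one channel as a numeric vector by its
#'   role label.
#' @param role channel role label.
#' @export
channelData <- function(x, role) {
  i <- match(role, x@channelRoles)
  if (is.na(i)) stop("no channel with role '", role, "'", call. = FALSE)
  x@samples[, i]
}

#' @describeIn signalBundle session metadata list.
#' @export
sessionMeta <- function(x) x@sessionMeta

setMethod("show", "SignalBundle", function(object) {
  cat("SignalBundle:", ncol(object@samples), "channel(s) [",
      paste(object@channelRoles, collapse = ", "), "]\n")
  cat(sprintf("  %d samples @ %g Hz (%.1f s)\n", nrow(object@samples),
              object@fs, nrow(object@samples) / object@fs))
  if (length(object@sessionMeta)) {
    cat("  meta:", paste(names(object@sessionMeta), collapse = ", "), "\n")
  }
})

#' Per-epoch sleep-state labels
#'
#' A `Hypnogram` is the sequence of sleep-state labels scored in fixed
#' epochs: `WAKE`/`NREM`/`INTERMEDIATE`/`REM` for natural-sleep (chronic)
#' recordings scored in 1-s epochs, or `NREM_LIKE`/`REM_LIKE`/`ARTIFACT`
#' for anesthetized (acute) recordings classified in 10-s epochs.
#'
#' @slot states character vector of per-epoch labels.
#' @slot epochS epoch duration, seconds.
#' @seealso [hypnogram()], [sleepArchitecture()], [classifySleepLike()].
#' @export
setClass("Hypnogram",
  representation(states = "character", epochS = "numeric")
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (length(object@epochS) != 1L || object@epochS <= 0) {
    msg <- c(msg, "epochS must be a single positive number")
  }
  bad <- setdiff(object@states, c(CHRONIC_STATES, ACUTE_STATES))
  if (length(bad)) {
    msg <- c(msg, paste0("unknown states: ", paste(unique(bad), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param states character vector of per-epoch state labels.
#' @param epochS seconds per epoch (1 for manually scored natural sleep,
#'   10 for the anesthesia classifier).
#' @return A [Hypnogram-class] object.
#' @examples
#' h <- hypnogram(c(rep("NREM", 10), rep("REM", 5)), epochS = 1)
#' states(h)
#' @export
hypnogram <- function(states, epochS = 1) {
  new("Hypnogram", states = as.character(states), epochS = epochS)
}

#' @describeIn hypnogram per-epoch state labels.
#' @param x a `Hypnogram`.
#' @export
states <- function(x) x@states

#' @describeIn hypnogram epoch duration in seconds.
#' @export
epochSeconds <- function(x) x@epochS

#' @describeIn hypnogram number of epochs.
#' @export
nEpochs <- function(x) length(x@states)

setMethod("show", "Hypnogram", function(object) {
  tab <- table(object@states)
  cat(sprintf("Hypnogram: %d epochs x %g s\n", length(object@states),
              object@epochS))
  for (s in names(tab)) {
    cat(sprintf("  %-13s %5d epochs (%.1f s)\n", s, tab[[s]],
                tab[[s]] * object@epochS))
  }
})

#' State bouts as time intervals
#'
#' Returns the maximal runs of a given state as half-open `[start, end)`
#' intervals in seconds.
#'
#' @param hyp a [Hypnogram-class].
#' @param state state label to extract.
#' @return data.frame with columns `start_s`, `end_s`.
#' @export
stateIntervals <- function(hyp, state) {
  r <- rle(states(hyp))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == state
  data.frame(start_s = starts[keep] * hyp@epochS,
             end_s = ends[keep] * hyp@epochS)
}
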