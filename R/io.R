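# File interchange: flat-binary signal bundles with JSON sidecars, and the
# CSV formats used for events, hypnograms, masks and ground truth.

#' Write / read a SignalBundle as flat binary + JSON sidecar
#'
#' The signal is stored as channel-interleaved little-endian signed 16-bit
#' integers in `<path>.dat`, with a JSON sidecar `<path>.json` recording
#' `fs`, `n_channels`, `channel_roles`, `units` and `scale_uV_per_count`
#' (one scale for all channels, chosen to span the full int16 range).
#'
#' @param bundle a [SignalBundle-class].
#' @param path file path without extension.
#' @return `writeSignalBundle` returns `path` invisibly;
#'   `readSignalBundle` returns the reconstructed [SignalBundle-class]
#'   (quantized to the stored resolution).
#' @export
writeSignalBundle <- function(bundle, path) {
  m <- bundle@samples
  peak <- max(abs(m), 1e-12)
  scale <- peak / 32000
  counts <- as.integer(round(t(m) / scale))  # channel-interleaved
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(counts, con, size = 2L, endian = "little")
  meta <- list(fs = bundle@fs, n_channels = ncol(m),
               channel_roles = bundle@channelRoles,
               units = "uV", scale_uV_per_count = scale,
               session_meta = bundle@sessionMeta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSignalBundle
#' @export
readSignalBundle <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sz <- file.info(paste0(path, ".dat"))$size
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  counts <- readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                    endian = "little")
  m <- t(matrix(counts * meta$scale_uV_per_count, nrow = meta$n_channels))
  signalBundle(m, meta$fs, meta$channel_roles,
               sessionMeta = as.list(meta$session_meta))
}

#' Write / read oscillation event tables
#'
#' Standard long CSV with one row per event:
#' `kind, context, channel_role, start_s, peak_s, end_s, duration_ms,
#' amplitude_uV, mean_freq_hz, length_class`.
#'
#' @param events event data.frame as emitted by the detectors.
#' @param path CSV path.
#' @export
writeEventsCsv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCsv
#' @export
readEventsCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a hypnogram as CSV (`epoch_index, state`)
#'
#' @param hyp a [Hypnogram-class].
#' @param path CSV path.
#' @param epochS epoch duration for `readHypnogramCsv`.
#' @export
writeHypnogramCsv <- function(hyp, path) {
  utils::write.csv(data.frame(epoch_index = seq_len(nEpochs(hyp)),
                              state = states(hyp)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHypnogramCsv
#' @export
readHypnogramCsv <- function(path, epochS = 1) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  hypnogram(d$state[order(d$epoch_index)], epochS)
}

#' Write a synthetic ground truth to CSV files
#'
#' Writes `<prefix>_events.csv` (kind, channel_role, start_s, peak_s,
#' end_s, amplitude_uV, frequency_hz) and `<prefix>_hypnogram.csv`.
#'
#' @param truth the `truth` element of [generateRecording()].
#' @param prefix output path prefix.
#' @export
writeGroundTruth <- function(truth, prefix) {
  ev <- truth$events
  names(ev)[names(ev) == "amplitude_uv"] <- "amplitude_uV"
  utils::write.csv(ev[, c("kind", "channel_role", "start_s", "peak_s",
                          "end_s", "amplitude_uV", "frequency_hz")],
                   paste0(prefix, "_events.csv"), row.names = FALSE)
  writeHypnogramCsv(truth$hypnogram, paste0(prefix, "_hypnogram.csv"))
  invisible(prefix)
}

#' Write an artifact mask as CSV (`start_s, end_s`)
#'
#' @param mask data.frame with `start_s`, `end_s`.
#' @param path CSV path.
#' @export
writeMaskCsv <- function(mask, path) {
  utils::write.csv(mask[, c("start_s", "end_s")], path, row.names = FALSE)
  invisible(path)
}
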