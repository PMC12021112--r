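#' In-memory recording segment
#'
#' A `recording_segment` holds a channels x samples matrix of extracellular
#' voltage in microvolts plus its sampling rate.  Row order follows
#' `channel_id` order of the accompanying probe map.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param sampling_rate Hz.
#' @param channel_ids integer channel ids for the rows (default 0..n-1).
#' @return a `recording_segment` object.
#' @export
recording_segment <- function(data, sampling_rate, channel_ids = NULL) {
  stopifnot(is.matrix(data), sampling_rate > 0)
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(data)) - 1L
  stopifnot(length(channel_ids) == nrow(data))
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_ids = as.integer(channel_ids)),
            class = "recording_segment")
}

#' @export
print.recording_segment <- function(x, ...) {
  cat(sprintf("<recording_segment> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Number of samples / duration of a segment
#' @param segment a `recording_segment`.
#' @return duration in seconds.
#' @export
segment_duration <- function(segment) ncol(segment$data) / segment$sampling_rate

channel_index <- function(segment, channel) {
  i <- match(channel, segment$channel_ids)
  if (any(is.na(i))) {
    stop("unknown channel id: ", paste(channel[is.na(i)], collapse = ", "))
  }
  i
}

#' Extract one channel's trace in microvolts
#' @param segment a `recording_segment`.
#' @param channel channel id.
#' @return numeric vector.
#' @export
channel_trace <- function(segment, channel) {
  segment$data[channel_index(segment, channel), ]
}

#' Write a recording as flat binary int16 plus a JSON sidecar
#'
#' Samples are stored interleaved in channel-major frame order (all channels
#' of sample 1, then sample 2, ...), signed 16-bit little-endian, quantised
#' at `gain_uv_per_bit` microvolts per bit.  The sidecar records the rate,
#' gain, channel count and ids, and an optional config echo.
#'
#' @param segment a `recording_segment`.
#' @param bin_path output binary path.
#' @param sidecar_path output JSON path.
#' @param gain_uv_per_bit quantisation step (default 0.2 uV/bit).
#' @param extra named list merged into the sidecar (e.g. seed, config echo).
#' @export
write_recording <- function(segment, bin_path, sidecar_path,
                            gain_uv_per_bit = 0.2, extra = list()) {
  q <- round(segment$data / gain_uv_per_bit)
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  # column-major write of channels x samples == channel-major frame order
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  sidecar <- c(list(
    n_channels = nrow(segment$data),
    sampling_rate_hz = segment$sampling_rate,
    gain_uv_per_bit = gain_uv_per_bit,
    dtype = "int16_le",
    channel_ids = segment$channel_ids
  ), extra)
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(bin_path)
}

#' Read a flat-binary recording via its JSON sidecar
#'
#' @param bin_path binary file path.
#' @param sidecar_path JSON sidecar path (declares channels, rate, gain).
#' @return a `recording_segment` in microvolts.
#' @export
read_recording <- function(bin_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  nch <- as.integer(side$n_channels)
  frame_bytes <- 2L * nch
  nbytes <- file.size(bin_path)
  if (nbytes %% frame_bytes != 0) {
    stop(sprintf("corrupt recording: %d bytes is not a multiple of the %d-byte frame (%d channels x int16)",
                 nbytes, frame_bytes, nch))
  }
  n_samp <- nbytes %/% frame_bytes
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nch * n_samp, size = 2L, signed = TRUE,
                 endian = "little")
  data <- matrix(raw * side$gain_uv_per_bit, nrow = nch, ncol = n_samp)
  recording_segment(data, side$sampling_rate_hz,
                    channel_ids = side$channel_ids %||% (seq_len(nch) - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
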