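#' Spike-LFP phase locking and gamma coherence mapping
#'
#' Spike-LFP coupling is the phase-locking value (PLV): the resultant length
#' of the unit phase vectors at spike times, with phases taken from the
#' analytic signal of the LFP filtered in a 5 Hz band centred on each
#' frequency of interest (30-200 Hz grid).  For display the adjacent four
#' pixels (the 2x2 column-pair block of one shank) are averaged.  Laminar
#' coherence maps band-pass the LFP with a Gaussian 30-90 Hz filter and
#' estimate magnitude-squared coherence against a reference channel from
#' interval-averaged cross-spectra over 100 one-second sharp-wave-ripple
#' windows.
#'
#' @name spectral_coupling
NULL

# Gaussian magnitude response over the full FFT frequency axis
gauss_response <- function(n, fs, center, sigma_f) {
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  exp(-(f - center)^2 / (2 * sigma_f^2))
}

#' Zero-phase Gaussian band-pass filter
#'
#' Frequency-domain filter with a Gaussian magnitude response centred on
#' the band midpoint whose half-amplitude points sit at the band edges.
#'
#' @param x signal vector.
#' @param fs sampling rate, Hz.
#' @param band c(low, high) Hz.
#' @return filtered signal.
#' @export
gaussian_bandpass <- function(x, fs, band) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  center <- mean(band)
  sigma_f <- (band[2] - band[1]) / (2 * sqrt(2 * log(2)))
  X <- stats::fft(x)
  Re(stats::fft(X * gauss_response(length(x), fs, center, sigma_f),
                inverse = TRUE)) / length(x)
}

# analytic (one-sided) narrow-band signal: Gaussian band centred on `center`
# with FWHM `bandwidth`, positive frequencies doubled, negatives zeroed
analytic_narrowband <- function(x, fs, center, bandwidth, X = NULL) {
  n <- length(x)
  if (is.null(X)) X <- stats::fft(x)
  sigma_f <- bandwidth / (2 * sqrt(2 * log(2)))
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  resp <- exp(-(f - center)^2 / (2 * sigma_f^2))
  mult <- numeric(n)
  pos <- f > 0 & f < fs / 2
  mult[pos] <- 2 * resp[pos]
  mult[1] <- 0
  if (n %% 2 == 0) mult[n / 2 + 1] <- resp[n / 2 + 1]
  stats::fft(X * mult, inverse = TRUE) / n
}

#' Instantaneous phase of the narrow-band LFP
#'
#' Zero-phase Gaussian narrow-band filter (FWHM `bandwidth_hz`) followed by
#' the analytic-signal phase.  The unwrapped phase of a pure tone at
#' `center_hz` advances at 2 pi center_hz rad/s.
#'
#' @param x signal vector.
#' @param fs sampling rate, Hz.
#' @param center_hz band centre, Hz.
#' @param bandwidth_hz band width, Hz (default 5).
#' @return phase series, radians in (-pi, pi].
#' @export
instantaneous_phase <- function(x, fs, center_hz, bandwidth_hz = 5) {
  if (center_hz - bandwidth_hz / 2 <= 0 || center_hz + bandwidth_hz / 2 >= fs / 2) {
    stop("band outside (0, Nyquist)")
  }
  Arg(analytic_narrowband(x, fs, center_hz, bandwidth_hz))
}

#' Resultant length of phases (PLV core)
#'
#' @param phases phase values, radians.
#' @return `|mean(exp(i phi))|` in [0, 1].
#' @export
resultant_length <- function(phases) {
  if (!length(phases)) stop("no phases")
  Mod(mean(exp(1i * phases)))
}

#' Phase-locking value of a spike train against a phase series
#'
#' Phases are looked up at the nearest sample to each spike time; spikes
#' outside the signal span are dropped.
#'
#' @param spike_times spike times, s.
#' @param phase phase series, radians.
#' @param fs sampling rate of the phase series, Hz.
#' @return PLV in [0, 1].
#' @export
plv <- function(spike_times, phase, fs) {
  idx <- round(spike_times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= length(phase)]
  if (!length(idx)) stop("no usable spikes inside the signal span")
  resultant_length(phase[idx])
}

#' Spike-LFP PLV map over channels and frequencies
#'
#' @param spike_times unit spike times, s.
#' @param segment a `recording_segment`.
#' @param map a `probe_map` covering the segment's channels.
#' @param freqs centre-frequency grid, Hz (default 30-200 in 5 Hz steps).
#' @param bandwidth_hz filter band width (default 5 Hz).
#' @param min_spikes refuse below this many spikes (PLV is biased upward at
#'   small n; default 200).
#' @param smooth average each value over its 2x2 lattice block (two columns
#'   x two adjacent rows of one shank).
#' @return a `plv_map`: list with `values` (channels x frequencies),
#'   `freqs`, `channel_ids`, `n_spikes`, `smoothed`.
#' @export
plv_map <- function(spike_times, segment, map,
                    freqs = seq(30, 200, by = 5), bandwidth_hz = 5,
                    min_spikes = 200, smooth = FALSE) {
  if (length(spike_times) < min_spikes) {
    stop("unit has fewer than ", min_spikes,
         " spikes; PLV would be unreliably biased")
  }
  fs <- segment$sampling_rate
  nch <- nrow(segment$data)
  idx <- round(spike_times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= ncol(segment$data)]
  vals <- matrix(NA_real_, nrow = nch, ncol = length(freqs),
                 dimnames = list(NULL, paste0("f", freqs)))
  for (ci in seq_len(nch)) {
    X <- stats::fft(segment$data[ci, ])
    for (fi in seq_along(freqs)) {
      a <- analytic_narrowband(segment$data[ci, ], fs, freqs[fi],
                               bandwidth_hz, X = X)
      vals[ci, fi] <- resultant_length(Arg(a[idx]))
    }
  }
  pm <- structure(list(values = vals, freqs = freqs,
                       channel_ids = segment$channel_ids,
                       n_spikes = length(idx), smoothed = FALSE),
                  class = "plv_map")
  if (smooth) smooth_plv_map(pm, map) else pm
}

#' Smooth a PLV map over 2x2 lattice blocks
#'
#' Each value is replaced by the mean of the four pixels in its block: the
#' two columns of the shank by two adjacent rows (rows 2k, 2k+1).
#'
#' @param pm a `plv_map`.
#' @param map a `probe_map`.
#' @return the smoothed `plv_map`.
#' @export
smooth_plv_map <- function(pm, map) {
  pos <- map[match(pm$channel_ids, map$channel_id), ]
  block <- paste(pos$shank, pos$row %/% 2L)
  out <- pm$values
  for (b in unique(block)) {
    rows <- which(block == b)
    out[rows, ] <- matrix(colMeans(pm$values[rows, , drop = FALSE]),
                          nrow = length(rows), ncol = ncol(out), byrow = TRUE)
  }
  pm$values <- out
  pm$smoothed <- TRUE
  pm
}

#' Select non-overlapping SWR-centred intervals
#'
#' Up to `n` windows of `duration_s` centred on ripple peaks, earliest
#' first, rejecting windows that overlap an already-selected one or leave
#' the recording.
#'
#' @param events ripple event-set data frame.
#' @param n maximum number of intervals (default 100).
#' @param duration_s window length (default 1 s).
#' @param recording_duration_s optional recording length for bounds checks.
#' @return data frame with `start`, `end` (s); fewer than `n` rows raises a
#'   warning.
#' @export
select_swr_intervals <- function(events, n = 100, duration_s = 1,
                                 recording_duration_s = NULL) {
  if (!nrow(events)) stop("empty event set")
  peaks <- sort(events$peak)
  out <- data.frame(start = numeric(0), end = numeric(0))
  for (p in peaks) {
    if (nrow(out) >= n) break
    a <- p - duration_s / 2
    b <- p + duration_s / 2
    if (a < 0) next
    if (!is.null(recording_duration_s) && b > recording_duration_s) next
    if (nrow(out) && any(a < out$end & b > out$start)) next
    out <- rbind(out, data.frame(start = a, end = b))
  }
  if (nrow(out) < n) {
    warning("only ", nrow(out), " of ", n, " requested intervals available")
  }
  out
}

#' Gamma-band coherence map against a reference channel
#'
#' All channels are Gaussian band-passed; magnitude-squared coherence with
#' the reference is estimated from interval-averaged cross-spectra (each
#' interval one mean-subtracted, Hann-tapered segment) and averaged over
#' the band.
#'
#' @param segment a `recording_segment`.
#' @param reference_channel channel id.
#' @param band c(low, high) Hz (default c(30, 90)).
#' @param intervals data frame with `start`, `end` (s); at least 2 rows,
#'   each at least 0.5 s.
#' @return a `coherence_map`: list with `values` (per channel, in [0, 1];
#'   exactly 1 for the reference), `channel_ids`, `reference_channel`,
#'   `band`, `n_intervals`.
#' @export
coherence_map <- function(segment, reference_channel, band = c(30, 90),
                          intervals) {
  if (nrow(intervals) < 2) {
    stop("coherence needs at least 2 intervals")
  }
  if (any(intervals$end - intervals$start < 0.5)) {
    stop("each interval must be at least 0.5 s")
  }
  fs <- segment$sampling_rate
  len <- min(round((intervals$end - intervals$start) * fs))
  starts <- pmax(1L, round(intervals$start * fs) + 1L)
  starts <- pmin(starts, ncol(segment$data) - len + 1L)
  nch <- nrow(segment$data)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
  fgrid <- seq(0, fs, length.out = len + 1)[seq_len(len)]
  pick <- fgrid >= band[1] & fgrid <= band[2]

  filt <- t(apply(segment$data, 1, gaussian_bandpass, fs = fs, band = band))
  ref_row <- channel_index(segment, reference_channel)
  Sxx <- matrix(0, nrow = nch, ncol = sum(pick))
  Sxy <- matrix(0 + 0i, nrow = nch, ncol = sum(pick))
  for (k in seq_along(starts)) {
    sl <- starts[k]:(starts[k] + len - 1L)
    seg <- filt[, sl, drop = FALSE]
    seg <- seg - rowMeans(seg)
    Fj <- t(apply(sweep(seg, 2, taper, `*`), 1,
                  function(v) stats::fft(v)[pick]))
    Sxx <- Sxx + Mod(Fj)^2
    Sxy <- Sxy + sweep(Fj, 2, Conj(Fj[ref_row, ]), `*`)
  }
  msc <- Mod(Sxy)^2 / sweep(Sxx, 2, Sxx[ref_row, ], `*`)
  vals <- rowMeans(msc)
  vals[ref_row] <- 1
  structure(list(values = vals, channel_ids = segment$channel_ids,
                 reference_channel = reference_channel, band = band,
                 n_intervals = length(starts)),
            class = "coherence_map")
}

#' Write a PLV or coherence map to CSV + JSON sidecar
#'
#' @param x a `plv_map` or `coherence_map`.
#' @param path CSV output path; axes metadata goes to `<path>.json`.
#' @export
write_coupling_csv <- function(x, path) {
  if (inherits(x, "plv_map")) {
    out <- data.frame(channel_id = x$channel_ids, x$values)
    meta <- list(kind = "plv_map", freqs_hz = x$freqs, n_spikes = x$n_spikes,
                 smoothed = x$smoothed)
  } else if (inherits(x, "coherence_map")) {
    out <- data.frame(channel_id = x$channel_ids, coherence = x$values)
    meta <- list(kind = "coherence_map",
                 reference_channel = x$reference_channel,
                 band_hz = x$band, n_intervals = x$n_intervals)
  } else stop("unsupported object")
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
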