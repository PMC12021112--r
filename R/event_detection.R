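#' Sharp-wave-ripple and dentate-spike detection
#'
#' Ripples are detected on a single pyramidal-layer channel from the
#' band-passed (80-250 Hz) LFP: the rectified, low-pass-smoothed envelope of
#' an amplitude-clipped copy supplies robust normalisation statistics, the
#' non-clipped envelope is thresholded at 4 SD, events are expanded to the
#' 1 SD crossings, and events shorter than 15 ms are discarded.  Dentate
#' spikes are positive deflections of the hilus-minus-molecular-layer LFP
#' difference (2-50 Hz) whose molecular-layer trace drops > 0.19 mV below
#' its own pre-event baseline (-36 to -16 ms).
#'
#' @name event_detection
NULL

#' Ripple detection parameters
#'
#' @param band band-pass edges, Hz (default c(80, 250)).
#' @param clip_sd amplitude clip for the normalisation envelope, in SD of
#'   the band-passed signal.
#' @param detect_sd detection threshold on the normalised envelope, SD.
#' @param expand_sd expansion threshold, SD.
#' @param min_duration_ms minimum event duration, ms.
#' @param cycles_p envelope-smoothing constant: the low-pass cutoff is the
#'   mean band-pass frequency divided by `cycles_p` cycles.
#' @return a `ripple_params` list.
#' @export
ripple_params <- function(band = c(80, 250), clip_sd = 4, detect_sd = 4,
                          expand_sd = 1, min_duration_ms = 15, cycles_p = 3) {
  stopifnot(band[1] > 0, band[2] > band[1], detect_sd > expand_sd,
            min_duration_ms > 0, cycles_p >= 1)
  structure(list(band = band, clip_sd = clip_sd, detect_sd = detect_sd,
                 expand_sd = expand_sd, min_duration_ms = min_duration_ms,
                 cycles_p = cycles_p), class = "ripple_params")
}

#' Dentate-spike detection parameters
#'
#' @param band band-pass edges, Hz.
#' @param baseline_window_ms baseline window relative to the event peak, ms
#'   (must precede the event).
#' @param mol_threshold_mv required molecular-layer drop below baseline, mV.
#' @param prominence_sd candidate screen: local maxima of the
#'   hilus-minus-molecular difference above this many SD of the difference.
#' @param event_halfwidth_ms half-width of the candidate event window around
#'   the difference peak, ms; the molecular-layer criterion averages over
#'   this crest so that the measured drop tracks the deflection amplitude.
#' @param min_separation_ms minimum separation between candidates, ms.
#' @return a `ds_params` list.
#' @export
ds_params <- function(band = c(2, 50), baseline_window_ms = c(-36, -16),
                      mol_threshold_mv = 0.19, prominence_sd = 2,
                      event_halfwidth_ms = 5, min_separation_ms = 100) {
  stopifnot(band[1] > 0, band[2] > band[1],
            baseline_window_ms[1] < baseline_window_ms[2],
            baseline_window_ms[2] < -event_halfwidth_ms + 1e-9)
  structure(list(band = band, baseline_window_ms = baseline_window_ms,
                 mol_threshold_mv = mol_threshold_mv,
                 prominence_sd = prominence_sd,
                 event_halfwidth_ms = event_halfwidth_ms,
                 min_separation_ms = min_separation_ms),
            class = "ds_params")
}

#' Envelope-smoothing low-pass cutoff
#'
#' The envelope low-pass cutoff corresponds to `cycles_p` cycles of the mean
#' band-pass frequency: `mean(band) / cycles_p`.  For the 80-250 Hz ripple
#' band with p = 3 this gives 55 Hz.
#'
#' @param band band-pass edges, Hz.
#' @param cycles_p number of cycles (>= 1).
#' @return cutoff frequency, Hz.
#' @export
#' @examples
#' ripple_lowpass_cutoff(c(80, 250), 3)  # 55
ripple_lowpass_cutoff <- function(band, cycles_p) {
  stopifnot(cycles_p >= 1)
  mean(band) / cycles_p
}

# zero-phase linear convolution with a symmetric kernel, reflection-padded
# edges, FFT-accelerated
fft_sym_filter <- function(x, kernel) {
  k <- length(kernel)
  if (k > length(x)) stop("filter kernel longer than the signal")
  half <- (k - 1L) %/% 2L
  pad <- if (half > 0) c(rev(x[2:(half + 1L)]), x,
                         rev(x[(length(x) - half):(length(x) - 1L)])) else x
  n <- length(pad)
  m <- stats::nextn(n + k - 1L, 2)
  X <- stats::fft(c(pad, numeric(m - n)))
  K <- stats::fft(c(kernel, numeric(m - k)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / m
  y[(2L * half + 1L):(2L * half + length(x))]
}

# gaussian kernel with -3 dB point at fc (Hz)
gauss_kernel <- function(fc, fs) {
  sigma_s <- sqrt(log(2)) / (2 * pi * fc)
  half <- max(1L, ceiling(4 * sigma_s * fs))
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma_s^2))
  k / sum(k)
}

#' High-pass a recording into the action-potential band
#'
#' Subtracts a zero-phase Gaussian low-pass (cutoff `cutoff_hz`) from every
#' channel, removing the LFP component.  Spike-waveform analyses (unit
#' footprints, trough timing) run on the high-passed segment, as spike
#' sorting pipelines do.
#'
#' @param segment a `recording_segment`.
#' @param cutoff_hz high-pass cutoff, Hz (default 300).
#' @return a `recording_segment` with the same channels and rate.
#' @export
highpass_segment <- function(segment, cutoff_hz = 300) {
  k <- gauss_kernel(cutoff_hz, segment$sampling_rate)
  out <- segment$data
  for (i in seq_len(nrow(out))) {
    out[i, ] <- out[i, ] - fft_sym_filter(out[i, ], k)
  }
  recording_segment(out, segment$sampling_rate, segment$channel_ids)
}

#' Difference-of-Gaussians band-pass filter (zero-lag FIR)
#'
#' The kernel is the difference of two Gaussian low-pass kernels with -3 dB
#' points at the band edges, normalised to unit gain at the band centre.
#' Being symmetric it is exactly linear-phase with zero group delay, and its
#' zero-sum construction rejects DC.
#'
#' @param x signal vector.
#' @param band c(low, high) Hz, within (0, Nyquist).
#' @param fs sampling rate, Hz.
#' @return filtered signal, same length as `x`.
#' @export
dog_bandpass <- function(x, band, fs) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  k_hi <- gauss_kernel(band[2], fs)   # narrow in time: passes up to band high
  k_lo <- gauss_kernel(band[1], fs)   # wide in time: passes up to band low
  half <- (length(k_lo) - 1L) %/% 2L
  pad <- function(k) c(numeric(half - (length(k) - 1L) %/% 2L), k,
                       numeric(half - (length(k) - 1L) %/% 2L))
  kern <- pad(k_hi) - k_lo
  kern <- kern - sum(kern) / length(kern)   # exact DC zero
  fc <- mean(band)
  tk <- (-half:half) / fs
  gain_c <- sum(kern * cos(2 * pi * fc * tk))
  kern <- kern / gain_c
  fft_sym_filter(x, kern)
}

# the envelope-smoothing kernel for the default ripple band (shared with
# the generator's amplitude calibration)
hippomap_env_kernel <- function(fs) {
  gauss_kernel(ripple_lowpass_cutoff(c(80, 250), 3), fs)
}

# rectified + low-pass-smoothed envelope of the band-passed signal;
# optionally amplitude-clipped at clip_sd * SD(band-passed) beforehand
ripple_envelope <- function(x_bp, fs, band, cycles_p, clip_sd = NULL) {
  if (!is.null(clip_sd)) {
    lim <- clip_sd * stats::sd(x_bp)
    x_bp <- pmin(pmax(x_bp, -lim), lim)
  }
  fft_sym_filter(abs(x_bp), gauss_kernel(ripple_lowpass_cutoff(band, cycles_p), fs))
}

# contiguous runs of a logical vector as (start, end) index pairs
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect sharp-wave ripples on one channel
#'
#' Pipeline: DoG band-pass; normalisation statistics (mean, SD) from the
#' envelope of the amplitude-clipped copy; the non-clipped envelope,
#' normalised by those statistics, is thresholded at `detect_sd`; events
#' are expanded to where the envelope falls below `expand_sd`, merged when
#' their expansions overlap, and discarded when shorter than
#' `min_duration_ms`.  The peak is the envelope maximum inside the event.
#'
#' @param segment a `recording_segment`.
#' @param channel channel id (pyramidal-layer site).
#' @param params a [ripple_params].
#' @return event-set data frame: `start`, `peak`, `end` (s), `score`
#'   (peak envelope, SD units), `class = "ripple"`.
#' @export
detect_ripples <- function(segment, channel, params = ripple_params()) {
  fs <- segment$sampling_rate
  x <- channel_trace(segment, channel)
  if (stats::sd(x) == 0) stop("silent/flat channel: SD is zero")
  bp <- dog_bandpass(x, params$band, fs)
  env_clip <- ripple_envelope(bp, fs, params$band, params$cycles_p,
                              clip_sd = params$clip_sd)
  env <- ripple_envelope(bp, fs, params$band, params$cycles_p)
  mu <- mean(env_clip)
  s <- stats::sd(env_clip)
  if (s == 0) stop("degenerate envelope: SD is zero")
  z <- (env - mu) / s

  det <- logical_runs(z > params$detect_sd)
  if (!nrow(det)) return(empty_event_set("ripple"))
  below <- z < params$expand_sd
  n <- length(z)
  iv <- matrix(NA_integer_, nrow = nrow(det), ncol = 4)
  for (i in seq_len(nrow(det))) {
    a <- det[i, 1]
    while (a > 1L && !below[a - 1L]) a <- a - 1L
    b <- det[i, 2]
    while (b < n && !below[b + 1L]) b <- b + 1L
    iv[i, ] <- c(a, b, det[i, 1], det[i, 2])
  }
  # merge events whose expansions overlap or touch; an event keeps the full
  # span of its suprathreshold cores
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    m <- nrow(merged)
    if (iv[i, 1] <= merged[m, 2] + 1L) {
      merged[m, 2] <- max(merged[m, 2], iv[i, 2])
      merged[m, 4] <- max(merged[m, 4], iv[i, 4])
    } else merged <- rbind(merged, iv[i, ])
  }
  # duration criterion on the suprathreshold span (first to last crossing of
  # the detection threshold): the expansion to expand_sd delimits the event
  # but a sub-criterion burst must not pass by envelope smearing alone
  core_ms <- (merged[, 4] - merged[, 3]) / fs * 1000
  merged <- merged[core_ms >= params$min_duration_ms, , drop = FALSE]
  if (!nrow(merged)) return(empty_event_set("ripple"))
  peak_i <- vapply(seq_len(nrow(merged)), function(i) {
    a <- merged[i, 1]; a + which.max(env[a:merged[i, 2]]) - 1L
  }, integer(1))
  data.frame(start = (merged[, 1] - 1L) / fs,
             peak = (peak_i - 1L) / fs,
             end = (merged[, 2] - 1L) / fs,
             score = z[peak_i],
             class = "ripple")
}

empty_event_set <- function(class) {
  data.frame(start = numeric(0), peak = numeric(0), end = numeric(0),
             score = numeric(0), class = character(0))
}

#' Detect dentate spikes from a hilus / molecular-layer channel pair
#'
#' Both channels are band-passed (2-50 Hz); local maxima of the
#' hilus-minus-molecular difference above `prominence_sd` SD are candidates;
#' a candidate passes only if the mean molecular-layer LFP inside the event
#' window is lower than its own mean over the baseline window by more than
#' `mol_threshold_mv`.  The reported peak time is the maximum of the
#' wide-band hilus LFP inside the candidate window.
#'
#' @param segment a `recording_segment`.
#' @param hilus_channel,molecular_channel distinct channel ids.
#' @param params a [ds_params].
#' @return event-set data frame (`start`, `peak`, `end` s, `score` = the
#'   molecular-layer drop in mV, `class = "dentate_spike"`).
#' @export
detect_dentate_spikes <- function(segment, hilus_channel, molecular_channel,
                                  params = ds_params()) {
  if (hilus_channel == molecular_channel) {
    stop("hilus and molecular channels must differ")
  }
  fs <- segment$sampling_rate
  hil_raw <- channel_trace(segment, hilus_channel)
  mol_raw <- channel_trace(segment, molecular_channel)
  hil <- dog_bandpass(hil_raw, params$band, fs)
  mol <- dog_bandpass(mol_raw, params$band, fs)
  dif <- hil - mol
  thr <- params$prominence_sd * stats::sd(dif)
  runs <- logical_runs(dif > thr)
  if (!nrow(runs)) return(empty_event_set("dentate_spike"))
  cand <- vapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, 1]; a + which.max(dif[a:runs[i, 2]]) - 1L
  }, integer(1))
  # enforce minimum separation, keeping the larger peak
  if (length(cand) > 1) {
    keep <- rep(TRUE, length(cand))
    for (i in 2:length(cand)) {
      j <- max(which(keep[1:(i - 1)]))
      if ((cand[i] - cand[j]) / fs * 1000 < params$min_separation_ms) {
        if (dif[cand[i]] > dif[cand[j]]) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
    cand <- cand[keep]
  }
  hw <- round(params$event_halfwidth_ms / 1000 * fs)
  b0 <- round(params$baseline_window_ms[1] / 1000 * fs)
  b1 <- round(params$baseline_window_ms[2] / 1000 * fs)
  n <- length(dif)
  out <- empty_event_set("dentate_spike")
  skipped <- 0L
  for (p in cand) {
    if (p + b0 < 1L) { skipped <- skipped + 1L; next }
    a <- max(1L, p - hw); b <- min(n, p + hw)
    ev_mean <- mean(mol[a:b])
    base_mean <- mean(mol[(p + b0):(p + b1)])
    drop_mv <- (base_mean - ev_mean) / 1000
    if (drop_mv > params$mol_threshold_mv) {
      pk <- a + which.max(hil_raw[a:b]) - 1L
      out <- rbind(out, data.frame(start = (a - 1L) / fs, peak = (pk - 1L) / fs,
                                   end = (b - 1L) / fs, score = drop_mv,
                                   class = "dentate_spike"))
    }
  }
  if (skipped > 0) {
    warning(skipped, " candidate(s) skipped: baseline window precedes recording start")
  }
  out
}

#' Write / read an event set as CSV
#'
#' Columns: `start_s`, `peak_s`, `end_s`, `score`, `class`.
#'
#' @param events event-set data frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(start_s = events$start, peak_s = events$peak,
                    end_s = events$end, score = events$score,
                    class = events$class)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- utils::read.csv(path)
  data.frame(start = x$start_s, peak = x$peak_s, end = x$end_s,
             score = x$score, class = x$class)
}
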