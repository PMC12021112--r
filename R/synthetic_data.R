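#' Synthetic multi-shank recordings with ground truth
#'
#' The generator emulates the statistical structure every downstream stage
#' assumes: layered LFP oscillations, sharp-wave ripples and dentate spikes
#' with known times and depth profiles, unit spike trains with spatial
#' waveform footprints (distance-dependent amplitude decay and linear trough
#' delays housing the backpropagation ground truth), von-Mises phase-locked
#' spiking against laminar gamma sources, and band-limited background noise
#' at the probe's measured RMS figures.
#'
#' @name synthetic_data
NULL

#' Default laminar row assignment for an n-row shank
#'
#' Fractional depth ranges, top to tip: CA1 stratum pyramidale, radiatum,
#' lacunosum-moleculare, dentate molecular layer, hilus.
#'
#' @param n_rows rows per shank.
#' @return named list of integer row vectors.
#' @export
default_layer_rows <- function(n_rows = 64L) {
  rng <- function(a, b) {
    lo <- max(0L, round(a * (n_rows - 1)))
    hi <- min(n_rows - 1L, round(b * (n_rows - 1)))
    seq.int(lo, hi)
  }
  list(pyramidale = rng(0.20, 0.27),
       radiatum   = rng(0.31, 0.45),
       lacunosum  = rng(0.47, 0.55),
       molecular  = rng(0.60, 0.70),
       hilus      = rng(0.76, 0.86))
}

#' Specify a simulated single unit
#'
#' @param soma_channel channel id of the soma site.
#' @param peak_amplitude peak-to-peak waveform amplitude at the soma, uV
#'   (default 82, the typical extracellular spike amplitude).
#' @param amplitude_length_constant spatial decay constant of the waveform
#'   amplitude with Euclidean distance from the soma, um.
#' @param slope_above,slope_below trough-delay slope (ms/mm) for channels
#'   above / below the soma; the inverse of the backpropagation speed.
#' @param trough_to_peak waveform trough-to-peak time, ms.
#' @param firing_rate mean rate, Hz.
#' @param kappa von Mises concentration of spike phases w.r.t. the
#'   designated gamma source (0 = uncoupled).
#' @param gamma_source index into the config's `gamma_specs` (NA = none).
#' @param phase_mu preferred phase, radians.
#' @param ripple_gain multiplicative firing-rate gain inside ripple events.
#' @return a `unit_spec` list.
#' @export
unit_spec <- function(soma_channel, peak_amplitude = 82,
                      amplitude_length_constant = 60,
                      slope_above = 0.5, slope_below = 0.5,
                      trough_to_peak = 0.6, firing_rate = 5,
                      kappa = 0, gamma_source = NA_integer_,
                      phase_mu = 0, ripple_gain = 1) {
  stopifnot(peak_amplitude > 0, firing_rate >= 0, kappa >= 0,
            trough_to_peak > 0, amplitude_length_constant > 0,
            ripple_gain >= 0)
  structure(list(soma_channel = soma_channel,
                 peak_amplitude = peak_amplitude,
                 amplitude_length_constant = amplitude_length_constant,
                 slope_above = slope_above, slope_below = slope_below,
                 trough_to_peak = trough_to_peak, firing_rate = firing_rate,
                 kappa = kappa, gamma_source = gamma_source,
                 phase_mu = phase_mu, ripple_gain = ripple_gain),
            class = "unit_spec")
}

#' Specify a laminar gamma oscillation source
#'
#' @param freq_hz centre frequency, Hz.
#' @param amplitude_uv oscillation amplitude, uV.
#' @param rows integer rows (within every shank) carrying the oscillation.
#' @param shanks shank indices carrying it (NULL = all).
#' @return a `gamma_spec` list.
#' @export
gamma_spec <- function(freq_hz, amplitude_uv, rows, shanks = NULL) {
  stopifnot(freq_hz > 0, amplitude_uv >= 0, length(rows) >= 1)
  structure(list(freq_hz = freq_hz, amplitude_uv = amplitude_uv,
                 rows = as.integer(rows), shanks = shanks),
            class = "gamma_spec")
}

#' Build a simulation configuration
#'
#' Defaults are the probe's measured operating conditions: 20 kS/s per
#' channel, 16.45 uV RMS background in the LFP band (0.1-300 Hz) and
#' 6.67 uV RMS in the AP band (300-5000 Hz), 150 Hz ripples of ~60 ms, and
#' ripple amplitude expressed as an in-band signal-to-noise ratio of 6
#' (calibrated at run time against the generator's own band-passed noise).
#'
#' @param probe a `probe_map` (default: the full 8-shank 1024-channel map).
#' @param sampling_rate Hz.
#' @param duration seconds.
#' @param seed RNG seed (integer).
#' @param lfp_noise_rms background RMS in 0.1-300 Hz, uV.
#' @param ap_noise_rms background RMS in 300-5000 Hz, uV.
#' @param ripple_rate events/s (ignored when `ripple_times` given).
#' @param ripple_times optional explicit ripple peak times, s.
#' @param ripple_freq ripple oscillation frequency, Hz.
#' @param ripple_duration_ms ripple envelope duration (~6 sigma), ms.
#' @param ripple_snr in-band signal-to-noise ratio of injected ripples: the
#'   peak ripple amplitude on the calibration (mid-pyramidale) channel in
#'   units of the SD of the 80-250 Hz band-passed background there.
#' @param sharp_wave_amp_uv depth of the concurrent negative radiatum
#'   sharp wave, uV.
#' @param ds_rate dentate-spike rate, events/s (ignored when `ds_times`).
#' @param ds_times optional explicit dentate-spike peak times, s.
#' @param ds_hilus_amp_mv positive hilar deflection amplitude, mV.
#' @param ds_mol_amp_mv molecular-layer (opposite-sign) deflection, mV;
#'   the detection criterion requires > 0.19 mV.
#' @param ds_duration_ms dentate-spike envelope duration, ms.
#' @param layer_rows named list of row ranges (see [default_layer_rows]).
#' @param unit_specs list of [unit_spec].
#' @param gamma_specs list of [gamma_spec].
#' @return a validated `simulation_config`.
#' @export
simulation_config <- function(probe = build_default_probe_map(),
                              sampling_rate = 20000, duration = 10,
                              seed = 1L,
                              lfp_noise_rms = 16.45, ap_noise_rms = 6.67,
                              ripple_rate = 0, ripple_times = NULL,
                              ripple_freq = 150, ripple_duration_ms = 60,
                              ripple_snr = 6, sharp_wave_amp_uv = 150,
                              ds_rate = 0, ds_times = NULL,
                              ds_hilus_amp_mv = 0.5, ds_mol_amp_mv = 0.30,
                              ds_duration_ms = 40,
                              layer_rows = NULL,
                              unit_specs = list(), gamma_specs = list()) {
  stopifnot(inherits(probe, "probe_map"), duration > 0, sampling_rate > 0)
  nyq <- sampling_rate / 2
  if (is.null(layer_rows)) layer_rows <- default_layer_rows(max(probe$row) + 1L)
  row_span <- range(probe$row)
  for (nm in names(layer_rows)) {
    r <- layer_rows[[nm]]
    if (any(r < row_span[1] | r > row_span[2])) {
      stop("layer_rows$", nm, " outside the probe's row span")
    }
  }
  if (length(ripple_times) || ripple_rate > 0) {
    if (ripple_freq >= nyq) stop("ripple_freq >= Nyquist")
  }
  for (g in gamma_specs) {
    if (!inherits(g, "gamma_spec")) stop("gamma_specs must be gamma_spec objects")
    if (g$freq_hz >= nyq) stop("gamma frequency >= Nyquist")
  }
  for (u in unit_specs) {
    if (!inherits(u, "unit_spec")) stop("unit_specs must be unit_spec objects")
    if (!u$soma_channel %in% probe$channel_id) {
      stop("unit soma_channel not in probe map: ", u$soma_channel)
    }
    if (u$kappa > 0 && is.na(u$gamma_source)) {
      stop("unit with kappa > 0 needs a gamma_source")
    }
    if (!is.na(u$gamma_source) &&
        (u$gamma_source < 1 || u$gamma_source > length(gamma_specs))) {
      stop("unit gamma_source index out of range")
    }
  }
  structure(list(probe = probe, sampling_rate = sampling_rate,
                 duration = duration, seed = as.integer(seed),
                 lfp_noise_rms = lfp_noise_rms, ap_noise_rms = ap_noise_rms,
                 ripple_rate = ripple_rate, ripple_times = ripple_times,
                 ripple_freq = ripple_freq,
                 ripple_duration_ms = ripple_duration_ms,
                 ripple_snr = ripple_snr,
                 sharp_wave_amp_uv = sharp_wave_amp_uv,
                 ds_rate = ds_rate, ds_times = ds_times,
                 ds_hilus_amp_mv = ds_hilus_amp_mv,
                 ds_mol_amp_mv = ds_mol_amp_mv,
                 ds_duration_ms = ds_duration_ms,
                 layer_rows = layer_rows,
                 unit_specs = unit_specs, gamma_specs = gamma_specs),
            class = "simulation_config")
}

#' Von Mises random phases
#'
#' Best-Fisher rejection sampler.  The population resultant length of a
#' von Mises sample converges to the Bessel ratio I1(kappa)/I0(kappa).
#'
#' @param n sample size (>= 0).
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @param mu preferred direction, radians.
#' @param seed optional integer seed (NULL = use the current RNG stream).
#' @return numeric vector of phases in (-pi, pi].
#' @export
spike_phases_von_mises <- function(n, kappa, mu = 0, seed = NULL) {
  if (kappa < 0) stop("kappa must be >= 0")
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    keep <- theta[ok]
    take <- min(length(keep), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- keep[seq_len(take)]
    got <- got + take
  }
  ph <- out + mu
  atan2(sin(ph), cos(ph))
}

#' Band-limited Gaussian noise with a target RMS
#'
#' White Gaussian noise restricted in the frequency domain to `band` and
#' rescaled so its standard deviation equals `rms`.  The band is intersected
#' with (0, Nyquist); an empty intersection yields zeros.
#'
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param band c(low, high), Hz.
#' @param rms target RMS, signal units.
#' @return numeric vector of length n.
#' @export
band_limited_noise <- function(n, fs, band, rms) {
  if (rms <= 0) return(numeric(n))
  nyq <- fs / 2
  lo <- max(band[1], 0)
  hi <- min(band[2], nyq)
  if (hi <= lo) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)            # absolute frequency of each bin
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * (rms / s)
}

#' Band-limited RMS from the power spectral density
#'
#' Integrates the one-sided periodogram PSD of one channel over a frequency
#' band; by Parseval this equals the RMS of the band-limited signal.
#'
#' @param segment a `recording_segment`.
#' @param channel channel id.
#' @param band c(low, high) Hz, within (0, Nyquist].
#' @return RMS in uV.
#' @export
band_rms <- function(segment, channel, band) {
  fs <- segment$sampling_rate
  if (band[1] < 0 || band[2] > fs / 2 || band[2] <= band[1]) {
    stop("band must lie within (0, Nyquist]")
  }
  x <- channel_trace(segment, channel)
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  pick <- f >= band[1] & f <= band[2]
  sqrt(sum(Mod(X[pick])^2) / n^2)
}

# continuous biphasic spike template (ms in, uV out): negative trough at 0,
# positive peak at t2p; scaled so soma peak-to-peak == p2p
spike_template <- function(t_ms, t2p_ms, p2p_uv) {
  s1 <- max(0.06, min(0.25 * t2p_ms, 0.12))
  s2 <- max(0.10, 0.35 * t2p_ms)
  trough <- p2p_uv / 1.35
  -trough * exp(-t_ms^2 / (2 * s1^2)) +
    0.35 * trough * exp(-(t_ms - t2p_ms)^2 / (2 * s2^2))
}

# draw event peak times: explicit times pass through; otherwise Poisson count
# at `rate`, placed uniformly with a minimum separation, inside margins
draw_event_times <- function(times, rate, duration, min_sep, margin) {
  if (!is.null(times)) return(sort(times))
  n <- stats::rpois(1, rate * duration)
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 200L * n) {
    cand <- stats::runif(1, margin, duration - margin)
    if (!length(out) || min(abs(out - cand)) >= min_sep) out <- c(out, cand)
    tries <- tries + 1L
  }
  sort(out)
}

# gaussian weight of each probe row over a row range (centre +- half-width)
row_profile <- function(rows_all, rows_on) {
  ctr <- mean(range(rows_on))
  sig <- max(diff(range(rows_on)) / 4, 0.75)
  w <- exp(-(rows_all - ctr)^2 / (2 * sig^2))
  w[!(rows_all %in% rows_on)] <- w[!(rows_all %in% rows_on)] *
    (abs(rows_all[!(rows_all %in% rows_on)] - ctr) < 2.5 * sig)
  w
}

#' Simulate a ground-truthed recording
#'
#' Returns the sum of (i) band-limited background noise at the configured
#' LFP- and AP-band RMS, (ii) ripple events — a `ripple_freq` sinusoid
#' under a Gaussian envelope on pyramidale rows plus a concurrent negative
#' sharp wave on radiatum rows (a radiatum sink flanked by sources in CSD),
#' (iii) dentate spikes — positive hilar deflection with an opposite-sign
#' molecular-layer deflection, (iv) laminar gamma oscillations, and (v) unit
#' spike waveforms whose amplitude decays exponentially with distance from
#' the soma and whose trough times shift linearly with axial distance.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config].
#' @return list with `segment` (a `recording_segment`) and `truth` — ripple
#'   (start, peak, end), dentate-spike peak times, per-unit spike times and
#'   ground-truth parameters, and per-gamma-source initial phases.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  probe <- config$probe
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  nch <- nrow(probe)
  set.seed(config$seed)

  data <- matrix(0, nrow = nch, ncol = n)
  for (i in seq_len(nch)) {
    data[i, ] <- band_limited_noise(n, fs, c(0.1, 300), config$lfp_noise_rms) +
      band_limited_noise(n, fs, c(300, 5000), config$ap_noise_rms)
  }
  tt <- (seq_len(n) - 1) / fs

  truth <- list(ripples = data.frame(start = numeric(0), peak = numeric(0),
                                     end = numeric(0)),
                ds_times = numeric(0), units = list(), gamma = list())

  layer <- config$layer_rows
  rows_all <- probe$row

  ## --- sharp-wave ripples ------------------------------------------------
  rip_dur_s <- config$ripple_duration_ms / 1000
  rip_times <- draw_event_times(config$ripple_times, config$ripple_rate,
                                config$duration,
                                min_sep = 4 * rip_dur_s,
                                margin = 2 * rip_dur_s)
  if (length(rip_times)) {
    # burst envelope: ~95% of the event's mass inside the nominal duration
    sig_t <- rip_dur_s / 4
    w_pyr <- row_profile(rows_all, layer$pyramidale)
    w_rad <- row_profile(rows_all, layer$radiatum)
    # ripple_snr is the in-band signal-to-noise ratio: the ripple's peak
    # amplitude on the calibration (mid-pyramidale) channel in units of the
    # SD of the 80-250 Hz band-passed background there
    pyr_ctr <- round(mean(range(layer$pyramidale)))
    cal_ch <- probe$channel_id[probe$row == pyr_ctr & probe$column == 0][1]
    w_cal <- w_pyr[match(cal_ch, probe$channel_id)]
    noise_cal <- data[match(cal_ch, probe$channel_id), ]
    amp <- config$ripple_snr *
      stats::sd(dog_bandpass(noise_cal, c(80, 250), fs)) / w_cal
    for (t0 in rip_times) {
      idx <- which(tt >= t0 - 3.5 * sig_t * 2 & tt <= t0 + 3.5 * sig_t * 2)
      dt <- tt[idx] - t0
      osc <- amp * exp(-dt^2 / (2 * sig_t^2)) * cos(2 * pi * config$ripple_freq * dt)
      sw <- -config$sharp_wave_amp_uv * exp(-dt^2 / (2 * (2 * sig_t)^2))
      data[, idx] <- data[, idx] + outer(w_pyr, osc) + outer(w_rad, sw)
    }
    truth$ripples <- data.frame(start = rip_times - rip_dur_s / 2,
                                peak = rip_times,
                                end = rip_times + rip_dur_s / 2)
  }

  ## --- dentate spikes ----------------------------------------------------
  ds_dur_s <- config$ds_duration_ms / 1000
  ds_times <- draw_event_times(config$ds_times, config$ds_rate,
                               config$duration,
                               min_sep = 0.25, margin = 0.1)
  if (length(ds_times)) {
    sig_t <- ds_dur_s / 5
    w_hil <- row_profile(rows_all, layer$hilus)
    w_mol <- row_profile(rows_all, layer$molecular)
    for (t0 in ds_times) {
      idx <- which(tt >= t0 - 4 * sig_t & tt <= t0 + 4 * sig_t)
      dt <- tt[idx] - t0
      env <- exp(-dt^2 / (2 * sig_t^2))
      data[, idx] <- data[, idx] +
        outer(w_hil, 1000 * config$ds_hilus_amp_mv * env) -
        outer(w_mol, 1000 * config$ds_mol_amp_mv * env)
    }
    truth$ds_times <- ds_times
  }

  ## --- laminar gamma sources ---------------------------------------------
  for (gi in seq_along(config$gamma_specs)) {
    g <- config$gamma_specs[[gi]]
    phi0 <- stats::runif(1, -pi, pi)
    on <- probe$row %in% g$rows
    if (!is.null(g$shanks)) on <- on & probe$shank %in% g$shanks
    osc <- g$amplitude_uv * sin(2 * pi * g$freq_hz * tt + phi0)
    data[on, ] <- sweep(data[on, , drop = FALSE], 2, osc, `+`)
    truth$gamma[[gi]] <- list(freq_hz = g$freq_hz, phi0 = phi0,
                              rows = g$rows, shanks = g$shanks)
  }

  ## --- units --------------------------------------------------------------
  margin <- 0.01
  for (ui in seq_along(config$unit_specs)) {
    u <- config$unit_specs[[ui]]
    n_sp <- stats::rpois(1, u$firing_rate * config$duration)
    if (u$kappa > 0 || !is.na(u$gamma_source)) {
      g <- truth$gamma[[u$gamma_source]]
      ph <- spike_phases_von_mises(n_sp, u$kappa, u$phase_mu)
      # analytic phase of sin(wt + phi0) is wt + phi0 - pi/2; invert for t
      cyc <- floor(stats::runif(n_sp, margin * g$freq_hz,
                                (config$duration - margin) * g$freq_hz))
      st <- (ph + pi / 2 - g$phi0) / (2 * pi * g$freq_hz) + cyc / g$freq_hz
      st <- st[st > margin & st < config$duration - margin]
    } else {
      st <- stats::runif(n_sp, margin, config$duration - margin)
    }
    if (u$ripple_gain != 1 && nrow(truth$ripples)) {
      extra <- numeric(0)
      for (k in seq_len(nrow(truth$ripples))) {
        a <- truth$ripples$start[k]; b <- truth$ripples$end[k]
        m <- stats::rpois(1, max(0, (u$ripple_gain - 1)) * u$firing_rate * (b - a))
        extra <- c(extra, stats::runif(m, a, b))
      }
      st <- c(st, extra)
    }
    st <- sort(st)
    if (length(st) > 1) st <- st[c(TRUE, diff(st) > 0.0015)]  # 1.5 ms refractory

    soma_i <- match(u$soma_channel, probe$channel_id)
    d <- sqrt((probe$x - probe$x[soma_i])^2 + (probe$y - probe$y[soma_i])^2)
    rel <- exp(-d / u$amplitude_length_constant)
    stamp <- which(rel >= 0.02)
    dy_mm <- (probe$y - probe$y[soma_i]) / 1000
    delay_ms <- ifelse(dy_mm < 0, u$slope_above * abs(dy_mm),
                       u$slope_below * dy_mm)
    half_w <- round(0.003 * fs)          # 3 ms stamping half-window
    for (t0 in st) {
      i0 <- round(t0 * fs) + 1L
      idx <- max(1L, i0 - half_w):min(n, i0 + half_w)
      t_ms <- (tt[idx] - t0) * 1000
      for (ci in stamp) {
        data[ci, idx] <- data[ci, idx] +
          rel[ci] * spike_template(t_ms - delay_ms[ci], u$trough_to_peak,
                                   u$peak_amplitude)
      }
    }
    truth$units[[ui]] <- list(unit_id = ui, spike_times = st,
                              soma_channel = u$soma_channel,
                              slope_above = u$slope_above,
                              slope_below = u$slope_below,
                              trough_to_peak = u$trough_to_peak,
                              peak_amplitude = u$peak_amplitude,
                              kappa = u$kappa, gamma_source = u$gamma_source,
                              phase_mu = u$phase_mu,
                              ripple_gain = u$ripple_gain)
  }

  list(segment = recording_segment(data, fs, channel_ids = probe$channel_id),
       truth = truth)
}

#' Write ground truth and spike times to disk
#'
#' Ground truth goes to JSON; spike times additionally to a two-column CSV
#' (`time_s`, `unit_id`), the same layout the pipeline accepts as input.
#'
#' @param truth the `truth` element of [simulate_recording] output.
#' @param json_path output JSON path (NULL to skip).
#' @param spikes_csv_path output CSV path (NULL to skip).
#' @export
write_ground_truth <- function(truth, json_path = NULL,
                               spikes_csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(spikes_csv_path)) {
    tab <- do.call(rbind, lapply(truth$units, function(u) {
      data.frame(time_s = u$spike_times, unit_id = u$unit_id)
    }))
    if (is.null(tab)) tab <- data.frame(time_s = numeric(0),
                                        unit_id = integer(0))
    tab <- tab[order(tab$time_s), ]
    utils::write.csv(tab, spikes_csv_path, row.names = FALSE)
  }
  invisible(NULL)
}
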