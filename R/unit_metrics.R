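#' Single-unit waveform and spike-train metrics
#'
#' Cell types follow a cascade: narrow interneuron if the waveform
#' trough-to-peak latency is below 0.425 ms; wide interneuron if the latency
#' is at or above 0.425 ms and the autocorrelogram rise time (tau_rise of a
#' triple-exponential fit) exceeds 6 ms; pyramidal otherwise.  Bursts are
#' maximal runs of spikes with inter-spike intervals under 9 ms.  The soma
#' is localised at the channel with the largest peak-to-peak mean waveform.
#'
#' @name unit_metrics
NULL

#' Construct a unit footprint
#'
#' @param waveform channels x samples mean waveform, uV.
#' @param t_ms sample-time axis relative to the soma trough, ms.
#' @param channel_ids channel ids of the rows.
#' @param spike_times spike times, s.
#' @param unit_id identifier.
#' @return a `unit_footprint`; `peak_channel` is the channel maximising the
#'   peak-to-peak amplitude (ties break to the lowest channel id).
#' @export
unit_footprint <- function(waveform, t_ms, channel_ids, spike_times = numeric(0),
                           unit_id = NA_integer_) {
  stopifnot(is.matrix(waveform), ncol(waveform) == length(t_ms),
            nrow(waveform) == length(channel_ids))
  p2p <- apply(waveform, 1, function(w) max(w) - min(w))
  ord <- order(-p2p, channel_ids)
  structure(list(unit_id = unit_id, waveform = waveform, t_ms = t_ms,
                 channel_ids = as.integer(channel_ids),
                 spike_times = spike_times,
                 peak_channel = as.integer(channel_ids[ord[1]])),
            class = "unit_footprint")
}

#' Spike-triggered mean waveform across channels
#'
#' @param segment a `recording_segment`.
#' @param spike_times spike times, s.
#' @param window_ms waveform window around the spike time, ms
#'   (default 1 ms before to 2 ms after).
#' @param unit_id identifier carried into the footprint.
#' @return a [unit_footprint].
#' @export
extract_footprint <- function(segment, spike_times, window_ms = c(-1, 2),
                              unit_id = NA_integer_) {
  avg <- event_triggered_average(segment, spike_times, window_ms)
  unit_footprint(avg$data, avg$lag_ms, avg$channel_ids,
                 spike_times = spike_times, unit_id = unit_id)
}

# parabolic (3-point) interpolation of an extremum position/value
parabolic_peak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(list(pos = i, val = y[i]))
  d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  list(pos = i + d, val = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d)
}

#' Waveform trough-to-peak latency
#'
#' Time from the waveform minimum to the subsequent maximum on the peak
#' channel, with parabolic sub-sample refinement.
#'
#' @param footprint a [unit_footprint].
#' @return latency, ms.
#' @export
trough_to_peak <- function(footprint) {
  w <- footprint$waveform[match(footprint$peak_channel,
                                footprint$channel_ids), ]
  it <- which.min(w)
  if (w[it] >= 0) stop("waveform has no negative trough on the peak channel")
  if (it >= length(w) - 1L) stop("no post-trough maximum within the window")
  post <- w[(it + 1L):length(w)]
  # the after-hyperpolarisation peak must be a genuine positive deflection,
  # not the decaying tail of the trough itself
  if (max(post) <= 0.05 * abs(w[it])) {
    stop("no post-trough maximum within the window")
  }
  ip <- it + which.max(post)
  dt <- footprint$t_ms[2] - footprint$t_ms[1]
  (parabolic_peak(w, ip)$pos - parabolic_peak(w, it)$pos) * dt
}

#' Spike-train autocorrelogram
#'
#' Counts of positive spike-time lags per bin up to `span_ms`.
#'
#' @param spike_times sorted spike times, s.
#' @param bin_ms bin width, ms.
#' @param span_ms maximum lag, ms.
#' @return data frame with `lag_ms` (bin centres) and `count`.
#' @export
spike_acg <- function(spike_times, bin_ms = 0.5, span_ms = 50) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted ascending")
  span_s <- span_ms / 1000
  lags <- numeric(0)
  k <- 1L
  repeat {
    if (k >= length(spike_times)) break
    d <- diff(spike_times, lag = k)
    d <- d[d < span_s]
    if (!length(d)) break
    lags <- c(lags, d)
    k <- k + 1L
  }
  breaks <- seq(0, span_ms, by = bin_ms)
  h <- graphics::hist(lags * 1000, breaks = breaks, plot = FALSE)
  data.frame(lag_ms = h$mids, count = h$counts)
}

#' Triple-exponential autocorrelogram fit
#'
#' Least-squares fit of
#' `acg(t) = max(c (exp(-(t-t0)/tau_decay) - d exp(-(t-t0)/tau_rise))
#'            + h exp(-(t-t0)/tau_burst) + r, 0)`
#' to the autocorrelogram expressed as a rate (Hz), from a deterministic
#' start with box constraints (L-BFGS-B).  `tau_rise` is the rise-time
#' statistic used by the cell-type cascade; a failed fit returns NaN and the
#' unit falls through to the waveform-only rule.  When the fitted curve has
#' no suppression dip (a flat autocorrelogram leaves the rise parameter
#' unconstrained), the rise time is reported as 0.
#'
#' @param spike_times sorted spike times, s.
#' @param bin_ms,span_ms autocorrelogram resolution and span.
#' @param min_spikes refuse the fit below this many spikes (default 500).
#' @return an `acg_fit` list: `tau_rise`, `tau_decay`, `tau_burst`, `t0`,
#'   amplitudes `c_amp`, `d_amp`, `h_amp`, asymptote `r`, `fitted`,
#'   `acg` (the histogram), `converged`.
#' @export
fit_acg_triple_exponential <- function(spike_times, bin_ms = 0.5,
                                       span_ms = 50, min_spikes = 500) {
  if (length(spike_times) < min_spikes) {
    stop("need at least ", min_spikes, " spikes for a stable ACG fit")
  }
  acg <- spike_acg(spike_times, bin_ms, span_ms)
  # counts -> conditional rate (Hz)
  y <- acg$count / (length(spike_times) * bin_ms / 1000)
  t <- acg$lag_ms
  model <- function(p) {
    pmax(p["c"] * (exp(-(t - p["t0"]) / p["tau_d"]) -
                   p["d"] * exp(-(t - p["t0"]) / p["tau_r"])) +
         p["h"] * exp(-(t - p["t0"]) / p["tau_b"]) + p["r"], 0)
  }
  sse <- function(par) {
    p <- stats::setNames(par, c("tau_d", "tau_r", "tau_b", "t0",
                                "c", "d", "h", "r"))
    sum((model(p) - y)^2)
  }
  # deterministic multi-start: the clamped objective is non-smooth and a
  # single start can stall in a constant fit when the suppression is long
  # t0 is a refractory offset (<= 4 ms) and the rise amplitude d is capped
  # at 1 so that slow recovery must be expressed through tau_rise itself
  # rather than through the clamp
  starts <- list(
    c(20, 1, 1.5, 1.5, max(y), 0.8, max(y) / 2, stats::median(y)),
    c(20, 8, 1.5, 0.5, max(y), 1, max(y) / 2, stats::median(y)),
    c(50, 12, 1.5, 0.5, 2 * max(y), 1, 0, stats::median(y)),
    c(10, 0.5, 1.5, 1, max(y), 0.5, max(y) / 2, stats::median(y)))
  lower <- c(1, 0.1, 0.1, 0, 0, 0, 0, 0)
  upper <- c(500, 50, 5, 4, 1000, 1, 1000, 500)
  fits <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, sse, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  fit <- if (length(fits)) fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
         else NULL
  if (is.null(fit)) {
    return(structure(list(tau_rise = NaN, tau_decay = NaN, tau_burst = NaN,
                          t0 = NaN, c_amp = NaN, d_amp = NaN, h_amp = NaN,
                          r = NaN, fitted = rep(NaN, length(t)), acg = acg,
                          converged = FALSE), class = "acg_fit"))
  }
  p <- stats::setNames(fit$par, c("tau_d", "tau_r", "tau_b", "t0",
                                  "c", "d", "h", "r"))
  fitted_y <- model(p)
  # identifiability guard: with no refractory suppression (flat ACG) the
  # rise-time parameter is unconstrained by the data; report 0 ("no
  # detectable rise") when the fitted curve lacks a dip
  plateau <- mean(fitted_y[t >= 0.75 * max(t)])
  early <- fitted_y[which(t > p["t0"])[1]]
  tau_rise <- if (!is.finite(plateau) || plateau <= 0 ||
                  (1 - early / plateau) < 0.15) 0 else unname(p["tau_r"])
  structure(list(tau_rise = tau_rise, tau_decay = unname(p["tau_d"]),
                 tau_burst = unname(p["tau_b"]), t0 = unname(p["t0"]),
                 c_amp = unname(p["c"]), d_amp = unname(p["d"]),
                 h_amp = unname(p["h"]), r = unname(p["r"]),
                 fitted = fitted_y, acg = acg,
                 converged = fit$convergence == 0),
            class = "acg_fit")
}

#' Cell-type classification cascade
#'
#' @param trough_to_peak_ms waveform trough-to-peak latency, ms.
#' @param acg_rise_ms autocorrelogram rise time (tau_rise), ms; NaN falls
#'   through to pyramidal.
#' @param t2p_threshold_ms narrow-interneuron latency threshold
#'   (default 0.425 ms).
#' @param rise_threshold_ms wide-interneuron rise-time threshold
#'   (default 6 ms).
#' @return one of "narrow_interneuron", "wide_interneuron", "pyramidal".
#' @export
#' @examples
#' classify_cell_type(0.30, 2.0)  # narrow_interneuron
#' classify_cell_type(0.50, 7.0)  # wide_interneuron
#' classify_cell_type(0.50, 3.0)  # pyramidal
classify_cell_type <- function(trough_to_peak_ms, acg_rise_ms,
                               t2p_threshold_ms = 0.425,
                               rise_threshold_ms = 6) {
  stopifnot(is.finite(trough_to_peak_ms))
  if (trough_to_peak_ms < t2p_threshold_ms) return("narrow_interneuron")
  if (is.finite(acg_rise_ms) && acg_rise_ms > rise_threshold_ms) {
    return("wide_interneuron")
  }
  "pyramidal"
}

#' Detect bursts as ISI runs
#'
#' Maximal runs of two or more spikes whose consecutive inter-spike
#' intervals are all below `max_isi_ms`.
#'
#' @param spike_times sorted spike times, s.
#' @param max_isi_ms burst ISI criterion, ms (default 9).
#' @return list of integer index vectors, one per burst.
#' @export
detect_bursts <- function(spike_times, max_isi_ms = 9) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted ascending")
  if (length(spike_times) < 2) return(list())
  short <- diff(spike_times) < max_isi_ms / 1000
  runs <- logical_runs(short)
  lapply(seq_len(nrow(runs)), function(i) runs[i, 1]:(runs[i, 2] + 1L))
}

#' Fraction of spikes fired in bursts
#' @inheritParams detect_bursts
#' @return scalar in [0, 1].
#' @export
burst_fraction <- function(spike_times, max_isi_ms = 9) {
  b <- detect_bursts(spike_times, max_isi_ms)
  if (!length(spike_times)) return(NaN)
  length(unique(unlist(b))) / length(spike_times)
}

#' Soma localisation by peak-to-peak amplitude
#'
#' @param footprint a [unit_footprint].
#' @param map a `probe_map`.
#' @return list with `channel_id`, `x_um`, `y_um`.
#' @export
estimate_soma_channel <- function(footprint, map) {
  if (all(footprint$waveform == 0)) stop("all-zero footprint")
  i <- match(footprint$peak_channel, map$channel_id)
  if (is.na(i)) stop("peak channel not in probe map")
  list(channel_id = footprint$peak_channel, x_um = map$x[i], y_um = map$y[i])
}

#' Peri-event firing-rate histogram
#'
#' @param spike_times spike times, s.
#' @param event_times trigger times, s.
#' @param window_ms c(before, after), ms; must be tiled exactly by `bin_ms`.
#' @param bin_ms bin width, ms.
#' @return data frame with `lag_ms` (bin centres) and `rate_hz`
#'   (counts / (n_events x bin width)).
#' @export
peri_event_histogram <- function(spike_times, event_times,
                                 window_ms = c(-100, 100), bin_ms = 10) {
  if (!length(event_times)) stop("zero events")
  span <- window_ms[2] - window_ms[1]
  if (abs(span / bin_ms - round(span / bin_ms)) > 1e-9) {
    stop("bins must tile the window exactly")
  }
  lags <- unlist(lapply(event_times, function(e) {
    d <- (spike_times - e) * 1000
    d[d >= window_ms[1] & d < window_ms[2]]
  }))
  breaks <- seq(window_ms[1], window_ms[2], by = bin_ms)
  h <- graphics::hist(lags, breaks = breaks, plot = FALSE)
  data.frame(lag_ms = h$mids,
             rate_hz = h$counts / (length(event_times) * bin_ms / 1000))
}

#' Unit metrics table
#'
#' Computes per-unit trough-to-peak latency, ACG rise time, burst fraction,
#' cell-type label and soma position for a list of footprints.
#'
#' @param footprints list of [unit_footprint].
#' @param map a `probe_map`.
#' @param min_spikes_acg spike floor for the ACG fit; below it the rise
#'   time is NaN and classification is waveform-only.
#' @return data frame with columns `unit_id`, `n_spikes`, `t2p_ms`,
#'   `acg_rise_ms`, `burst_fraction`, `label`, `soma_channel`, `soma_x_um`,
#'   `soma_y_um`.
#' @export
unit_metrics_table <- function(footprints, map, min_spikes_acg = 500) {
  rows <- lapply(footprints, function(fp) {
    t2p <- tryCatch(trough_to_peak(fp), error = function(e) NaN)
    rise <- if (length(fp$spike_times) >= min_spikes_acg) {
      fit <- fit_acg_triple_exponential(fp$spike_times,
                                        min_spikes = min_spikes_acg)
      if (fit$converged) fit$tau_rise else NaN
    } else NaN
    soma <- estimate_soma_channel(fp, map)
    data.frame(unit_id = fp$unit_id, n_spikes = length(fp$spike_times),
               t2p_ms = t2p, acg_rise_ms = rise,
               burst_fraction = burst_fraction(fp$spike_times),
               label = if (is.finite(t2p)) classify_cell_type(t2p, rise)
                       else NA_character_,
               soma_channel = soma$channel_id, soma_x_um = soma$x_um,
               soma_y_um = soma$y_um)
  })
  do.call(rbind, rows)
}
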