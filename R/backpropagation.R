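#' Action-potential backpropagation from multi-channel footprints
#'
#' On a dense shank the somatic action potential is visible on neighbouring
#' electrodes with a trough that arrives progressively later with axial
#' distance.  Channels within +-250 um (same shank) whose trough depth
#' exceeds 12% of the dominant trough contribute; trough times are refined
#' to sub-sample precision by parabolic interpolation; delays are referenced
#' to the earliest trough, whose channel is the putative initiation site,
#' and regressed against axial distance separately above and below it.  The
#' fitted slope (ms/mm) is the inverse propagation speed.  Cells propagate
#' above the soma (ascending), below (descending), both (curved), or are
#' undetermined.
#'
#' @name backpropagation
NULL

#' Per-channel trough times and amplitudes near the soma
#'
#' @param footprint a [unit_footprint].
#' @param map a `probe_map`.
#' @param threshold_frac amplitude threshold as a fraction of the dominant
#'   (largest) trough depth (default 0.12).
#' @param radius_um axial search radius around the dominant channel
#'   (default 250 um, same shank).
#' @param smooth_cutoff_hz Gaussian low-pass applied to each waveform before
#'   trough estimation (default 3000 Hz, above the spike's spectral content;
#'   roughly halves the timing variance of weak-channel troughs).  NULL
#'   disables.
#' @return data frame with `channel_id`, `y_um`, `dy_um` (signed axial
#'   offset from the dominant channel; negative = above), `trough_ms`
#'   (sub-sample trough time on the footprint lag axis), `amplitude_uv`
#'   (trough depth).  Only channels passing the threshold appear; the
#'   dominant channel always passes.
#' @export
detect_trough_channels <- function(footprint, map, threshold_frac = 0.12,
                                   radius_um = 250, smooth_cutoff_hz = 3000) {
  stopifnot(inherits(footprint, "unit_footprint"), inherits(map, "probe_map"))
  dom <- footprint$peak_channel
  near <- channels_within_radius(map, dom, radius_um, same_shank = TRUE)
  near <- intersect(near, footprint$channel_ids)
  dt <- footprint$t_ms[2] - footprint$t_ms[1]
  fs <- 1000 / dt
  k <- if (!is.null(smooth_cutoff_hz) && smooth_cutoff_hz < fs / 2) {
    gauss_kernel(smooth_cutoff_hz, fs)
  }
  rows <- lapply(near, function(ch) {
    w <- footprint$waveform[match(ch, footprint$channel_ids), ]
    if (!is.null(k)) w <- fft_sym_filter(w, k)
    it <- which.min(w)
    # sub-sample trough by cubic-spline interpolation around the minimum
    # (parabolic 3-point interpolation leaves a periodic phase-dependent
    # bias of a few microseconds, visible at shallow delay slopes)
    lo <- max(1L, it - 4L)
    hi <- min(length(w), it + 4L)
    sp <- stats::spline(lo:hi, w[lo:hi], n = (hi - lo) * 50L + 1L)
    imin <- which.min(sp$y)
    data.frame(channel_id = ch,
               y_um = map$y[match(ch, map$channel_id)],
               trough_ms = footprint$t_ms[1] + (sp$x[imin] - 1) * dt,
               amplitude_uv = -sp$y[imin])
  })
  tab <- do.call(rbind, rows)
  dom_amp <- tab$amplitude_uv[tab$channel_id == dom]
  stopifnot(length(dom_amp) == 1)
  tab$dy_um <- tab$y_um - tab$y_um[tab$channel_id == dom]
  keep <- tab$amplitude_uv >= threshold_frac * dom_amp
  keep[tab$channel_id == dom] <- TRUE
  tab[keep, c("channel_id", "y_um", "dy_um", "trough_ms", "amplitude_uv")]
}

#' Fit backpropagation slopes above and below the soma
#'
#' Delays are re-referenced to the earliest trough; its channel is the
#' putative initiation site (ties break to the channel closest to the soma,
#' then the lowest id).  Ordinary least squares of delay (ms) against
#' absolute axial distance from the soma (mm), with a free intercept, is
#' fitted separately for channels above and below the soma; a side is
#' fitted only when it has at least `min_side_channels` channels strictly
#' on that side.  Channels are weighted by squared trough amplitude: the
#' timing variance of a trough estimate scales inversely with its squared
#' amplitude, so weak channels near the 12% threshold contribute
#' proportionally less.  A fitted slope <= 0 marks a non-propagating side.
#'
#' @param troughs output of [detect_trough_channels].
#' @param soma_y_um soma axial position, um.
#' @param min_side_channels minimum channels per side (default 3).
#' @return list with `initiation_channel`, `slope_above`, `slope_below`
#'   (ms/mm, NA when unfitted), `r2_above`, `r2_below`, `speed_above`,
#'   `speed_below` (mm/ms), and `simultaneous` (TRUE when all delays are 0,
#'   reported as slope 0).
#' @export
fit_backprop_slopes <- function(troughs, soma_y_um,
                                min_side_channels = 3) {
  d <- troughs
  d$delay <- d$trough_ms - min(d$trough_ms)
  cand <- which(d$delay == 0)
  cand <- cand[order(abs(d$y_um[cand] - soma_y_um), d$channel_id[cand])]
  init <- cand[1]
  d$dist_mm <- abs(d$y_um - soma_y_um) / 1000

  fit_side <- function(side_rows) {
    if (length(side_rows) < min_side_channels) {
      return(list(slope = NA_real_, r2 = NA_real_))
    }
    sub <- d[side_rows, ]
    if (all(sub$delay == sub$delay[1])) return(list(slope = 0, r2 = 1))
    f <- stats::lm(delay ~ dist_mm, data = sub,
                   weights = sub$amplitude_uv^2)
    list(slope = unname(stats::coef(f)[2]),
         r2 = summary(f)$r.squared)
  }
  above <- fit_side(which(d$y_um < soma_y_um))
  below <- fit_side(which(d$y_um > soma_y_um))
  list(initiation_channel = d$channel_id[init],
       slope_above = above$slope, slope_below = below$slope,
       r2_above = above$r2, r2_below = below$r2,
       speed_above = if (!is.na(above$slope) && above$slope > 0)
         1 / above$slope else NA_real_,
       speed_below = if (!is.na(below$slope) && below$slope > 0)
         1 / below$slope else NA_real_,
       simultaneous = all(d$delay == 0))
}

#' Classify the backpropagation direction
#'
#' A side counts as propagating when its fit exists and its slope exceeds
#' `min_slope` (later troughs further away; the floor keeps timing noise on
#' effectively simultaneous troughs from counting as propagation).
#' Ascending = only above, descending = only below, curved = both,
#' undetermined = neither.
#'
#' @param fit output of [fit_backprop_slopes].
#' @param min_slope minimum slope treated as genuine propagation, ms/mm
#'   (default 0.1, i.e. apparent speeds above 10 mm/ms are treated as
#'   simultaneous).
#' @return one of "ascending", "descending", "curved", "undetermined".
#' @export
classify_backprop <- function(fit, min_slope = 0.1) {
  up <- !is.na(fit$slope_above) && fit$slope_above > min_slope
  down <- !is.na(fit$slope_below) && fit$slope_below > min_slope
  if (up && down) "curved"
  else if (up) "ascending"
  else if (down) "descending"
  else "undetermined"
}

#' Full backpropagation analysis of one unit
#'
#' @param footprint a [unit_footprint].
#' @param map a `probe_map`.
#' @inheritParams detect_trough_channels
#' @inheritParams fit_backprop_slopes
#' @return one-row data frame: `unit_id`, `initiation_channel`,
#'   `soma_channel`, `n_channels`, `slope_above_ms_per_mm`,
#'   `slope_below_ms_per_mm`, `r2_above`, `r2_below`, `direction`.
#' @export
backprop_analysis <- function(footprint, map, threshold_frac = 0.12,
                              radius_um = 250, min_side_channels = 3) {
  tr <- detect_trough_channels(footprint, map, threshold_frac, radius_um)
  soma_y <- map$y[match(footprint$peak_channel, map$channel_id)]
  fit <- fit_backprop_slopes(tr, soma_y, min_side_channels)
  data.frame(unit_id = footprint$unit_id,
             initiation_channel = fit$initiation_channel,
             soma_channel = footprint$peak_channel,
             n_channels = nrow(tr),
             slope_above_ms_per_mm = fit$slope_above,
             slope_below_ms_per_mm = fit$slope_below,
             r2_above = fit$r2_above, r2_below = fit$r2_below,
             direction = classify_backprop(fit))
}
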