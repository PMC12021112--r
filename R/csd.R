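#' Event-triggered averages and current source density maps
#'
#' The laminar CSD along one electrode column is estimated as the negative
#' second spatial difference of the (event-triggered average) potential:
#' `CSD(i) = -(V(i-1) - 2 V(i) + V(i+1)) / h^2` with uniform vertical pitch
#' `h`.  Sinks (inward transmembrane current) are negative.  Boundary rows
#' duplicate the edge potentials (Vaknin padding) so the map spans all rows.
#'
#' @name csd
NULL

#' Construct a triggered-average container
#'
#' @param data channels x lags matrix of mean LFP, uV.
#' @param lag_ms lag axis, ms (symmetric about 0).
#' @param n number of contributing events.
#' @param channel_ids channel ids of the rows.
#' @return a `triggered_average` object.
#' @export
triggered_average <- function(data, lag_ms, n, channel_ids) {
  stopifnot(is.matrix(data), ncol(data) == length(lag_ms),
            nrow(data) == length(channel_ids), n >= 1)
  structure(list(data = data, lag_ms = lag_ms, n = n,
                 channel_ids = as.integer(channel_ids)),
            class = "triggered_average")
}

#' Event-triggered average LFP
#'
#' Arithmetic mean over events of aligned signal snippets.  Events whose
#' padded window leaves the recording are dropped (their count is reported
#' via a message).
#'
#' @param segment a `recording_segment`.
#' @param event_times event (trigger) times, s.
#' @param window_ms c(before, after) window relative to the trigger, ms.
#' @param channels channel ids to include (NULL = all).
#' @return a [triggered_average].
#' @export
event_triggered_average <- function(segment, event_times,
                                    window_ms = c(-100, 100),
                                    channels = NULL) {
  fs <- segment$sampling_rate
  if (is.null(channels)) channels <- segment$channel_ids
  rows <- channel_index(segment, channels)
  w0 <- round(window_ms[1] / 1000 * fs)
  w1 <- round(window_ms[2] / 1000 * fs)
  n_samp <- ncol(segment$data)
  centers <- round(event_times * fs) + 1L
  ok <- centers + w0 >= 1L & centers + w1 <= n_samp
  if (sum(!ok) > 0) {
    message(sum(!ok), " event(s) dropped: window outside the recording")
  }
  centers <- centers[ok]
  if (!length(centers)) stop("no usable events for the triggered average")
  acc <- matrix(0, nrow = length(rows), ncol = w1 - w0 + 1L)
  for (c0 in centers) {
    acc <- acc + segment$data[rows, (c0 + w0):(c0 + w1), drop = FALSE]
  }
  triggered_average(acc / length(centers), lag_ms = (w0:w1) / fs * 1000,
                    n = length(centers), channel_ids = channels)
}

#' One-dimensional CSD along a shank column
#'
#' @param avg a [triggered_average] covering the selected column.
#' @param map a `probe_map`.
#' @param shank,column column selector.
#' @param smooth apply a 3-point Hamming smoothing across depth before
#'   differencing (default FALSE; the detection-side default is no
#'   smoothing).
#' @return a `csd_map`: list with `values` (rows x lags, sinks negative,
#'   units proportional to uV/um^2), `rows`, `y_um`, `lag_ms`, `shank`,
#'   `column`, `n`.
#' @export
compute_csd <- function(avg, map, shank, column, smooth = FALSE) {
  stopifnot(inherits(avg, "triggered_average"), inherits(map, "probe_map"))
  sel <- map[map$shank == shank & map$column == column, ]
  sel <- sel[order(sel$y), ]
  idx <- match(sel$channel_id, avg$channel_ids)
  if (any(is.na(idx))) {
    stop("triggered average does not cover the requested column")
  }
  h <- diff(sel$y)
  if (length(h) < 2) stop("need at least 3 rows for a CSD")
  if (max(abs(h - h[1])) > 1e-6) stop("non-uniform vertical pitch in selection")
  h <- h[1]
  V <- avg$data[idx, , drop = FALSE]
  if (smooth) {
    w <- c(0.23, 0.54, 0.23)
    Vp <- rbind(V[1, ], V, V[nrow(V), ])
    V <- (w[1] * Vp[1:(nrow(Vp) - 2), , drop = FALSE] +
          w[2] * Vp[2:(nrow(Vp) - 1), , drop = FALSE] +
          w[3] * Vp[3:nrow(Vp), , drop = FALSE])
  }
  Vpad <- rbind(V[1, ], V, V[nrow(V), ])       # Vaknin padding
  csd <- -(Vpad[1:(nrow(Vpad) - 2), , drop = FALSE] -
           2 * Vpad[2:(nrow(Vpad) - 1), , drop = FALSE] +
           Vpad[3:nrow(Vpad), , drop = FALSE]) / h^2
  structure(list(values = csd, rows = sel$row, y_um = sel$y,
                 lag_ms = avg$lag_ms, shank = shank, column = column,
                 n = avg$n),
            class = "csd_map")
}

#' Write a triggered average or CSD map as CSV + JSON axes sidecar
#'
#' The matrix goes to CSV (rows = channels or depth rows, columns = lags);
#' the axes and event count go to a JSON sidecar next to it.
#'
#' @param x a `triggered_average` or `csd_map`.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @export
write_map_csv <- function(x, path) {
  if (inherits(x, "triggered_average")) {
    utils::write.csv(as.data.frame(x$data), path, row.names = FALSE)
    meta <- list(kind = "triggered_average", lag_ms = x$lag_ms, n = x$n,
                 channel_ids = x$channel_ids)
  } else if (inherits(x, "csd_map")) {
    utils::write.csv(as.data.frame(x$values), path, row.names = FALSE)
    meta <- list(kind = "csd_map", lag_ms = x$lag_ms, rows = x$rows,
                 y_um = x$y_um, shank = x$shank, column = x$column, n = x$n)
  } else stop("unsupported object")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
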