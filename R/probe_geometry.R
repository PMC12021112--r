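#' Probe lattice construction and queries
#'
#' An 8-shank CMOS probe carries 1024 recording sites ("electrode-pixels"):
#' each shank holds four 32-pixel frontend modules arranged as two vertical
#' columns of 64 rows.  A probe map is a data frame with one row per channel
#' and the columns `channel_id`, `shank`, `module`, `row`, `column`, `x`,
#' `y`, `electrode_size` (all distances in micrometres).  `y` is 0 at the
#' topmost (most superficial) electrode row and increases toward the tip;
#' `x` is 0 at shank 0's left column.
#'
#' @name probe_map
NULL

#' Build a rectangular multi-shank probe map
#'
#' @param n_shanks number of shanks.
#' @param n_rows electrode rows per shank (two columns each).
#' @param shank_pitch_um centre-to-centre shank separation, micrometres.
#' @param row_pitch_um vertical centre-to-centre electrode pitch, micrometres.
#' @param column_sep_um lateral centre separation of the two columns.
#' @param electrode_size_um side of the square platinum contact.
#' @param rows_per_module electrode rows per frontend module (each module
#'   serves `2 * rows_per_module` pixels through one multiplexed output).
#' @param nominal_active_length_um optional device-datasheet active length
#'   stored as metadata; `NA` to derive it from the geometry.
#'
#' @return A `probe_map` data frame (see [probe_map]).  Channel ordering is
#'   shank-major, then row-major, then column.
#' @export
build_probe_map <- function(n_shanks = 8L, n_rows = 64L,
                            shank_pitch_um = 300, row_pitch_um = 30,
                            column_sep_um = 27, electrode_size_um = 14,
                            rows_per_module = 16L,
                            nominal_active_length_um = NA_real_) {
  stopifnot(n_shanks >= 1L, n_rows >= 1L, shank_pitch_um > 0,
            row_pitch_um > 0, row_pitch_um <= 30 + 1e-9)
  shank <- rep(seq_len(n_shanks) - 1L, each = 2L * n_rows)
  row <- rep(rep(seq_len(n_rows) - 1L, each = 2L), times = n_shanks)
  column <- rep(c(0L, 1L), times = n_rows * n_shanks)
  m <- data.frame(
    channel_id = seq_len(2L * n_rows * n_shanks) - 1L,
    shank = shank,
    module = row %/% as.integer(rows_per_module),
    row = row,
    column = column,
    x = shank * shank_pitch_um + column * column_sep_um,
    y = row * row_pitch_um,
    electrode_size = electrode_size_um
  )
  attr(m, "shank_pitch_um") <- shank_pitch_um
  attr(m, "pitch_um") <- row_pitch_um
  attr(m, "column_sep_um") <- column_sep_um
  attr(m, "electrode_size_um") <- electrode_size_um
  attr(m, "rows_per_module") <- as.integer(rows_per_module)
  geom_len <- (n_rows - 1L) * row_pitch_um + electrode_size_um
  attr(m, "active_length_um") <-
    if (is.na(nominal_active_length_um)) geom_len else nominal_active_length_um
  class(m) <- c("probe_map", "data.frame")
  m
}

#' Build the canonical 8-shank 1024-channel probe map
#'
#' Eight shanks at 300 um pitch, each with 2 columns x 64 rows at 30 um
#' vertical pitch, 27 um column separation, 14 um contacts, four 32-pixel
#' modules per shank.  The geometric column length (63 x 30 + 14 = 1904 um)
#' falls slightly short of the device's nominal active recording length of
#' 1924 um, which is kept as metadata (`attr(map, "active_length_um")`) and
#' used for the printed recording-span figures.
#'
#' @return A 1024-channel `probe_map`.
#' @export
#' @examples
#' map <- build_default_probe_map()
#' nrow(map)                       # 1024
#' sum(map$shank == 0)             # 128
build_default_probe_map <- function() {
  build_probe_map(n_shanks = 8L, n_rows = 64L, shank_pitch_um = 300,
                  row_pitch_um = 30, column_sep_um = 27,
                  electrode_size_um = 14, rows_per_module = 16L,
                  nominal_active_length_um = 1924)
}

#' Summarise probe accounting figures
#'
#' @param map a `probe_map`.
#' @param sampling_rate_hz per-channel sampling rate (Hz).
#' @return list with channel counts, the per-module multiplexed throughput
#'   (pixels/s), the lateral and axial recording spans (edge-to-edge,
#'   micrometres; the axial span uses the nominal active length), and the
#'   recording-span area in mm^2.
#' @export
probe_summary <- function(map, sampling_rate_hz = 20000) {
  stopifnot(inherits(map, "probe_map"))
  per_module <- nrow(map) / length(unique(paste(map$shank, map$module)))
  esz <- attr(map, "electrode_size_um")
  span_x <- diff(range(map$x)) + esz
  span_y <- attr(map, "active_length_um")
  list(
    n_channels = nrow(map),
    channels_per_shank = nrow(map) / length(unique(map$shank)),
    channels_per_module = per_module,
    module_multiplex_rate_px_per_s = per_module * sampling_rate_hz,
    span_x_um = span_x,
    span_y_um = span_y,
    area_mm2 = span_x * span_y / 1e6
  )
}

#' Channels within an axial radius of a centre channel
#'
#' Selects channels whose axial (depth) distance from the centre channel is
#' at most `radius_um`; used e.g. by the backpropagation search over nearby
#' electrodes (+-250 um).
#'
#' @param map a `probe_map`.
#' @param center_channel channel id present in `map`.
#' @param radius_um axial radius, micrometres (>= 0).
#' @param same_shank restrict to the centre channel's shank (default TRUE).
#' @return integer vector of channel ids (always includes `center_channel`).
#' @export
channels_within_radius <- function(map, center_channel, radius_um,
                                   same_shank = TRUE) {
  stopifnot(inherits(map, "probe_map"), radius_um >= 0)
  i <- match(center_channel, map$channel_id)
  if (is.na(i)) {
    stop("unknown channel id: ", center_channel)
  }
  keep <- abs(map$y - map$y[i]) <= radius_um + 1e-9
  if (same_shank) keep <- keep & map$shank == map$shank[i]
  sort(map$channel_id[keep])
}

probe_map_attrs <- c("shank_pitch_um", "pitch_um", "column_sep_um",
                     "electrode_size_um", "rows_per_module",
                     "active_length_um")

validate_probe_map <- function(m) {
  req <- c("channel_id", "shank", "module", "row", "column", "x", "y",
           "electrode_size")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("probe map missing key(s): ",
                         paste(miss, collapse = ", "))
  for (k in req) {
    if (!is.numeric(m[[k]])) stop("non-numeric probe map column: ", k)
  }
  if (anyDuplicated(m$channel_id)) {
    stop("duplicate channel_id in probe map: ",
         paste(unique(m$channel_id[duplicated(m$channel_id)]), collapse = ", "))
  }
  key <- paste(m$shank, m$row, m$column)
  if (anyDuplicated(key)) {
    stop("duplicate (shank, row, column) triple in probe map: ",
         key[anyDuplicated(key)])
  }
  invisible(m)
}

#' Write / read a probe map as JSON
#'
#' The file has top-level keys `pitch_um`, `shank_pitch_um`,
#' `electrode_size_um`, further metadata, and `channels` — a list of objects
#' with the probe-map fields.  `read_probe_map(write_probe_map(m))` is the
#' identity on all fields.
#'
#' @param map a `probe_map`.
#' @param path output / input file path.
#' @return `read_probe_map` returns a `probe_map`; `write_probe_map`
#'   returns `path` invisibly.
#' @export
write_probe_map <- function(map, path) {
  stopifnot(inherits(map, "probe_map"))
  obj <- c(
    stats::setNames(lapply(probe_map_attrs, function(a) attr(map, a)),
                    probe_map_attrs),
    list(channels = as.data.frame(map))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$channels)) stop("probe map file lacks key 'channels': ", path)
  m <- as.data.frame(obj$channels)
  validate_probe_map(m)
  m$channel_id <- as.integer(m$channel_id)
  for (k in c("shank", "module", "row", "column")) m[[k]] <- as.integer(m[[k]])
  for (a in probe_map_attrs) attr(m, a) <- obj[[a]]
  class(m) <- c("probe_map", "data.frame")
  m
}

#' Export a probe map in the PRB group/geometry dialect
#'
#' Writes a python-syntax `.prb` file with one channel group per shank and a
#' `geometry` dict mapping channel id to (x, y), the layout common spike
#' sorters consume.
#'
#' @param map a `probe_map`.
#' @param path output path.
#' @export
write_prb <- function(map, path) {
  stopifnot(inherits(map, "probe_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("channel_groups = {", con)
  for (s in sort(unique(map$shank))) {
    sub <- map[map$shank == s, ]
    writeLines(sprintf("  %d: {", s), con)
    writeLines(sprintf("    'channels': [%s],",
                       paste(sub$channel_id, collapse = ", ")), con)
    writeLines("    'geometry': {", con)
    writeLines(sprintf("      %d: (%.3f, %.3f),", sub$channel_id, sub$x, sub$y),
               con)
    writeLines("    },", con)
    writeLines("  },", con)
  }
  writeLines("}", con)
  invisible(path)
}
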