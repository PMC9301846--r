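# Mass-axis windows. Every (frame, scan) pair owns one mass axis; the axis
# is cut into compact intervals of fixed length L on two grids: the primary
# grid with starts at anchor + k*L and an offset grid shifted by L/2, so
# that any isotopic pattern of extent <= L/2 is wholly inside at least one
# window. Windows without peaks are never materialised (an all-zero
# intensity vector has no defined projection sign and carries no signal).

#' Window grid configuration
#'
#' @param window_length Window extent L in m/z; 10 resolves one isotopic
#'   pattern (extent up to ~5 Da) per window without routinely capturing two.
#' @param bin_resolution Bin width in m/z used when windows are rasterised
#'   for hashing; 0.1 still resolves charge-5 spacing (0.2 m/z).
#' @param anchor m/z origin of the grid. Window starts are
#'   `anchor + k * window_length` (primary grid) and shifted by half a
#'   window length (offset grid).
#' @return A list of class `window_grid_config`.
#' @export
window_grid_config <- function(window_length = 10, bin_resolution = 0.1,
                               anchor = 0) {
  stop_if_not_scalar_number(window_length, "window_length", lower = 1e-9)
  stop_if_not_scalar_number(bin_resolution, "bin_resolution", lower = 1e-12)
  stop_if_not_scalar_number(anchor, "anchor")
  d <- window_length / bin_resolution
  if (abs(d - round(d)) > 1e-9) {
    stop("window_length must be an exact multiple of bin_resolution",
         call. = FALSE)
  }
  structure(list(window_length = window_length,
                 bin_resolution = bin_resolution,
                 anchor = anchor,
                 n_bins = as.integer(round(d))),
            class = "window_grid_config")
}

#' Cut peak data into overlapping mass-axis windows
#'
#' Assigns every peak to exactly one window of the primary grid and one of
#' the half-offset grid within its (frame, scan) mass axis. The interval
#' convention is half-open, `start <= mz < start + L`, so a peak exactly on
#' a boundary belongs to the upper window and no peak is counted twice
#' within one grid.
#'
#' @param peaks A peak table (see [as_peak_table()]).
#' @param config A [window_grid_config()].
#' @return An object of class `lsh_windows`: a list with
#'   \describe{
#'     \item{windows}{data.table of emitted (nonempty) windows:
#'       `window_id`, `frame`, `scan`, `start`, `offset_grid`, `n_peaks`.}
#'     \item{assign}{data.table mapping peaks to windows: `window_id`,
#'       `peak_id` (row number in `peaks`), plus peak columns.}
#'     \item{peaks}{the validated input peak table with `peak_id`.}
#'     \item{config}{the grid configuration.}
#'   }
#' @export
make_windows <- function(peaks, config = window_grid_config()) {
  peaks <- as_peak_table(peaks)
  peaks[, peak_id := .I]
  L <- config$window_length
  a <- config$anchor
  assign <- rbindlist(lapply(c(FALSE, TRUE), function(off) {
    shift <- if (off) L / 2 else 0
    dt <- peaks[, .(peak_id, frame, scan, mz, intensity, label)]
    dt[, start := a + shift + floor((mz - a - shift) / L) * L]
    dt[, offset_grid := off]
    dt
  }))
  setorder(assign, offset_grid, frame, scan, start, mz)
  assign[, window_id := rleid(offset_grid, frame, scan, start)]
  windows <- assign[, .(frame = frame[1L], scan = scan[1L],
                        start = start[1L], offset_grid = offset_grid[1L],
                        n_peaks = .N), by = window_id]
  structure(list(windows = windows, assign = assign, peaks = peaks,
                 config = config),
            class = "lsh_windows")
}

#' @export
print.lsh_windows <- function(x, ...) {
  cat(sprintf("<lsh_windows> %d windows (%d primary / %d offset), %d peaks\n",
              nrow(x$windows), sum(!x$windows$offset_grid),
              sum(x$windows$offset_grid), nrow(x$peaks)))
  invisible(x)
}

#' Rasterise windows into fixed-resolution intensity vectors
#'
#' The bin index of a peak is `floor((mz - start) / bin_resolution)`;
#' intensities of peaks sharing a bin are summed and all other bins are 0.
#' Emitted windows contain at least one peak, so every row has a strictly
#' positive entry.
#'
#' @param ws An `lsh_windows` object from [make_windows()] or
#'   [dataset_windows()].
#' @param config Grid configuration; defaults to the one stored in `ws`.
#' @return A list with `intensities` (matrix, one row per window, `n_bins`
#'   columns) and `windows` (the window metadata, row-aligned with the
#'   matrix).
#' @export
bin_windows <- function(ws, config = NULL) {
  stopifnot(inherits(ws, "lsh_windows"))
  config <- config %||% ws$config
  d <- config$n_bins
  assign <- ws$assign
  bin <- floor((assign$mz - assign$start) / config$bin_resolution) + 1L
  if (any(bin < 1L | bin > d)) {
    stop("internal error: peak outside its window during binning",
         call. = FALSE)
  }
  row <- match(assign$window_id, ws$windows$window_id)
  agg <- data.table(row = row, bin = bin, intensity = assign$intensity)
  agg <- agg[, .(v = sum(intensity)), by = .(row, bin)]
  X <- matrix(0, nrow = nrow(ws$windows), ncol = d)
  X[cbind(agg$row, agg$bin)] <- agg$v
  list(intensities = X, windows = ws$windows)
}

#' Summarise windows as a table (debug/eval dump)
#'
#' @param ws An `lsh_windows` object.
#' @param path Optional path; when given the table is written as TSV.
#' @return The window metadata table, invisibly when written.
#' @export
window_summary <- function(ws, path = NULL) {
  stopifnot(inherits(ws, "lsh_windows"))
  out <- ws$windows[, .(window_id, start, frame, scan, offset_grid, n_peaks)]
  if (!is.null(path)) {
    fwrite(out, path, sep = "\t", quote = FALSE)
    return(invisible(out))
  }
  out
}
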