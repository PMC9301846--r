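# Classification by collision. All hashed windows feed one collision
# table: per band, a map from key to its number of occurrences. Keys seen
# at least twice are "collided"; a window is signal iff one of its band
# keys is collided, and a peak is signal iff any window containing it is
# signal (a peak sits in up to two windows, one per grid).

#' Build a collision table from signatures
#'
#' Counts, per band, how often each key occurs across all windows of the
#' processed unit. The collided set is every (band, key) with count >= 2;
#' two occurrences collide even when they come from the same mass axis.
#'
#' @param signatures Numeric matrix of band keys from [lsh_signatures()].
#' @return A data.table of class `collision_table` with columns `band`,
#'   `key`, `count`, and attribute `n_windows`.
#' @export
build_collision_table <- function(signatures) {
  if (is.null(dim(signatures))) signatures <- matrix(signatures, nrow = 1L)
  W <- nrow(signatures); m <- ncol(signatures)
  if (W == 0L) {
    tab <- data.table(band = integer(), key = numeric(), count = integer())
  } else {
    long <- setDT(list(band = rep(seq_len(m), each = W),
                       key = as.vector(signatures)))
    tab <- long[, .(count = .N), by = .(band, key)]
  }
  setattr(tab, "n_windows", W)
  setattr(tab, "class", c("collision_table", class(tab)))
  tab[]
}

#' Classify windows by collision-table lookup
#'
#' A window is called `"signal"` iff at least one of its m band keys is
#' found in the collided set (count >= 2) of the table, otherwise
#' `"noise"`.
#'
#' @param signatures Signature matrix of the windows to classify.
#' @param table A [build_collision_table()] result built from the same
#'   signature universe.
#' @return Character vector of calls, one per signature row.
#' @export
classify_windows <- function(signatures, table) {
  if (is.null(dim(signatures))) signatures <- matrix(signatures, nrow = 1L)
  W <- nrow(signatures); m <- ncol(signatures)
  if (W == 0L) return(character())
  collided <- table[count >= 2L]
  calls <- rep(FALSE, W)
  if (nrow(collided)) {
    long <- setDT(list(row = rep(seq_len(W), times = m),
                       band = rep(seq_len(m), each = W),
                       key = as.vector(signatures)))
    hit <- collided[long, on = c("band", "key"), nomatch = NULL]
    calls[unique(hit$row)] <- TRUE
  }
  ifelse(calls, "signal", "noise")
}

#' Count collided bands per window
#'
#' How many of a window's m band keys are in the collided set; a window
#' is signal iff the count is positive.
#'
#' @inheritParams classify_windows
#' @return Integer vector, one count in `0..m` per signature row.
#' @export
count_collided_bands <- function(signatures, table) {
  if (is.null(dim(signatures))) signatures <- matrix(signatures, nrow = 1L)
  W <- nrow(signatures); m <- ncol(signatures)
  if (W == 0L) return(integer())
  collided <- table[count >= 2L]
  out <- integer(W)
  if (nrow(collided)) {
    long <- setDT(list(row = rep(seq_len(W), times = m),
                       band = rep(seq_len(m), each = W),
                       key = as.vector(signatures)))
    hit <- collided[long, on = c("band", "key"), nomatch = NULL]
    cnt <- hit[, .N, by = row]
    out[cnt$row] <- cnt$N
  }
  out
}

#' Propagate window calls to peaks
#'
#' A peak is signal iff at least one window containing it was called
#' signal. With the two overlapping grids a peak whose primary window is
#' noise is still rescued by a collided offset window.
#'
#' @param ws An `lsh_windows` object.
#' @param window_calls Character vector of calls aligned with
#'   `ws$windows`.
#' @return The peak table of `ws` with a `call` column appended.
#' @export
classify_peaks <- function(ws, window_calls) {
  stopifnot(inherits(ws, "lsh_windows"),
            length(window_calls) == nrow(ws$windows))
  wc <- data.table(window_id = ws$windows$window_id, wcall = window_calls)
  hit <- ws$assign[wc, on = "window_id"][, .(signal = any(wcall == "signal")),
                                         by = peak_id]
  if (nrow(hit) < nrow(ws$peaks) || anyNA(hit$signal)) {
    stop("internal error: peak belongs to no window", call. = FALSE)
  }
  out <- copy(ws$peaks)
  out[hit, call := ifelse(i.signal, "signal", "noise"), on = "peak_id"]
  out[]
}

#' Intensity-threshold baseline classifier
#'
#' The signal-to-noise thresholding baseline under a global noise
#' estimate: a peak is signal iff its intensity is at least `threshold`.
#' Unlike the LSH calls this is *not* scale invariant.
#'
#' @param peaks A peak table.
#' @param threshold Non-negative intensity cutoff.
#' @return The peak table with a `call` column appended.
#' @export
snr_threshold_classifier <- function(peaks, threshold) {
  stop_if_not_scalar_number(threshold, "threshold", lower = 0)
  peaks <- as_peak_table(peaks)
  out <- copy(peaks)
  out[, call := ifelse(intensity >= threshold, "signal", "noise")]
  out[]
}

#' End-to-end LSH classification
#'
#' Runs the full pipeline: window generation (unless the input already is
#' a window set), binning, hashing, collision-table construction, and
#' window/peak calls.
#'
#' @param x A peak table, an `lsh_windows` object, or an `lsh_dataset`
#'   from [generate_dataset()] (whose generator-defined windows are used
#'   directly).
#' @param family A [hash_family()] with `d` equal to the number of bins
#'   per window.
#' @param config A [window_grid_config()]; defaults to the one carried by
#'   `x` when present.
#' @param per_frame When TRUE the collision table is restricted to one
#'   frame at a time (frame-wise scope); default pools all windows of the
#'   input.
#' @param workers Number of parallel workers for the signature
#'   computation (forked; results are independent of `workers`).
#' @return A list of class `lsh_calls`:
#'   `windows` (metadata plus `call`), `peaks` (peak table plus `call`),
#'   `signatures`, `table` (NULL when `per_frame`), `family`.
#' @export
lsh_classify <- function(x, family, config = NULL, per_frame = FALSE,
                         workers = 1L) {
  if (inherits(x, "lsh_dataset")) {
    ws <- dataset_windows(x)
  } else if (inherits(x, "lsh_windows")) {
    ws <- x
  } else {
    ws <- make_windows(x, config %||% window_grid_config())
  }
  config <- config %||% ws$config
  binned <- bin_windows(ws, config)
  sig <- .signatures_parallel(binned$intensities, family, workers)
  if (per_frame) {
    frames <- ws$windows$frame
    wcalls <- rep(NA_character_, nrow(sig))
    nbands <- rep(NA_integer_, nrow(sig))
    for (f in unique(frames)) {
      idx <- which(frames == f)
      tab <- build_collision_table(sig[idx, , drop = FALSE])
      wcalls[idx] <- classify_windows(sig[idx, , drop = FALSE], tab)
      nbands[idx] <- count_collided_bands(sig[idx, , drop = FALSE], tab)
    }
    tab <- NULL
  } else {
    tab <- build_collision_table(sig)
    wcalls <- classify_windows(sig, tab)
    nbands <- count_collided_bands(sig, tab)
  }
  windows <- copy(ws$windows)
  windows[, call := wcalls]
  windows[, n_collided_bands := nbands]
  peaks <- classify_peaks(ws, wcalls)
  structure(list(windows = windows, peaks = peaks, signatures = sig,
                 table = tab, family = family),
            class = "lsh_calls")
}

#' @export
print.lsh_calls <- function(x, ...) {
  cat(sprintf(
    "<lsh_calls> %d windows (%.1f%% signal), %d peaks (%.1f%% signal)\n",
    nrow(x$windows), 100 * mean(x$windows$call == "signal"),
    nrow(x$peaks), 100 * mean(x$peaks$call == "signal")))
  invisible(x)
}

# Row-chunked signature computation; chunking does not change any dot
# product, so results are bit-identical to the serial path.
.signatures_parallel <- function(X, family, workers = 1L) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || nrow(X) < 2L * workers ||
      .Platform$OS.type == "windows") {
    return(lsh_signatures(X, family))
  }
  idx <- parallel::splitIndices(nrow(X), workers)
  parts <- parallel::mclapply(idx, function(i) {
    lsh_signatures(X[i, , drop = FALSE], family)
  }, mc.cores = workers)
  do.call(rbind, parts)
}
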