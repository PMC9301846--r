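# Peak tables: the package's in-memory representation of centroided MS1
# data is a data.table with one row per detected peak and columns
#   frame     integer >= 0, retention-time index
#   scan      integer >= 0, ion-mobility index (0 for plain LC-MS)
#   mz        double  > 0,  mass-to-charge ratio
#   intensity double >= 0,  abundance in arbitrary counts
#   label     character, one of signal / noise_1 / noise_2 / unlabeled
# The on-disk form is a tab-separated table with a header and '.' decimals.

#' Validate (and normalise) a peak table
#'
#' Checks the column contract shared by every function in the package and
#' fills in the optional `label` column. Input order is preserved.
#'
#' @param peaks A data.frame or data.table with columns `frame`, `scan`,
#'   `mz`, `intensity` and optionally `label`.
#' @return A data.table with the five canonical columns.
#' @export
as_peak_table <- function(peaks) {
  peaks <- as.data.table(peaks)
  need <- c("frame", "scan", "mz", "intensity")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(peaks[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(peaks[[col]]))))
      stop(sprintf("column '%s' is not numeric (first bad data row: %d)",
                   col, if (length(bad)) bad[1L] else NA_integer_),
           call. = FALSE)
    }
  }
  if (anyNA(peaks[, need, with = FALSE])) {
    bad <- which(!stats::complete.cases(peaks[, need, with = FALSE]))
    stop(sprintf("malformed peak table: missing value in data row %d", bad[1L]),
         call. = FALSE)
  }
  if (any(peaks$mz <= 0)) {
    stop("all m/z values must be > 0", call. = FALSE)
  }
  if (any(peaks$intensity < 0)) {
    stop(sprintf("negative intensity in data row %d",
                 which(peaks$intensity < 0)[1L]), call. = FALSE)
  }
  if (!"label" %in% names(peaks)) {
    peaks[, label := "unlabeled"]
  } else {
    peaks[is.na(label) | label == "", label := "unlabeled"]
    bad <- setdiff(unique(peaks$label), .peak_labels)
    if (length(bad)) {
      stop("unknown peak label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  peaks[, frame := as.integer(frame)]
  peaks[, scan := as.integer(scan)]
  peaks[]
}

#' Read a peak table from a TSV file
#'
#' Expects a tab-separated file with header columns `frame`, `scan`, `mz`,
#' `intensity` and optionally `label`. Extra columns are carried along.
#'
#' @param path Path to the file.
#' @return A peak data.table (see [as_peak_table()]); zero data rows give an
#'   empty table with the canonical columns.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = NULL,
              showProgress = FALSE)
  if (nrow(dt) == 0L) {
    dt <- data.table(frame = integer(), scan = integer(), mz = numeric(),
                     intensity = numeric(), label = character())
  }
  tryCatch(as_peak_table(dt), error = function(e) {
    stop(sprintf("%s (while reading %s)", conditionMessage(e), path),
         call. = FALSE)
  })
}

#' Write a peak table to a TSV file
#'
#' @param peaks A peak table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- as_peak_table(peaks)
  fwrite(peaks, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read MS1 peaks from an mzML file
#'
#' Consumes only MS-level-1 spectra. The retention-time dimension is
#' represented by `frame`, the 0-based index of the MS1 spectrum in
#' acquisition order; `scan` carries the ion-mobility bin when the file
#' provides drift times, otherwise 0.
#'
#' @param path Path to an mzML file.
#' @return A peak table. An mzML without MS1 spectra yields an empty table
#'   with a warning.
#' @export
read_mzml_ms1 <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) {
    warning("no MS1 spectra in ", path)
    return(as_peak_table(data.table(frame = integer(), scan = integer(),
                                    mz = numeric(), intensity = numeric())))
  }
  drift <- if ("ionMobilityDriftTime" %in% names(hdr)) {
    hdr$ionMobilityDriftTime[ms1]
  } else rep(NA_real_, length(ms1))
  specs <- mzR::peaks(ms, ms1)
  if (is.matrix(specs)) specs <- list(specs)
  npk <- vapply(specs, nrow, integer(1))
  dt <- data.table(
    frame = rep(seq_along(ms1) - 1L, npk),
    scan = rep(ifelse(is.na(drift), 0L, as.integer(round(drift))), npk),
    mz = unlist(lapply(specs, function(s) s[, 1L]), use.names = FALSE),
    intensity = unlist(lapply(specs, function(s) s[, 2L]), use.names = FALSE)
  )
  # drop zero-intensity centroids some converters emit, and guard mz > 0
  dt <- dt[mz > 0]
  as_peak_table(dt)
}
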