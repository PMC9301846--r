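# Evaluation: ROC on labelled synthetic data, precursor matching in
# (m/z, scan) or (m/z, scan, charge) space, and per-frame reduction
# rates. Peaks labelled noise_2 (noise sharing a window with a pattern)
# are excluded from the classification rates: a window-level classifier
# necessarily tags them with the window's call, and downstream feature
# finding removes them; keeping them would only mask the error rate of
# interest.

#' True- and false-positive rate of peak calls
#'
#' `tpr` = signal peaks called signal / all signal peaks;
#' `fpr` = noise_1 peaks called signal / all noise_1 peaks.
#' Peaks labelled `noise_2` or `unlabeled` are ignored.
#'
#' @param calls A peak table with `label` and `call` columns (e.g. from
#'   [lsh_classify()] or [snr_threshold_classifier()]).
#' @param setting Optional identifier copied to the output.
#' @return A one-row data.table with `setting`, `tpr`, `fpr`, `n_signal`,
#'   `n_noise`.
#' @export
roc_point <- function(calls, setting = NA_character_) {
  if (!all(c("label", "call") %in% names(calls))) {
    stop("`calls` needs 'label' and 'call' columns", call. = FALSE)
  }
  calls <- as.data.table(calls)
  sig <- calls$label == "signal"
  noi <- calls$label == "noise_1"
  if (!any(sig) || !any(noi)) {
    stop("labels must include both 'signal' and 'noise_1' peaks",
         call. = FALSE)
  }
  data.table(setting = as.character(setting),
             tpr = mean(calls$call[sig] == "signal"),
             fpr = mean(calls$call[noi] == "signal"),
             n_signal = sum(sig), n_noise = sum(noi))
}

#' ROC sweep of the intensity-threshold baseline
#'
#' One ROC point per threshold. The default thresholds span the quantile
#' range of the observed intensities, reaching both degenerate corners.
#'
#' @param peaks A labelled peak table.
#' @param thresholds Optional numeric vector of intensity cutoffs.
#' @param n_thresholds Number of quantile-spaced cutoffs when
#'   `thresholds` is NULL.
#' @return data.table of ROC points ordered by decreasing threshold, with
#'   a `threshold` column.
#' @export
snr_roc <- function(peaks, thresholds = NULL, n_thresholds = 50L) {
  peaks <- as_peak_table(peaks)
  if (is.null(thresholds)) {
    qs <- quantile(peaks$intensity, probs = seq(0, 1, length.out =
                                                  n_thresholds))
    thresholds <- sort(unique(c(0, qs, max(peaks$intensity) * 1.01)))
  }
  rbindlist(lapply(thresholds, function(t) {
    pt <- roc_point(snr_threshold_classifier(peaks, t),
                    setting = sprintf("snr>=%.4g", t))
    pt[, threshold := t]
    pt
  }))
}

#' Fraction of precursors recovered by the signal windows (2-d matching)
#'
#' Windows called signal are represented as 2-d points (window-centre
#' m/z, scan number); a precursor is matched when its nearest window
#' point lies strictly closer than `radius` in Manhattan distance. The
#' distance mixes m/z units and scan indices; unit scale factors are
#' exposed and default to 1 as no normalisation is defined for the
#' metric.
#'
#' @param windows Window table with `start`, `scan` and `call` columns
#'   (from [lsh_classify()]), or precomputed points with `mz` and `scan`.
#' @param precursors data.table with `mono_mz` and `scan_apex` (or
#'   `scan`) columns.
#' @param radius Manhattan radius (default 5).
#' @param mz_scale,scan_scale Unit weights of the two coordinates.
#' @param window_length Used to turn `start` into the window centre.
#' @return A list with `fraction`, logical `matched` per precursor, and
#'   `nn_dist`.
#' @export
match_precursors_2d <- function(windows, precursors, radius = 5,
                                mz_scale = 1, scan_scale = 1,
                                window_length = 10) {
  windows <- as.data.table(windows)
  precursors <- as.data.table(precursors)
  if (nrow(precursors) == 0L) stop("empty precursor list", call. = FALSE)
  if ("call" %in% names(windows)) windows <- windows[call == "signal"]
  wmz <- if ("mz" %in% names(windows)) windows$mz
         else windows$start + window_length / 2
  wscan <- windows$scan
  pmz <- precursors$mono_mz
  pscan <- precursors[[if ("scan_apex" %in% names(precursors)) "scan_apex"
                       else "scan"]]
  if (length(wmz) == 0L) {
    return(list(fraction = 0, matched = rep(FALSE, nrow(precursors)),
                nn_dist = rep(Inf, nrow(precursors))))
  }
  nn <- vapply(seq_along(pmz), function(i) {
    min(mz_scale * abs(wmz - pmz[i]) + scan_scale * abs(wscan - pscan[i]))
  }, numeric(1))
  matched <- nn < radius
  list(fraction = mean(matched), matched = matched, nn_dist = nn)
}

#' Nested precursor matching in (m/z, scan, charge) space
#'
#' Mirrors the nested tallies of the reference-search evaluation:
#' `k1` precursors have a deisotoping match within `radius` (Manhattan
#' distance over monoisotopic m/z, scan and charge), `k2` of those have a
#' neighbour within the radius whose charge is exactly right, and `k3` of
#' those also reproduce the monoisotopic m/z to `mz_tol`. A match whose
#' m/z is displaced by whole isotope spacings (the characteristic failure
#' of pattern-based deisotoping) therefore counts towards k1/k2 but not
#' k3.
#'
#' @param matches data.table of deisotoping results: `mono_mz`, `scan`,
#'   `charge`.
#' @param precursors data.table with `mono_mz`, `scan_apex` (or `scan`),
#'   `charge`.
#' @param radius Manhattan radius (default 10).
#' @param mz_tol Absolute m/z tolerance of a "perfect" match (default
#'   0.005, half a reference bin).
#' @return list with counts `k1`, `k2`, `k3`, `n` and the per-precursor
#'   logical vectors.
#' @export
match_precursors_3d <- function(matches, precursors, radius = 10,
                                mz_tol = 0.005) {
  matches <- as.data.table(matches)
  precursors <- as.data.table(precursors)
  if (!"charge" %in% names(precursors) || anyNA(precursors$charge)) {
    stop("3-d matching requires precursor charges", call. = FALSE)
  }
  pscan <- precursors[[if ("scan_apex" %in% names(precursors)) "scan_apex"
                       else "scan"]]
  n <- nrow(precursors)
  in1 <- logical(n); in2 <- logical(n); in3 <- logical(n)
  if (nrow(matches)) {
    for (i in seq_len(n)) {
      d <- abs(matches$mono_mz - precursors$mono_mz[i]) +
        abs(matches$scan - pscan[i]) +
        abs(matches$charge - precursors$charge[i])
      near <- d < radius
      in1[i] <- any(near)
      zok <- near & matches$charge == precursors$charge[i]
      in2[i] <- any(zok)
      in3[i] <- any(zok &
                      abs(matches$mono_mz - precursors$mono_mz[i]) <= mz_tol)
    }
  }
  list(k1 = sum(in1), k2 = sum(in2), k3 = sum(in3), n = n,
       matched_k1 = in1, matched_k2 = in2, matched_k3 = in3)
}

#' Data reduction rates of a classification
#'
#' `window_rate` = 1 - (signal windows / all windows);
#' `peak_rate` = 1 - (peaks in signal windows / all peaks), every peak of
#' a signal window counting as kept.
#'
#' @param calls An `lsh_calls` object, or a list with `windows` and
#'   `peaks` tables carrying `call` columns.
#' @return A one-row data.table with `window_rate` and `peak_rate`.
#' @export
reduction_rates <- function(calls) {
  w <- as.data.table(calls$windows)
  p <- as.data.table(calls$peaks)
  if (nrow(w) == 0L || nrow(p) == 0L) {
    warning("empty evaluation unit; rates undefined")
    return(data.table(window_rate = NA_real_, peak_rate = NA_real_))
  }
  data.table(window_rate = 1 - mean(w$call == "signal"),
             peak_rate = 1 - mean(p$call == "signal"))
}

#' Sweep (m, n) settings over randomly sampled frames
#'
#' For every hash-family setting, classifies each sampled frame on its
#' own (frame-wise collision scope), computes the kept-precursor
#' fraction and both reduction rates, and averages over frames.
#'
#' @param peaks A peak table with frame indices.
#' @param precursors Precursor list with `frame`, `mono_mz` and
#'   `scan_apex`/`scan` columns.
#' @param settings data.frame/list of (m, n) pairs, e.g.
#'   `data.frame(m = c(32, 64), n = c(16, 32))`.
#' @param config A [window_grid_config()].
#' @param n_frames Number of frames to sample (default 50).
#' @param skip_first Frames with index below this are excluded from
#'   sampling (default 1500; set 0 for synthetic data).
#' @param radius Manhattan radius of the 2-d matching.
#' @param seed Seed for the frame sample and the hash families.
#' @return data.table with one row per setting: `m`, `n`,
#'   `kept_fraction`, `window_reduction`, `peak_reduction`, `n_frames`.
#' @export
frame_sweep <- function(peaks, precursors, settings, config =
                          window_grid_config(), n_frames = 50L,
                        skip_first = 1500L, radius = 5, seed = 1L) {
  peaks <- as_peak_table(peaks)
  precursors <- as.data.table(precursors)
  settings <- as.data.table(settings)
  avail <- sort(unique(peaks$frame))
  avail <- avail[avail >= skip_first]
  if (length(avail) == 0L) stop("no frames left after skip_first",
                                call. = FALSE)
  if (length(avail) < n_frames) {
    warning(sprintf("only %d frames available; using all", length(avail)))
    n_frames <- length(avail)
  }
  frames <- with_seed(seed, sort(sample(avail, n_frames)))
  rbindlist(lapply(seq_len(nrow(settings)), function(si) {
    fam <- hash_family(settings$m[si], settings$n[si], d = config$n_bins,
                       seed = seed)
    per_frame <- lapply(frames, function(f) {
      fp <- peaks[frame == f]
      if (nrow(fp) == 0L) return(NULL)
      cl <- lsh_classify(fp, fam, config = config)
      red <- reduction_rates(cl)
      pre <- precursors[frame == f]
      kept <- if (nrow(pre)) {
        match_precursors_2d(cl$windows, pre, radius = radius,
                            window_length = config$window_length)$fraction
      } else NA_real_
      data.table(kept = kept, wr = red$window_rate, pr = red$peak_rate)
    })
    per_frame <- rbindlist(per_frame)
    data.table(m = settings$m[si], n = settings$n[si],
               kept_fraction = mean(per_frame$kept, na.rm = TRUE),
               window_reduction = mean(per_frame$wr),
               peak_reduction = mean(per_frame$pr),
               n_frames = nrow(per_frame))
  }))
}
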