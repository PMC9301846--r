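# Labelled synthetic benchmark generator. Two window populations:
#   * noise-only windows: k ~ Pois(lambda_p) + 1 peaks at uniform
#     positions with Exp-distributed intensities, every peak labelled
#     noise_1;
#   * signal windows: an averagine isotopic pattern centred in the
#     window (peaks labelled signal) plus one independently sampled noise
#     overlay (labelled noise_2); each pattern is emitted once at full
#     scale and as n_copies extra windows at half intensity, modelling
#     the recurrence of a pattern across consecutive time points.
# The (mass, charge) grid and the m/z filter determine the number of
# signal windows; the defaults reproduce the published benchmark counts
# (4338 signal + 14107 noise = 18445 windows) under the "window" filter
# convention with plain m/z and charges 1-4, which the manifest records.

#' Noise model for synthetic windows
#'
#' Peak count per window is `Pois(lambda_p) + 1` (so never zero);
#' positions are uniform within the window; intensities follow an
#' exponential law.
#'
#' @param lambda_p Mean of the Poisson count term (default 4, i.e. five
#'   peaks per window on average).
#' @param lambda_e Exponential intensity parameter (default 15).
#' @param intensity_param Either `"rate"` (default; mean intensity
#'   `1/lambda_e`) or `"mean"` (mean intensity `lambda_e`). The two
#'   parametrisations differ only by the intensity scale, to which the
#'   LSH calls are blind; the intensity-threshold baseline is not.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(lambda_p = 4, lambda_e = 15,
                        intensity_param = c("rate", "mean")) {
  stop_if_not_scalar_number(lambda_p, "lambda_p", lower = 1e-12)
  stop_if_not_scalar_number(lambda_e, "lambda_e", lower = 1e-12)
  intensity_param <- match.arg(intensity_param)
  structure(list(lambda_p = lambda_p, lambda_e = lambda_e,
                 intensity_param = intensity_param,
                 rate = if (intensity_param == "rate") lambda_e
                        else 1 / lambda_e),
            class = "noise_model")
}

#' Sample noise peaks for one or more windows
#'
#' @param model A [noise_model()].
#' @param window_length Window extent in m/z.
#' @param n_windows Number of windows to fill.
#' @param seed Optional seed (caller RNG preserved).
#' @return data.table with columns `window` (1..n_windows), `pos`
#'   (offset from the window start, in \[0, window_length)) and
#'   `intensity`.
#' @export
sample_noise_peaks <- function(model = noise_model(), window_length = 10,
                               n_windows = 1L, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  with_seed(seed, {
    k <- rpois(n_windows, model$lambda_p) + 1L
    data.table(
      window = rep(seq_len(n_windows), k),
      pos = runif(sum(k), 0, window_length),
      intensity = rexp(sum(k), rate = model$rate)
    )
  })
}

#' Configuration of the synthetic signal grid
#'
#' @param mass_min,mass_max,mass_step Neutral monoisotopic mass grid in u
#'   (defaults 150 to 5000 in steps of 10).
#' @param charges Charge states to combine with each mass (default 1:4;
#'   see `mz_filter`).
#' @param mz_min,mz_max m/z interval of the simulated acquisition
#'   (default \[150, 2000\]).
#' @param mz_filter How a (mass, charge) combination is tested against
#'   the interval: `"window"` (default) requires the whole 10-m/z window
#'   centred on the monoisotopic peak to fit inside; `"mono"` tests the
#'   monoisotopic m/z only. With the defaults (`"window"`, plain m/z,
#'   charges 1:4) the grid yields exactly 1446 combinations and hence
#'   4338 signal windows.
#' @param protonated When TRUE the filter m/z is
#'   `(mass + z * m_proton) / z`; default FALSE uses `mass / z`.
#' @param n_extra_isotope_peaks Isotopologues beyond the monoisotopic one
#'   (default 5, i.e. six-peak patterns).
#' @param n_copies Half-intensity repeat windows per pattern (default 2).
#' @param copy_scale Intensity scale of the copies (default 0.5).
#' @param max_intensity Intensity of the strongest signal peak of each
#'   full-scale pattern (default 1000; the benchmark series also uses
#'   500, 250, 125, 64, 32).
#' @param window_length Window extent in m/z (default 10).
#' @param n_noise_windows Number of noise-only windows (default 14107).
#' @return A list of class `signal_grid_config`.
#' @export
signal_grid_config <- function(mass_min = 150, mass_max = 5000,
                               mass_step = 10, charges = 1:4,
                               mz_min = 150, mz_max = 2000,
                               mz_filter = c("window", "mono"),
                               protonated = FALSE,
                               n_extra_isotope_peaks = 5L,
                               n_copies = 2L, copy_scale = 0.5,
                               max_intensity = 1000,
                               window_length = 10,
                               n_noise_windows = 14107L) {
  mz_filter <- match.arg(mz_filter)
  stopifnot(mass_min <= mass_max, mass_step > 0,
            copy_scale > 0, copy_scale <= 1,
            n_copies >= 0, max_intensity > 0, n_noise_windows >= 0)
  structure(list(mass_min = mass_min, mass_max = mass_max,
                 mass_step = mass_step, charges = as.integer(charges),
                 mz_min = mz_min, mz_max = mz_max, mz_filter = mz_filter,
                 protonated = protonated,
                 n_extra_isotope_peaks = as.integer(n_extra_isotope_peaks),
                 n_copies = as.integer(n_copies), copy_scale = copy_scale,
                 max_intensity = max_intensity,
                 window_length = window_length,
                 n_noise_windows = as.integer(n_noise_windows)),
            class = "signal_grid_config")
}

#' Accepted (mass, charge) combinations of a signal grid
#'
#' Applies the m/z filter of the configuration and returns one row per
#' surviving combination with the window geometry.
#'
#' @param grid A [signal_grid_config()].
#' @return data.table with `mono_mass`, `charge`, `center_mz` (filter
#'   m/z, the window centre) and `start` (window start).
#' @export
signal_grid_combos <- function(grid) {
  stopifnot(inherits(grid, "signal_grid_config"))
  masses <- seq(grid$mass_min, grid$mass_max, by = grid$mass_step)
  combos <- CJ(charge = grid$charges, mono_mass = masses)
  mp <- if (grid$protonated) .mass_proton else 0
  combos[, center_mz := (mono_mass + charge * mp) / charge]
  half <- grid$window_length / 2
  keep <- if (grid$mz_filter == "window") {
    combos$center_mz - half >= grid$mz_min &
      combos$center_mz + half <= grid$mz_max
  } else {
    combos$center_mz >= grid$mz_min & combos$center_mz <= grid$mz_max
  }
  combos <- combos[keep]
  combos[, start := center_mz - half]
  setorder(combos, mono_mass, charge)
  combos[]
}

# pattern peaks (no noise) for each combo row; intensities unit-max
.pattern_peaks <- function(combos, grid) {
  if (nrow(combos) == 0L) {
    return(data.table(combo = integer(), pos = numeric(),
                      intensity = numeric()))
  }
  n_pk <- grid$n_extra_isotope_peaks + 1L
  u_mass <- unique(combos$mono_mass)
  env <- vapply(u_mass, function(M) {
    isotope_distribution(averagine_composition(M), n_pk)
  }, numeric(n_pk))
  half <- grid$window_length / 2
  k <- rep(0:(n_pk - 1L), times = nrow(combos))
  combo <- rep(seq_len(nrow(combos)), each = n_pk)
  pos <- half + k * .iso_spacing / combos$charge[combo]
  intensity <- env[, match(combos$mono_mass, u_mass),
                   drop = FALSE][cbind(k + 1L, combo)]
  out <- data.table(combo = combo, pos = pos, intensity = intensity)
  # peaks spilling past the window end are not representable (at z = 1
  # the fifth extra isotopologue sits 5.017 m/z above the centre), and a
  # zero-abundance isotopologue is no peak at all (light masses have
  # fewer than six isotopologues above numerical zero)
  out[pos < grid$window_length & intensity > 0]
}

#' Generate the signal windows of one (mass, charge) combination
#'
#' One full-scale window plus `n_copies` windows with the pattern scaled
#' by `copy_scale`, each with its own independently sampled noise
#' overlay. Returns an empty table when the combination fails the m/z
#' filter.
#'
#' @param mono_mass,charge The combination.
#' @param grid A [signal_grid_config()].
#' @param noise A [noise_model()].
#' @param seed Optional seed.
#' @return data.table of peaks with `copy` (0 = original), `window_start`,
#'   `mz`, `intensity`, `label` (signal / noise_2).
#' @export
make_signal_windows <- function(mono_mass, charge,
                                grid = signal_grid_config(),
                                noise = noise_model(), seed = NULL) {
  one <- signal_grid_config(mass_min = mono_mass, mass_max = mono_mass,
                            mass_step = grid$mass_step, charges = charge,
                            mz_min = grid$mz_min, mz_max = grid$mz_max,
                            mz_filter = grid$mz_filter,
                            protonated = grid$protonated,
                            n_extra_isotope_peaks = grid$n_extra_isotope_peaks,
                            n_copies = grid$n_copies,
                            copy_scale = grid$copy_scale,
                            max_intensity = grid$max_intensity,
                            window_length = grid$window_length,
                            n_noise_windows = 0L)
  ds <- generate_dataset(one, noise, seed = seed %||% 1L)
  pk <- ds$peaks[, .(copy = ds$windows$copy[window_id], window_start,
                     mz, intensity, label)]
  pk[]
}

#' Generate a labelled synthetic benchmark dataset
#'
#' See the package vignette for the full construction. With the default
#' configuration the dataset holds 18445 windows: 14107 noise-only and
#' 4338 signal-bearing (1446 grid combinations times three windows).
#'
#' @param grid A [signal_grid_config()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-identically.
#' @param as_frames When TRUE, windows are scattered over `n_frames`
#'   synthetic frames: the three repeats of a pattern occupy consecutive
#'   frames at the same m/z, noise windows land on random frames. The
#'   default keeps the repeat index as the frame.
#' @param n_frames Number of frames for `as_frames`.
#' @return An object of class `lsh_dataset`: list with `peaks` (peak
#'   table plus `window_id`, `window_start`), `windows` (per-window
#'   metadata: `window_id`, `kind`, `frame`, `scan`, `start`, `mono_mass`,
#'   `charge`, `copy`) and `manifest` (named list of generation
#'   parameters, the filter convention and the achieved class counts).
#' @export
generate_dataset <- function(grid = signal_grid_config(),
                             noise = noise_model(), seed = 1L,
                             as_frames = FALSE, n_frames = 100L) {
  stopifnot(inherits(grid, "signal_grid_config"),
            inherits(noise, "noise_model"))
  combos <- signal_grid_combos(grid)
  n_combo <- nrow(combos)
  n_per <- grid$n_copies + 1L
  n_sig <- n_combo * n_per
  n_noise <- grid$n_noise_windows
  L <- grid$window_length

  pattern <- .pattern_peaks(combos, grid)
  pattern[, intensity := intensity * grid$max_intensity]

  out <- with_seed(seed, {
    # -- signal windows: original + copies, each with its own overlay
    sig_windows <- data.table(
      combo = rep(seq_len(max(n_combo, 0L)), each = n_per),
      copy = rep(0:grid$n_copies, times = n_combo)
    )
    sig_windows[, window_id := .I]
    sig_peaks <- if (n_sig > 0L) {
      pk <- pattern[rep(seq_len(nrow(pattern)), times = n_per)]
      wrow <- sig_windows[, .(window_id, combo, copy)]
      # replicate pattern per copy: order by copy-block, combo
      pk[, copy := rep(0:grid$n_copies, each = nrow(pattern))]
      pk <- merge(pk, wrow, by = c("combo", "copy"), sort = FALSE)
      pk[copy > 0L, intensity := intensity * grid$copy_scale]
      pk[, label := "signal"]
      pk
    } else {
      data.table(combo = integer(), pos = numeric(), intensity = numeric(),
                 copy = integer(), window_id = integer(),
                 label = character())
    }
    overlay <- sample_noise_peaks(noise, L, n_windows = n_sig)
    overlay[, `:=`(window_id = window, label = "noise_2",
                   combo = sig_windows$combo[window],
                   copy = sig_windows$copy[window])]
    overlay[, c("pos", "window") := .(pos, NULL)]

    # -- noise-only windows on random positions of the m/z range
    noise_starts <- runif(n_noise, grid$mz_min, grid$mz_max - L)
    noise_pk <- sample_noise_peaks(noise, L, n_windows = n_noise)
    noise_pk[, `:=`(window_id = n_sig + window, label = "noise_1",
                    combo = NA_integer_, copy = NA_integer_)]
    noise_pk[, window := NULL]

    windows <- rbind(
      data.table(window_id = sig_windows$window_id, kind = "signal",
                 start = combos$start[sig_windows$combo],
                 mono_mass = combos$mono_mass[sig_windows$combo],
                 charge = combos$charge[sig_windows$combo],
                 copy = sig_windows$copy),
      data.table(window_id = n_sig + seq_len(n_noise), kind = "noise",
                 start = noise_starts, mono_mass = NA_real_,
                 charge = NA_integer_, copy = NA_integer_)
    )
    if (as_frames) {
      # one frame per pattern; the repeats occupy consecutive mobility
      # scans of that frame, so frame-wise collision scope still sees the
      # recurrence (as it does across scans of an ion-mobility frame)
      base <- sample.int(n_frames, n_combo, replace = TRUE) - 1L
      frame <- c(base[sig_windows$combo],
                 sample.int(n_frames, n_noise, replace = TRUE) - 1L)
      scan <- c(sig_windows$copy,
                sample.int(n_per + 1L, n_noise, replace = TRUE) - 1L)
    } else {
      frame <- c(sig_windows$copy, rep(0L, n_noise))
      scan <- rep(0L, n_sig + n_noise)
    }
    windows[, frame := as.integer(frame)]
    windows[, scan := as.integer(scan)]

    peaks <- rbind(sig_peaks[, .(window_id, pos, intensity, label)],
                   overlay[, .(window_id, pos, intensity, label)],
                   noise_pk[, .(window_id, pos, intensity, label)])
    setorder(peaks, window_id, pos)
    peaks[, window_start := windows$start[window_id]]
    peaks[, mz := window_start + pos]
    peaks[, `:=`(frame = windows$frame[window_id],
                 scan = windows$scan[window_id])]
    list(windows = windows, peaks = peaks)
  })

  peaks <- out$peaks[, .(frame, scan, mz, intensity, label,
                         window_id, window_start)]
  label_counts <- table(factor(peaks$label, levels = .peak_labels))
  manifest <- c(
    list(seed = seed,
         n_windows = n_sig + n_noise,
         n_noise_windows = n_noise,
         n_signal_windows = n_sig,
         n_grid_combinations = n_combo,
         n_peaks = nrow(peaks)),
    as.list(setNames(as.integer(label_counts),
                     paste0("n_peaks_", names(label_counts)))),
    unclass(grid),
    list(charges = paste(grid$charges, collapse = ",")),
    list(noise_lambda_p = noise$lambda_p, noise_lambda_e = noise$lambda_e,
         noise_intensity_param = noise$intensity_param,
         as_frames = as_frames,
         mz_convention = sprintf(
           "%s filter, %s m/z, charges %s",
           grid$mz_filter,
           if (grid$protonated) "protonated" else "plain",
           paste(range(grid$charges), collapse = "-")))
  )
  structure(list(peaks = peaks, windows = out$windows, manifest = manifest),
            class = "lsh_dataset")
}

#' @export
print.lsh_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<lsh_dataset> %d windows (%d signal-bearing, %d noise-only), %d peaks\n",
    m$n_windows, m$n_signal_windows, m$n_noise_windows, m$n_peaks))
  cat(sprintf("  seed %s | max signal intensity %s | %s\n",
              format(m$seed), format(m$max_intensity), m$mz_convention))
  invisible(x)
}

#' Intensity series of benchmark datasets
#'
#' One dataset per maximum signal intensity, sharing the seed: the grid,
#' the noise-only windows and every noise peak are identical across the
#' series, only the signal-labelled peaks are rescaled.
#'
#' @param grid Base configuration (its `max_intensity` is overridden).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param intensities Maximum signal intensities (default the benchmark
#'   series 1000, 500, 250, 125, 64, 32).
#' @return Named list of `lsh_dataset` objects.
#' @export
intensity_series <- function(grid = signal_grid_config(),
                             noise = noise_model(), seed = 1L,
                             intensities = c(1000, 500, 250, 125, 64, 32)) {
  base_int <- intensities[1L]
  base_grid <- grid
  base_grid$max_intensity <- base_int
  base <- generate_dataset(base_grid, noise, seed = seed)
  out <- lapply(intensities, function(I) {
    ds <- base
    ds$peaks <- copy(base$peaks)
    ds$peaks[label == "signal", intensity := intensity * (I / base_int)]
    ds$manifest$max_intensity <- I
    ds
  })
  names(out) <- paste0("I", intensities)
  out
}

#' Interpret a dataset's generator windows as an `lsh_windows` object
#'
#' The generator emits windows directly (each peak belongs to exactly one
#' window), so no re-windowing is applied before hashing.
#'
#' @param dataset An `lsh_dataset`.
#' @param config Optional [window_grid_config()]; the default uses the
#'   dataset's window length with 0.1 m/z bins.
#' @return An `lsh_windows` object (see [make_windows()]).
#' @export
dataset_windows <- function(dataset, config = NULL) {
  stopifnot(inherits(dataset, "lsh_dataset"))
  config <- config %||%
    window_grid_config(window_length = dataset$manifest$window_length,
                       bin_resolution = 0.1)
  peaks <- as_peak_table(dataset$peaks[, .(frame, scan, mz, intensity,
                                           label)])
  peaks[, peak_id := .I]
  assign <- copy(peaks)
  assign[, `:=`(window_id = dataset$peaks$window_id,
                start = dataset$peaks$window_start,
                offset_grid = FALSE)]
  windows <- dataset$windows[, .(window_id, frame, scan, start,
                                 offset_grid = FALSE)]
  windows[, n_peaks := tabulate(assign$window_id, nbins = max(window_id))]
  structure(list(windows = windows, assign = assign, peaks = peaks,
                 config = config),
            class = "lsh_windows")
}

#' Write a dataset (peaks + manifest) to disk
#'
#' Peaks go to `<prefix>_peaks.tsv` (the standard peak-table TSV with
#' `window_id` and `window_start` columns appended); the manifest to
#' `<prefix>_manifest.txt` as tab-separated key/value lines.
#'
#' @param dataset An `lsh_dataset`.
#' @param prefix Path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "lsh_dataset"))
  peaks_path <- paste0(prefix, "_peaks.tsv")
  man_path <- paste0(prefix, "_manifest.txt")
  fwrite(dataset$peaks, peaks_path, sep = "\t", quote = FALSE)
  man <- dataset$manifest
  lines <- sprintf("%s\t%s", names(man),
                   vapply(man, function(v) paste(format(v, scientific = FALSE),
                                                 collapse = ","),
                          character(1)))
  writeLines(lines, man_path)
  invisible(c(peaks = peaks_path, manifest = man_path))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `lsh_dataset` (manifest values come back as character).
#' @export
read_dataset <- function(prefix) {
  peaks <- fread(paste0(prefix, "_peaks.tsv"), sep = "\t",
                 showProgress = FALSE)
  man_lines <- readLines(paste0(prefix, "_manifest.txt"))
  kv <- strsplit(man_lines, "\t", fixed = TRUE)
  manifest <- setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  windows <- peaks[, .(frame = frame[1L], scan = scan[1L],
                       start = window_start[1L],
                       kind = if (any(label %in% c("signal", "noise_2")))
                         "signal" else "noise"),
                   by = window_id]
  windows[, `:=`(mono_mass = NA_real_, charge = NA_integer_,
                 copy = NA_integer_)]
  structure(list(peaks = peaks, windows = windows, manifest = manifest),
            class = "lsh_dataset")
}
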