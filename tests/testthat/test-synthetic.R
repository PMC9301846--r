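test_that("noise peak counts and intensities follow the stated laws", {
  nm <- noise_model()
  pk <- sample_noise_peaks(nm, 10, n_windows = 100000L, seed = 4)
  k <- pk[, .N, by = window]$N
  expect_gte(min(k), 1L)                       # the +1 term
  se_k <- sqrt(4 / 1e5)                        # var of Pois(4) draws
  expect_lt(abs(mean(k) - 5), 3 * se_k)
  se_i <- (1 / 15) / sqrt(nrow(pk))
  expect_lt(abs(mean(pk$intensity) - 1 / 15), 3 * se_i)
  expect_true(all(pk$pos >= 0 & pk$pos < 10))
  # alternative parametrisation: lambda_e as the mean
  nm2 <- noise_model(intensity_param = "mean")
  pk2 <- sample_noise_peaks(nm2, 10, n_windows = 20000L, seed = 4)
  expect_lt(abs(mean(pk2$intensity) - 15), 3 * 15 / sqrt(nrow(pk2)))
})

test_that("the default grid reproduces the benchmark combination count", {
  combos <- signal_grid_combos(signal_grid_config())
  expect_equal(nrow(combos), 1446L)
  # the window-fit filter: every window inside [150, 2000]
  expect_true(all(combos$start >= 150 & combos$start + 10 <= 2000))
})

test_that("signal windows carry the pattern, its copies and an overlay", {
  grid <- signal_grid_config()
  pk <- make_signal_windows(1000, 2, grid, seed = 8)
  expect_equal(length(unique(pk$copy)), 3L)    # original + 2 copies
  orig <- pk[copy == 0 & label == "signal"]
  cp1 <- pk[copy == 1 & label == "signal"]
  expect_equal(nrow(orig), 6L)                 # mono + 5, charge 2 fits
  expect_equal(cp1$intensity, 0.5 * orig$intensity)
  expect_equal(max(orig$intensity), 1000)
  expect_equal(sort(unique(pk$label)), c("noise_2", "signal"))
  # charge-3 spacing
  pk3 <- make_signal_windows(900, 3, grid, seed = 8)[label == "signal" &
                                                       copy == 0]
  expect_equal(unique(round(diff(pk3$mz), 4)), round(1.003355 / 3, 4))
})

test_that("a degenerate grid yields exactly one signal window", {
  grid <- signal_grid_config(mass_min = 1000, mass_max = 1000,
                             charges = 2L, n_copies = 0L,
                             n_noise_windows = 0L)
  ds <- generate_dataset(grid, seed = 1)
  expect_equal(ds$manifest$n_windows, 1L)
  expect_equal(ds$manifest$n_signal_windows, 1L)
})

test_that("labels partition the peaks and the manifest counts add up", {
  ds <- generate_dataset(small_grid(), seed = 2)
  m <- ds$manifest
  expect_true(all(ds$peaks$label %in% c("signal", "noise_1", "noise_2")))
  expect_equal(m$n_peaks_signal + m$n_peaks_noise_1 + m$n_peaks_noise_2,
               nrow(ds$peaks))
  expect_equal(m$n_windows, m$n_signal_windows + m$n_noise_windows)
  # noise-only windows hold only noise_1; signal windows only signal/noise_2
  kinds <- ds$windows[, .(window_id, kind)]
  bywin <- ds$peaks[kinds, on = "window_id"]
  expect_true(all(bywin[kind == "noise", label] == "noise_1"))
  expect_true(all(bywin[kind == "signal", label] %in%
                    c("signal", "noise_2")))
  # every signal window keeps at least 4 pattern peaks: at charge 1 the
  # fifth extra isotopologue falls past the window end, and below ~250 Da
  # the far envelope terms are numerically zero (no peak is emitted)
  nsig <- bywin[kind == "signal" & label == "signal", .N, by = window_id]
  expect_gte(min(nsig$N), 4L)
  z2 <- ds$windows[kind == "signal" & charge >= 2 & mono_mass >= 250,
                   window_id]
  expect_true(all(nsig[window_id %in% z2, N] == 6L))
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(generate_dataset(small_grid(), seed = 33), d1)
  write_dataset(generate_dataset(small_grid(), seed = 33), d2)
  expect_identical(readLines(paste0(d1, "_peaks.tsv")),
                   readLines(paste0(d2, "_peaks.tsv")))
  expect_identical(readLines(paste0(d1, "_manifest.txt")),
                   readLines(paste0(d2, "_manifest.txt")))
  d3 <- generate_dataset(small_grid(), seed = 34)
  expect_false(identical(generate_dataset(small_grid(), seed = 33)$peaks,
                         d3$peaks))
})

test_that("the intensity series rescales signal only", {
  series <- intensity_series(small_grid(), seed = 6)
  expect_length(series, 6L)
  expect_equal(vapply(series, function(d) d$manifest$max_intensity,
                      numeric(1)),
               c(I1000 = 1000, I500 = 500, I250 = 250, I125 = 125,
                 I64 = 64, I32 = 32))
  a <- series$I1000$peaks; b <- series$I500$peaks
  expect_equal(a[label == "signal", intensity],
               2 * b[label == "signal", intensity], tolerance = 1e-12)
  expect_identical(a[label != "signal", intensity],
                   b[label != "signal", intensity])
  expect_identical(a$mz, b$mz)
})

test_that("dataset windows round-trip into the classification pipeline", {
  ds <- generate_dataset(small_grid(n_noise = 50L), seed = 3)
  dw <- dataset_windows(ds)
  expect_equal(nrow(dw$windows), ds$manifest$n_windows)
  expect_equal(nrow(dw$assign), nrow(ds$peaks))
  b <- bin_windows(dw)
  expect_equal(ncol(b$intensities), 100L)
  expect_true(all(rowSums(b$intensities) > 0))
})

test_that("datasets survive a disk round trip", {
  ds <- generate_dataset(small_grid(n_noise = 40L), seed = 12)
  prefix <- tempfile()
  write_dataset(ds, prefix)
  back <- read_dataset(prefix)
  expect_equal(nrow(back$peaks), nrow(ds$peaks))
  expect_equal(back$peaks$mz, ds$peaks$mz, tolerance = 1e-9)
  expect_equal(as.integer(back$manifest$n_windows), ds$manifest$n_windows)
  expect_equal(nrow(back$windows), ds$manifest$n_windows)
})
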