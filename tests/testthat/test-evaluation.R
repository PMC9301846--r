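make_calls <- function(labels, calls) {
  data.table(frame = 0L, scan = 0L, mz = seq_along(labels) + 100,
             intensity = 1, label = labels, call = calls)
}

test_that("ROC points hit the degenerate corners and exclude noise_2", {
  labels <- c(rep("signal", 4), rep("noise_1", 4), rep("noise_2", 2))
  perfect <- make_calls(labels, c(rep("signal", 4), rep("noise", 6)))
  expect_equal(roc_point(perfect)[, .(tpr, fpr)], data.table(tpr = 1,
                                                             fpr = 0))
  all_in <- make_calls(labels, rep("signal", 10))
  expect_equal(roc_point(all_in)[, .(tpr, fpr)], data.table(tpr = 1,
                                                            fpr = 1))
  none <- make_calls(labels, rep("noise", 10))
  expect_equal(roc_point(none)[, .(tpr, fpr)], data.table(tpr = 0, fpr = 0))
  # flipping the noise_2 calls changes nothing
  flipped <- make_calls(labels, c(rep("signal", 4), rep("noise", 4),
                                  "signal", "signal"))
  expect_equal(roc_point(flipped)[, .(tpr, fpr)],
               roc_point(perfect)[, .(tpr, fpr)])
  expect_error(roc_point(make_calls(rep("signal", 3), rep("signal", 3))),
               "noise_1")
})

test_that("a coin-flip classifier sits near (0.5, 0.5)", {
  set.seed(17)
  n <- 10000L
  labels <- sample(c("signal", "noise_1"), n, TRUE)
  calls <- sample(c("signal", "noise"), n, TRUE)
  pt <- roc_point(make_calls(labels, calls))
  se <- 0.5 / sqrt(n / 2)
  expect_lt(abs(pt$tpr - 0.5), 3 * se)
  expect_lt(abs(pt$fpr - 0.5), 3 * se)
})

test_that("the SNR sweep spans both ROC corners monotonically", {
  ds <- generate_dataset(small_grid(), seed = 7)
  roc <- snr_roc(ds$peaks, n_thresholds = 25)
  setorder(roc, threshold)
  expect_equal(roc[1, .(tpr, fpr)], data.table(tpr = 1, fpr = 1))
  expect_equal(roc[.N, .(tpr, fpr)], data.table(tpr = 0, fpr = 0))
  expect_true(all(diff(roc$tpr) <= 1e-12))
  expect_true(all(diff(roc$fpr) <= 1e-12))
})

test_that("2-d precursor matching applies the Manhattan radius strictly", {
  windows <- data.table(start = c(495, 605), scan = c(10L, 40L),
                        call = c("signal", "signal"))
  # centres at 500 and 610
  res <- match_precursors_2d(windows,
                             data.table(mono_mz = 500, scan_apex = 10))
  expect_equal(res$fraction, 1)
  expect_equal(res$nn_dist, 0)
  expect_true(match_precursors_2d(
    windows, data.table(mono_mz = 502, scan_apex = 12))$matched)   # 4 < 5
  expect_false(match_precursors_2d(
    windows, data.table(mono_mz = 503, scan_apex = 13))$matched)   # 6 >= 5
  expect_false(match_precursors_2d(
    windows, data.table(mono_mz = 502.5, scan_apex = 12.5))$matched) # 5 >= 5
  expect_error(match_precursors_2d(windows, data.table(mono_mz = numeric(),
                                                       scan_apex = numeric())),
               "empty")
  # noise-only windows keep nothing
  res0 <- match_precursors_2d(
    data.table(start = 495, scan = 10L, call = "noise"),
    data.table(mono_mz = 500, scan_apex = 10))
  expect_equal(res0$fraction, 0)
})

test_that("3-d matching produces the nested k1/k2/k3 tallies", {
  pre <- data.table(mono_mz = c(500, 600, 700), scan_apex = c(5, 5, 5),
                    charge = c(2L, 2L, 3L))
  matches <- data.table(
    mono_mz = c(500,                      # exact -> k1, k2, k3
                600,                      # charge off by one -> k1 only
                700 + 1.003355 / 3),      # shifted by one spacing -> k1, k2
    scan = c(5, 5, 5),
    charge = c(2L, 3L, 3L))
  res <- match_precursors_3d(matches, pre)
  expect_equal(res$k1, 3L)
  expect_equal(res$k2, 2L)
  expect_equal(res$k3, 1L)
  expect_true(all(res$matched_k3 <= res$matched_k2))
  expect_true(all(res$matched_k2 <= res$matched_k1))
  expect_error(match_precursors_3d(matches, pre[, .(mono_mz, scan_apex)]),
               "charge")
})

test_that("reduction rates are the kept-fraction complements", {
  calls <- list(
    windows = data.table(call = c(rep("signal", 4), rep("noise", 6))),
    peaks = data.table(call = c(rep("signal", 55), rep("noise", 45)))
  )
  expect_equal(reduction_rates(calls),
               data.table(window_rate = 0.6, peak_rate = 0.45))
  all_noise <- list(windows = data.table(call = rep("noise", 3)),
                    peaks = data.table(call = rep("noise", 9)))
  expect_equal(reduction_rates(all_noise),
               data.table(window_rate = 1, peak_rate = 1))
  all_sig <- list(windows = data.table(call = rep("signal", 3)),
                  peaks = data.table(call = rep("signal", 9)))
  expect_equal(reduction_rates(all_sig),
               data.table(window_rate = 0, peak_rate = 0))
})

test_that("frame sweep is seeded, shaped per setting, and self-consistent", {
  ds <- generate_dataset(small_grid(n_noise = 120L), seed = 10,
                         as_frames = TRUE, n_frames = 12L)
  pre <- ds$windows[kind == "signal" & copy == 0,
                    .(frame, mono_mz = start + 5, scan_apex = scan)]
  settings <- data.table(m = c(8, 64), n = c(16, 8))
  s1 <- frame_sweep(ds$peaks, pre, settings, n_frames = 6L, skip_first = 0L,
                    seed = 5)
  s2 <- frame_sweep(ds$peaks, pre, settings, n_frames = 6L, skip_first = 0L,
                    seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2L)
  expect_true(all(s1$kept_fraction >= 0 & s1$kept_fraction <= 1))
  expect_true(all(s1$window_reduction >= 0 & s1$window_reduction <= 1))
  # more frames requested than exist: use all, with a warning
  expect_warning(
    frame_sweep(ds$peaks, pre, settings[1], n_frames = 500L,
                skip_first = 0L, seed = 5),
    "using all")
})

test_that("keeping rate rises with m while the reduction rate falls", {
  ds <- generate_dataset(small_grid(n_noise = 200L), seed = 20,
                         as_frames = TRUE, n_frames = 10L)
  pre <- ds$windows[kind == "signal" & copy == 0,
                    .(frame, mono_mz = start + 5, scan_apex = scan)]
  settings <- data.table(m = c(4, 16, 64), n = 16)
  sw <- frame_sweep(ds$peaks, pre, settings, n_frames = 8L, skip_first = 0L,
                    seed = 2)
  expect_true(all(diff(sw$kept_fraction) >= -0.05))
  expect_true(all(diff(sw$window_reduction) <= 0.05))
})
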