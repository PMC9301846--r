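# shared fixtures and independent oracles, built in code at test time

library(data.table)

# small peak table spanning a few windows on two mass axes
toy_peaks <- function() {
  data.table(
    frame = c(0L, 0L, 0L, 0L, 1L, 1L),
    scan = c(0L, 0L, 0L, 0L, 0L, 0L),
    mz = c(500.2, 502.55, 509.8, 155.0, 500.2, 502.55),
    intensity = c(3, 7, 2, 1, 3, 7)
  )
}

# brute-force collision oracle: all-pairs band comparison, independent of
# the collision-table path
brute_force_window_calls <- function(signatures) {
  W <- nrow(signatures)
  calls <- rep("noise", W)
  if (W < 2L) return(calls)
  for (i in seq_len(W - 1L)) {
    for (j in seq(i + 1L, W)) {
      if (any(signatures[i, ] == signatures[j, ])) {
        calls[i] <- "signal"
        calls[j] <- "signal"
      }
    }
  }
  calls
}

# brute-force collided (band, key) pairs
brute_force_collided_pairs <- function(signatures) {
  out <- list()
  for (b in seq_len(ncol(signatures))) {
    k <- signatures[, b]
    dup <- unique(k[duplicated(k)])
    for (d in dup) out[[length(out) + 1L]] <- c(band = b, key = d)
  }
  out
}

# a pair of unit vectors in R^d with exact cosine similarity s
fixed_cosine_pair <- function(s, d = 100L, seed = 1L) {
  set.seed(seed)
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  w <- rnorm(d); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
  list(u = u, v = s * u + sqrt(1 - s^2) * w)
}

# minimal centroided mzML written through mzR
write_test_mzml <- function(path, spectra, ms_level = 1L) {
  n <- length(spectra)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(ms_level, n), polarity = rep(1L, n),
    peaksCount = vapply(spectra, nrow, integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s[, 2]), numeric(1)),
    retentionTime = seq_len(n) * 1.0,
    basePeakMZ = vapply(spectra, function(s) s[which.max(s[, 2]), 1],
                        numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) max(s[, 2]), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) min(s[, 1]), numeric(1)),
    highMZ = vapply(spectra, function(s) max(s[, 1]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(spectra, path, header = hdr, outformat = "mzml")
  path
}

# tiny benchmark configuration for fast end-to-end runs
small_grid <- function(n_noise = 300L, max_intensity = 1000) {
  signal_grid_config(mass_min = 300, mass_max = 1500, mass_step = 50,
                     n_noise_windows = n_noise,
                     max_intensity = max_intensity)
}
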