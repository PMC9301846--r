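# Averagine isotope-envelope model. A peptide of unknown sequence is
# approximated by a fictitious average residue of composition
# C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 and mass 111.1254 Da (Senko's
# averagine); scaling the residue to a target mass gives fractional
# element counts, which are used directly -- the aggregated isotope
# distribution of a fractional atom count is well defined through the
# generating-function power (p(x))^count, evaluated with the J.C.P. Miller
# recurrence.

.averagine_residue <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                        S = 0.0417)
.averagine_residue_mass <- 111.1254

# natural isotope abundances aggregated by nucleon-count shift (IUPAC)
.element_isotopes <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Averagine elemental composition for a given mass
#'
#' Scales the average residue linearly: counts =
#' `(mass / 111.1254) * (C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417)`.
#' Counts are fractional by design.
#'
#' @param mass Neutral monoisotopic mass in Da (> 0).
#' @return Named numeric vector of element counts (C, H, N, O, S).
#' @export
averagine_composition <- function(mass) {
  stop_if_not_scalar_number(mass, "mass", lower = 1e-9)
  (mass / .averagine_residue_mass) * .averagine_residue
}

# Coefficients of (sum_k a[k+1] x^k)^alpha up to x^(nterms-1), a[1] > 0.
# J.C.P. Miller: b_0 = a_0^alpha,
#   b_j = (1/(j a_0)) * sum_{k=1..j} (k (alpha+1) - j) a_k b_{j-k}.
.series_power <- function(a, alpha, nterms) {
  a <- c(a, rep(0, max(0, nterms - length(a))))[seq_len(nterms)]
  b <- numeric(nterms)
  b[1] <- a[1]^alpha
  for (j in seq_len(nterms - 1L)) {
    k <- seq_len(j)
    b[j + 1L] <- sum((k * (alpha + 1) - j) * a[k + 1L] * b[j - k + 1L]) /
      (j * a[1])
  }
  b
}

# multiply two truncated power series
.series_mult <- function(a, b, nterms) {
  out <- numeric(nterms)
  for (j in seq_along(a)) {
    k <- j:min(nterms, j + length(b) - 1L)
    out[k] <- out[k] + a[j] * b[k - j + 1L]
  }
  out
}

#' Aggregated isotope distribution of an elemental composition
#'
#' Convolves the per-element natural isotope distributions (aggregated by
#' nucleon-count shift) and returns the relative abundances of the first
#' `n_peaks` isotopologues, normalised to a maximum of 1. Fractional
#' element counts are supported.
#'
#' @param composition Named counts over C, H, N, O, S (see
#'   [averagine_composition()]).
#' @param n_peaks Number of isotopologue peaks to return (default 6: the
#'   monoisotopic peak plus the next five).
#' @return Numeric vector `a_0 .. a_{n_peaks-1}` with `max == 1`.
#' @export
isotope_distribution <- function(composition, n_peaks = 6L) {
  stop_if_not_scalar_number(n_peaks, "n_peaks", lower = 1)
  n_peaks <- as.integer(n_peaks)
  if (any(composition < 0)) stop("negative element count", call. = FALSE)
  out <- c(1, numeric(n_peaks - 1L))
  for (el in names(.element_isotopes)) {
    cnt <- unname(composition[el])
    if (is.na(cnt) || cnt == 0) next
    p <- .element_isotopes[[el]]
    p <- p / sum(p)
    out <- .series_mult(out, .series_power(p, cnt, n_peaks), n_peaks)
  }
  # fractional powers of a polynomial can carry tiny negative high-order
  # coefficients (|a| < 1e-4 relative); abundances are clamped at zero
  out <- pmax(out, 0)
  out / max(out)
}

#' Theoretical averagine isotopic pattern of an ion
#'
#' Places isotopologue peak k at
#' `mz = (mono_mass + charge * m_proton + k * delta) / charge`, with
#' `delta = 1.003355` Da (the 13C-12C spacing), and takes peak heights
#' from the averagine envelope. Adjacent peaks are `delta / charge` apart
#' on the m/z axis: ~1 m/z at z = 1, ~0.5 at z = 2.
#'
#' @param mono_mass Neutral monoisotopic mass in Da.
#' @param charge Charge state, integer 1 to 5.
#' @param n_peaks Number of peaks (default 6).
#' @return data.table with columns `k`, `mz`, `intensity` (max 1).
#' @export
theoretical_pattern <- function(mono_mass, charge, n_peaks = 6L) {
  stop_if_not_scalar_number(mono_mass, "mono_mass", lower = 1e-9)
  if (!charge %in% 1:5) stop("charge must be an integer in 1..5",
                             call. = FALSE)
  k <- 0:(n_peaks - 1L)
  ab <- isotope_distribution(averagine_composition(mono_mass), n_peaks)
  data.table(
    k = k,
    mz = (mono_mass + charge * .mass_proton + k * .iso_spacing) / charge,
    intensity = ab
  )
}
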