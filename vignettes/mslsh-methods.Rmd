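---
title: "Methods: LSH-based signal classification in MS1 raw data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LSH-based signal classification in MS1 raw data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslsh)
library(data.table)
```

## The problem and the idea

An MS1 survey spectrum of a complex peptide sample contains isotopic
patterns — series of peaks spaced `1.003355 / z` m/z apart whose envelope
is set by the elemental composition — buried among electronic noise.
Because analytes elute gradually from the chromatographic (and, with ion
mobility, the mobility) separation, a genuine pattern recurs almost
unchanged on several consecutive mass axes, while noise does not repeat.
`mslsh` turns that observation into a classifier that needs **no model of
the signal shape**: a short mass-axis interval (a *window*) is called
signal exactly when some other window in the data looks like it.

"Looks like" is cosine similarity between binned intensity vectors, and
the search for similar windows is done in linear time with
locality-sensitive hashing (LSH), so the method scales to raw files with
millions of peaks and is embarrassingly parallel.

## Windows and binning

Each (frame, scan) pair owns one mass axis. The axis is cut into windows
of length `L = 10` m/z on two grids anchored at 0 m/z: starts at
`k * L` and, to avoid splitting a pattern across a boundary, a second
grid shifted by `L / 2`. Any pattern of extent up to 5 Da (six
isotopologues at charge >= 2; five at charge 1) is then wholly contained
in at least one window. Intervals are half-open, `[start, start + L)`,
so each grid partitions its axis; empty windows are never materialised
because an all-zero vector has no defined projection sign and cannot
carry signal.

For hashing, a window is rasterised at `0.1` m/z into `d = 100` bins
(`bin = floor((mz - start) / 0.1)`, intensities in a shared bin summed).
0.1 m/z still separates adjacent peaks at charge 5 (0.2 m/z spacing)
while keeping the vectors small; a much finer grid would make the
similarity brittle against m/z jitter, a much coarser one would merge
neighbouring isotopologues.

## Hashing and amplification

The hash family for cosine similarity is the sign of a random
projection, `h(I) = sign(<I, r>)` with `r` standard normal. For a pair
with cosine similarity `s` a single bit agrees with probability
`p = 1 - acos(s) / pi`. Bits are amplified into `m` OR-bands of `n`
AND-bits: a band matches only when all `n` bits agree, and two windows
*collide* when at least one band matches, which happens with probability

```
P_{m,n}(s) = 1 - (1 - p^n)^m .
```

`collision_probability()` evaluates this curve; `simulate_collision_rate()`
estimates it by direct simulation (drawing fresh Gaussian directions per
trial, reduced exactly to the 2-d span of the pair) and is used in the
tests as the independent check of the closed form. Raising `n` sharpens
the sigmoid (a stricter similarity threshold), raising `m` shifts it
left (more permissive). `(m, n) = (64, 32)` is the package default for
classification — a strict setting whose transition sits near `s ~ 0.9` —
with `(32, 16)` as a permissive and `(32, 32)` as a strong-filter
alternative.

Numerical conventions, each fixed once and tested:

* `sign(0) := +1`. Binned integer-like intensities can produce an exact
  zero projection; any fixed convention preserves the LSH guarantee.
* Band keys pack their `n` bits little-endian into one double
  (`n <= 52` keeps keys exact); collision lookup is exact key equality
  per band index.
* Directions are drawn band-major from a single seeded stream, so
  families with the same seed share leading directions across `(m, n)`
  sweeps, and `(m, n, d, seed)` reproduces a family bit-identically.
* Intensities enter the hash un-normalised: signatures are invariant
  under positive scaling anyway, which the suite asserts end-to-end.

## Classification by collision

All windows of the processed unit are hashed and their band keys counted
(`build_collision_table()`); keys seen at least twice are *collided*. A
window is signal iff one of its keys is collided; a peak is signal iff
any window containing it (up to two, one per grid) is signal. Two
scopes are provided because pooling is a genuinely open choice: the
default pools every window of the input, `per_frame = TRUE` restricts
the table to one frame at a time (the scope used for frame-wise
evaluation). Both grids feed one shared table; overlapping windows over
the same pattern have shifted bin vectors and hence low mutual
similarity, so no cross-grid exclusion is needed. A count of 2 from the
same mass axis counts as a collision — the method does not require the
partner to come from a different time point.

The baseline classifier (`snr_threshold_classifier()`) is
signal-to-noise thresholding under a global noise estimate, i.e. one
scalar intensity cutoff — deliberately the simplest competitor, and the
contrast case for scale invariance: multiplying all intensities by
`alpha > 0` changes none of the LSH calls but shifts every threshold
call.

## The synthetic benchmark

`generate_dataset()` reproduces the study conditions under which the
method was characterised. Defaults are the conditions; they are not
tuning knobs.

* **Noise windows** (14107 by default): `k ~ Pois(4) + 1` peaks,
  positions uniform in the window, intensities exponential. The
  exponential parameter is 15; the package reads it as a *rate* (mean
  1/15), the literal reading, and exposes
  `noise_model(intensity_param = "mean")` for the alternative reading
  (mean 15) because the published text leaves the parametrisation
  genuinely ambiguous. The LSH calls are identical under both (scale
  invariance); only the intensity-threshold baseline moves.
* **Signal windows**: for every accepted (monoisotopic mass, charge)
  combination, a six-peak averagine pattern with the monoisotopic peak
  at the window centre, scaled so the strongest peak reaches
  `max_intensity` (default 1000; the benchmark series is 1000, 500,
  250, 125, 64, 32, rescaling signal only). Two extra windows carry the
  same pattern at half intensity, modelling the recurrence over
  consecutive time points — emitted as *separate* windows, because
  recurrence across axes is precisely what the classifier detects.
  Every signal window receives its own independently sampled noise
  overlay (label `noise_2`); pattern peaks are labelled `signal`, peaks
  of noise-only windows `noise_1`.
* **The grid and its filter**: masses 150 to 5000 u in steps of 10 u;
  the m/z interval is [150, 2000]. Among the documented filter
  conventions, exactly one reproduces the published benchmark counts of
  4338 signal windows (1446 combinations x 3) in 18445 total: charge
  states 1-4, plain m/z (`mass / z`, no protonation), and the
  *window-fit* filter requiring the whole 10-m/z window inside the
  interval. That convention is therefore the default, and the manifest
  of every dataset records it; `mz_filter = "mono"`,
  `protonated = TRUE` and `charges = 1:5` give the prose-level
  alternatives.
* Two geometric facts trim some patterns: at charge 1 the fifth extra
  isotopologue lies 5.017 m/z above the centre and falls outside the
  window, and below ~250 Da the far envelope terms are numerically zero
  and are not emitted as peaks. Signal windows therefore carry between
  4 and 6 pattern peaks.
* `as_frames = TRUE` scatters each pattern's three windows onto one
  random frame at three consecutive scans (and noise windows onto
  random frames and scans). Placing the repeats *within* a frame —
  rather than on consecutive frames — keeps the recurrence visible to
  the frame-wise collision scope, exactly as the repeats across
  mobility scans of an ion-mobility frame are.

All randomness flows through one seeded stream in a fixed draw order,
so a seed reproduces a dataset byte-identically; the manifest records
the seed, every parameter and the achieved class counts.

What the generator does **not** emulate: chemical noise (self-similar
contaminants, which this classifier will by construction keep), m/z
jitter and peak-width effects, intensity drift across repeats other
than the fixed halving, and correlated noise. Passing the synthetic
suite therefore shows correctness of the machinery under the stated
model, not performance on any particular instrument's data.

## Averagine reference search (deisotoping)

The second use of the same hashing machinery swaps self-similarity for
a precomputed reference: theoretical isotope patterns built from the
averagine residue (C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417 per
111.1254 Da) for masses 150-1800 Da (step 10, a density choice mirroring
the synthetic grid; the step is exposed) and charges 1-5. Fractional
element counts are used directly: the aggregated isotope distribution is
the product of per-element generating functions raised to fractional
powers, evaluated with the J.C.P. Miller recurrence. Fractional powers
can produce tiny negative high-order coefficients (|a| < 1e-4
relative); abundances are clamped at zero. The exact first-order
identity `a1/a0 = sum_e n_e p_e(1)/p_e(0)` and binomial single-element
oracles verify the recurrence in the tests.

Each pattern is rendered as stick peaks quantised on a 1e-5 Da fine
grid spanning -1 to +9 Da around the monoisotopic peak, summed down
into 1e-2 Da bins (1000-dimensional vectors, unit maximum), and hashed.
A query window is hashed with the same family; patterns sharing at
least one band key are candidates, the explicit cosine is computed for
candidates only, and the best match is returned if it reaches 0.6.
Ties break to the lowest charge, then lowest mass.

Aligning a raw acquisition window onto the reference grid is the main
free choice here, since a raw window does not reveal its monoisotopic
peak: `deisotope_window()` anchors the query at its most intense peak
and enumerates the hypotheses "the base peak is isotopologue k at
charge z" for small k, keeping the best-scoring alignment. The
characteristic failure mode — locking onto the right pattern displaced
by whole isotope spacings — is not hidden: `isotope_shift()` reports
the integer displacement, and the evaluation tallies shifted matches
separately from exact ones.

## Evaluation conventions

* **ROC on synthetic data**: TPR over `signal` peaks, FPR over
  `noise_1` peaks; `noise_2` peaks are excluded from both, because a
  window-level classifier necessarily tags them with their window's
  call and later feature-finding removes them — including them would
  only mask the error of interest. LSH yields one ROC *point* per
  `(m, n)`; the baseline yields a curve over thresholds.
* **Precursor matching**: signal windows become 2-d points
  (window-centre m/z, scan); a precursor is matched when its nearest
  point is closer than 5 in Manhattan distance. The metric mixes m/z
  units and scan indices as printed; unit weights are exposed and
  default to 1. The 3-d variant over (m/z, scan, charge) with radius 10
  produces nested tallies: k1 (a neighbour within the radius), k2
  (within k1, exact charge), k3 (within k2, exact monoisotopic m/z).
* **Reduction rates**: one minus the kept fraction, in windows and in
  peaks (every peak of a signal window counts as kept).
* **Frame sweep**: metrics averaged over randomly sampled frames
  (seeded), one row per `(m, n)`; keeping rate and reduction rate move
  in opposite directions as the amplification is varied.

## Problem sizes and determinism in the test suite

The suite exercises the full default benchmark (18445 windows, ~117k
peaks) for the count, dominance and scale-invariance checks — a
classification at `(64, 32)` takes a few seconds — and smaller seeded
configurations (a coarser mass grid with a few hundred noise windows)
where many repetitions are needed. Monte-Carlo checks use 1e4-4e4
trials and 3-standard-error bands. Parallel classification chunks rows
of the signature matrix; every dot product is computed identically, so
worker counts cannot change results, which the suite asserts
byte-identically.

## Known limitations

* Chemical noise is self-similar and will be kept; removing
  contaminants is downstream work.
* Signals with low intensity relative to in-window noise lose cosine
  similarity between repeats and can be missed; the low end of the
  intensity series probes exactly this regime.
* The collision rate among noise-only windows grows with the number of
  windows pooled into one table (more chances for an accidental
  high-similarity pair); at the benchmark's 14107 noise windows the
  strict `(64, 32)` setting already calls a substantial fraction of
  noise windows signal, which is why the comparison with the baseline
  is made at matched false-positive rates.
* The reference search assumes averagine-like compositions; strongly
  atypical analytes (glyco/lipo-forms) will score poorly.
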