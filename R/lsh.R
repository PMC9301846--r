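# Sign-random-projection LSH for cosine similarity, with AND/OR band
# amplification. A family holds m*n unit-free Gaussian direction vectors;
# a window's signature is the matrix of projection signs, packed band-wise
# into m integer keys of n bits. Two windows collide when at least one
# band key is equal, which happens with probability
#   P_{m,n}(s) = 1 - (1 - p^n)^m,   p = 1 - acos(s)/pi,
# a sigmoid in the cosine similarity s whose steepness and midpoint are
# tuned through (m, n).

#' Cosine similarity between two intensity vectors
#'
#' `<a, b> / (||a|| ||b||)`. Intensities are non-negative, so the result
#' lies in \[0, 1\]. Scale invariant: `cosine_similarity(alpha * a, b)` is
#' unchanged for any `alpha > 0`, which makes the classifier blind to
#' absolute intensity.
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return A single number.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm input", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Create a sign-random-projection hash family
#'
#' Draws `m * n` direction vectors of dimension `d` with i.i.d. standard
#' normal components from a single seeded stream, band-major: the first
#' `n` vectors form band 1, and families with the same seed share their
#' leading directions regardless of how (m, n) splits them. The caller's
#' RNG state is left untouched.
#'
#' @param m Number of OR-bands (>= 1).
#' @param n Number of AND-bits per band (>= 1, <= 52 so keys stay exact
#'   doubles).
#' @param d Dimension of the vectors being hashed.
#' @param seed Integer seed making the family reproducible.
#' @return A list of class `hash_family` with the direction matrix
#'   (`d` rows, `m * n` columns) and its parameters.
#' @export
hash_family <- function(m, n, d, seed = 1L) {
  stop_if_not_scalar_number(m, "m", lower = 1)
  stop_if_not_scalar_number(n, "n", lower = 1, upper = 52)
  stop_if_not_scalar_number(d, "d", lower = 1)
  m <- as.integer(m); n <- as.integer(n); d <- as.integer(d)
  directions <- with_seed(seed, matrix(rnorm(d * m * n), nrow = d))
  structure(list(m = m, n = n, d = d, seed = seed, directions = directions),
            class = "hash_family")
}

#' @export
print.hash_family <- function(x, ...) {
  cat(sprintf("<hash_family> m = %d bands x n = %d bits, d = %d, seed = %s\n",
              x$m, x$n, x$d, format(x$seed)))
  invisible(x)
}

#' Compute banded LSH signatures
#'
#' Bit (j, k) of a vector's signature is `1` iff the scalar product with
#' direction (j, k) is `>= 0` (the tie at exactly zero maps to 1; any fixed
#' convention preserves the LSH guarantee). Each band's n bits are packed
#' little-endian into one key in `[0, 2^n)`. Signatures are invariant under
#' positive scaling of the input.
#'
#' @param x A numeric matrix (one row per window, `family$d` columns), a
#'   single vector of length `family$d`, or the result of [bin_windows()].
#' @param family A [hash_family()].
#' @return A numeric matrix of band keys with one row per input row and
#'   `family$m` columns.
#' @export
lsh_signatures <- function(x, family) {
  stopifnot(inherits(family, "hash_family"))
  if (is.list(x) && !is.null(x$intensities)) x <- x$intensities
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != family$d) {
    stop(sprintf("dimension mismatch: vectors have %d bins, family expects %d",
                 ncol(x), family$d), call. = FALSE)
  }
  bits <- (x %*% family$directions) >= 0
  m <- family$m; n <- family$n
  pow <- 2^(0:(n - 1L))
  keys <- matrix(0, nrow = nrow(x), ncol = m)
  for (j in seq_len(m)) {
    keys[, j] <- bits[, (j - 1L) * n + seq_len(n), drop = FALSE] %*% pow
  }
  keys
}

#' Dump signatures as a long TSV (window id, band index, key)
#'
#' @param signatures Matrix from [lsh_signatures()].
#' @param path Output path.
#' @param window_ids Optional ids; default row numbers.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path, window_ids = NULL) {
  if (is.null(dim(signatures))) signatures <- matrix(signatures, nrow = 1L)
  ids <- window_ids %||% seq_len(nrow(signatures))
  long <- setDT(list(
    window_id = rep(ids, times = ncol(signatures)),
    band = rep(seq_len(ncol(signatures)), each = nrow(signatures)),
    key = as.vector(signatures)))
  setorder(long, window_id, band)
  fwrite(long, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Do two signatures collide?
#'
#' True iff at least one band key is equal (the OR over m AND-bands).
#'
#' @param a,b Signature rows (numeric vectors of m keys) from
#'   [lsh_signatures()].
#' @return Logical scalar.
#' @export
collide <- function(a, b) {
  a <- drop(a); b <- drop(b)
  if (length(a) != length(b)) stop("signature shape mismatch", call. = FALSE)
  any(a == b)
}

#' Analytic collision probability of the amplified LSH
#'
#' For a pair with cosine similarity `s`, a single projection bit agrees
#' with probability `p = 1 - acos(s)/pi`; a band of n bits matches with
#' `p^n`, and at least one of m bands matches with `1 - (1 - p^n)^m`.
#'
#' @param s Cosine similarity, in \[-1, 1\] (vectorised).
#' @param m,n Amplification parameters.
#' @return Collision probabilities in \[0, 1\].
#' @export
collision_probability <- function(s, m, n) {
  if (any(s < -1 - 1e-12 | s > 1 + 1e-12)) {
    stop("similarity outside [-1, 1]", call. = FALSE)
  }
  s <- pmin(1, pmax(-1, s))
  p <- 1 - acos(s) / pi
  1 - (1 - p^n)^m
}

#' Monte-Carlo estimate of the amplified collision rate
#'
#' Independent simulation of the banded scheme: for each trial a fresh set
#' of `m * n` Gaussian directions is drawn and a collision is recorded when
#' some band's n projection signs all agree between the two vectors of a
#' fixed-similarity pair. Because the two vectors span a plane and the
#' standard normal is rotation invariant, only the in-plane components of
#' each direction matter, so the simulation draws 2-dimensional Gaussians;
#' this is exact, not an approximation.
#'
#' @param s Cosine similarity of the simulated pair.
#' @param m,n Amplification parameters.
#' @param trials Number of simulated families.
#' @param seed RNG seed.
#' @param chunk Trials per memory chunk.
#' @return A list with `rate`, its binomial standard error `se`, and
#'   `trials`.
#' @export
simulate_collision_rate <- function(s, m, n, trials = 10000L, seed = 1L,
                                    chunk = 2000L) {
  stop_if_not_scalar_number(s, "s", lower = -1, upper = 1)
  m <- as.integer(m); n <- as.integer(n)
  c2 <- sqrt(1 - s^2)
  hits <- with_seed(seed, {
    total <- 0L
    done <- 0L
    while (done < trials) {
      nt <- min(chunk, trials - done)
      x <- matrix(rnorm(nt * m * n), nrow = nt)   # projection onto u
      y <- matrix(rnorm(nt * m * n), nrow = nt)
      agree <- (x >= 0) == (s * x + c2 * y >= 0)  # projection onto v
      # band j occupies columns (j-1)*n + 1 .. j*n
      band_ok <- matrix(FALSE, nrow = nt, ncol = m)
      for (j in seq_len(m)) {
        band_ok[, j] <- rowSums(agree[, (j - 1L) * n + seq_len(n),
                                      drop = FALSE]) == n
      }
      total <- total + sum(rowSums(band_ok) > 0L)
      done <- done + nt
    }
    total
  })
  rate <- hits / trials
  list(rate = rate, se = sqrt(rate * (1 - rate) / trials), trials = trials)
}
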