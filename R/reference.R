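# LSH-indexed reference database of theoretical averagine patterns, used
# for deisotoping: a query window is hashed with the same family as the
# references; patterns sharing at least one band key are candidates, the
# explicit cosine similarity is computed for those only, and the best
# match above a similarity threshold yields monoisotopic m/z and charge.
#
# Reference vectors live on a dedicated coarse grid: the pattern is
# rendered as stick peaks on a 1e-5 Da fine grid spanning -1 to +9 Da
# around the monoisotopic peak, then summed down into 1e-2 Da bins
# (1000 bins per pattern).

.ref_span <- c(-1, 9)       # Da around the monoisotopic peak
.ref_fine_step <- 1e-5      # Da, stick-placement quantisation
.ref_coarse_step <- 1e-2    # Da, bin width of the stored vectors

#' Render one reference pattern on the coarse grid
#'
#' @param mono_mass Neutral monoisotopic mass in Da.
#' @param charge Charge state 1..5.
#' @param min_rel Isotopologue peaks below this relative abundance are
#'   not rendered.
#' @return Numeric vector of length 1000 (10 Da at 0.01 Da), unit
#'   maximum, bin 1 starting 1 Da below the monoisotopic m/z.
#' @export
render_reference_pattern <- function(mono_mass, charge, min_rel = 1e-5) {
  n_bins <- as.integer(round(diff(.ref_span) / .ref_coarse_step))
  ratio <- as.integer(round(.ref_coarse_step / .ref_fine_step))
  # isotopologues that can fall inside the +9 Da span
  kmax <- floor(diff(.ref_span) * charge / .iso_spacing)
  ab <- isotope_distribution(averagine_composition(mono_mass), kmax + 1L)
  k <- which(ab >= min_rel) - 1L
  offset <- -.ref_span[1] + k * .iso_spacing / charge   # Da from span start
  fine <- round(offset / .ref_fine_step)
  coarse <- as.integer(fine %/% ratio) + 1L
  keep <- coarse >= 1L & coarse <= n_bins
  v <- numeric(n_bins)
  for (i in which(keep)) v[coarse[i]] <- v[coarse[i]] + ab[k[i] + 1L]
  v / max(v)
}

#' Build an LSH-indexed averagine reference database
#'
#' Renders the theoretical pattern of every (monoisotopic mass, charge)
#' combination on the coarse reference grid and hashes it with a shared
#' sign-random-projection family, so that candidate patterns for a query
#' can be fetched by band-key equality instead of scanning the whole
#' database.
#'
#' @param mass_min,mass_max,mass_step Neutral monoisotopic mass grid in
#'   Da (defaults 150 to 1800 in steps of 10).
#' @param charges Charge states (default 1:5).
#' @param m,n,seed Hash-family parameters (d is fixed by the grid).
#' @param family Optionally a ready-made [hash_family()] with d = 1000;
#'   overrides `m`, `n`, `seed`.
#' @return A list of class `reference_db`: `patterns` (data.table with
#'   `id`, `mono_mass`, `charge`, `mono_mz`), `vectors` (matrix, one row
#'   per pattern), `signatures`, `family`.
#' @export
build_reference_db <- function(mass_min = 150, mass_max = 1800,
                               mass_step = 10, charges = 1:5,
                               m = 64L, n = 32L, seed = 1L,
                               family = NULL) {
  masses <- seq(mass_min, mass_max, by = mass_step)
  grid <- CJ(charge = as.integer(charges), mono_mass = masses)
  n_bins <- as.integer(round(diff(.ref_span) / .ref_coarse_step))
  family <- family %||% hash_family(m, n, d = n_bins, seed = seed)
  if (family$d != n_bins) {
    stop("reference family must have d = ", n_bins, call. = FALSE)
  }
  if (nrow(grid) == 0L) {
    return(structure(list(patterns = data.table(), vectors = NULL,
                          signatures = NULL, family = family),
                     class = "reference_db"))
  }
  vectors <- matrix(0, nrow = nrow(grid), ncol = n_bins)
  for (i in seq_len(nrow(grid))) {
    vectors[i, ] <- render_reference_pattern(grid$mono_mass[i],
                                             grid$charge[i])
  }
  patterns <- data.table(
    id = seq_len(nrow(grid)),
    mono_mass = grid$mono_mass,
    charge = grid$charge,
    mono_mz = (grid$mono_mass + grid$charge * .mass_proton) / grid$charge
  )
  structure(list(patterns = patterns, vectors = vectors,
                 signatures = lsh_signatures(vectors, family),
                 family = family),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "<reference_db> %d averagine patterns, charges %s, (m, n) = (%d, %d)\n",
    nrow(x$patterns),
    paste(range(x$patterns$charge), collapse = "-"),
    x$family$m, x$family$n))
  invisible(x)
}

#' Persist a reference database as a portable TSV
#'
#' Header comment lines carry the hash-family parameters and the
#' rendering constants; data rows carry one pattern each with its band
#' keys (comma-joined). Vectors are not stored: they are re-rendered
#' deterministically on load.
#'
#' @param db A [build_reference_db()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  hdr <- sprintf("# mslsh reference_db m=%d n=%d d=%d seed=%s",
                 db$family$m, db$family$n, db$family$d,
                 format(db$family$seed))
  tab <- copy(db$patterns)
  tab[, keys := apply(db$signatures, 1L, function(k)
    paste(format(k, scientific = FALSE, trim = TRUE), collapse = ","))]
  rows <- do.call(paste, c(lapply(tab, function(col) {
    if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE,
                                 digits = 15) else col
  }), sep = "\t"))
  writeLines(c(hdr, paste(names(tab), collapse = "\t"), rows), path)
  invisible(path)
}

#' Load a reference database written by [write_reference_db()]
#'
#' Re-renders the pattern vectors from the stored (mass, charge) grid
#' and rebuilds the hash family from its seed; the stored band keys are
#' verified against the recomputed signatures.
#'
#' @param path Path to the TSV.
#' @return A `reference_db`.
#' @export
read_reference_db <- function(path) {
  hdr <- readLines(path, n = 1L)
  par <- regmatches(hdr, gregexpr("[a-z]+=[-0-9.]+", hdr))[[1]]
  kv <- strsplit(par, "=", fixed = TRUE)
  pars <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                   vapply(kv, `[`, "", 1L))
  tab <- fread(path, sep = "\t", skip = 1L, header = TRUE,
               showProgress = FALSE)
  db <- build_reference_db(
    mass_min = min(tab$mono_mass), mass_max = max(tab$mono_mass),
    mass_step = if (nrow(tab) > 1L) min(diff(sort(unique(tab$mono_mass))))
                else 10,
    charges = sort(unique(tab$charge)),
    m = pars[["m"]], n = pars[["n"]], seed = as.integer(pars[["seed"]]))
  stored <- do.call(rbind, lapply(strsplit(tab$keys, ",", fixed = TRUE),
                                  as.numeric))
  reorder <- match(paste(db$patterns$mono_mass, db$patterns$charge),
                   paste(tab$mono_mass, tab$charge))
  if (anyNA(reorder) ||
      !isTRUE(all.equal(db$signatures, stored[reorder, , drop = FALSE],
                        check.attributes = FALSE))) {
    stop("stored band keys do not match the re-rendered database; ",
         "file corrupt or written by an incompatible version",
         call. = FALSE)
  }
  db
}

#' Search the reference database for the best-matching isotope pattern
#'
#' Hashes the query, collects every pattern sharing at least one band key
#' (the LSH candidate set), computes the explicit cosine similarity for
#' the candidates only, and returns the highest-scoring pattern if its
#' similarity reaches `threshold`. Ties are broken towards the lowest
#' charge, then the lowest mass, for deterministic output.
#'
#' @param query Numeric vector on the reference coarse grid (length 1000,
#'   anchored 1 Da below the presumed monoisotopic peak).
#' @param db A [build_reference_db()] result.
#' @param threshold Minimum cosine similarity (default 0.6).
#' @return A one-row data.table (`mono_mass`, `charge`, `mono_mz`,
#'   `score`, `n_candidates`) or an empty table when nothing reaches the
#'   threshold.
#' @export
reference_search <- function(query, db, threshold = 0.6) {
  stopifnot(inherits(db, "reference_db"))
  empty <- data.table(mono_mass = numeric(), charge = integer(),
                      mono_mz = numeric(), score = numeric(),
                      n_candidates = integer())
  if (length(query) != db$family$d) {
    stop("query resolution mismatch: expected length ", db$family$d,
         call. = FALSE)
  }
  if (nrow(db$patterns) == 0L || all(query == 0)) return(empty)
  qsig <- lsh_signatures(query, db$family)
  cand <- which(rowSums(db$signatures == matrix(qsig, nrow(db$signatures),
                                                db$family$m,
                                                byrow = TRUE)) > 0L)
  if (length(cand) == 0L) return(empty)
  qn <- sqrt(sum(query^2))
  vn <- sqrt(rowSums(db$vectors[cand, , drop = FALSE]^2))
  scores <- as.vector(db$vectors[cand, , drop = FALSE] %*% query) / (qn * vn)
  hits <- db$patterns[cand][, score := scores]
  setorder(hits, -score, charge, mono_mass)
  best <- hits[1L]
  if (best$score < threshold) return(empty)
  best[, n_candidates := length(cand)]
  best[, .(mono_mass, charge, mono_mz, score, n_candidates)]
}

#' Deisotope a window of peaks against a reference database
#'
#' How an acquisition window is aligned onto the reference grid is the
#' main free choice of the reference search: the database anchors every
#' pattern 1 Da below its monoisotopic peak, but a raw window does not
#' reveal which of its peaks is monoisotopic. This routine anchors the
#' query at the window's most intense peak -- assuming it to be
#' isotopologue k of an unknown pattern -- and tries k = 0..`max_shift`
#' for every charge in `charges`, keeping the best-scoring alignment.
#'
#' @param peaks A peak table (one window's peaks; `frame`/`scan` are
#'   ignored here).
#' @param db A [build_reference_db()] result.
#' @param threshold Minimum cosine similarity (default 0.6).
#' @param charges Candidate charges for the anchor shift enumeration.
#' @param max_shift Highest isotopologue index assumed for the base peak.
#' @return Best match as in [reference_search()], with an extra
#'   `anchor_mz` column, or an empty table.
#' @export
deisotope_window <- function(peaks, db, threshold = 0.6, charges = 1:5,
                             max_shift = 3L) {
  peaks <- as_peak_table(peaks)
  if (nrow(peaks) == 0L) {
    return(data.table(mono_mass = numeric(), charge = integer(),
                      mono_mz = numeric(), score = numeric(),
                      n_candidates = integer(), anchor_mz = numeric()))
  }
  base_mz <- peaks$mz[which.max(peaks$intensity)]
  anchors <- unique(unlist(lapply(charges, function(z) {
    base_mz - (0:max_shift) * .iso_spacing / z
  })))
  best <- NULL
  for (a in anchors) {
    q <- bin_reference_query(peaks, a)
    if (all(q == 0)) next
    hit <- reference_search(q, db, threshold)
    if (nrow(hit) && (is.null(best) || hit$score > best$score)) {
      best <- hit[, anchor_mz := a]
    }
  }
  if (is.null(best)) {
    data.table(mono_mass = numeric(), charge = integer(),
               mono_mz = numeric(), score = numeric(),
               n_candidates = integer(), anchor_mz = numeric())
  } else best
}

#' Bin peaks onto the reference coarse grid
#'
#' @param peaks A peak table.
#' @param mono_mz Presumed monoisotopic m/z; the grid spans
#'   `[mono_mz - 1, mono_mz + 9)` at 0.01 Da. Peaks outside are dropped.
#' @return Numeric vector of length 1000.
#' @export
bin_reference_query <- function(peaks, mono_mz) {
  peaks <- as_peak_table(peaks)
  n_bins <- as.integer(round(diff(.ref_span) / .ref_coarse_step))
  lo <- mono_mz + .ref_span[1]
  idx <- floor((peaks$mz - lo) / .ref_coarse_step) + 1L
  keep <- idx >= 1L & idx <= n_bins
  v <- numeric(n_bins)
  for (i in which(keep)) v[idx[i]] <- v[idx[i]] + peaks$intensity[i]
  v
}

#' Diagnose an isotopologue-shift match failure
#'
#' The reference search can lock onto the right pattern displaced by a
#' whole number of isotope spacings (the matched monoisotopic m/z is then
#' off by multiples of the spacing over the charge). Returns that integer
#' shift: 0 for an exact match, a nonzero integer for a shifted match,
#' and NA when the discrepancy is not a whole number of spacings.
#'
#' @param matched_mono_mz Monoisotopic m/z reported by the search.
#' @param true_mono_mz Ground-truth monoisotopic m/z.
#' @param charge Charge state used for the spacing.
#' @param tol Absolute tolerance in m/z (default half a coarse bin).
#' @return Integer shift (vectorised) or NA.
#' @export
isotope_shift <- function(matched_mono_mz, true_mono_mz, charge,
                          tol = .ref_coarse_step / 2) {
  delta <- (matched_mono_mz - true_mono_mz) * charge / .iso_spacing
  shift <- round(delta)
  err <- abs(matched_mono_mz - (true_mono_mz + shift * .iso_spacing / charge))
  ifelse(err <= tol, as.integer(shift), NA_integer_)
}
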