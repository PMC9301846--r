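test_that("averagine composition scales the unit residue linearly", {
  one <- averagine_composition(111.1254)
  expect_equal(unname(one),
               c(4.9384, 7.7583, 1.3577, 1.4773, 0.0417), tolerance = 1e-12)
  expect_equal(averagine_composition(222.2508), 2 * one, tolerance = 1e-12)
  expect_equal(unname(averagine_composition(1000)["C"]),
               1000 / 111.1254 * 4.9384, tolerance = 1e-12)
  expect_error(averagine_composition(0), "mass")
})

test_that("isotope distribution matches binomial oracles for pure carbon", {
  # 1 carbon: a1/a0 is the abundance ratio itself
  d1 <- isotope_distribution(c(C = 1), 3)
  expect_equal(d1[2] / d1[1], 0.0107 / 0.9893, tolerance = 1e-10)
  # n carbons: binomial law, independent oracle via dbinom
  for (nC in c(10, 40)) {
    d <- isotope_distribution(c(C = nC), 5)
    oracle <- dbinom(0:4, nC, 0.0107)
    expect_equal(d / d[1], oracle / oracle[1], tolerance = 1e-9)
  }
})

test_that("averagine a1/a0 matches the exact first-order closed form", {
  # coefficient identity: a1/a0 = sum_e n_e * p_e(1)/p_e(0), exact for
  # the generating-function product regardless of fractional counts
  iso <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
              N = c(0.99636, 0.00364), O = c(0.99757, 0.00038),
              S = c(0.9499, 0.0075))
  for (mass in c(400, 1000, 3000)) {
    comp <- averagine_composition(mass)
    d <- isotope_distribution(comp, 2)
    expected <- sum(vapply(names(iso), function(e) {
      comp[e] * iso[[e]][2] / iso[[e]][1]
    }, numeric(1)))
    expect_equal(d[2] / d[1], expected, tolerance = 1e-9)
  }
  # the documented magnitude at 1000 Da
  d1000 <- isotope_distribution(averagine_composition(1000), 6)
  expect_lt(abs(d1000[2] / d1000[1] - 0.53), 0.05)
})

test_that("abundances are non-negative with unit maximum", {
  for (mass in c(150, 800, 5000)) {
    d <- isotope_distribution(averagine_composition(mass), 10)
    expect_true(all(d >= 0))
    expect_equal(max(d), 1)
  }
})

test_that("pattern spacing is the isotope gap over the charge", {
  p1 <- theoretical_pattern(1000, 1)
  expect_equal(diff(p1$mz), rep(1.003355, 5), tolerance = 1e-9)
  p2 <- theoretical_pattern(1000, 2)
  expect_equal(diff(p2$mz), rep(1.003355 / 2, 5), tolerance = 1e-9)
  expect_equal(p2$mz[1], (1000 + 2 * 1.007276) / 2, tolerance = 1e-9)
  p3 <- theoretical_pattern(600, 3)
  expect_equal(diff(p3$mz)[1], 1.003355 / 3, tolerance = 1e-9)
  expect_error(theoretical_pattern(1000, 7), "charge")
})

test_that("reference patterns live on a 1000-bin coarse grid", {
  v <- render_reference_pattern(1000, 2)
  expect_length(v, 1000L)
  expect_equal(max(v), 1)
  # nonzero bins sit one isotope spacing / charge apart
  nz <- which(v > 0)
  gaps <- diff(nz) * 0.01 * 2            # m/z gap times charge
  expect_true(all(abs(gaps - 1.003355) <= 0.01 * 2 + 1e-9))
  # monoisotopic peak sits 1 Da above the span start
  expect_equal(nz[1], 101L)
})

test_that("a degenerate database holds one signed pattern", {
  db <- build_reference_db(mass_min = 700, mass_max = 700, charges = 2,
                           m = 8, n = 6, seed = 3)
  expect_equal(nrow(db$patterns), 1L)
  expect_equal(ncol(db$signatures), 8L)
  hit <- reference_search(db$vectors[1, ], db)
  expect_equal(hit$score, 1, tolerance = 1e-12)
  expect_equal(hit$charge, 2L)
})

test_that("reference search agrees with explicit search over a small db", {
  db <- build_reference_db(mass_min = 300, mass_max = 1200, mass_step = 50,
                           charges = 1:3, m = 32, n = 8, seed = 7)
  expect_lte(nrow(db$patterns), 200L)
  set.seed(31)
  for (i in sample(nrow(db$patterns), 15)) {
    q <- db$vectors[i, ] * 0.3
    noise <- runif(1000) * 0.003           # small, sub-threshold noise
    q <- q + noise
    hit <- reference_search(q, db)
    # brute-force oracle: explicit cosine against every pattern
    scores <- as.vector(db$vectors %*% q) /
      (sqrt(rowSums(db$vectors^2)) * sqrt(sum(q^2)))
    expect_equal(hit$mono_mass, db$patterns$mono_mass[which.max(scores)])
    expect_equal(hit$charge, db$patterns$charge[which.max(scores)])
    expect_equal(hit$score, max(scores), tolerance = 1e-9)
    expect_equal(hit$mono_mass, db$patterns$mono_mass[i])
  }
})

test_that("pure-noise queries stay below the similarity threshold", {
  db <- build_reference_db(mass_min = 300, mass_max = 1200, mass_step = 50,
                           charges = 1:3, m = 32, n = 8, seed = 7)
  set.seed(13)
  misses <- vapply(1:20, function(i) {
    q <- numeric(1000)
    idx <- sample(1000, 6)
    q[idx] <- rexp(6)
    nrow(reference_search(q, db, threshold = 0.6)) == 0L
  }, logical(1))
  expect_gte(mean(misses), 0.9)
})

test_that("isotopologue shifts are diagnosed as integer spacings", {
  expect_equal(isotope_shift(500.501678, 500.0, 2), 1L)
  expect_equal(isotope_shift(499.0 - 1.003355, 499.0, 1), -1L)
  expect_equal(isotope_shift(500.0, 500.0, 3), 0L)
  expect_true(is.na(isotope_shift(500.21, 500.0, 2)))
})

test_that("a persisted database searches identically after reload", {
  db <- build_reference_db(mass_min = 400, mass_max = 900, mass_step = 100,
                           charges = 1:2, m = 16, n = 8, seed = 19)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reference_db(db, f)
  back <- read_reference_db(f)
  expect_equal(back$patterns, db$patterns)
  expect_equal(back$signatures, db$signatures)
  q <- db$vectors[7, ] * 3.5
  expect_equal(reference_search(q, back), reference_search(q, db))
  # corruption is caught
  lines <- readLines(f)
  lines[3] <- sub("\t1\t", "\t2\t", lines[3])
  writeLines(lines, f)
  expect_error(read_reference_db(f), "(not match|corrupt)")
})

test_that("deisotoping a raw window recovers mass and charge", {
  db <- build_reference_db(mass_min = 300, mass_max = 1200, mass_step = 50,
                           charges = 1:3, m = 32, n = 8, seed = 7)
  pat <- theoretical_pattern(800, 2, n_peaks = 6)
  pk <- data.table(frame = 0L, scan = 0L, mz = pat$mz,
                   intensity = pat$intensity * 500)
  hit <- deisotope_window(pk, db, charges = 1:3)
  expect_equal(hit$mono_mass, 800)
  expect_equal(hit$charge, 2L)
  expect_gt(hit$score, 0.95)
})
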