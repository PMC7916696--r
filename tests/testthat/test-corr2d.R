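test_that("Hilbert-Noda matrix has the printed discrete form", {
  expect_error(hilbertNoda(1), "k must be")
  expect_error(hilbertNoda(2.5), "k must be")
  M3 <- hilbertNoda(3)
  expect_equal(M3[1, 2], 1 / pi)
  expect_equal(M3[1, 3], 1 / (2 * pi))
  for (k in 2:12) {
    M <- hilbertNoda(k)
    expect_identical(diag(M), rep(0, k))
    expect_identical(M + t(M), matrix(0, k, k))   # exactly antisymmetric
    expect_identical(M, oracleNoda(k))
  }
})

test_that("dynamic spectra honor every reference mode", {
  sim <- generateSeries(threeBandSpec())
  s <- sim$series
  I <- intensities(s)
  k <- nSpectra(s)

  dFirst <- dynamicSpectra(s, "first")
  expect_identical(dynamicMatrix(dFirst)[1, ], rep(0, nWavenumbers(s)))
  expect_identical(referenceSpectrum(dFirst), I[1, ])

  dLast <- dynamicSpectra(s, "last")
  expect_identical(dynamicMatrix(dLast)[k, ], rep(0, nWavenumbers(s)))

  dMean <- dynamicSpectra(s, "mean")
  expect_equal(colSums(dynamicMatrix(dMean)), rep(0, nWavenumbers(s)))

  # zero reference reproduces the measured intensities exactly
  dZero <- dynamicSpectra(s, "zero")
  expect_identical(dynamicMatrix(dZero), I)

  dIdx <- dynamicSpectra(s, 3)
  expect_identical(dynamicMatrix(dIdx)[3, ], rep(0, nWavenumbers(s)))
  expect_identical(referenceMode(dIdx), "index:3")

  expect_error(dynamicSpectra(s, "median"))
  expect_error(dynamicSpectra(s, 11), "1..k")

  # constant-in-T series: dynamic spectra vanish for any data-derived mode
  const <- spectralSeries(wavenumbers(s)[1:5], temperatures(s),
                          matrix(rep(1:5, each = k), k, 5))
  for (mode in list("first", "last", "mean", 2)) {
    expect_true(all(dynamicMatrix(dynamicSpectra(const, mode)) == 0))
  }
})

test_that("both maps agree with the brute-force oracle on random inputs", {
  set.seed(101)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    n <- sample(2:8, 1)
    dyn <- randomDynamic(k, n)
    S <- synchronousMap(dyn)
    A <- suppressWarnings(asynchronousMap(dyn))
    SO <- oracleSync(dynamicMatrix(dyn))
    AO <- oracleAsync(dynamicMatrix(dyn))
    expect_lt(max(abs(unname(S) - SO)), 1e-12 * max(abs(SO)))
    expect_lt(max(abs(unname(A) - AO)), 1e-12 * max(max(abs(AO)), 1e-300))
  }
})

test_that("map structure: symmetry, antisymmetry, Cauchy-Schwarz", {
  set.seed(202)
  dyn <- randomDynamic(6, 8)
  S <- synchronousMap(dyn)
  A <- asynchronousMap(dyn)
  expect_identical(S, t(S))
  expect_identical(A, -t(A))
  expect_identical(diag(A), stats::setNames(rep(0, 8), dimnames(A)[[1]]))
  expect_true(all(diag(S) >= 0))
  cs <- S^2 <= outer(diag(S), diag(S)) * (1 + 1e-12)
  expect_true(all(cs))
})

test_that("proportional dynamic traces give zero asynchronicity", {
  set.seed(303)
  k <- 10
  base <- rnorm(k)
  dynm <- cbind(base, 2.5 * base, -0.7 * base, rnorm(k))
  s <- spectralSeries(c(1000, 1004, 1008, 1012), seq(250, 340, 10), dynm)
  A <- asynchronousMap(dynamicSpectra(s, "zero"))
  top <- max(abs(A))
  expect_gt(top, 0)                       # the independent channel correlates
  expect_lt(abs(A[1, 2]), 1e-10 * top)    # proportional pairs do not
  expect_lt(abs(A[1, 3]), 1e-10 * top)
  expect_lt(abs(A[2, 3]), 1e-10 * top)
})

test_that("a 90-degree phase lead gives a positive asynchronous intensity", {
  k <- 8
  i <- seq_len(k)
  lead <- sin(2 * pi * i / k)
  lag <- sin(2 * pi * i / k - pi / 2)
  s <- spectralSeries(c(1000, 1004), i * 10 + 240, cbind(lead, lag))
  dyn <- dynamicSpectra(s, "zero")
  A <- asynchronousMap(dyn)
  expect_equal(unname(A), oracleAsync(cbind(lead, lag)))
  # channel 1 leads: async(nu1, nu2) > 0, and with sync >= 0 the sign rules
  # must declare nu1 prior to nu2
  expect_gt(A[1, 2], 0)
  peak <- data.frame(nu1 = 1000, nu2 = 1004, kind = "cross",
                     sync_sign = "+", async_sign = "+",
                     sync_value = 1, async_value = A[1, 2], prominence = 1)
  expect_identical(applyNodaRules(peak)$relations$verdict, "nu1_first")
})

test_that("correlate2d composes the pipeline and scales bilinearly", {
  sim <- generateSeries(threeBandSpec())
  maps <- correlate2d(sim$series, "first")
  expect_s4_class(maps, "CorrelationMaps")
  expect_identical(nSpectra(maps), 10L)
  expect_identical(nodaMatrix(maps), hilbertNoda(10))

  # constant series: both maps identically zero
  const <- spectralSeries(c(1000, 1004, 1008), seq(250, 340, 10),
                          matrix(rep(c(1, 2, 3), each = 10), 10, 3))
  m0 <- correlate2d(const, "first")
  expect_true(all(syncMap(m0) == 0) && all(asyncMap(m0) == 0))

  # scaling all intensities by c scales both maps by c^2
  c2 <- 3
  scaled <- spectralSeries(wavenumbers(sim$series), temperatures(sim$series),
                           c2 * intensities(sim$series))
  m1 <- correlate2d(scaled, "first")
  expect_equal(syncMap(m1), c2^2 * syncMap(maps))
  expect_equal(asyncMap(m1), c2^2 * asyncMap(maps))

  # k = 2 asynchronous maps are computed but flagged
  s2 <- spectralSeries(c(1000, 1004), c(250, 260), matrix(rnorm(4), 2, 2))
  expect_warning(correlate2d(s2, "first"), "k = 2")
})

test_that("permuting wavenumber channels permutes both maps identically", {
  set.seed(404)
  sim <- generateSeries(threeBandSpec(noiseSigma = 0.01, seed = 5L))
  s <- sim$series
  maps <- correlate2d(s, "first")
  # reversing the wavenumber axis (the container re-sorts ascending) must
  # leave the maps unchanged, i.e. sorting is canonical
  rev_s <- spectralSeries(rev(wavenumbers(s)), temperatures(s),
                          intensities(s)[, rev(seq_len(nWavenumbers(s)))])
  maps2 <- correlate2d(rev_s, "first")
  expect_equal(syncMap(maps2), syncMap(maps))
  expect_equal(asyncMap(maps2), asyncMap(maps))
})

test_that("maps round-trip through CSV and the binary container", {
  sim <- generateSeries(threeBandSpec())
  maps <- correlate2d(selectRegion(sim$series, 980, 1060))
  fs <- tempfile(fileext = ".csv"); fa <- tempfile(fileext = ".csv")
  writeMaps(maps, fs, fa)
  back <- readMapsCSV(fs, fa, k = nSpectra(maps))
  expect_identical(unname(syncMap(back)), unname(syncMap(maps)))
  expect_identical(unname(asyncMap(back)), unname(asyncMap(maps)))

  fb <- tempfile(fileext = ".rds")
  saveMaps(maps, fb)
  expect_identical(loadMaps(fb), maps)
})
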