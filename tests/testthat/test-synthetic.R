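test_that("band profiles follow the amplitude-response model", {
  # no response: identical profiles at any two temperatures
  b0 <- bandSpec(1031, 10, deltaAmplitude = 0)
  nu <- seq(1000, 1060, by = 4)
  expect_identical(bandProfile(b0, nu, 250), bandProfile(b0, nu, 340))

  # sigmoid midpoint: amplitude is exactly base + delta/2 at the onset
  b <- bandSpec(1031, 10, baseAmplitude = 1, deltaAmplitude = 0.4, onsetT = 290)
  expect_equal(bandProfile(b, 1031, 290), 1 + 0.4 / 2)

  # unit peak height: value at the center is amplitude(T) * 1 exactly
  bl <- bandSpec(1031, 10, shape = "lorentzian", baseAmplitude = 2,
                 deltaAmplitude = 0, onsetT = 290)
  expect_identical(bandProfile(bl, 1031, 300), 2)

  # linear response spans exactly 0..1 over the temperature range
  lin <- bandSpec(1031, 10, response = "linear", baseAmplitude = 1,
                  deltaAmplitude = 0.5)
  expect_equal(bandProfile(lin, 1031, 250, tRange = c(250, 340)), 1)
  expect_equal(bandProfile(lin, 1031, 340, tRange = c(250, 340)), 1.5)
  expect_error(bandProfile(lin, 1031, 300), "tRange")
})

test_that("generated series match the acquisition design", {
  sim <- generateSeries(threeBandSpec())
  expect_s4_class(sim$series, "SpectralSeries")
  expect_identical(nSpectra(sim$series), 10L)       # 250..340 step 10
  expect_equal(temperatures(sim$series), seq(250, 340, 10))
  expect_equal(diff(range(wavenumbers(sim$series))), 300)

  # noise off + no response: all spectra identical
  flat <- syntheticSpec(bandSpec(1031, 10, deltaAmplitude = 0))
  I <- intensities(generateSeries(flat)$series)
  for (i in 2:nrow(I)) expect_identical(I[i, ], I[1, ])
})

test_that("generation is deterministic, superposable and non-negative", {
  spNoisy <- threeBandSpec(noiseSigma = 0.01, seed = 42L)
  a <- generateSeries(spNoisy)
  b <- generateSeries(spNoisy)
  expect_identical(intensities(a$series), intensities(b$series))
  c <- generateSeries(threeBandSpec(noiseSigma = 0.01, seed = 43L))
  expect_false(identical(intensities(a$series), intensities(c$series)))

  # superposition (noise off): A+B equals sum of A alone and B alone
  bandA <- bandSpec(1000, 10, onsetT = 270)
  bandB <- bandSpec(1100, 12, onsetT = 310, shape = "lorentzian")
  both <- generateSeries(syntheticSpec(list(bandA, bandB)))
  onlyA <- generateSeries(syntheticSpec(list(bandA)))
  onlyB <- generateSeries(syntheticSpec(list(bandB)))
  expect_equal(intensities(both$series),
               intensities(onlyA$series) + intensities(onlyB$series))

  # non-negativity with noise off
  expect_true(all(intensities(both$series) >= 0))
  dec <- generateSeries(syntheticSpec(
    bandSpec(1000, 10, baseAmplitude = 0.3, deltaAmplitude = -0.3)))
  expect_true(all(intensities(dec$series) >= 0))
})

test_that("generator RNG use does not disturb the session RNG state", {
  set.seed(7)
  before <- .Random.seed
  invisible(generateSeries(threeBandSpec(noiseSigma = 0.01, seed = 99L)))
  expect_identical(.Random.seed, before)
})

test_that("ground truth orders responding bands by onset", {
  sp <- syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 270),
    bandSpec(1100, 10, onsetT = 310)
  ))
  tr <- groundTruth(sp)
  expect_identical(tr$relation, "before")
  expect_identical(tr$center_a, 1000)

  # simultaneous requires identical onset and identical response shape
  sp2 <- syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 290),
    bandSpec(1100, 10, onsetT = 290)
  ))
  expect_identical(groundTruth(sp2)$relation, "simultaneous")

  # silent bands (delta = 0) never appear in the truth
  sp3 <- syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 270),
    bandSpec(1050, 10, deltaAmplitude = 0),
    bandSpec(1100, 10, onsetT = 310)
  ))
  expect_identical(nrow(groundTruth(sp3)), 1L)

  # onset tie between different response shapes has no defined order
  sp4 <- syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 295, response = "sigmoid"),
    bandSpec(1100, 10, response = "linear")
  ))
  expect_identical(groundTruth(sp4)$relation, "ambiguous")
})

test_that("invariant violations and degenerate grids are flagged", {
  expect_error(bandSpec(1000, width = -1), "width")
  expect_error(bandSpec(1000, 10, baseAmplitude = 0.1, deltaAmplitude = -0.2),
               "never negative")
  expect_error(syntheticSpec(bandSpec(1000, 10), tMin = 250, tMax = 340, tStep = 7),
               "divisible")
  # undersampling: grid step wider than the narrowest band is a warning
  expect_warning(generateSeries(syntheticSpec(bandSpec(1000, 3), nuStep = 4)),
                 "undersampled")
})

test_that("a SyntheticSpec round-trips through YAML", {
  sp <- threeBandSpec(noiseSigma = 0.005, seed = 11L)
  f <- tempfile(fileext = ".yaml")
  syntheticSpecToYAML(sp, f)
  sp2 <- syntheticSpecFromYAML(f)
  expect_equal(sp2, sp)
  # and the generated data are identical
  expect_identical(intensities(generateSeries(sp)$series),
                   intensities(generateSeries(sp2)$series))
})
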