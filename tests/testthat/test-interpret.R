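test_that("auto-peaks appear at responding band positions, always positive", {
  # one responding band at 1031: exactly one AP at the nearest grid point
  one <- generateSeries(syntheticSpec(bandSpec(1031, 10, onsetT = 290),
                                      nuMin = 900, nuMax = 1200, nuStep = 4))
  maps <- correlate2d(one$series)
  aps <- detectAutopeaks(maps)
  expect_identical(nrow(aps), 1L)
  nu <- wavenumbers(maps)
  expect_identical(aps$nu1, nu[which.min(abs(nu - 1031))])
  expect_identical(aps$sync_sign, "+")

  # two bands with equal amplitude response: two APs of equal height
  two <- generateSeries(syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 290), bandSpec(1100, 10, onsetT = 290))))
  aps2 <- detectAutopeaks(correlate2d(two$series))
  expect_identical(nrow(aps2), 2L)
  expect_equal(aps2$sync_value[1], aps2$sync_value[2])

  # a near-1 threshold keeps only the taller AP
  tall <- generateSeries(syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 290, deltaAmplitude = 0.4),
    bandSpec(1100, 10, onsetT = 290, deltaAmplitude = 0.1))))
  mt <- correlate2d(tall$series)
  expect_identical(nrow(detectAutopeaks(mt, 0.99)), 1L)
  expect_identical(detectAutopeaks(mt, 0.99)$nu1, 1000)

  # all-zero map: empty table, not an error
  const <- spectralSeries(c(1000, 1004, 1008), seq(250, 340, 10),
                          matrix(1, 10, 3))
  expect_identical(nrow(detectAutopeaks(correlate2d(const))), 0L)
  expect_error(detectAutopeaks(maps, 1.5), "thresholdFrac")
})

test_that("cross-peak signs reflect in-phase, anti-phase and sequential responses", {
  # two in-phase bands (same onset): sync +, async ~0
  inphase <- generateSeries(syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 290), bandSpec(1100, 10, onsetT = 290))))
  cp1 <- detectCrosspeaks(correlate2d(inphase$series))
  expect_gte(nrow(cp1), 1L)
  main1 <- cp1[which.min(abs(cp1$nu1 - 1100) + abs(cp1$nu2 - 1000)), ]
  expect_identical(main1$sync_sign, "+")
  expect_identical(main1$async_sign, "~0")

  # one increasing, one decreasing in phase: sync -
  anti <- generateSeries(syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 290, deltaAmplitude = 0.2),
    bandSpec(1100, 10, onsetT = 290, baseAmplitude = 0.5,
             deltaAmplitude = -0.2))))
  cp2 <- detectCrosspeaks(correlate2d(anti$series))
  main2 <- cp2[which.min(abs(cp2$nu1 - 1100) + abs(cp2$nu2 - 1000)), ]
  expect_identical(main2$sync_sign, "-")
  expect_identical(main2$async_sign, "~0")

  # staggered onsets (270 vs 310 K): both signs definite
  seq2 <- generateSeries(syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 270), bandSpec(1100, 10, onsetT = 310))))
  cp3 <- detectCrosspeaks(correlate2d(seq2$series))
  main3 <- cp3[which.min(abs(cp3$nu1 - 1100) + abs(cp3$nu2 - 1000)), ]
  expect_false(main3$sync_sign == "~0")
  expect_false(main3$async_sign == "~0")

  # all cross-peaks live off the diagonal
  expect_true(all(abs(cp3$nu1 - cp3$nu2) >= 8))
})

test_that("the sign-rule quadrants give the stated verdicts", {
  mkpeak <- function(ss, as_) data.frame(
    nu1 = 1100, nu2 = 1000, kind = "cross",
    sync_sign = ss, async_sign = as_,
    sync_value = ifelse(ss == "+", 1, ifelse(ss == "-", -1, 0)),
    async_value = ifelse(as_ == "+", 1, ifelse(as_ == "-", -1, 0)),
    prominence = 1, stringsAsFactors = FALSE
  )
  verdict <- function(ss, as_) applyNodaRules(mkpeak(ss, as_))$relations$verdict
  expect_identical(verdict("+", "+"), "nu1_first")
  expect_identical(verdict("+", "-"), "nu2_first")
  expect_identical(verdict("-", "+"), "nu2_first")   # reversed
  expect_identical(verdict("-", "-"), "nu1_first")   # reversed
  expect_identical(verdict("+", "~0"), "in_phase")
  expect_identical(verdict("-", "~0"), "in_phase")
  expect_identical(verdict("~0", "+"), "indeterminate")
})

test_that("swapping cross-peak coordinates mirrors the verdict", {
  sim <- generateSeries(threeBandSpec())
  maps <- correlate2d(sim$series)
  cps <- detectCrosspeaks(maps)
  expect_gte(nrow(cps), 3L)
  swapped <- cps
  swapped$nu1 <- cps$nu2; swapped$nu2 <- cps$nu1
  swapped$sync_value <- cps$sync_value          # sync symmetric
  swapped$async_value <- -cps$async_value       # async antisymmetric
  swapped$async_sign <- chartr("+-", "-+", cps$async_sign)
  v1 <- applyNodaRules(cps)$relations
  v2 <- applyNodaRules(swapped)$relations
  mirror <- c(nu1_first = "nu2_first", nu2_first = "nu1_first",
              in_phase = "in_phase", indeterminate = "indeterminate")
  direct1 <- v1[v1$rule != "transitive closure", ]
  direct2 <- v2[v2$rule != "transitive closure", ]
  expect_identical(unname(mirror[direct1$verdict]), direct2$verdict)
})

test_that("asynchronous slices are exact rows with a zero diagonal point", {
  sim <- generateSeries(threeBandSpec())
  maps <- correlate2d(sim$series)
  nu <- wavenumbers(maps)
  sl <- sliceAsync(maps, 1000)
  expect_identical(attr(sl, "nu2"), 1000)
  j <- which(nu == 1000)
  expect_identical(sl$async, unname(asyncMap(maps)[, j]))
  expect_identical(sl$async[j], 0)                 # diagonal point
  # off-grid request snaps to the nearest grid point
  expect_identical(attr(sliceAsync(maps, 1001.7), "nu2"), 1000)
  expect_error(sliceAsync(maps, 10), "outside")
  # horizontal vs vertical slice of an antisymmetric map: negatives
  expect_equal(sl$async, -unname(asyncMap(maps)[j, ]))
})

test_that("recovery harness scores matches, swaps and empty truths sanely", {
  sim <- generateSeries(threeBandSpec())
  maps <- correlate2d(sim$series)
  ord <- applyNodaRules(detectCrosspeaks(maps))
  rec <- recoverOrder(ord, sim$truth)
  expect_identical(rec$fraction, 1)
  expect_true(all(rec$report$outcome == "match"))

  # deliberately swapped verdicts score zero
  bad <- ord
  bad$relations$verdict <- chartr("12", "21", ord$relations$verdict)
  expect_identical(recoverOrder(bad, sim$truth)$fraction, 0)

  # truth with zero pairs: zero comparisons, NaN fraction
  empty <- recoverOrder(ord, sim$truth[0, ])
  expect_identical(nrow(empty$report), 0L)
  expect_true(is.nan(empty$fraction))

  # a truth pair with no matching detected relation counts as undetected
  far <- data.frame(center_a = 500, center_b = 600, relation = "before")
  expect_identical(recoverOrder(ord, far)$report$outcome, "undetected")
})

test_that("sequential-order recovery is exact on well-separated noise-free bands", {
  sim <- generateSeries(threeBandSpec())    # onsets 270/290/310, >= 3 HWHM apart
  res <- recoverOrder(
    applyNodaRules(detectCrosspeaks(correlate2d(sim$series))),
    sim$truth
  )
  expect_identical(res$fraction, 1)
})

test_that("band assignment labels land on the nearest catalogued band", {
  tab <- bandAssignments()
  expect_true(all(c(1031, 1055, 1654) %in% tab$center))
  sim <- generateSeries(syntheticSpec(bandSpec(1031, 10, onsetT = 290)))
  maps <- correlate2d(sim$series)
  f <- tempfile(fileext = ".csv")
  writePeakTable(detectAutopeaks(maps), f)
  out <- utils::read.csv(f)
  expect_match(out$assignment[1], "primary alcohol")
})
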