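test_that("cohort generation is deterministic and follows the preset", {
  p <- growthPreset("FW", "LnCap")
  a <- observations(generateCohort(p, seed = 7))
  b <- observations(generateCohort(p, seed = 7))
  expect_identical(a, b)
  d <- observations(generateCohort(p, seed = 8))
  expect_false(identical(a, d))

  # noise-free growth is exactly the preset trajectory
  p0 <- GrowthPreset("FW", "LnCap", 6, 1, 2.0,
                     c("7" = 100, "14" = 382), noiseSigma = 0)
  ob <- observations(generateCohort(p0, seed = 1))
  for (id in unique(ob$animalId)) {
    a7 <- ob$areaMm2[ob$animalId == id & ob$day == 7]
    a14 <- ob$areaMm2[ob$animalId == id & ob$day == 14]
    expect_equal(a14 / a7, 3.82, tolerance = 1e-12)
  }
})

test_that("degenerate engraftment probabilities behave as expected", {
  p0 <- GrowthPreset("DSC", "Pc3", 20, 0, 1.0, c("7" = 100, "21" = 210))
  ob <- observations(generateCohort(p0, seed = 3))
  expect_true(all(ob$status == "excluded_no_engraftment"))
  res <- summarizeCohort(generateCohort(p0, seed = 3))
  expect_identical(res@takeRatePct, 0L)

  p1 <- GrowthPreset("DSC", "Pc3", 20, 1, 1.0, c("7" = 100, "21" = 210))
  ob1 <- observations(generateCohort(p1, seed = 3))
  expect_false(any(ob1$status == "excluded_no_engraftment"))
})

test_that("engrafted counts follow the Bernoulli draw across many seeds", {
  p <- GrowthPreset("FW", "LnCap", 15, 0.93, 1.0, c("7" = 100, "14" = 382))
  counts <- vapply(1:10000, function(s) {
    ob <- observations(generateCohort(p, seed = s))
    length(unique(ob$animalId[ob$status != "excluded_no_engraftment"]))
  }, numeric(1))
  # binomial mean n * p = 13.95
  expect_equal(mean(counts), 15 * 0.93, tolerance = 0.1 / 13.95)
})

test_that("rendered tubes have FWHM equal to the true diameter", {
  for (D in c(12, 25)) {
    fov <- straightTubeField(-10, 50, 210, 50, diameterUm = D,
                             fieldSize = c(200, 100), pixelSize = 0.5,
                             frameRate = 1, duration = 1)
    img <- frames(fov)[, , 1]
    # perpendicular profile through the tube at mid-field (independent of
    # the package's diameter estimator)
    col <- img[200, ]
    xs <- (seq_along(col) - 0.5) * 0.5
    expect_equal(profileFwhm(xs, col), D, tolerance = 0.5 / D)
  }
})

test_that("an empty field renders pure background", {
  params <- vesselFieldParams(nSegments = 0L, fieldSize = c(50, 50),
                              velocityRange = c(0, 0), frameRate = 2,
                              duration = 1)
  fov <- generateVesselField(params, seed = 1)
  expect_identical(nrow(groundTruth(fov)), 0L)
  expect_equal(max(frames(fov)) - min(frames(fov)), 0)
})

test_that("perfusion flags follow the binomial draw", {
  params <- vesselFieldParams(nSegments = 4L, fieldSize = c(200, 200),
                              pixelSize = 1, diameterRange = c(6, 10),
                              velocityRange = c(0, 0), perfusedFraction = 0.5,
                              frameRate = 1, duration = 1)
  perfused <- unlist(lapply(1:50, function(s)
    groundTruth(generateVesselField(params, seed = s))$perfused))
  expect_length(perfused, 200)
  # within 3 binomial SD of 100
  expect_lt(abs(sum(perfused) - 100), 3 * sqrt(200 * 0.25))
})

test_that("field generation is bit-deterministic under a fixed seed", {
  params <- vesselFieldParams(nSegments = 2L, fieldSize = c(80, 80),
                              frameRate = 2, duration = 10, noiseSd = 0.02)
  f1 <- generateVesselField(params, seed = 5)
  f2 <- generateVesselField(params, seed = 5)
  expect_identical(frames(f1), frames(f2))
  expect_identical(groundTruth(f1), groundTruth(f2))
})

test_that("permeability traces encode the inverse of the P formula", {
  # slope-zero fixed point: P = (1 - HT) * V/S / K
  pFix <- 0.81 * 2.5 / 9100 * 1e-4
  tr <- generatePermeabilityTrace(pFix, I0 = 100, Ib = 10, vsRatio = 2.5,
                                  HT = 0.19, K = 9.1e3, noiseSd = 0)
  expect_equal(max(abs(intensities(tr) - 100)), 0, tolerance = 1e-10)
  expect_equal(pFix, 2.2253e-8, tolerance = 1e-4)

  # round trip over a logarithmic grid of permeabilities
  for (P in 10^seq(-9, -5, by = 1)) {
    tr <- generatePermeabilityTrace(P, I0 = 80, Ib = 5, vsRatio = 3.2,
                                    noiseSd = 0)
    expect_equal(estimatePermeability(tr)$P, P, tolerance = 1e-6)
  }
})

test_that("trace generation rejects inconsistent parameters", {
  expect_error(generatePermeabilityTrace(1e-7, 100, 10, vsRatio = -1),
               "vsRatio")
  expect_error(generatePermeabilityTrace(1e-7, 100, 10, vsRatio = 2.5,
                                         K = 0), "K")
  expect_error(generatePermeabilityTrace(1e-7, 10, 100, vsRatio = 2.5),
               "I0")
  expect_error(generatePermeabilityTrace(1e-7, 100, 10, vsRatio = 2.5,
                                         duration = 30), "duration")
})
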