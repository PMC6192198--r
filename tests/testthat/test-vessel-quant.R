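test_that("blood flow rate matches brute-force evaluation on a grid", {
  expect_identical(bloodFlowRate(0, 500), 0)
  expect_identical(bloodFlowRate(10, 0), 0)
  expect_equal(bloodFlowRate(10, 1600), pi * 25 * 1000 / 1000,
               tolerance = 1e-12)
  expect_equal(bloodFlowRate(20, 800), 157.0796, tolerance = 1e-6)
  for (d in c(4, 8, 12.5, 25)) for (v in c(10, 250, 1600)) {
    expect_equal(bloodFlowRate(d, v), bruteBfr(d, v), tolerance = 1e-12)
  }
  # exactly quadratic in D, linear in v
  expect_equal(bloodFlowRate(24, 100) / bloodFlowRate(12, 100), 4)
  expect_equal(bloodFlowRate(12, 300) / bloodFlowRate(12, 100), 3)
  expect_error(bloodFlowRate(-1, 100), "non-negative")
})

test_that("vessel density is perfused length per area with unit handling", {
  segs <- data.frame(lengthUm = 1000, perfused = TRUE)  # 0.1 cm
  expect_equal(vesselDensity(segs, 0.01), 10)
  expect_equal(vesselDensity(segs, 0.02), 5)             # doubling A halves VD
  segs$perfused <- FALSE
  expect_equal(vesselDensity(segs, 0.01), 0)
})

test_that("tissue perfusion rate is intensive and excludes unperfused", {
  segs <- data.frame(bfr = 78.54, perfused = TRUE)
  expect_equal(tissuePerfusionRate(segs, 0.01), 7854)
  expect_equal(tissuePerfusionRate(segs[0, ], 0.01), 0)
  # merging two identical disjoint fields leaves TPR unchanged
  expect_equal(tissuePerfusionRate(rbind(segs, segs), 0.02),
               tissuePerfusionRate(segs, 0.01))
  segs2 <- data.frame(bfr = c(50, 999), perfused = c(TRUE, FALSE))
  expect_equal(tissuePerfusionRate(segs2, 0.01), 5000)
})

test_that("three-ROI aggregation is an unweighted mean over fixed labels", {
  m <- c(VD = 10, meanD = 12, Vmean = 300)
  agg <- aggregateRois(list(border_1 = m, border_2 = m, center = m))
  expect_equal(agg$aggregate, m)
  vals <- list(border_1 = c(VD = 10), border_2 = c(VD = 20),
               center = c(VD = 30))
  expect_equal(aggregateRois(vals)$aggregate[["VD"]], 20)
  # permutation invariance
  expect_equal(aggregateRois(vals[c(3, 1, 2)])$aggregate,
               aggregateRois(vals)$aggregate)
  expect_error(aggregateRois(vals[1:2]), "center")
})

test_that("a single straight tube is traced at its full in-field length", {
  fov <- straightTubeField(-10, 50, 510, 50, diameterUm = 10,
                           fieldSize = c(500, 100), pixelSize = 1,
                           frameRate = 1, duration = 1)
  segs <- segmentVessels(fov)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$lengthUm, 500, tolerance = 2 * 1 / 500 * 5)
  expect_lt(abs(segs$lengthUm - 500), 5)
})

test_that("a blank stack yields no segments", {
  params <- vesselFieldParams(nSegments = 0L, fieldSize = c(60, 60),
                              velocityRange = c(0, 0), frameRate = 1,
                              duration = 1)
  fov <- generateVesselField(params, seed = 1)
  expect_identical(nrow(segmentVessels(fov)), 0L)
  q <- quantifyField(fov, velocity = FALSE)
  expect_equal(unname(q$metrics["VD"]), 0)
})

test_that("FWHM diameter estimation recovers true diameters", {
  for (D in c(12, 25)) {
    fov <- straightTubeField(-10, 40, 210, 60, diameterUm = D,
                             fieldSize = c(200, 100), pixelSize = 0.5,
                             frameRate = 1, duration = 1)
    segs <- segmentVessels(fov)
    est <- estimateDiameter(fov, segs$centerline[[1]])
    expect_equal(est, D, tolerance = 0.5 / D)  # within one pixel
  }
})

test_that("diameter estimation is invariant to field orientation", {
  ds <- vapply(list(c(-10, 20, 210, 90), c(20, -10, 90, 210)), function(g) {
    fov <- straightTubeField(g[1], g[2], g[3], g[4], diameterUm = 14,
                             fieldSize = c(200, 200), pixelSize = 0.5,
                             frameRate = 1, duration = 1)
    segs <- segmentVessels(fov)
    estimateDiameter(fov, segs$centerline[[1]])
  }, numeric(1))
  expect_equal(ds[1], ds[2], tolerance = 0.05)
  expect_equal(ds, rep(14, 2), tolerance = 0.05)
})

test_that("kymograph velocimetry recovers an advected gap train", {
  fov <- straightTubeField(-10, 30, 310, 30, diameterUm = 12,
                           velocityUmS = 500, fieldSize = c(300, 60),
                           pixelSize = 0.5, frameRate = 20, duration = 10)
  segs <- segmentVessels(fov)
  v <- estimateVelocity(fov, segs$centerline[[1]])
  expect_equal(v, 500, tolerance = 0.05)

  # time reversal leaves the speed magnitude unchanged
  rev <- fov
  rev@frames <- fov@frames[, , rev(seq_len(dim(fov@frames)[3]))]
  vr <- estimateVelocity(rev, segs$centerline[[1]])
  expect_equal(vr, v, tolerance = 0.02)
})

test_that("static vessels yield zero velocity and are unperfused", {
  fov <- straightTubeField(-10, 30, 310, 30, diameterUm = 12,
                           velocityUmS = 0, fieldSize = c(300, 60),
                           pixelSize = 0.5, frameRate = 2, duration = 10)
  segs <- segmentVessels(fov)
  expect_identical(estimateVelocity(fov, segs$centerline[[1]]), 0)
  q <- quantifyField(fov)
  expect_false(any(q$segments$perfused))
  expect_equal(unname(q$metrics["VD"]), 0)
  expect_match(q$flag, "no perfused")
})

test_that("a dense noisy field retains at least 90% of centerline length", {
  n <- 50
  segs <- data.frame(x0 = 15 + 30 * (seq_len(n) - 1), y0 = -10,
                     x1 = 15 + 30 * (seq_len(n) - 1), y1 = 210,
                     diameterUm = rep(c(6, 8, 10, 12), length.out = n),
                     velocityUmS = 0, perfused = FALSE)
  params <- vesselFieldParams(fieldSize = c(1510, 200), pixelSize = 1,
                              nSegments = n, diameterRange = c(6, 12),
                              velocityRange = c(0, 0), frameRate = 1,
                              duration = 1, noiseSd = 0.05)
  fov <- generateVesselField(params, seed = 13, segments = segs)
  est <- segmentVessels(fov)
  gtLen <- sum(groundTruth(fov)$lengthUm)
  expect_gte(sum(est$lengthUm), 0.9 * gtLen)
  expect_lte(sum(est$lengthUm), 1.1 * gtLen)
})
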