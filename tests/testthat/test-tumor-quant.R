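test_that("segmentation recovers the area of a rendered disk", {
  # disk of radius 564.19 um has area 1.00 mm^2
  img <- renderTumorFrame(pi * 0.56419^2, pixelSize = 16,
                          dim = c(256L, 256L), noiseSd = 0)
  expect_equal(segmentTumorArea(img, pixelSize = 16), 1.00, tolerance = 0.01)
})

test_that("blank frames segment to zero area with a warning", {
  img <- matrix(0.1, 64, 64)
  expect_warning(a <- segmentTumorArea(img, pixelSize = 32), "empty|signal")
  expect_identical(a, 0)
  set.seed(1)
  noise <- matrix(0.1 + rnorm(64 * 64, 0, 0.02), 64)
  expect_warning(a2 <- segmentTumorArea(noise, pixelSize = 32))
  expect_identical(a2, 0)
})

test_that("segmentation requires a calibration", {
  img <- renderTumorFrame(1.0, noiseSd = 0)
  expect_error(segmentTumorArea(img), "pixelSize")
  expect_error(segmentTumorArea(img, pixelSize = -1), "pixelSize")
})

test_that("segmented area is monotone in the true area on clean renders", {
  areas <- c(0.5, 1, 2, 4, 7)
  meas <- vapply(areas, function(a)
    segmentTumorArea(renderTumorFrame(a, noiseSd = 0), 32), numeric(1))
  expect_true(all(diff(meas) > 0))
  expect_true(all(abs(meas / areas - 1) < 0.02))
})

test_that("relative growth normalizes each animal to its own day 7", {
  df <- data.frame(animalId = "a", day = c(7, 21), areaMm2 = c(1.0, 7.3))
  expect_equal(relativeGrowth(df)$relativeArea, c(100, 730))
  df2 <- data.frame(animalId = "b", day = c(7, 14), areaMm2 = c(2.0, 7.64))
  expect_equal(relativeGrowth(df2)$relativeArea, c(100, 382))
  # constant series stays at 100%
  df3 <- data.frame(animalId = "c", day = c(7, 14, 21), areaMm2 = rep(3, 3))
  expect_equal(relativeGrowth(df3)$relativeArea, c(100, 100, 100))
  # invariance under rescaling all areas
  df4 <- df; df4$areaMm2 <- df4$areaMm2 * 17.3
  expect_equal(relativeGrowth(df4)$relativeArea,
               relativeGrowth(df)$relativeArea)
  # undefined baseline
  df5 <- data.frame(animalId = "d", day = c(7, 14), areaMm2 = c(NA, 2))
  expect_true(all(is.na(relativeGrowth(df5)$relativeArea)))
})

test_that("take rate is the exact engrafted fraction in percent", {
  expect_identical(takeRate(15, 14)$percent, 93L)
  expect_identical(takeRate(20, 14)$percent, 70L)
  expect_identical(takeRate(15, 10)$percent, 67L)
  expect_identical(takeRate(20, 9)$percent, 45L)
  expect_identical(takeRate(20, 0)$percent, 0L)
  # exactness before rounding: rate/100 * n == k
  for (n in c(5, 15, 20)) for (k in 0:n) {
    expect_equal(takeRate(n, k)$exact / 100 * n, k, tolerance = 1e-12)
  }
  expect_error(takeRate(0, 0), "undefined")
  expect_error(takeRate(10, 11), "nEngrafted")
})

test_that("protocol rules exclude, censor and audit correctly", {
  ob <- rbind(
    data.frame(animalId = "m1", tissue = "FW", cellLine = "LnCap",
               day = c(7, 14), areaMm2 = c(1, 3.8),
               status = c("engrafted", "censored_fracture")),
    data.frame(animalId = "m2", tissue = "FW", cellLine = "LnCap",
               day = 7, areaMm2 = NA, status = "excluded_no_engraftment"),
    data.frame(animalId = "m3", tissue = "FW", cellLine = "LnCap",
               day = c(7, 14), areaMm2 = c(1.1, 4),
               status = c("engrafted", "engrafted")))
  pr <- applyProtocolRules(ob)
  expect_identical(pr$nImplanted, 3L)
  expect_identical(pr$nEngrafted, 2L)
  expect_false("m2" %in% pr$included$animalId)
  expect_true(all(c("m1", "m3") %in% pr$included$animalId))
  expect_setequal(pr$audit$rule, c("exclude_no_engraftment",
                                   "censor_fracture"))
  # censored animal contributes only to the days it was observed
  res <- summarizeCohort(ob)
  expect_identical(res@growth$n, c(2L, 2L))
  expect_identical(res@takeRatePct, 67L)

  # cohort with no exclusions passes through unchanged
  clean <- ob[ob$animalId == "m3", ]
  pr2 <- applyProtocolRules(clean)
  expect_identical(pr2$included, clean)
  expect_identical(nrow(pr2$audit), 0L)
})

test_that("fracture censoring truncates bone LnCap series after day 14", {
  co <- generateCohort(growthPreset("FW", "LnCap"), seed = 2)
  ob <- observations(co)
  expect_false(21 %in% ob$day)
  engrafted <- unique(ob$animalId[ob$status != "excluded_no_engraftment"])
  last <- vapply(engrafted, function(id)
    max(ob$day[ob$animalId == id]), numeric(1))
  expect_true(all(last == 14))
  expect_true(all(ob$status[ob$day == 14] == "censored_fracture"))
})

test_that("image-based measurement recovers generated areas within 2%", {
  p <- GrowthPreset("DSC", "Du145", 5, 1, 2.0,
                    c("7" = 100, "14" = 150, "21" = 225), noiseSigma = 0.1)
  co <- generateCohort(p, seed = 4)
  meas <- measureCohortAreas(co, noiseSd = 0.01)
  ob <- observations(meas)
  expect_true(all(abs(ob$areaMm2 / ob$renderedAreaMm2 - 1) < 0.02))
})

test_that("noise-free cohorts reproduce the preset growth exactly", {
  p <- GrowthPreset("FW", "Du145", 8, 1, 1.0,
                    c("7" = 100, "14" = 250, "21" = 340), noiseSigma = 0)
  res <- summarizeCohort(generateCohort(p, seed = 9))
  expect_equal(res@growth$meanRel, c(100, 250, 340), tolerance = 1e-12)
})
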