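test_that("generators are pure functions of config and seed", {
  cfg <- growthPreset("reference")
  expect_identical(simulateGrowthCohort(cfg, seed = 7),
                   simulateGrowthCohort(cfg, seed = 7))
  expect_false(identical(measurements(simulateGrowthCohort(cfg, seed = 7)),
                         measurements(simulateGrowthCohort(cfg, seed = 8))))
  expect_identical(simulateTimeActivity(2, 0.05, c(1, 24, 72), 0.05, seed = 3),
                   simulateTimeActivity(2, 0.05, c(1, 24, 72), 0.05, seed = 3))
  l <- sectionLayout(canvasPx = c(64, 64))
  expect_identical(renderSectionPair(l, seed = 4), renderSectionPair(l, seed = 4))
  ## generators leave the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(simulateGrowthCohort(cfg, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("a null-treatment arm reduces to exponential growth with RTV e^(g t)", {
  cfg <- growthConfig(
    arms = list(armSpec("control", n = 4, followUpDays = 21)),
    controlArm = "control", noiseCv = 0)
  co <- simulateGrowthCohort(cfg, seed = 2)
  r <- relativeVolumes(co)
  expect_equal(r$rtv, exp(cfg$growthRate * r$day), tolerance = 1e-9)
})

test_that("noiseless RTV is independent of baseline volume", {
  cfg <- growthConfig(
    arms = list(armSpec("control", n = 8, followUpDays = 14),
                armSpec("rad", n = 8, followUpDays = 14, fsRad = 0.3)),
    controlArm = "control", noiseCv = 0)
  r <- relativeVolumes(simulateGrowthCohort(cfg, seed = 5))
  for (g in c("control", "rad")) {
    byDay <- split(r$rtv[r$group == g], r$day[r$group == g])
    expect_true(all(vapply(byDay, function(x) diff(range(x)) < 1e-9,
                           logical(1))))
  }
})

test_that("noiseless untreated animals progress at the first visit", {
  cfg <- growthConfig(
    arms = list(armSpec("control", n = 6, followUpDays = 21)),
    controlArm = "control", noiseCv = 0)
  rec <- detectProgression(simulateGrowthCohort(cfg, seed = 1))
  expect_true(all(rec$event))
  expect_true(all(rec$time == 3))
})

test_that("calliper triples round-trip the simulated volume exactly", {
  cfg <- growthConfig(arms = list(armSpec("control", n = 3, followUpDays = 10)),
                      controlArm = "control", noiseCv = 0)
  co <- simulateGrowthCohort(cfg, seed = 9)
  m <- measurements(co)
  vol <- ellipsoidVolume(m$length_mm, m$width_mm, m$height_mm)
  v0 <- vol[m$day == 0][match(m$animal_id, unique(m$animal_id))]
  expect_equal(vol / v0, exp(cfg$growthRate * m$day), tolerance = 1e-9)
})

test_that("the volume cap kills fast-growing animals and truncates follow-up", {
  cfg <- growthConfig(arms = list(armSpec("control", n = 6, followUpDays = 59)),
                      controlArm = "control", noiseCv = 0,
                      killVolumeMm3 = 1500)
  co <- simulateGrowthCohort(cfg, seed = 4)
  f <- fates(co)
  expect_true(any(f$fate == "killed"))
  for (id in f$animal_id[f$fate == "killed"]) {
    lastDay <- max(measurements(co)$day[measurements(co)$animal_id == id])
    expect_equal(f$fate_day[f$animal_id == id], lastDay)
  }
})

test_that("the reference preset reproduces the calibrated effect sizes", {
  ## large n to suppress sampling noise
  co <- simulateGrowthCohort(growthPreset("reference", nPerArm = 200), seed = 31)
  g <- summariseGroups(co)
  ## drug arm settles near half the control RTV after the dosing window
  mid <- g$ratio_to_control[g$group == "gem" & g$day >= 14 & g$day <= 24]
  expect_true(all(abs(mid - 0.5) < 0.10))
  ## radiation arm shows a clear nadir below baseline, then regrows
  rad <- g[g$group == "rad" & g$day <= 30, ]
  expect_lt(min(rad$mean_rtv), 0.75)
  expect_gt(rad$mean_rtv[which.max(rad$day)], min(rad$mean_rtv))
  nadirDay <- rad$day[which.min(rad$mean_rtv)]
  expect_true(nadirDay >= 7 && nadirDay <= 17)
})

test_that("time-activity simulation is exact at zero noise and unbiased at 5% CV", {
  s <- simulateTimeActivity(2, 0.05, c(1, 24, 72, 168), noiseCv = 0, seed = 1)
  expect_equal(s@concentrations, 2 * exp(-0.05 * c(1, 24, 72, 168)))
  lams <- vapply(1:200, function(i) {
    fitMonoexponential(simulateTimeActivity(2, 0.05, c(1, 8, 24, 48, 96, 168),
                                            noiseCv = 0.05, seed = i))$lambdaEff
  }, numeric(1))
  expect_lt(abs(median(lams) - 0.05) / 0.05, 0.02)
})

test_that("section renderer places the requested fractions and exact control points", {
  l <- sectionLayout(ki67Fraction = 0.64, mtFraction = 0.03,
                     necroticFraction = 0.15)
  pair <- renderSectionPair(l, seed = 27)
  expect_equal(pair$truth$ki67PercentViable, 64, tolerance = 0.02)
  expect_equal(pair$truth$mtPercentWhole, 3, tolerance = 0.02)
  expect_equal(pair$truth$necroticFraction, 0.15, tolerance = 0.1)
  tf <- fitRegistration(pair$controlPoints)
  expect_lt(tf$rmsPx, 1e-3)
  expect_equal(tf$A, pair$truth$transform$A, tolerance = 1e-9)
  expect_true(validObject(pair$mt) && validObject(pair$ki67))
})
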