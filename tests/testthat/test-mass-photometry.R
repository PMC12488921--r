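test_that("histogram bins are anchored at oligomer masses", {
  h <- buildHistogram(rep(269, 7), monomerMass = 26.9)
  centers <- binCenters(h)
  expect_true(all(abs(centers / 26.9 - round(centers / 26.9)) < 1e-9))
  expect_equal(binCounts(h)[abs(centers - 269) < 1e-6], 7)
  expect_equal(sum(binCounts(h)), 7)
  expect_identical(weighting(h), "number")
  expect_error(buildHistogram(numeric(0)), "zero events")
  expect_error(buildHistogram(c(100), binWidth = 0), "binWidth")
})

test_that("mass weighting multiplies counts by N and conserves total mass", {
  masses <- rep(c(26.9, 269, 538), c(4, 5, 2))
  h <- buildHistogram(masses, 26.9)
  mw <- toMassWeighted(h)
  expect_identical(weighting(mw), "mass")
  n <- round(binCenters(h) / 26.9)
  expect_equal(binCounts(mw), binCounts(h) * n)
  expect_equal(sum(binCounts(mw)), sum(n * binCounts(h)))
  # counts at N = 1 unchanged; counts 5 at N = 10 become 50
  expect_equal(binCounts(mw)[n == 1], binCounts(h)[n == 1])
  expect_equal(binCounts(mw)[n == 10], 50)
  # total mass-weighted count equals total mass / monomer mass (n_min = 1)
  expect_equal(sum(binCounts(mw)) * 26.9, sum(masses))
  expect_error(toMassWeighted(mw), "twice")
})

test_that("mean aggregation number respects weighting and n_min", {
  h10 <- buildHistogram(rep(269, 3), 26.9)
  expect_equal(as.numeric(meanAggregationNumber(h10)), 10)
  expect_equal(as.numeric(meanAggregationNumber(toMassWeighted(h10))), 10)

  h <- buildHistogram(c(269, 807), 26.9)  # one N=10 and one N=30 particle
  expect_equal(as.numeric(meanAggregationNumber(h, nMin = 3)), 20)
  expect_equal(as.numeric(meanAggregationNumber(toMassWeighted(h), nMin = 3)),
               25)
  expect_identical(attr(meanAggregationNumber(h), "weighting"), "number")
  expect_error(meanAggregationNumber(h, nMin = 50), "undefined")
})

test_that("mean aggregation number is invariant to bin refinement", {
  masses <- rep(c(269, 538, 807), c(5, 3, 2))
  coarse <- meanAggregationNumber(buildHistogram(masses, 26.9), 3)
  fine <- meanAggregationNumber(
    buildHistogram(masses, 26.9, binWidth = 26.9 / 2), 3)
  expect_equal(as.numeric(coarse), as.numeric(fine))
})

test_that("number-weighted <N> never exceeds mass-weighted <N>", {
  for (seed in 1:5) {
    pop <- buildPopulation(totalConc = 30)
    ev <- sampleMPEvents(pop, 2000, seed = seed)
    h <- buildHistogram(measuredMasses(ev), 26.9)
    expect_lte(as.numeric(meanAggregationNumber(h, 3)),
               as.numeric(meanAggregationNumber(toMassWeighted(h), 3)))
  }
})

test_that("noiseless events round-trip through the histogram exactly", {
  pop <- buildPopulation(totalConc = 30)
  ev <- sampleMPEvents(pop, 5000, noise = mpNoiseModel(0, 0), seed = 9)
  h <- buildHistogram(measuredMasses(ev), 26.9)
  mw <- toMassWeighted(h)
  n <- trueAggregationNumbers(ev)
  n <- n[n >= 3]
  expect_equal(as.numeric(meanAggregationNumber(mw, 3)),
               sum(n^2) / sum(n))
  expect_equal(oligomerMassTotal(h, 3), sum(n) * 26.9)
})

test_that("oligomer mass reporter counts only N > 2 species", {
  h <- buildHistogram(rep(c(26.9, 53.8), c(10, 5)), 26.9)
  expect_equal(oligomerMassTotal(h), 0)
  h2 <- buildHistogram(rep(269, 2), 26.9)
  expect_equal(oligomerMassTotal(h2), 538)
  expect_error(oligomerMassTotal(toMassWeighted(h2)), "number-weighted")
})

test_that("calibration recovers an exact linear contrast layer", {
  set.seed(1)
  mkStd <- function(name, mass, slope = 1e-3, noise = 0) {
    contr <- toContrast(rep(mass, 500) + rnorm(500, 0, 0.01 * mass),
                        slope = slope)
    list(name = name, mass = mass, contrasts = contr)
  }
  cal <- fitCalibration(list(mkStd("BSA", 66), mkStd("IgG", 150),
                             mkStd("Tg", 669)))
  expect_equal(cal@slope, 1e-3, tolerance = 0.01)
  expect_lt(abs(cal@intercept), 0.005)
  # round trip: contrast -> mass is the identity within noise
  m <- applyCalibration(toContrast(c(100, 300, 669)), cal)
  expect_equal(as.numeric(m), c(100, 300, 669), tolerance = 0.01)
})

test_that("calibration tolerates noise and standard dimer peaks", {
  set.seed(2)
  stds <- lapply(list(c(66, 1), c(132, 2), c(150, 3), c(669, 4)),
                 function(ms) {
                   contr <- toContrast(rep(ms[1], 400), slope = 1e-3,
                                       noiseRel = 0.02, seed = ms[2])
                   list(name = paste0("std", ms[1]), mass = ms[1],
                        contrasts = contr)
                 })
  cal <- fitCalibration(stds)  # includes the BSA dimer at 132 kDa
  expect_equal(cal@slope, 1e-3, tolerance = 0.03)
  expect_equal(nrow(cal@standards), 4)
})

test_that("calibration inputs are validated and low masses flagged", {
  one <- list(list(name = "only", mass = 66, contrasts = rnorm(100, 0.066)))
  expect_error(fitCalibration(one), ">= 2 standards")
  few <- list(list(name = "a", mass = 66, contrasts = rnorm(10, 0.066)),
              list(name = "b", mass = 150, contrasts = rnorm(10, 0.15)))
  expect_error(fitCalibration(few), ">= 50 events")

  cal <- new("CalibrationCurve", slope = 1e-3, intercept = 0.002,
             validMassMin = 40, residualSd = 0,
             standards = data.frame(name = "x", nominalMass = 66,
                                    peakContrast = 0.068))
  m <- applyCalibration(c(0.002, 0.0289, 0.1), cal)
  expect_equal(as.numeric(m[1]), 0)
  expect_identical(attr(m, "flagged"), c(TRUE, TRUE, FALSE))
  # a 10 nM pre-equilibrated monomer sample: one flagged sub-40 mode only
  monoContr <- toContrast(rep(26.9, 300), slope = 1e-3, noiseRel = 0.05,
                          seed = 7) + 0.002
  mm <- applyCalibration(monoContr, cal)
  expect_true(all(attr(mm, "flagged")))
  expect_lt(max(mm), 53.8 / 2 + 26.9 / 2)  # no dimer mode
})

test_that("particle concentration is subunit concentration over <N>", {
  expect_identical(particleConcentration(200, 20), 10)
  expect_identical(particleConcentration(7.7, 1), 7.7)
  expect_equal(particleConcentration(30000, 35), 30000 / 35)
  expect_equal(particleConcentration(200, 20) * 20, 200)
  expect_error(particleConcentration(200, 0), "meanN")
})

test_that("monomer-dimer speciation solves the association quadratic", {
  expect_equal(monomerDimer(2e-7, 0), c(c1 = 2e-7, c2 = 0))
  x <- monomerDimer(2e-7, 1e6)
  # quadratic-formula oracle: c1 = (-1 + sqrt(1 + 8 K2 ct)) / (4 K2)
  expect_equal(unname(x["c1"]), (-1 + sqrt(1 + 8 * 1e6 * 2e-7)) / 4e6,
               tolerance = 1e-12)
  expect_equal(unname(x["c1"]), 1.531e-7, tolerance = 1e-3)
  expect_equal(unname(x["c2"]), 2.34e-8, tolerance = 1e-2)
  expect_equal(unname(x["c1"] + 2 * x["c2"]), 2e-7, tolerance = 1e-12)
  expect_error(monomerDimer(-1, 1), ">= 0")
})
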