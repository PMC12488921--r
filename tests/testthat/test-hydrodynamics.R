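test_that("the Svedberg forward map matches brute-force evaluation", {
  ctx <- svedbergContext(eta = 1.002, rhoP = 1.39, rhoW = 1.00)
  # hand evaluation with literal constants, independent of the package path
  oracle <- function(mKda, rhNm) {
    mp <- mKda * 1.66054e-24                       # kg
    mp * (1 - 1.00 / 1.39) / (6 * pi * 1.002e-3 * rhNm * 1e-9) / 1e-13
  }
  expect_equal(sedimentationCoefficient(26.9, 3.3, ctx), oracle(26.9, 3.3),
               tolerance = 1e-12)
  expect_equal(sedimentationCoefficient(26.9, 3.3, ctx), 2.01,
               tolerance = 0.005)
  expect_equal(sedimentationCoefficient(941.5, 9.0, ctx), oracle(941.5, 9.0),
               tolerance = 1e-12)
  expect_equal(sedimentationCoefficient(941.5, 9.0, ctx), 25.8,
               tolerance = 0.005)
  # linearity in mass at fixed radius
  expect_equal(sedimentationCoefficient(200, 5, ctx),
               2 * sedimentationCoefficient(100, 5, ctx))
  expect_error(sedimentationCoefficient(-1, 3, ctx), "> 0")
})

test_that("forward and inverse Svedberg round-trip to 1e-12", {
  ctx <- svedbergContext(293.15)
  set.seed(101)
  m <- exp(runif(1000, log(20), log(5000)))
  r <- exp(runif(1000, log(2), log(20)))
  s <- sedimentationCoefficient(m, r, ctx)
  expect_equal(hydrodynamicRadius(m, s, ctx), r, tolerance = 1e-12)
  expect_equal(hydrodynamicRadius(26.9, 2.01,
                                  svedbergContext(eta = 1.002, rhoW = 1.00)),
               3.3, tolerance = 0.01)
})

test_that("a 100 kDa, 3 nm particle sediments in the single-digit S range", {
  s <- sedimentationCoefficient(100, 3, svedbergContext(293.15))
  expect_gt(s, 1)
  expect_lt(s, 10)
})

test_that("s20,w correction is identity at 20 C and uses both factors", {
  ctx20 <- svedbergContext(293.15)
  expect_equal(correctS20W(12.5, ctx20, ctx20), 12.5)
  ctx37 <- svedbergContext(310.15)
  # frozen from the package's solvent tables:
  # 30 * (0.69126/1.002) * ((1 - 0.99821/1.39)/(1 - 0.99333/1.39))
  expect_equal(correctS20W(30, ctx37, ctx20), 20.4422, tolerance = 1e-4)
  # viscosity-only variant drops the buoyancy ratio
  expect_equal(correctS20W(30, ctx37, ctx20, viscosityOnly = TRUE),
               30 * ctx37$eta / ctx20$eta)
  # lower viscosity at the higher temperature shrinks s on correction
  expect_lt(correctS20W(30, ctx37, ctx20), 30)
})

test_that("s20,w correction of a distribution sets the flag once", {
  pop <- buildPopulation(totalConc = 30)
  sed <- forwardAUC(pop, temperature = 310.15)
  expect_false(isCorrectedTo20W(sed))
  sed20 <- correctS20W(sed)
  expect_true(isCorrectedTo20W(sed20))
  expect_identical(amplitudes(sed20), amplitudes(sed))
  expect_warning(correctS20W(sed20), "already corrected")
})

test_that("packing density follows the spherical-volume definition", {
  expect_equal(packingDensity(941.5, 9.0), 0.512, tolerance = 1e-3)
  expect_equal(packingDensity(941.5, 18.0), packingDensity(941.5, 9.0) / 8)
  # the anhydrous compact sphere recovers the protein density
  rCompact <- packingRadius(500, 0, svedbergContext())
  expect_equal(packingDensity(500, rCompact), 1.39, tolerance = 1e-9)
})

test_that("water mass fraction inverts the packing model", {
  ctx <- svedbergContext()
  expect_equal(waterMassFraction(1.39, ctx), 0)
  expect_equal(waterMassFraction(0.512, ctx), 0.552, tolerance = 1e-3)
  # strictly decreasing in density
  d <- seq(0.2, 1.39, length.out = 50)
  expect_true(all(diff(waterMassFraction(d, ctx)) < 0))
  # closed loop: density of the packing-model sphere returns the input f
  for (f in c(0, 0.3, 0.65, 0.88, 0.9)) {
    rh <- packingRadius(941.5, f, ctx)
    expect_equal(waterMassFraction(packingDensity(941.5, rh), ctx), f,
                 tolerance = 1e-9)
  }
  expect_error(waterMassFraction(1.5, ctx), "impossible packing")
})

test_that("the forward AUC map places species where the Svedberg law says", {
  ctx <- svedbergContext(293.15)
  one <- singleSpeciesPopulation(35, particleConc = 1)
  sed <- forwardAUC(one, ctx = ctx, includeMonomer = FALSE)
  sPeak <- sValues(sed)[which.max(amplitudes(sed))]
  rh <- packingRadius(35 * 26.9, 0.65, ctx)
  expect_equal(rh, 9.87, tolerance = 1e-3)
  expect_equal(sPeak, sedimentationCoefficient(35 * 26.9, rh, ctx),
               tolerance = 0.01)

  mono <- singleSpeciesPopulation(1, particleConc = 0, monomer = 1)
  sedM <- forwardAUC(mono, ctx = svedbergContext(eta = 1.002, rhoW = 1.00))
  sMono <- sValues(sedM)[which.max(amplitudes(sedM))]
  expect_equal(sMono, 2.01, tolerance = 0.03)

  # integrated amplitude tracks the mass-weighted total
  pop <- buildPopulation(totalConc = 30)
  sed30 <- forwardAUC(pop, includeMonomer = FALSE)
  integral <- sum((amplitudes(sed30)[-1] + head(amplitudes(sed30), -1)) / 2 *
                    diff(sValues(sed30)))
  expect_equal(integral,
               sum(aggregationNumbers(pop) * numberConcentrations(pop)),
               tolerance = 1e-3)
})
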