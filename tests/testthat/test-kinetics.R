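test_that("a noiseless exponential is recovered to 1e-8", {
  tt <- seq(0, 1e5, length.out = 20)
  ser <- makeSeries(tt, 5 * exp(-2e-5 * tt) + 4)
  fit <- fitDecay(ser)
  p <- decayParameters(fit)
  expect_equal(unname(p["a"]), 5, tolerance = 1e-8)
  expect_equal(unname(p["k"]), 2e-5, tolerance = 1e-8)
  expect_equal(unname(p["c"]), 4, tolerance = 1e-8)
  expect_lt(fit@rmsResidual, 1e-8)
})

test_that("noiseless generator series are fitted with negligible residual", {
  kp <- kineticParams(noiseSd = 0)
  ser <- simulateDissociation(kp, c(295.15, 310.15), replicates = 1,
                              seed = 1)
  for (s in ser) {
    fit <- fitDecay(s)
    expect_lt(fit@rmsResidual, 1e-8)
    expect_equal(fit@k, arrheniusRate(kp, s@temperature), tolerance = 1e-6)
  }
  # t = 0 of a noiseless series is a + c exactly
  expect_equal(ser[[1]]@values[1], 5.0 + 4.5)
})

test_that("default synthetic series plateau at the temperature-set radii", {
  kp <- kineticParams()
  ser <- simulateDissociation(kp, c(295.15, 313.15), replicates = 3,
                              seed = 17)
  c22 <- mean(vapply(ser[1:3], function(s) fitDecay(s)@c, numeric(1)))
  c40 <- mean(vapply(ser[4:6], function(s) fitDecay(s)@c, numeric(1)))
  expect_lt(abs(c22 - 4.5), 0.4)
  expect_lt(abs(c40 - 3.3), 0.4)
})

test_that("near-constant series return the degenerate fit", {
  tt <- seq(0, 100, length.out = 10)
  ser <- makeSeries(tt, rep(4, 10) + c(0.01, -0.01), sd = rep(0.3, 10))
  fit <- fitDecay(ser)
  expect_true(fit@degenerate)
  expect_equal(decayParameters(fit)[c("a", "k")], c(a = 0, k = 0))
  expect_equal(unname(decayParameters(fit)["c"]), 4, tolerance = 0.01)
})

test_that("Arrhenius regression is exact on log-linear data", {
  kp <- kineticParams()
  # two points define the line exactly
  t2 <- c(295.15, 310.15)
  fit2 <- fitArrhenius(data.frame(temperature = t2,
                                  k = arrheniusRate(kp, t2)))
  expect_equal(fit2@ea, 250, tolerance = 1e-10)
  # any size: seven exact points, still exact
  t7 <- seq(295.15, 313.15, by = 3)
  fit7 <- fitArrhenius(data.frame(temperature = t7,
                                  k = arrheniusRate(kp, t7)))
  expect_equal(fit7@ea, 250, tolerance = 1e-10)
  expect_lt(fit7@seEa, 1e-8)
})

test_that("printed-scale rate pairs give the expected barrier", {
  pts <- data.frame(temperature = c(295.15, 310.15), k = c(6.02e-6, 8.33e-4))
  # closed-form oracle: Ea = R ln(k2/k1) / (1/T1 - 1/T2)
  eaOracle <- 8.314 * log(8.33e-4 / 6.02e-6) /
    (1 / 295.15 - 1 / 310.15) / 1000
  fit <- fitArrhenius(pts)
  expect_equal(fit@ea, eaOracle, tolerance = 1e-10)
  expect_equal(fit@ea, 250, tolerance = 0.01)
  expect_error(fitArrhenius(data.frame(temperature = c(295, 310),
                                       k = c(-1, 1))), "> 0")
})

test_that("rate constants increase with temperature and set the time scale", {
  kp <- kineticParams()
  tGrid <- seq(280, 320, by = 5)
  expect_true(all(diff(arrheniusRate(kp, tGrid)) > 0))

  t7 <- seq(295.15, 313.15, by = 3)
  fit <- fitArrhenius(data.frame(temperature = t7,
                                 k = arrheniusRate(kp, t7)))
  at37 <- rateAndTimescale(fit, 310.15)
  expect_equal(unname(at37["k"]), arrheniusRate(kp, 310.15),
               tolerance = 1e-8)
  expect_equal(unname(at37["timescale"]) / 60, 20, tolerance = 1e-6)
  # at room temperature dissociation takes tens of hours
  hours22 <- rateAndTimescale(fit, 295.15)["timescale"] / 3600
  expect_gt(hours22, 10)
  expect_lt(hours22, 100)
  # the 37/22 C rate ratio implied by a 250 kJ/mol barrier
  expect_equal(arrheniusRate(kp, 310.15) / arrheniusRate(kp, 295.15),
               exp(250000 / 8.314 * (1 / 295.15 - 1 / 310.15)),
               tolerance = 1e-12)
})

test_that("rate recovery stays accurate under 3 percent noise", {
  set.seed(77)
  relErr <- replicate(200, {
    a <- runif(1, 2, 8); k <- 10^runif(1, -5, -3); cc <- runif(1, 2, 5)
    tt <- seq(0, 5 / k, length.out = 25)
    y <- a * exp(-k * tt) + cc
    y <- y + rnorm(length(y), 0, 0.03 * mean(y))
    fit <- fitDecay(makeSeries(tt, y))
    abs(fit@k - k) / k
  })
  expect_lt(median(relErr), 0.05)
})

test_that("hydrodynamic and mass-reporter rates give one consistent barrier", {
  # same Arrhenius truth observed through two reporters: R_H decay in nm and
  # an oligomer-mass decay in kDa (different amplitudes/plateaus/noise)
  kpMds <- kineticParams(noiseSd = 0.3)
  kpMp <- kineticParams(noiseSd = 40,
                        plateauByT = c("295.15" = 500, "313.15" = 300),
                        amplitudeByT = c("295.15" = 2000, "313.15" = 2000))
  temps <- seq(295.15, 313.15, by = 6)
  serMds <- simulateDissociation(kpMds, temps, replicates = 2, seed = 5)
  serMp <- simulateDissociation(kpMp, temps, replicates = 2, seed = 6)
  fitMds <- arrheniusFromSeries(serMds, source = "MDS")
  fitMp <- arrheniusFromSeries(serMp, source = "MP")
  pooled <- fitArrhenius(rbind(fitMds@points, fitMp@points))
  expect_lt(abs(pooled@ea - fitMds@ea), fitMds@seEa + pooled@seEa)
  expect_equal(pooled@ea, 250, tolerance = 0.1)
  expect_setequal(unique(pooled@points$source), c("MDS", "MP"))
})
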