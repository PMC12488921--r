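test_that("net charge hits the titration asymptotes", {
  # glycylglycine at pH 0: only the termini ionize and the acid is protonated
  expect_equal(netCharge("GG", 0), 1, tolerance = 1e-3)
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # arginine's model pKa (12.0) is only two units below the pH ceiling, so
  # its protonation tail is excluded from the exact-count basic-limit check
  aaNoR <- setdiff(aa, "R")
  for (i in 1:5) {
    seq <- paste(sample(aa, 60, replace = TRUE), collapse = "")
    counts <- table(factor(strsplit(seq, "")[[1]], levels = aa))
    nBasic <- sum(counts[c("K", "R", "H")]) + 1
    expect_lt(abs(netCharge(seq, 0.01) - nBasic), 0.05)

    seqNoR <- paste(sample(aaNoR, 60, replace = TRUE), collapse = "")
    countsNoR <- table(factor(strsplit(seqNoR, "")[[1]], levels = aa))
    nAcid <- sum(countsNoR[c("D", "E", "C", "Y")]) + 1
    expect_lt(abs(netCharge(seqNoR, 13.99) + nAcid), 0.05)
  }
  expect_error(netCharge("GXZ", 7), "unknown residue")
})

test_that("charge curves decrease monotonically and locate the pI", {
  curve <- chargeCurve("DKAAAG")
  expect_true(all(diff(curve$net_charge) < 0))
  pI <- isoelectricPoint("DK")
  expect_gt(pI, pKaSet()$D)
  expect_lt(pI, pKaSet()$K)
  expect_equal(netCharge("DK", pI), 0, tolerance = 1e-6)
})

test_that("the synthetic chaperone stand-in reproduces the charge profile", {
  seq <- jb6SyntheticSequence()
  expect_equal(nchar(seq), 241)
  # strongly cationic with the C-terminal domain regime fully protonated
  expect_lt(abs(netCharge(seq, 2) - 40), 3)
  # weakly negative at pH 8, with the zero crossing between pH 5 and 8
  z8 <- netCharge(seq, 8)
  expect_lt(z8, 0)
  expect_gt(z8, -5)
  pI <- isoelectricPoint(seq)
  expect_gt(pI, 5)
  expect_lt(pI, 8)
})

test_that("phosphate speciation follows Henderson-Hasselbalch", {
  atPka2 <- phosphateSpeciation(20, 7.21)
  expect_equal(atPka2$concentration_mM[atPka2$name == "H2PO4-"],
               atPka2$concentration_mM[atPka2$name == "HPO4 2-"],
               tolerance = 1e-9)
  sp <- phosphateSpeciation(20, 8.0)
  phos <- sp[sp$name != "Na+", ]
  expect_equal(sum(phos$concentration_mM), 20, tolerance = 1e-12)
  expect_equal(sp$concentration_mM[sp$name == "HPO4 2-"], 17.2,
               tolerance = 0.01)
  expect_equal(sp$concentration_mM[sp$name == "H2PO4-"], 2.8,
               tolerance = 0.01)
  expect_equal(sp$concentration_mM[sp$name == "Na+"], 37.2, tolerance = 0.01)
  # electroneutral by construction
  expect_equal(sum(sp$charge * sp$concentration_mM), 0, tolerance = 1e-12)
  acid <- phosphateSpeciation(20, 4.0)
  expect_gt(acid$concentration_mM[acid$name == "H2PO4-"] / 20, 0.98)
  expect_error(phosphateSpeciation(0, 8), "totalPhosphate")
})

test_that("ionic strength is linear and exact for 1:1 salts", {
  nacl <- data.frame(charge = c(1, -1), concentration_mM = c(150, 150))
  expect_equal(ionicStrength(nacl), 150)
  sp <- phosphateSpeciation(20, 8.0)
  I1 <- ionicStrength(sp)
  sp2 <- sp; sp2$concentration_mM <- 2 * sp2$concentration_mM
  expect_equal(ionicStrength(sp2), 2 * I1)
  expect_warning(
    ionicStrength(data.frame(charge = c(1, -1),
                             concentration_mM = c(150, 100))),
    "electroneutral")
})

test_that("the Debye length matches the molar shortcut and scales as I^-1/2", {
  # 0.304 nm * M^(-1/2) shortcut as the independent oracle
  expect_equal(debyeLength(1000), 0.304, tolerance = 0.01)
  expect_equal(debyeLength(150), 0.304 / sqrt(0.15), tolerance = 0.01)
  expect_equal(debyeLength(4 * 50), debyeLength(50) / 2, tolerance = 1e-12)
  expect_error(debyeLength(0), "> 0")
})

test_that("dn/dc fits recover the refractive-index increment", {
  exact <- fitDnDc(simulateRefractometry(dndc = 0.17, noiseSd = 0))
  expect_equal(exact@dndc, 0.17, tolerance = 1e-12)
  expect_equal(exact@n0, 1.3330, tolerance = 1e-12)
  expect_equal(exact@rSquared, 1, tolerance = 1e-12)

  noisy <- fitDnDc(simulateRefractometry(dndc = 0.17, seed = 8))
  expect_lt(abs(noisy@dndc - 0.17), 0.01)
  second <- fitDnDc(simulateRefractometry(dndc = 0.18, wavelength = 579,
                                          seed = 9))
  expect_lt(abs(second@dndc - 0.18), 0.01)
  expect_equal(second@wavelength, 579)

  flat <- data.frame(conc_mg_ml = rep(1, 5), n = rep(1.333, 5))
  expect_error(fitDnDc(flat), "rank-deficient")
})
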