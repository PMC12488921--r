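#' Mass-measurement noise model for simulated landing events
#'
#' Affine mass-dependent Gaussian noise, sigma(m) = sigma0 + sigma1 * m.
#' The defaults (9 kDa + 2 % of mass) put sigma(669 kDa) at ~22.4 kDa, i.e.
#' a full width at half maximum of ~52 kDa for a 669 kDa standard — the
#' single printed width anchor, with the affine form as the simplest
#' extrapolation. The optional sub-40 kDa bias reproduces the direction of
#' the known low-mass calibration artifact (linear extrapolation
#' overestimates masses below ~30-40 kDa): an additive positive offset
#' `biasAmp * exp(-(m - 20)/10)` kDa for true masses below 40 kDa. It is
#' off by default and qualitative only.
#'
#' @param sigma0 constant noise term (kDa), default 9.
#' @param sigma1 mass-proportional noise term (dimensionless), default 0.02.
#' @param bias logical; enable the sub-40 kDa positive bias, default FALSE.
#' @param biasAmp bias amplitude (kDa), default 12.
#' @return a list of class `MPNoiseModel`.
#' @export
mpNoiseModel <- function(sigma0 = 9, sigma1 = 0.02, bias = FALSE,
                         biasAmp = 12) {
  stopifnot(sigma0 >= 0, sigma1 >= 0)
  structure(list(sigma0 = sigma0, sigma1 = sigma1, bias = bias,
                 biasAmp = biasAmp), class = "MPNoiseModel")
}

.mpBias <- function(mass, noise) {
  ifelse(noise$bias & mass < 40, noise$biasAmp * exp(-(mass - 20) / 10), 0)
}

#' Simulate single-particle landing events from a population
#'
#' Each event's true aggregation number is drawn with probability
#' proportional to the number concentration of the species (the free
#' monomer pool included); the measured mass is `N * monomerMass` plus
#' Gaussian noise from the [mpNoiseModel()]. Reproducible under a fixed
#' seed.
#'
#' @param pop a [MicellePopulation-class].
#' @param nEvents number of landing events (> 0).
#' @param noise an [mpNoiseModel()].
#' @param seed integer RNG seed.
#' @param duration nominal acquisition time (s), default 60.
#' @return an [MPEventSet-class].
#' @export
#' @examples
#' pop <- buildPopulation(totalConc = 30)
#' ev <- sampleMPEvents(pop, 1000, seed = 1)
sampleMPEvents <- function(pop, nEvents, noise = mpNoiseModel(), seed,
                           duration = 60) {
  if (nEvents <= 0) stop("nEvents must be > 0")
  nSpecies <- c(1L, aggregationNumbers(pop))
  w <- c(monomerConc(pop), numberConcentrations(pop))
  if (sum(w) <= 0) stop("population has no particles to sample")
  set.seed(as.integer(seed))
  trueN <- sample(nSpecies, nEvents, replace = TRUE, prob = w)
  trueMass <- trueN * monomerMass(pop)
  sd <- noise$sigma0 + noise$sigma1 * trueMass
  measured <- trueMass + .mpBias(trueMass, noise) +
    if (all(sd == 0)) 0 else stats::rnorm(nEvents, 0, sd)
  methods::new("MPEventSet", measuredMass = measured,
               trueN = as.integer(trueN), seed = as.integer(seed),
               duration = duration, monomerMass = monomerMass(pop))
}

#' Linear optical-contrast layer for calibration tests
#'
#' Maps masses to synthetic scattering contrasts through a linear layer
#' `contrast = slope * mass + intercept` with optional relative Gaussian
#' noise. There is no contrast physics here: the layer exists so that the
#' calibration chain (contrast peaks, line fit, inversion) can be exercised
#' against a known ground truth.
#'
#' @param masses particle masses (kDa).
#' @param slope contrast per kDa, default 1e-3.
#' @param intercept contrast offset, default 0.
#' @param noiseRel relative sd of multiplicative Gaussian noise, default 0.
#' @param seed integer RNG seed (required when `noiseRel > 0`).
#' @return numeric contrast vector.
#' @export
toContrast <- function(masses, slope = 1e-3, intercept = 0, noiseRel = 0,
                       seed = NULL) {
  contrast <- slope * masses + intercept
  if (noiseRel > 0) {
    if (is.null(seed)) stop("seed is required for noisy contrasts")
    set.seed(as.integer(seed))
    contrast <- contrast * (1 + stats::rnorm(length(contrast), 0, noiseRel))
  }
  contrast
}

#' Forward-map a population to a sedimentation-coefficient distribution
#'
#' For each N-mer, the packing model ([packingRadius()]) gives R_H and the
#' Svedberg relation gives s; the species' amplitude is proportional to
#' N * C_N (absorbance detection is mass-weighted). The free monomer enters
#' with its folded-protein radius, not the micellar packing model. Each
#' species is smeared with a Gaussian of relative width `relWidth` in s,
#' emulating the finite resolution of the sedimentation analysis.
#'
#' @param pop a [MicellePopulation-class].
#' @param temperature measurement temperature (K), default 293.15.
#' @param ctx a [svedbergContext()]; default water at `temperature`.
#' @param relWidth relative Gaussian smearing width in s, default 0.05.
#' @param monomerRH hydrodynamic radius of the free monomer (nm),
#'   default 3.3.
#' @param includeMonomer logical, default TRUE.
#' @param nGrid number of points of the s grid, default 600.
#' @return a [SedimentationDistribution-class] (uncorrected, tagged with
#'   `temperature`); the integrated amplitude equals the mass-weighted
#'   total `sum(N * C_N) (+ monomer)`.
#' @export
forwardAUC <- function(pop, temperature = 293.15,
                       ctx = svedbergContext(temperature), relWidth = 0.05,
                       monomerRH = 3.3, includeMonomer = TRUE,
                       nGrid = 600) {
  n <- aggregationNumbers(pop)
  cN <- numberConcentrations(pop)
  keep <- cN > 0
  n <- n[keep]; cN <- cN[keep]
  mMono <- monomerMass(pop)
  sSp <- wSp <- numeric(0)
  if (length(n)) {
    rh <- packingRadius(n * mMono, waterFraction(pop), ctx)
    sSp <- sedimentationCoefficient(n * mMono, rh, ctx)
    wSp <- n * cN
  }
  if (includeMonomer && monomerConc(pop) > 0) {
    sSp <- c(sedimentationCoefficient(mMono, monomerRH, ctx), sSp)
    wSp <- c(monomerConc(pop), wSp)
  }
  if (!length(sSp)) stop("population is empty")
  sGrid <- seq(max(min(sSp) * (1 - 6 * relWidth), 1e-3),
               max(sSp) * (1 + 6 * relWidth), length.out = nGrid)
  amp <- rowSums(vapply(seq_along(sSp), function(i)
    wSp[i] * stats::dnorm(sGrid, sSp[i], relWidth * sSp[i]),
    numeric(length(sGrid))))
  methods::new("SedimentationDistribution", sValues = sGrid,
               amplitudes = amp, temperature = temperature,
               correctedTo20W = FALSE)
}

#' Kinetic parameters of micelle dissociation
#'
#' Arrhenius-activated single-exponential dissociation:
#' \eqn{k(T) = k_{ref} \exp[-(E_a/R)(1/T - 1/T_{ref})]} with
#' \eqn{\langle R_H \rangle(t) = a e^{-k(T) t} + c}. Defaults: activation
#' energy 250 kJ/mol and a reference rate of 1/(20 min) at 37 C (310.15 K),
#' the fitted dissociation barrier and time scale of the micelles; plateau
#' radii 4.5 nm at 22 C and 3.3 nm at 40 C, amplitudes 5.0-5.7 nm over the
#' same span, both linearly interpolated in temperature.
#'
#' @param ea activation energy (kJ/mol), > 0.
#' @param kRef rate constant at `tRef` (1/s), > 0.
#' @param tRef reference temperature (K).
#' @param plateauByT named numeric: plateau radius c (nm) at anchor
#'   temperatures (K), linearly interpolated (constant beyond the anchors).
#' @param amplitudeByT named numeric: amplitude a (nm) at anchor
#'   temperatures (K), same interpolation.
#' @param noiseSd additive Gaussian noise per point (nm), default 0.3.
#' @return a list of class `KineticParams`.
#' @export
kineticParams <- function(ea = 250, kRef = 1 / 1200, tRef = 310.15,
                          plateauByT = c("295.15" = 4.5, "313.15" = 3.3),
                          amplitudeByT = c("295.15" = 5.0, "313.15" = 5.7),
                          noiseSd = 0.3) {
  stopifnot(ea > 0, kRef > 0, all(plateauByT > 0))
  structure(list(ea = ea, kRef = kRef, tRef = tRef,
                 plateauByT = plateauByT, amplitudeByT = amplitudeByT,
                 noiseSd = noiseSd), class = "KineticParams")
}

.interpByT <- function(map, temperature) {
  tAnchor <- as.numeric(names(map))
  if (length(tAnchor) == 1) return(rep(unname(map), length(temperature)))
  stats::approx(tAnchor, unname(map), xout = temperature, rule = 2)$y
}

#' Arrhenius rate constant at a temperature
#'
#' @param kparams a [kineticParams()].
#' @param temperature K.
#' @return rate constant (1/s).
#' @export
#' @examples
#' arrheniusRate(kineticParams(), 310.15) * 1200  # 1 by construction
arrheniusRate <- function(kparams, temperature) {
  eaJ <- kparams$ea * 1000
  kparams$kRef *
    exp(-eaJ / micellabConstants$R_J * (1 / temperature - 1 / kparams$tRef))
}

#' Simulate micelle-dissociation time courses
#'
#' Generates replicate \eqn{\langle R_H \rangle(t)} series at each requested
#' temperature from the Arrhenius-activated single-exponential model, with
#' independent additive Gaussian noise per point and replicate.
#' Reproducible under a fixed seed. The default time grids span five decay
#' times at each temperature (25 points), mirroring how dissociation
#' experiments are run to the plateau.
#'
#' @param kparams a [kineticParams()].
#' @param temperatures numeric vector of temperatures (K), non-empty.
#' @param times list of time grids (s), one per temperature, or NULL for
#'   the default `seq(0, 5/k(T), length.out = 25)`.
#' @param replicates technical replicates per temperature, >= 1, default 3.
#' @param seed integer RNG seed.
#' @return list of [SizeTimeSeries-class], one per (temperature, replicate).
#' @export
#' @examples
#' ser <- simulateDissociation(kineticParams(), temperatures = 295.15 + c(0, 15),
#'                             replicates = 1, seed = 1)
simulateDissociation <- function(kparams, temperatures, times = NULL,
                                 replicates = 3, seed) {
  if (length(temperatures) == 0) stop("empty temperature list")
  if (replicates < 1) stop("replicates must be >= 1")
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_along(temperatures)) {
    temp <- temperatures[i]
    k <- arrheniusRate(kparams, temp)
    a <- .interpByT(kparams$amplitudeByT, temp)
    cc <- .interpByT(kparams$plateauByT, temp)
    tt <- if (is.null(times)) seq(0, 5 / k, length.out = 25) else times[[i]]
    if (any(tt < 0) || is.unsorted(tt, strictly = TRUE))
      stop("times must be nonnegative and strictly increasing")
    for (r in seq_len(replicates)) {
      vals <- a * exp(-k * tt) + cc +
        if (kparams$noiseSd > 0)
          stats::rnorm(length(tt), 0, kparams$noiseSd) else 0
      out[[length(out) + 1L]] <-
        methods::new("SizeTimeSeries", times = tt, values = vals,
                     sd = rep(kparams$noiseSd, length(tt)),
                     temperature = temp, replicate = as.character(r),
                     unit = "nm")
    }
  }
  out
}

#' Simulate a refractometry concentration series
#'
#' Refractive index versus protein mass concentration,
#' `n(c) = n0 + dndc * c / 1000` (dn/dc in ml/g, c in mg/ml), with additive
#' Gaussian noise. The downstream [fitDnDc()] recovers the increment.
#'
#' @param dndc refractive-index increment (ml/g), >= 0; default 0.17.
#' @param n0 solvent refractive index, default 1.3330.
#' @param concentrations mass concentrations (mg/ml); the default is an
#'   8-step ~1.5-fold dilution series from 12.5 down to ~0.1 mg/ml.
#' @param noiseSd additive noise in index units, default 1e-5.
#' @param seed integer RNG seed (required when `noiseSd > 0`).
#' @param wavelength nm, carried along, default 546.
#' @return data.frame with columns `conc_mg_ml`, `n`, `wavelength_nm`.
#' @export
simulateRefractometry <- function(dndc = 0.17, n0 = 1.3330,
                                  concentrations = 12.5 / 1.5^(7:0),
                                  noiseSd = 1e-5, seed = NULL,
                                  wavelength = 546) {
  if (dndc < 0) stop("dndc must be >= 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  n <- n0 + dndc * concentrations / 1000
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed is required for noisy series")
    set.seed(as.integer(seed))
    n <- n + stats::rnorm(length(n), 0, noiseSd)
  }
  data.frame(conc_mg_ml = concentrations, n = n,
             wavelength_nm = wavelength)
}
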