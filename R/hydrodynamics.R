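#' Solvent context for Svedberg-equation calculations
#'
#' Bundles the solvent viscosity and the protein/water densities at a given
#' temperature. By default viscosity and water density come from the
#' package's pure-water tables ([waterViscosity()], [waterDensity()]); the
#' protein partial density defaults to 1.39 g/ml.
#'
#' @param temperature K.
#' @param eta solvent viscosity (mPa s); default pure water at `temperature`.
#' @param rhoP protein density (g/ml), default 1.39.
#' @param rhoW solvent (water) density (g/ml); default from the water table.
#' @return a list of class `SvedbergContext`.
#' @export
#' @examples
#' svedbergContext(293.15)
svedbergContext <- function(temperature = 293.15, eta = NULL, rhoP = 1.39,
                            rhoW = NULL) {
  if (is.null(eta)) eta <- waterViscosity(temperature)
  if (is.null(rhoW)) rhoW <- waterDensity(temperature)
  if (eta <= 0) stop("viscosity must be > 0")
  if (!(rhoP > rhoW && rhoW > 0))
    stop("densities must satisfy rhoP > rhoW > 0")
  structure(list(eta = eta, rhoP = rhoP, rhoW = rhoW,
                 temperature = temperature),
            class = "SvedbergContext")
}

#' Sedimentation coefficient of a buoyant sphere
#'
#' The Svedberg relation for a particle of protein mass m and hydrodynamic
#' radius R_H:
#' \deqn{s = m_p (1 - \rho_w/\rho_p) / (6 \pi \eta R_H)}
#' with the buoyancy factor from the protein and water densities. Unit
#' bookkeeping (kDa to kg, m to nm, s to Svedbergs = 1e-13 s) is centralized
#' in [micellabConstants].
#'
#' @param mass protein mass (kDa), > 0.
#' @param rh hydrodynamic radius (nm), > 0.
#' @param ctx a [svedbergContext()].
#' @return sedimentation coefficient in Svedbergs.
#' @export
#' @examples
#' sedimentationCoefficient(26.9, 3.3, svedbergContext(eta = 1.002))  # ~2.0 S
sedimentationCoefficient <- function(mass, rh, ctx = svedbergContext()) {
  if (any(mass <= 0) || any(rh <= 0)) stop("mass and rh must be > 0")
  mp <- mass * micellabConstants$kDa_kg              # kg
  buoy <- 1 - ctx$rhoW / ctx$rhoP
  sSec <- mp * buoy / (6 * pi * ctx$eta * 1e-3 * rh * 1e-9)
  sSec / micellabConstants$svedberg_s
}

#' Hydrodynamic radius from mass and sedimentation coefficient
#'
#' Exact algebraic inversion of the Svedberg relation
#' ([sedimentationCoefficient()]).
#'
#' @param mass protein mass (kDa), > 0.
#' @param s sedimentation coefficient (Svedbergs), > 0.
#' @param ctx a [svedbergContext()].
#' @return hydrodynamic radius in nm.
#' @export
#' @examples
#' hydrodynamicRadius(26.9, 2.01, svedbergContext(eta = 1.002))  # ~3.3 nm
hydrodynamicRadius <- function(mass, s, ctx = svedbergContext()) {
  if (any(mass <= 0) || any(s <= 0)) stop("mass and s must be > 0")
  mp <- mass * micellabConstants$kDa_kg
  buoy <- 1 - ctx$rhoW / ctx$rhoP
  rhM <- mp * buoy / (6 * pi * ctx$eta * 1e-3 * s * micellabConstants$svedberg_s)
  rh <- rhM * 1e9
  if (any(rh <= 0)) stop("inputs imply a nonpositive radius")
  rh
}

#' Correct sedimentation coefficients to standard conditions (s20,w)
#'
#' Standardizes an observed sedimentation coefficient to water at 20 C:
#' \deqn{s_{20,w} = s_{obs} \frac{\eta_{obs}}{\eta_{20,w}}
#'   \frac{1 - \rho_{20,w}/\rho_p}{1 - \rho_{obs}/\rho_p}}
#' Applied to a [SedimentationDistribution-class] it rescales the s grid and
#' sets the `correctedTo20W` flag; the uncorrected object keeps its
#' measurement temperature, so provenance stays auditable. Set
#' `viscosityOnly = TRUE` to skip the buoyancy-density factor.
#'
#' @param x a [SedimentationDistribution-class] or numeric s values
#'   (Svedbergs).
#' @param ctxObs [svedbergContext()] of the observation (defaults to water
#'   at the distribution's temperature).
#' @param ctx20 [svedbergContext()] of the standard state (water, 20 C).
#' @param viscosityOnly logical; if TRUE only the viscosity ratio is applied.
#' @return same type as `x`, corrected.
#' @export
correctS20W <- function(x, ctxObs = NULL, ctx20 = svedbergContext(293.15),
                        viscosityOnly = FALSE) {
  if (methods::is(x, "SedimentationDistribution")) {
    if (x@correctedTo20W) {
      warning("distribution is already corrected to s20,w; returning as-is")
      return(x)
    }
    if (is.null(ctxObs)) ctxObs <- svedbergContext(x@temperature)
    sNew <- correctS20W(x@sValues, ctxObs, ctx20, viscosityOnly)
    return(methods::new("SedimentationDistribution", sValues = sNew,
                        amplitudes = x@amplitudes, temperature = x@temperature,
                        correctedTo20W = TRUE))
  }
  if (is.null(ctxObs)) stop("ctxObs is required for numeric input")
  fac <- ctxObs$eta / ctx20$eta
  if (!viscosityOnly)
    fac <- fac * (1 - ctx20$rhoW / ctx20$rhoP) / (1 - ctxObs$rhoW / ctxObs$rhoP)
  x * fac
}

#' Hydrodynamic radius of a micelle from the packing model
#'
#' The generator's packing model: a micelle of N subunits is an equivalent
#' sphere whose volume is the anhydrous protein volume \eqn{m_p/\rho_p} plus
#' the water volume implied by the water mass fraction f
#' (\eqn{m_w = m_p f/(1-f)}, \eqn{V_w = m_w/\rho_w}).
#'
#' @param mass protein mass (kDa).
#' @param waterFraction water mass fraction in \[0, 1).
#' @param ctx a [svedbergContext()] (supplies the densities).
#' @return equivalent-sphere radius in nm.
#' @export
#' @examples
#' packingRadius(35 * 26.9, 0.65)  # ~9.9 nm
packingRadius <- function(mass, waterFraction, ctx = svedbergContext()) {
  if (any(waterFraction < 0 | waterFraction >= 1))
    stop("waterFraction must lie in [0, 1)")
  mg <- mass * micellabConstants$kDa_g                      # g
  vol <- mg / ctx$rhoP + mg * waterFraction / (1 - waterFraction) / ctx$rhoW
  (3 * vol / (4 * pi))^(1 / 3) * 1e7                       # cm -> nm
}

#' Packing density of a particle
#'
#' Particle protein mass divided by the volume of the sphere of radius R_H.
#'
#' @param mass protein mass (kDa).
#' @param rh hydrodynamic radius (nm).
#' @return density in g/ml.
#' @export
#' @examples
#' packingDensity(941.5, 9.0)  # ~0.51 g/ml
packingDensity <- function(mass, rh) {
  if (any(mass <= 0) || any(rh <= 0)) stop("mass and rh must be > 0")
  mg <- mass * micellabConstants$kDa_g
  vol <- 4 / 3 * pi * (rh * 1e-7)^3                        # ml
  mg / vol
}

#' Water mass fraction from packing density
#'
#' Given a particle's packing density d, the sphere volume in excess of the
#' anhydrous protein volume is assigned to water:
#' \deqn{f = \frac{\rho_w (1/d - 1/\rho_p)}{\rho_w (1/d - 1/\rho_p) + 1}}
#' The anhydrous limit d = rho_p gives f = 0; f decreases strictly with d.
#'
#' @param density packing density (g/ml), in (0, rhoP].
#' @param ctx a [svedbergContext()].
#' @return water mass fraction in \[0, 1).
#' @export
#' @examples
#' waterMassFraction(0.512)  # ~0.55
waterMassFraction <- function(density, ctx = svedbergContext()) {
  if (any(density <= 0)) stop("density must be > 0")
  if (any(density > ctx$rhoP + 1e-9))
    stop("density exceeds the protein density: impossible packing")
  wv <- ctx$rhoW * (1 / density - 1 / ctx$rhoP)
  pmax(wv / (wv + 1), 0)
}

#' Fuse mass and sedimentation distributions by quantile alignment
#'
#' Realizes the joint analysis of the two orthogonal size distributions:
#' both the mass-weighted mass histogram and the mass-weighted (and
#' s20,w-corrected) sedimentation distribution are converted to normalized
#' cumulative form, and each sedimentation bin is paired with the mass at
#' the equal cumulative weight (monotone quantile map, piecewise-linear
#' within mass bins). At each (mass, s) pair the Svedberg inversion gives
#' R_H, from which the packing density and water mass fraction follow.
#'
#' @param massHist a mass-weighted [MassHistogram-class].
#' @param sedDist a [SedimentationDistribution-class] corrected to 20 C.
#' @param ctx [svedbergContext()] of the standard state (water at 20 C).
#' @param minWeight sedimentation bins carrying less than this fraction of
#'   the total amplitude are dropped from the output (default 1e-4); they
#'   sit in the far tails where the quantile map is ill-conditioned.
#' @return a [FusedDistribution-class].
#' @export
fuseDistributions <- function(massHist, sedDist,
                              ctx = svedbergContext(293.15),
                              minWeight = 1e-4) {
  if (weighting(massHist) != "mass")
    stop("massHist must be mass-weighted (see toMassWeighted)")
  if (!isCorrectedTo20W(sedDist))
    stop("sedDist must be corrected to s20,w first (see correctS20W)")
  counts <- binCounts(massHist)
  if (sum(counts) <= 0) stop("empty mass histogram")
  amp <- amplitudes(sedDist)
  s <- sValues(sedDist)
  if (sum(amp) <= 0) stop("empty sedimentation distribution")

  ## mass CDF: piecewise linear through the bin edges of occupied bins
  edges <- massHist@breaks
  cumMass <- c(0, cumsum(counts)) / sum(counts)
  if (any(diff(cumMass) < 0)) stop("non-monotone mass cumulative")
  ## drop flat runs (empty bins) so the inverse map is single-valued
  rising <- c(TRUE, diff(cumMass) > 0)
  cumMass <- cumMass[rising]
  edges <- edges[rising]

  ## sedimentation CDF at the s grid (trapezoidal between grid points)
  dA <- c(0, (amp[-1] + amp[-length(amp)]) / 2 * diff(s))
  cumS <- cumsum(dA) / sum(dA)
  binWeight <- dA / sum(dA)

  keep <- binWeight >= minWeight
  q <- cumS[keep]
  ## invert the mass CDF at the sedimentation quantiles
  mass <- stats::approx(cumMass, edges, xout = q, ties = "ordered",
                        rule = 2)$y
  sKeep <- s[keep]
  ok <- mass > 0 & sKeep > 0
  mass <- mass[ok]; sKeep <- sKeep[ok]; w <- binWeight[keep][ok]
  rh <- hydrodynamicRadius(mass, sKeep, ctx)
  dens <- packingDensity(mass, rh)
  wf <- waterMassFraction(pmin(dens, ctx$rhoP), ctx)
  methods::new("FusedDistribution", mass = mass, s = sKeep, rh = rh,
               density = dens, waterFraction = wf, weight = w)
}
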