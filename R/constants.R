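## Physical constants and unit conversions, centralized so that every module
## does its unit bookkeeping through the same table.

#' Physical constants used throughout micellab
#'
#' A named list of physical constants and unit conversions. All internal unit
#' conventions of the package are anchored here: concentrations in uM, masses
#' in kDa, radii in nm, sedimentation coefficients in Svedbergs (1e-13 s),
#' activation energies in kJ/mol.
#'
#' @format Named list with elements
#' \describe{
#'   \item{kDa_g}{grams per kDa (1.66054e-21)}
#'   \item{kDa_kg}{kilograms per kDa (1.66054e-24)}
#'   \item{R_J}{gas constant, J mol^-1 K^-1}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{avogadro}{Avogadro's number, 1/mol}
#'   \item{e}{elementary charge, C}
#'   \item{eps0}{vacuum permittivity, F/m}
#'   \item{svedberg_s}{seconds per Svedberg (1e-13)}
#'   \item{fwhm_factor}{FWHM/sigma conversion for a Gaussian (2.355)}
#' }
#' @export
#' @examples
#' micellabConstants$R_J
micellabConstants <- list(
  kDa_g       = 1.66054e-21,
  kDa_kg      = 1.66054e-24,
  R_J         = 8.314,
  kB          = 1.380649e-23,
  avogadro    = 6.02214076e23,
  e           = 1.602176634e-19,
  eps0        = 8.8541878128e-12,
  svedberg_s  = 1e-13,
  fwhm_factor = 2.355
)

## Water viscosity table, 4-40 C at 1 C resolution, from the standard
## log10(eta_t/eta_20) = (20-t)(1.2364 - 1.37e-3 (20-t) + 5.7e-6 (20-t)^2)/(t+96)
## correlation anchored at eta(20 C) = 1.002 mPa s. Linear interpolation
## between entries; queries outside 4-40 C are an error (the instruments
## operate within this span).
.waterViscosityTable <- local({
  tC <- 4:40
  d <- 20 - tC
  eta <- 1.002 * 10^(d * (1.2364 - 1.37e-3 * d + 5.7e-6 * d^2) / (tC + 96))
  data.frame(tempC = tC, eta_mPas = eta)
})

#' Viscosity of pure water
#'
#' Tabulated water viscosity (4-40 C span, 1 C resolution, linear
#' interpolation) used for Svedberg-equation calculations and the s20,w
#' temperature correction.
#'
#' @param temperature temperature in K.
#' @return viscosity in mPa s.
#' @export
#' @examples
#' waterViscosity(293.15)  # 1.002
waterViscosity <- function(temperature) {
  tC <- temperature - 273.15
  if (any(tC < 4 - 1e-9 | tC > 40 + 1e-9))
    stop("waterViscosity: temperature outside the tabulated 4-40 C span")
  stats::approx(.waterViscosityTable$tempC, .waterViscosityTable$eta_mPas,
                xout = tC, rule = 1)$y
}

#' Density of pure water
#'
#' Kell's polynomial for the density of air-free water at atmospheric
#' pressure, valid over the 4-40 C instrument span.
#'
#' @param temperature temperature in K.
#' @return density in g/ml.
#' @export
#' @examples
#' waterDensity(293.15)  # 0.99821
waterDensity <- function(temperature) {
  t <- temperature - 273.15
  if (any(t < 0 | t > 100))
    stop("waterDensity: temperature outside 0-100 C")
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.879850e-3 * t) / 1000
}

#' Derive a per-stage RNG seed from a global seed
#'
#' One global seed is expanded into per-stage substreams by stage name, so
#' that enabling or disabling one pipeline stage does not shift the
#' randomness of the others. Plain polynomial string hash; the result stays
#' below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed for the stage.
#' @export
#' @examples
#' stageSeed(1, "simulate")
stageSeed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000003L
  as.integer((as.numeric(seed) %% 2147483647 + 97 * h) %% 2147483647)
}
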