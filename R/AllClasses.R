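## S4 containers for the micelle self-assembly analysis. Each class carries a
## validity method enforcing the contracts the downstream operations rely on;
## user code accesses slots through the accessor generics, never with @.

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' MicellePopulation: the generative truth object
#'
#' Number concentrations \eqn{C_N} of N-mers together with the free monomer
#' pool. The defining invariant is subunit mass balance:
#' \eqn{monomer + \sum_N N C_N = total} (relative tolerance 1e-9).
#'
#' @slot nValues integer aggregation numbers with nonzero support.
#' @slot concentrations number concentration of each N-mer (uM of particles).
#' @slot monomerConc free monomer concentration (uM).
#' @slot totalConc total subunit concentration (uM monomer units).
#' @slot pH character preset label (e.g. "pH8").
#' @slot waterFraction water mass fraction used by the packing model.
#' @slot monomerMass subunit mass (kDa).
#' @export
setClass("MicellePopulation",
  representation(nValues = "integer", concentrations = "numeric",
                 monomerConc = "numeric", totalConc = "numeric",
                 pH = "character", waterFraction = "numeric",
                 monomerMass = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nValues) != length(object@concentrations))
      msg <- c(msg, "nValues and concentrations must have equal length")
    if (any(object@concentrations < 0))
      msg <- c(msg, "all C_N must be >= 0")
    if (object@waterFraction < 0 || object@waterFraction >= 1)
      msg <- c(msg, "waterFraction must lie in [0, 1)")
    total <- object@monomerConc + sum(object@nValues * object@concentrations)
    if (abs(total - object@totalConc) > 1e-9 * max(object@totalConc, 1e-300))
      msg <- c(msg, "subunit mass balance violated")
    if (length(msg)) msg else TRUE
  })

#' MPEventSet: single-particle landing events
#'
#' Measured mass per mass-photometry landing event, with the generator's
#' true aggregation numbers retained when the events are synthetic.
#'
#' @slot measuredMass measured mass per event (kDa).
#' @slot trueN integer truth (generator only) or NULL.
#' @slot seed RNG seed used to generate the events (NA for real data).
#' @slot duration acquisition time (s).
#' @slot monomerMass subunit mass (kDa).
#' @export
setClass("MPEventSet",
  representation(measuredMass = "numeric", trueN = "integerOrNULL",
                 seed = "integer", duration = "numeric",
                 monomerMass = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@measuredMass) == 0)
      msg <- c(msg, "event set must be non-empty")
    if (any(!is.finite(object@measuredMass)))
      msg <- c(msg, "measured masses must be finite")
    if (!is.null(object@trueN) &&
        length(object@trueN) != length(object@measuredMass))
      msg <- c(msg, "trueN must match measuredMass in length")
    if (length(msg)) msg else TRUE
  })

#' MassHistogram: binned particle-mass distribution
#'
#' Uniform-width mass histogram with an explicit weighting flag. With the
#' default bin width equal to the monomer mass, bin centers sit at integer
#' multiples of the monomer mass so aggregation numbers map exactly onto bins.
#'
#' @slot breaks bin edges (kDa), uniform.
#' @slot counts per-bin counts (number weighting) or count*N (mass weighting).
#' @slot weighting "number" or "mass".
#' @slot monomerMass subunit mass (kDa).
#' @slot nEvents number of events binned.
#' @export
setClass("MassHistogram",
  representation(breaks = "numeric", counts = "numeric",
                 weighting = "character", monomerMass = "numeric",
                 nEvents = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) != length(object@breaks) - 1L)
      msg <- c(msg, "counts must have length(breaks) - 1")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (!object@weighting %in% c("number", "mass"))
      msg <- c(msg, "weighting must be 'number' or 'mass'")
    w <- diff(object@breaks)
    if (length(w) && any(abs(w - w[1]) > 1e-9 * w[1]))
      msg <- c(msg, "bins must be uniform")
    if (length(msg)) msg else TRUE
  })

#' SedimentationDistribution: (s, amplitude) distribution from velocity AUC
#'
#' Mass-weighted sedimentation-coefficient distribution tagged with the
#' measurement temperature. The s20,w correction is an explicit, flagged
#' step ([correctS20W()]), never implicit.
#'
#' @slot sValues sedimentation coefficients (Svedbergs), strictly increasing.
#' @slot amplitudes nonnegative mass-weighted amplitudes.
#' @slot temperature measurement temperature (K).
#' @slot correctedTo20W logical; TRUE after standardization to water at 20 C.
#' @export
setClass("SedimentationDistribution",
  representation(sValues = "numeric", amplitudes = "numeric",
                 temperature = "numeric", correctedTo20W = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@sValues) != length(object@amplitudes))
      msg <- c(msg, "sValues and amplitudes must have equal length")
    if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
    if (is.unsorted(object@sValues, strictly = TRUE))
      msg <- c(msg, "sValues must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' FusedDistribution: joint mass / s / R_H / density / hydration profile
#'
#' Output of the quantile alignment of a mass-weighted mass histogram with a
#' mass-weighted sedimentation distribution: per sedimentation bin, the mass
#' at equal cumulative weight, the Svedberg-inverted hydrodynamic radius, the
#' packing density and the inferred water mass fraction.
#'
#' @slot mass per-bin mass (kDa).
#' @slot s per-bin sedimentation coefficient (Svedbergs).
#' @slot rh hydrodynamic radius (nm).
#' @slot density packing density (g/ml).
#' @slot waterFraction water mass fraction.
#' @slot weight mass-weighted amplitude share per bin.
#' @export
setClass("FusedDistribution",
  representation(mass = "numeric", s = "numeric", rh = "numeric",
                 density = "numeric", waterFraction = "numeric",
                 weight = "numeric"),
  validity = function(object) {
    n <- length(object@mass)
    msg <- character()
    if (any(lengths(list(object@s, object@rh, object@density,
                         object@waterFraction, object@weight)) != n))
      msg <- c(msg, "all slots must have equal length")
    if (any(object@rh <= 0)) msg <- c(msg, "R_H must be > 0")
    if (any(object@waterFraction < -1e-12 | object@waterFraction > 1))
      msg <- c(msg, "water fraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' SizeTimeSeries: a dissociation time course
#'
#' Mean hydrodynamic radius (or an oligomer-mass reporter; the unit slot
#' says which) as a function of time since dilution at one temperature.
#'
#' @slot times time since dilution (s), strictly increasing.
#' @slot values observable per time point.
#' @slot sd per-point standard deviation (may be zero).
#' @slot temperature K.
#' @slot replicate replicate identifier.
#' @slot unit unit of `values`, e.g. "nm" or "kDa".
#' @export
setClass("SizeTimeSeries",
  representation(times = "numeric", values = "numeric", sd = "numeric",
                 temperature = "numeric", replicate = "character",
                 unit = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@values))
      msg <- c(msg, "times and values must have equal length")
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' DecayFit: single-exponential dissociation fit
#'
#' Parameters of \eqn{y(t) = a e^{-kt} + c} fitted to one time course.
#'
#' @slot a amplitude (value units).
#' @slot k rate constant (1/s).
#' @slot c plateau (value units).
#' @slot covariance 3x3 parameter covariance (a, k, c).
#' @slot rmsResidual root-mean-square residual.
#' @slot degenerate TRUE for near-constant series fitted as a = 0, k = 0.
#' @slot temperature K, copied from the series.
#' @export
setClass("DecayFit",
  representation(a = "numeric", k = "numeric", c = "numeric",
                 covariance = "matrix", rmsResidual = "numeric",
                 degenerate = "logical", temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@k < 0) msg <- c(msg, "k must be >= 0")
    if (!all(dim(object@covariance) == c(3L, 3L)))
      msg <- c(msg, "covariance must be 3x3")
    if (length(msg)) msg else TRUE
  })

#' ArrheniusFit: activation energy from rate constants versus temperature
#'
#' Ordinary least squares of \eqn{\ln k} on \eqn{1/T};
#' \eqn{E_a = -slope \cdot R}.
#'
#' @slot ea activation energy (kJ/mol).
#' @slot lnA intercept, ln of the pre-exponential factor (k in 1/s).
#' @slot seEa standard error of ea (kJ/mol).
#' @slot points data.frame with columns temperature (K), k (1/s), source.
#' @export
setClass("ArrheniusFit",
  representation(ea = "numeric", lnA = "numeric", seEa = "numeric",
                 points = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@points) < 2)
      msg <- c(msg, "at least two (T, k) points required")
    if (length(unique(object@points$temperature)) < 2)
      msg <- c(msg, "at least two distinct temperatures required")
    if (length(msg)) msg else TRUE
  })

#' CalibrationCurve: contrast-to-mass calibration
#'
#' Linear calibration contrast = slope * mass + intercept from standard
#' proteins of known mass, with the lower reliable-quantification limit.
#'
#' @slot slope contrast per kDa (> 0).
#' @slot intercept contrast units.
#' @slot validMassMin lower limit of reliable mass quantification (kDa).
#' @slot residualSd residual standard deviation of the line fit.
#' @slot standards data.frame: name, nominalMass (kDa), peakContrast.
#' @export
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric",
                 validMassMin = "numeric", residualSd = "numeric",
                 standards = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@slope <= 0) msg <- c(msg, "slope must be > 0")
    if (object@validMassMin < 0) msg <- c(msg, "validMassMin must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' DnDcFit: refractive-index increment fit
#'
#' @slot dndc refractive-index increment (ml/g).
#' @slot n0 refractive index at zero concentration.
#' @slot rSquared coefficient of determination of the line fit.
#' @slot wavelength nm.
#' @export
setClass("DnDcFit",
  representation(dndc = "numeric", n0 = "numeric", rSquared = "numeric",
                 wavelength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@dndc)) msg <- c(msg, "dndc must be finite")
    if (object@n0 <= 0 || object@n0 >= 2)
      msg <- c(msg, "n0 must lie in (0, 2)")
    if (length(msg)) msg else TRUE
  })
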