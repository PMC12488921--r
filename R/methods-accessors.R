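#' Accessors for micellab containers
#'
#' Small, read-only views into the S4 containers: aggregation numbers and
#' number concentrations of a [MicellePopulation-class], measured masses of
#' an [MPEventSet-class], bin centers/counts/weighting of a
#' [MassHistogram-class], the (s, amplitude) grid of a
#' [SedimentationDistribution-class], and fitted parameters of
#' [DecayFit-class] / [ArrheniusFit-class].
#'
#' @param object a micellab S4 object.
#' @return the requested component (numeric vector, scalar, or data.frame).
#' @name accessors
NULL

#' @rdname accessors
setMethod("aggregationNumbers", "MicellePopulation",
          function(object) object@nValues)
#' @rdname accessors
setMethod("numberConcentrations", "MicellePopulation",
          function(object) object@concentrations)
#' @rdname accessors
setMethod("monomerConc", "MicellePopulation", function(object)
  object@monomerConc)
#' @rdname accessors
setMethod("totalConc", "MicellePopulation", function(object)
  object@totalConc)
#' @rdname accessors
setMethod("monomerMass", "MicellePopulation", function(object)
  object@monomerMass)
#' @rdname accessors
setMethod("monomerMass", "MPEventSet", function(object) object@monomerMass)
#' @rdname accessors
setMethod("monomerMass", "MassHistogram", function(object)
  object@monomerMass)
#' @rdname accessors
setMethod("waterFraction", "MicellePopulation", function(object)
  object@waterFraction)
#' @rdname accessors
setMethod("measuredMasses", "MPEventSet", function(object)
  object@measuredMass)
#' @rdname accessors
setMethod("trueAggregationNumbers", "MPEventSet", function(object)
  object@trueN)
#' @rdname accessors
setMethod("binCenters", "MassHistogram", function(object)
  (utils::head(object@breaks, -1) + utils::tail(object@breaks, -1)) / 2)
#' @rdname accessors
setMethod("binCounts", "MassHistogram", function(object) object@counts)
#' @rdname accessors
setMethod("weighting", "MassHistogram", function(object) object@weighting)
#' @rdname accessors
setMethod("sValues", "SedimentationDistribution", function(object)
  object@sValues)
#' @rdname accessors
setMethod("amplitudes", "SedimentationDistribution", function(object)
  object@amplitudes)
#' @rdname accessors
setMethod("measurementTemperature", "SedimentationDistribution",
          function(object) object@temperature)
#' @rdname accessors
setMethod("measurementTemperature", "SizeTimeSeries", function(object)
  object@temperature)
#' @rdname accessors
setMethod("isCorrectedTo20W", "SedimentationDistribution", function(object)
  object@correctedTo20W)
#' @rdname accessors
setMethod("decayParameters", "DecayFit", function(object)
  c(a = object@a, k = object@k, c = object@c))
#' @rdname accessors
setMethod("activationEnergy", "ArrheniusFit", function(object)
  c(Ea_kJ_mol = object@ea, se = object@seEa))

#' @rdname asDataFrame
setMethod("asDataFrame", "MassHistogram", function(object)
  data.frame(binCenter_kDa = binCenters(object), count = object@counts,
             weighting = object@weighting))
#' @rdname asDataFrame
setMethod("asDataFrame", "SedimentationDistribution", function(object)
  data.frame(s_svedberg = object@sValues, amplitude = object@amplitudes,
             temperature_K = object@temperature,
             corrected = object@correctedTo20W))
#' @rdname asDataFrame
setMethod("asDataFrame", "FusedDistribution", function(object)
  data.frame(mass_kDa = object@mass, s_svedberg = object@s,
             rh_nm = object@rh, density_g_ml = object@density,
             water_fraction = object@waterFraction, weight = object@weight))
#' @rdname asDataFrame
setMethod("asDataFrame", "SizeTimeSeries", function(object)
  data.frame(time_s = object@times, value = object@values, sd = object@sd,
             temperature_K = object@temperature,
             replicate = object@replicate, unit = object@unit))
#' @rdname asDataFrame
setMethod("asDataFrame", "MicellePopulation", function(object)
  data.frame(N = object@nValues, concentration_uM = object@concentrations))

setMethod("show", "MicellePopulation", function(object) {
  occ <- object@concentrations > 0
  cat("MicellePopulation (", object@pH, "), total ",
      format(object@totalConc, digits = 4), " uM\n",
      "  monomer: ", format(object@monomerConc, digits = 4), " uM; ",
      sum(occ), " occupied N values",
      if (sum(occ)) paste0(" [", min(object@nValues[occ]), "-",
                           max(object@nValues[occ]), "]"),
      "\n  water fraction (packing model): ", object@waterFraction, "\n",
      sep = "")
})

setMethod("show", "MPEventSet", function(object) {
  cat("MPEventSet: ", length(object@measuredMass), " landing events, ",
      "median mass ", format(stats::median(object@measuredMass), digits = 4),
      " kDa\n", sep = "")
})

setMethod("show", "MassHistogram", function(object) {
  cat("MassHistogram (", object@weighting, "-weighted): ",
      length(object@counts), " bins of ",
      format(diff(object@breaks[1:2]), digits = 4), " kDa, ",
      object@nEvents, " events\n", sep = "")
})

setMethod("show", "SedimentationDistribution", function(object) {
  cat("SedimentationDistribution: ", length(object@sValues), " points, ",
      format(min(object@sValues), digits = 3), "-",
      format(max(object@sValues), digits = 3), " S, T = ",
      object@temperature, " K",
      if (object@correctedTo20W) " (corrected to s20,w)", "\n", sep = "")
})

setMethod("show", "FusedDistribution", function(object) {
  cat("FusedDistribution: ", length(object@mass), " bins; R_H ",
      format(min(object@rh), digits = 3), "-",
      format(max(object@rh), digits = 3), " nm\n", sep = "")
})

setMethod("show", "SizeTimeSeries", function(object) {
  cat("SizeTimeSeries (", object@unit, "): ", length(object@times),
      " points over ", format(max(object@times), digits = 4), " s at ",
      object@temperature, " K, replicate ", object@replicate, "\n", sep = "")
})

setMethod("show", "DecayFit", function(object) {
  cat("DecayFit: a = ", format(object@a, digits = 4),
      ", k = ", format(object@k, digits = 4),
      " 1/s (1/k = ", format(1 / object@k, digits = 4), " s), c = ",
      format(object@c, digits = 4),
      if (object@degenerate) " [degenerate: near-constant series]",
      "\n", sep = "")
})

setMethod("show", "ArrheniusFit", function(object) {
  cat("ArrheniusFit: Ea = ", format(object@ea, digits = 4), " +/- ",
      format(object@seEa, digits = 3), " kJ/mol, lnA = ",
      format(object@lnA, digits = 4), " (", nrow(object@points),
      " points)\n", sep = "")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve: contrast = ", format(object@slope, digits = 4),
      " * mass + ", format(object@intercept, digits = 4), "; reliable above ",
      object@validMassMin, " kDa (", nrow(object@standards),
      " standards)\n", sep = "")
})

setMethod("show", "DnDcFit", function(object) {
  cat("DnDcFit: dn/dc = ", format(object@dndc, digits = 3), " ml/g at ",
      object@wavelength, " nm (R^2 = ", format(object@rSquared, digits = 4),
      ")\n", sep = "")
})
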