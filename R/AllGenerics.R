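## Accessor generics. Slot access from user code goes through these.

#' @rdname accessors
#' @param object a micellab S4 object.
#' @export
setGeneric("aggregationNumbers", function(object)
  standardGeneric("aggregationNumbers"))
#' @rdname accessors
#' @export
setGeneric("numberConcentrations", function(object)
  standardGeneric("numberConcentrations"))
#' @rdname accessors
#' @export
setGeneric("monomerConc", function(object) standardGeneric("monomerConc"))
#' @rdname accessors
#' @export
setGeneric("totalConc", function(object) standardGeneric("totalConc"))
#' @rdname accessors
#' @export
setGeneric("monomerMass", function(object) standardGeneric("monomerMass"))
#' @rdname accessors
#' @export
setGeneric("waterFraction", function(object) standardGeneric("waterFraction"))
#' @rdname accessors
#' @export
setGeneric("measuredMasses", function(object)
  standardGeneric("measuredMasses"))
#' @rdname accessors
#' @export
setGeneric("trueAggregationNumbers", function(object)
  standardGeneric("trueAggregationNumbers"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("weighting", function(object) standardGeneric("weighting"))
#' @rdname accessors
#' @export
setGeneric("sValues", function(object) standardGeneric("sValues"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("measurementTemperature", function(object)
  standardGeneric("measurementTemperature"))
#' @rdname accessors
#' @export
setGeneric("isCorrectedTo20W", function(object)
  standardGeneric("isCorrectedTo20W"))
#' @rdname accessors
#' @export
setGeneric("decayParameters", function(object)
  standardGeneric("decayParameters"))
#' @rdname accessors
#' @export
setGeneric("activationEnergy", function(object)
  standardGeneric("activationEnergy"))

#' Coerce a micellab container to a data.frame
#'
#' @name asDataFrame
#' @param object a micellab S4 object.
#' @return a base data.frame view of the object's per-bin / per-point data.
#' @export
setGeneric("asDataFrame", function(object) standardGeneric("asDataFrame"))
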