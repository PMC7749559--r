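#' Accessor generics
#'
#' Accessors for the core S4 classes: labelling protocol parameters, pool
#' trajectory state, isotopomer fractions, cohort tables and ANOVA results.
#' Each is documented with the method of the class it belongs to.
#'
#' @param x an object of the documented class
#' @return the slot value; see the class documentation for units.
#' @name accessors
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("bolusDose", function(x) standardGeneric("bolusDose"))

#' @rdname accessors
#' @export
setGeneric("waterEnrichment", function(x) standardGeneric("waterEnrichment"))

#' @rdname accessors
#' @export
setGeneric("labelDuration", function(x) standardGeneric("labelDuration"))

#' @rdname accessors
#' @export
setGeneric("bodyWaterPool", function(x) standardGeneric("bodyWaterPool"))

#' @rdname accessors
#' @export
setGeneric("waterTurnover", function(x) standardGeneric("waterTurnover"))

#' @rdname accessors
#' @export
setGeneric("kdeg", function(x) standardGeneric("kdeg"))

#' @rdname accessors
#' @export
setGeneric("ksyn", function(x) standardGeneric("ksyn"))

#' @rdname accessors
#' @export
setGeneric("poolRatio", function(x) standardGeneric("poolRatio"))

#' @rdname accessors
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))

#' @rdname accessors
#' @export
setGeneric("newProteinMass", function(x) standardGeneric("newProteinMass"))

#' @rdname accessors
#' @export
setGeneric("equilibriumPool", function(x) standardGeneric("equilibriumPool"))

#' @rdname accessors
#' @export
setGeneric("isotopomerFractions",
           function(x) standardGeneric("isotopomerFractions"))

#' @rdname accessors
#' @export
setGeneric("animals", function(x) standardGeneric("animals"))

#' @rdname accessors
#' @export
setGeneric("isotopomers", function(x) standardGeneric("isotopomers"))

#' @rdname accessors
#' @export
setGeneric("fiberAreas", function(x) standardGeneric("fiberAreas"))

#' @rdname accessors
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @rdname accessors
#' @export
setGeneric("cellMeans", function(x) standardGeneric("cellMeans"))

#' @rdname accessors
#' @export
setGeneric("residualDf", function(x) standardGeneric("residualDf"))

#' @rdname accessors
#' @export
setGeneric("meanSquaredError", function(x) standardGeneric("meanSquaredError"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
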