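#' Accessors for package classes
#'
#' `counts()` returns the integer sample-by-taxon matrix; `sampleIDs()` and
#' `taxonIDs()` its row and column labels; `nSamples()` and `nTaxa()` its
#' dimensions; `dissValues()` the square matrix inside a
#' [DissimilarityMatrix-class]; `ordCoords()` and `ordStress()` the
#' configuration and Kruskal stress of an [Ordination-class].
#'
#' @param object a package object.
#' @return the slot contents described above.
#' @name accessors
#' @aliases counts sampleIDs taxonIDs nSamples nTaxa dissValues ordCoords
#'   ordStress
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("taxonIDs", function(object) standardGeneric("taxonIDs"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nTaxa", function(object) standardGeneric("nTaxa"))

#' @rdname accessors
#' @export
setGeneric("dissValues", function(object) standardGeneric("dissValues"))

#' @rdname accessors
#' @export
setGeneric("ordCoords", function(object) standardGeneric("ordCoords"))

#' @rdname accessors
#' @export
setGeneric("ordStress", function(object) standardGeneric("ordStress"))
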