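#' @name NetSuscept-accessors
#' @title Accessors for NetSuscept classes
#' @description Slot accessors: \code{regionNames()}, \code{nCortical()},
#'   \code{nSubcortical()}, \code{centroids()}, \code{hemispheres()},
#'   \code{structureClass()} for \linkS4class{Parcellation};
#'   \code{mapValues()}, \code{mapScope()}, \code{mapKind()} for
#'   \linkS4class{RegionalMap}; \code{connWeights()}, \code{connModality()},
#'   \code{corticoCortical()}, \code{subcorticoCortical()} for
#'   \linkS4class{ConnectivityMatrix}; \code{cohortMeasure()} for
#'   \linkS4class{MorphoCohort}; \code{parcellationOf()} and
#'   \code{resultTable()} wherever they apply.
#' @param x an object of the matching class
#' @return the slot contents (see each class page)
NULL

#' @rdname NetSuscept-accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("nCortical", function(x) standardGeneric("nCortical"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("nSubcortical", function(x) standardGeneric("nSubcortical"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("structureClass", function(x) standardGeneric("structureClass"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("mapScope", function(x) standardGeneric("mapScope"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("connWeights", function(x) standardGeneric("connWeights"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("connModality", function(x) standardGeneric("connModality"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("corticoCortical", function(x) standardGeneric("corticoCortical"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("subcorticoCortical", function(x) standardGeneric("subcorticoCortical"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("cohortMeasure", function(x) standardGeneric("cohortMeasure"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("parcellationOf", function(x) standardGeneric("parcellationOf"))
#' @rdname NetSuscept-accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
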