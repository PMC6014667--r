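# Accessor generics for the package's S4 containers.

#' @rdname BarcodeSet-accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname BarcodeSet-accessors
#' @export
setGeneric("declaredTaxon", function(x) standardGeneric("declaredTaxon"))

#' @rdname BarcodeSet-accessors
#' @export
setGeneric("taxonGroup", function(x) standardGeneric("taxonGroup"))

#' @rdname BarcodeSet-accessors
#' @export
setGeneric("geneLabels", function(x) standardGeneric("geneLabels"))

#' @rdname BarcodeSet-accessors
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' @rdname BarcodeSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname PDistanceMatrix-accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' @rdname PDistanceMatrix-accessors
#' @export
setGeneric("comparableSites", function(x) standardGeneric("comparableSites"))
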