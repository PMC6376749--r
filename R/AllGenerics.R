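#' Accessors for asePGA classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("countsTable", function(x) standardGeneric("countsTable"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))
#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname accessors
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))
#' @rdname accessors
#' @export
setGeneric("genotypeSegments", function(x) standardGeneric("genotypeSegments"))
#' @rdname accessors
#' @export
setGeneric("genotypeBreakpoints",
           function(x) standardGeneric("genotypeBreakpoints"))
#' @rdname accessors
#' @export
setGeneric("imbalanceTable", function(x) standardGeneric("imbalanceTable"))
#' @rdname accessors
#' @export
setGeneric("truthSegments", function(x) standardGeneric("truthSegments"))
#' @rdname accessors
#' @export
setGeneric("truthCrossovers", function(x) standardGeneric("truthCrossovers"))
#' @rdname accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))

#' @rdname accessors
#' @export
setMethod("sampleId", "AllelicCounts", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "GenotypeMap", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("countsTable", "AllelicCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("chromLengths", "AllelicCounts", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("chromLengths", "SimTruth", function(x) x@chromLengths)
#' @rdname accessors
#' @export
setMethod("geneTable", "GeneModels", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("exonTable", "GeneModels", function(x) x@exons)
#' @rdname accessors
#' @export
setMethod("siteTable", "GeneModels", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("binTable", "GenotypeMap", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("genotypeSegments", "GenotypeMap", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("genotypeBreakpoints", "GenotypeMap", function(x) x@breakpoints)
#' @rdname accessors
#' @export
setMethod("imbalanceTable", "GenotypeMap", function(x) x@imbalance)
#' @rdname accessors
#' @export
setMethod("truthSegments", "SimTruth", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("truthCrossovers", "SimTruth", function(x) x@crossovers)
#' @rdname accessors
#' @export
setMethod("truthGenes", "SimTruth", function(x) x@genes)
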