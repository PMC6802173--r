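#' @rdname accessors
#' @export
setGeneric("seRegions", function(x) standardGeneric("seRegions"))

#' @rdname accessors
#' @export
setGeneric("superEnhancers", function(x) standardGeneric("superEnhancers"))

#' @rdname accessors
#' @export
setGeneric("typicalEnhancers", function(x) standardGeneric("typicalEnhancers"))

#' @rdname accessors
#' @export
setGeneric("cutoffSignal", function(x) standardGeneric("cutoffSignal"))

#' @rdname accessors
#' @export
setGeneric("cutoffIndex", function(x) standardGeneric("cutoffIndex"))

#' @rdname accessors
#' @export
setGeneric("networkTFs", function(x) standardGeneric("networkTFs"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("tfGeneMap", function(x) standardGeneric("tfGeneMap"))

#' @rdname findCircuitry
#' @export
setGeneric("findCircuitry", function(network) standardGeneric("findCircuitry"))

#' @rdname coregulatedGeneSet
#' @export
setGeneric("coregulatedGeneSet", function(x, threshold, ...)
  standardGeneric("coregulatedGeneSet"))

#' @rdname exportEdgeList
#' @export
setGeneric("exportEdgeList", function(network, path)
  standardGeneric("exportEdgeList"))

#' Accessors for pipeline result objects
#'
#' `seRegions()` returns all stitched regions of an [SECallResult-class]
#' (ascending total signal); `superEnhancers()` and `typicalEnhancers()`
#' return the partition above/below the elbow; `cutoffSignal()` and
#' `cutoffIndex()` return the elbow itself. `networkTFs()`,
#' `networkEdges()` and `tfGeneMap()` access a
#' [RegulatoryNetwork-class].
#'
#' @param x An `SECallResult` or `RegulatoryNetwork`.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("seRegions", "SECallResult", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("superEnhancers", "SECallResult", function(x)
  x@regions[x@regions$isSE])

#' @rdname accessors
#' @export
setMethod("typicalEnhancers", "SECallResult", function(x)
  x@regions[!x@regions$isSE])

#' @rdname accessors
#' @export
setMethod("cutoffSignal", "SECallResult", function(x) x@cutoffSignal)

#' @rdname accessors
#' @export
setMethod("cutoffIndex", "SECallResult", function(x) x@cutoffIndex)

#' @rdname accessors
#' @export
setMethod("networkTFs", "RegulatoryNetwork", function(x) x@tfs)

#' @rdname accessors
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("tfGeneMap", "RegulatoryNetwork", function(x) x@tfGeneMap)
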