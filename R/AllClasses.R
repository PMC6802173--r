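#' SECallResult: ranked stitched regions with an elbow cutoff
#'
#' Holds all stitched regions sorted by ascending total signal, the elbow
#' cutoff that separates super-enhancers (SEs) from typical enhancers, and
#' the derived SE flag per region. Construct with [rankAndCutoff()] or
#' [callSuperEnhancers()].
#'
#' @slot regions `GRanges` sorted by ascending `totalSignal`, with metadata
#'   columns `totalSignal`, `nPeaks`, `rank`, `isSE` and the scaled rank
#'   curve coordinates `x`, `y`.
#' @slot cutoffSignal Signal value at the elbow; regions strictly above it
#'   are super-enhancers.
#' @slot cutoffIndex 1-based rank position of the elbow.
#' @aliases SECallResult
#' @export
setClass("SECallResult",
         representation(regions = "GRanges",
                        cutoffSignal = "numeric",
                        cutoffIndex = "integer"))

setValidity("SECallResult", function(object) {
  r <- object@regions
  msg <- character()
  if (is.null(r$totalSignal) || is.null(r$isSE))
    msg <- c(msg, "regions need 'totalSignal' and 'isSE' metadata columns")
  else {
    if (is.unsorted(r$totalSignal))
      msg <- c(msg, "regions must be sorted by ascending totalSignal")
    if (length(r) && min(r$totalSignal[r$isSE], Inf) <=
          max(r$totalSignal[!r$isSE], -Inf))
      msg <- c(msg, "every SE must outrank every typical enhancer")
  }
  if (length(msg)) msg else TRUE
})

#' OccupancyMatrix: binary union-site-by-factor binding indicator
#'
#' A `RangedSummarizedExperiment` whose rows are union binding sites (merged
#' single-linkage clusters of peak centers within the overlap window), whose
#' columns are factors, and whose single assay `"occupancy"` holds 0/1
#' indicators. Row ranges carry the site `anchor` (the lower-median member
#' center, 0-based) and `nMembers`. Construct with [buildUnionSites()].
#'
#' @aliases OccupancyMatrix
#' @export
setClass("OccupancyMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("OccupancyMatrix", function(object) {
  a <- SummarizedExperiment::assay(object, "occupancy")
  msg <- character()
  if (!all(a %in% c(0L, 1L))) msg <- c(msg, "occupancy values must be 0/1")
  if (nrow(a) && any(rowSums(a) < 1L))
    msg <- c(msg, "every union site must have at least one bound factor")
  if (length(msg)) msg else TRUE
})

#' RegulatoryNetwork: directed TF-to-target-gene edges with peak evidence
#'
#' Edge semantics follow binding-implies-regulation: an edge (TF, gene)
#' exists iff at least one of the TF's peaks was assigned to the gene.
#' `tfGeneMap` links each factor name to its own gene symbol so that
#' self-edges (autoregulation) and TF--TF motifs can be detected without
#' relying on name equality between factor and gene labels.
#'
#' @slot tfs Ordered character vector of factor names.
#' @slot edges `DataFrame` with columns `tf`, `target` and `evidence`
#'   (an `IntegerList` of supporting peak indices within each factor's
#'   peak set; always non-empty).
#' @slot tfGeneMap Named character vector, factor name -> gene symbol.
#' @aliases RegulatoryNetwork
#' @export
setClass("RegulatoryNetwork",
         representation(tfs = "character",
                        edges = "DataFrame",
                        tfGeneMap = "character"))

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("tf", "target", "evidence")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, "edges need columns tf, target, evidence")
  else {
    if (nrow(e) && any(lengths(e$evidence) < 1L))
      msg <- c(msg, "every edge needs non-empty evidence")
    if (anyDuplicated(paste(e$tf, e$target, sep = "\r")))
      msg <- c(msg, "edge set must be deduplicated")
    if (!all(e$tf %in% object@tfs))
      msg <- c(msg, "edge sources must be listed in tfs")
  }
  if (!all(object@tfs %in% names(object@tfGeneMap)))
    msg <- c(msg, "tfGeneMap must cover all tfs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SECallResult", function(object) {
  r <- object@regions
  cat("SECallResult with", length(r), "stitched regions\n")
  cat(sprintf("  superenhancers: %d (total signal > %.4g, elbow at rank %d)\n",
              sum(r$isSE), object@cutoffSignal, object@cutoffIndex))
  cat(sprintf("  typical enhancers: %d\n", sum(!r$isSE)))
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork with", length(object@tfs), "TFs,",
      nrow(object@edges), "edges,",
      length(unique(object@edges$target)), "target genes\n")
})
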