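#' Construct a regulatory network from peak sets
#'
#' For every factor, each peak is assigned to its target gene(s) via
#' [assignTargetGenes()]; the edge (TF, gene) exists iff at least one peak
#' was assigned, carrying the supporting peak indices as evidence.
#' Binding is taken to imply regulatory control, so the edge set is the
#' binding-derived transcriptional regulatory network.
#'
#' @param peaksets Named list (factor -> peak `GRanges`), every factor with
#'   at least one peak.
#' @param genes Gene-model `GRanges`.
#' @param tfGeneMap Named character vector mapping every factor name to its
#'   own gene symbol (used for self-edge / motif detection).
#' @param config A [pipelineConfig()].
#' @return A [RegulatoryNetwork-class].
#' @export
buildTRN <- function(peaksets, genes, tfGeneMap,
                     config = pipelineConfig()) {
  stopifnot(is.list(peaksets), !is.null(names(peaksets)))
  missing <- setdiff(names(peaksets), names(tfGeneMap))
  if (length(missing))
    stop("buildTRN: factor(s) missing from tfGeneMap: ",
         paste(missing, collapse = ", "))
  if (any(lengths(peaksets) == 0L))
    stop("buildTRN: every factor needs at least one peak")
  tfs <- names(peaksets)
  tfCol <- character(); tgCol <- character(); evid <- list()
  for (tf in tfs) {
    targets <- assignTargetGenes(peaksets[[tf]], genes, config)
    pk <- rep(seq_along(targets), lengths(targets))
    gene <- unlist(targets, use.names = FALSE)
    sp <- split(pk, gene)
    tfCol <- c(tfCol, rep(tf, length(sp)))
    tgCol <- c(tgCol, names(sp))
    evid <- c(evid, unname(sp))
  }
  o <- radixOrder(tfCol, tgCol)
  edges <- DataFrame(tf = tfCol[o], target = tgCol[o],
                     evidence = IRanges::IntegerList(evid[o]))
  new("RegulatoryNetwork", tfs = tfs, edges = edges,
      tfGeneMap = tfGeneMap[tfs])
}

#' Construct a regulatory network from an explicit edge list
#'
#' For networks defined directly (or re-imported with [readEdgeList()])
#' rather than derived from peaks. Each edge receives a single placeholder
#' evidence id when none is supplied.
#'
#' @param tf,target Equal-length character vectors of edges.
#' @param tfGeneMap Named character vector, factor -> gene symbol.
#'   Defaults to the identity map over the TFs mentioned.
#' @param nEvidence Optional integer vector of supporting peak counts.
#' @return A [RegulatoryNetwork-class].
#' @export
regulatoryNetwork <- function(tf, target, tfGeneMap = NULL,
                              nEvidence = NULL) {
  stopifnot(length(tf) == length(target))
  tfs <- sort(unique(tf), method = "radix")
  if (is.null(tfGeneMap)) tfGeneMap <- setNames(tfs, tfs)
  if (is.null(nEvidence)) nEvidence <- rep(1L, length(tf))
  key <- paste(tf, target, sep = "\r")
  keep <- !duplicated(key)
  o <- radixOrder(tf[keep], target[keep])
  ev <- lapply(nEvidence[keep][o], seq_len)
  new("RegulatoryNetwork", tfs = tfs,
      edges = DataFrame(tf = tf[keep][o], target = target[keep][o],
                        evidence = IRanges::IntegerList(ev)),
      tfGeneMap = tfGeneMap)
}

#' Enumerate regulatory circuitry motifs
#'
#' Restricts the network to its TF nodes (an edge TF A -> TF B exists iff
#' A targets B's gene, via the network's `tfGeneMap`) and enumerates:
#' autoregulators (A -> A), feedback pairs (unordered \{A, B\} with A -> B
#' and B -> A, A != B) and feed-forward loops (ordered triples (A, B, C) of
#' distinct TFs with A -> B, B -> C and A -> C -- the standard FFL
#' definition). Self-loops do not contribute to pair or triad motifs.
#'
#' @param network A [RegulatoryNetwork-class].
#' @return List of class `CircuitrySummary`: `autoregulators` (character),
#'   `feedbackPairs` (2-column character matrix, rows sorted),
#'   `feedforwardTriads` (3-column character matrix).
#' @export
setMethod("findCircuitry", "RegulatoryNetwork", function(network) {
  tfs <- network@tfs
  k <- length(tfs)
  gene <- network@tfGeneMap[tfs]
  e <- network@edges
  key <- paste(e$tf, e$target, sep = "\r")
  A <- matrix(FALSE, k, k, dimnames = list(tfs, tfs))
  for (i in seq_len(k)) for (j in seq_len(k))
    A[i, j] <- paste(tfs[i], gene[j], sep = "\r") %in% key
  auto <- tfs[diag(A)]
  Ao <- A; diag(Ao) <- FALSE
  fb <- which(Ao & t(Ao) & upper.tri(A), arr.ind = TRUE)
  feedback <- cbind(tfs[fb[, 1L]], tfs[fb[, 2L]])
  ff <- list()
  for (a in seq_len(k)) for (b in seq_len(k)) for (cc in seq_len(k)) {
    if (a == b || b == cc || a == cc) next
    if (Ao[a, b] && Ao[b, cc] && Ao[a, cc])
      ff[[length(ff) + 1L]] <- c(tfs[a], tfs[b], tfs[cc])
  }
  feedforward <- if (length(ff)) do.call(rbind, ff)
                 else matrix(character(), 0L, 3L)
  colnames(feedback) <- c("tf1", "tf2")
  colnames(feedforward) <- c("a", "b", "c")
  structure(list(autoregulators = auto, feedbackPairs = feedback,
                 feedforwardTriads = feedforward),
            class = "CircuitrySummary")
})

#' @export
print.CircuitrySummary <- function(x, ...) {
  cat("CircuitrySummary:",
      length(x$autoregulators), "autoregulators,",
      nrow(x$feedbackPairs), "feedback pairs,",
      nrow(x$feedforwardTriads), "feed-forward triads\n")
  invisible(x)
}

#' Genes co-occupied by more than a threshold number of factors
#'
#' Returns the genes targeted (per the network's binding-derived edge
#' semantics) by strictly more than `threshold` distinct factors. With 27
#' profiled factors and the default threshold of 22 this reproduces the
#' published ">22 TFs" co-regulated gene-set construction.
#'
#' @param x A [RegulatoryNetwork-class].
#' @param threshold Strict lower bound on the number of distinct factors;
#'   must not exceed the number of factors in the network.
#' @param ... Unused.
#' @return Character vector of gene symbols (lexicographic order).
#' @export
setMethod("coregulatedGeneSet", "RegulatoryNetwork",
          function(x, threshold, ...) {
  if (threshold > length(x@tfs))
    stop("coregulatedGeneSet: threshold (", threshold,
         ") exceeds the number of factors (", length(x@tfs), ")")
  tab <- table(x@edges$target)
  sort(names(tab)[tab > threshold], method = "radix")
})

#' Export the network as an edge-list TSV
#'
#' Writes columns (source TF, target gene, supporting peak count) in
#' deterministic order (source, then target, lexicographic; byte order),
#' loadable by standard network viewers.
#'
#' @param network A [RegulatoryNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
setMethod("exportEdgeList", "RegulatoryNetwork", function(network, path) {
  e <- network@edges
  o <- radixOrder(e$tf, e$target)
  writeTsv(data.frame(source = e$tf[o], target = e$target[o],
                      n_peaks = lengths(e$evidence)[o]),
           path)
})

#' Read an edge-list TSV back into a network
#'
#' Inverse of [exportEdgeList()] up to evidence peak identities (only the
#' supporting counts survive the round trip); circuitry enumeration on the
#' re-imported network is identical.
#'
#' @param path Path written by [exportEdgeList()].
#' @param tfGeneMap Optional factor -> gene map; defaults to identity.
#' @return A [RegulatoryNetwork-class].
#' @export
readEdgeList <- function(path, tfGeneMap = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  regulatoryNetwork(df$source, df$target, tfGeneMap, df$n_peaks)
}
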