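#' Do two peaks occupy the same binding site?
#'
#' Two peaks from different tracks are the same binding site iff they lie
#' on the same chromosome and their center distance is strictly less than
#' the overlap window (500 bp by default).
#'
#' @param a,b Single-peak `GRanges` (or equal-length vectors, compared
#'   elementwise).
#' @param overlapWindow Center-distance window in bp.
#' @return Logical.
#' @export
centersOverlap <- function(a, b, overlapWindow = 500) {
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    abs(peakCenters(a) - peakCenters(b)) < overlapWindow
}

#' Build the union binding-site occupancy matrix
#'
#' Pools the peaks of all factors and single-linkage-clusters their centers
#' under the [centersOverlap()] relation (chained overlaps merge
#' transitively, mirroring a moving window across the genome). Each cluster
#' becomes one union site; the binary matrix records which factors
#' contributed at least one peak. Factors are ordered lexicographically and
#' sites by genome position, so the result is invariant to the order of
#' peak sets and of peaks within sets.
#'
#' @param peaksets Named list (factor name -> peak `GRanges`) of at least
#'   two peak sets, or a single combined `GRanges` with a `factor` column
#'   carrying at least two factors.
#' @param overlapWindow Center-distance window in bp.
#' @return An [OccupancyMatrix-class]. Row ranges span
#'   `[min member start, max member end)` with the lower-median member
#'   center as `anchor`.
#' @export
buildUnionSites <- function(peaksets, overlapWindow = 500) {
  all <- poolPeaksets(peaksets)
  factors <- sort(unique(all$factor), method = "radix")
  if (length(factors) < 2L)
    stop("buildUnionSites: need at least 2 peak sets")
  centers <- peakCenters(all)
  chrom <- as.character(seqnames(all))
  o <- radixOrder(chrom, centers)
  cluster <- integer(length(all))
  ## single linkage in 1-D: break whenever the sorted center gap >= window
  newClust <- c(TRUE, chrom[o][-1L] != chrom[o][-length(o)] |
                  diff(centers[o]) >= overlapWindow)
  cluster[o] <- cumsum(newClust)
  nSite <- max(cluster)
  lowerMedian <- function(v) sort(v)[(length(v) + 1L) %/% 2L]
  siteChrom <- character(nSite); siteS <- integer(nSite)
  siteE <- integer(nSite); anchor <- integer(nSite)
  sIdx <- split(seq_along(all), cluster)
  for (k in seq_len(nSite)) {
    m <- sIdx[[k]]
    siteChrom[k] <- chrom[m[1L]]
    siteS[k] <- min(bedStart(all)[m])
    siteE[k] <- max(bedEnd(all)[m])
    anchor[k] <- lowerMedian(centers[m])
  }
  mat <- matrix(0L, nSite, length(factors),
                dimnames = list(NULL, factors))
  fi <- match(all$factor, factors)
  mat[cbind(cluster, fi)] <- 1L
  sites <- grFromBed(siteChrom, siteS, siteE)
  sites$anchor <- anchor
  sites$nMembers <- lengths(sIdx)
  o2 <- radixOrder(siteChrom, siteS, siteE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(occupancy = mat[o2, , drop = FALSE]),
    rowRanges = sites[o2])
  new("OccupancyMatrix", se)
}

poolPeaksets <- function(peaksets) {
  if (is(peaksets, "GRanges")) {
    if (is.null(peaksets$factor))
      stop("combined peak GRanges needs a 'factor' column")
    return(peaksets)
  }
  stopifnot(is.list(peaksets))
  ps <- peaksets
  if (!is.null(names(ps)))
    for (nm in names(ps))
      if (length(ps[[nm]])) ps[[nm]]$factor <- nm
  ## peak sets may live on disjoint chromosome sets; the seqinfo merge
  ## warning for that case is expected and uninformative here
  suppressWarnings(do.call(c, unname(ps)))
}

#' Pairwise factor correlation with clustering order
#'
#' Pearson correlation between the binary occupancy columns of each factor
#' pair over all union sites. A factor bound at every site (or none --
#' a constant column) has undefined correlation: its entries are reported
#' as `NA` and it is excluded from the clustering. Average-linkage
#' hierarchical clustering on distance `1 - r` supplies the display order.
#'
#' @param x An [OccupancyMatrix-class] with at least 2 sites, or a list of
#'   peak sets (then union sites are built first; see `universe`).
#' @param overlapWindow Used only when `x` is a list of peak sets.
#' @param universe `"global"` (one union-site universe across all factors,
#'   the default) or `"pairwise"` (each pair correlated over the union of
#'   just its two peak sets).
#' @return List with `r` (factor x factor matrix, unit diagonal),
#'   `order` (factor names in dendrogram order) and `hclust` (or `NULL`
#'   when fewer than 3 non-constant factors).
#' @export
pairwiseCorrelation <- function(x, overlapWindow = 500,
                                universe = c("global", "pairwise")) {
  universe <- match.arg(universe)
  if (universe == "pairwise") {
    stopifnot(is.list(x))
    nm <- names(x)
    r <- diag(1, length(nm)); dimnames(r) <- list(nm, nm)
    for (i in seq_along(nm)[-1L]) for (j in seq_len(i - 1L)) {
      om <- buildUnionSites(x[c(i, j)], overlapWindow)
      m <- SummarizedExperiment::assay(om, "occupancy")
      r[i, j] <- r[j, i] <- suppressWarnings(cor(m[, 1L], m[, 2L]))
    }
    return(orderCorrelation(r))
  }
  if (is.list(x)) x <- buildUnionSites(x, overlapWindow)
  m <- SummarizedExperiment::assay(x, "occupancy")
  if (nrow(m) < 2L)
    stop("pairwiseCorrelation: insufficient data (need >= 2 union sites)")
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  orderCorrelation(r)
}

orderCorrelation <- function(r) {
  ## constant occupancy columns have NA correlation with every other factor;
  ## they are excluded from the clustering and appended at the end
  usable <- colnames(r)[vapply(seq_len(ncol(r)), function(j)
    sum(!is.na(r[, j])) > 1L, logical(1L))]
  hc <- NULL
  ord <- colnames(r)
  if (length(usable) >= 3L) {
    hc <- hclust(stats::as.dist(1 - r[usable, usable]), method = "average")
    ord <- c(usable[hc$order], setdiff(colnames(r), usable))
  }
  list(r = r, order = ord, hclust = hc)
}

#' Count distinct bound factors per region
#'
#' For each region, the number of distinct factors with at least one peak
#' center inside it. With the published thresholds this yields the
#' "co-occupied by more than 8 TFs" summary over super-enhancers.
#'
#' @param regions `GRanges` of regions (e.g. [superEnhancers()]).
#' @param peaksets Named list of peak `GRanges`, or combined `GRanges` with
#'   a `factor` column.
#' @return Integer vector along `regions`.
#' @export
countFactorsPerRegion <- function(regions, peaksets) {
  all <- poolPeaksets(peaksets)
  if (!length(regions)) return(integer())
  if (!length(all)) return(integer(length(regions)))
  pts <- pointGR(seqnames(all), peakCenters(all))
  hits <- findOverlaps(pts, regions, ignore.strand = TRUE)
  n <- integer(length(regions))
  if (length(hits)) {
    pair <- unique(data.frame(r = subjectHits(hits),
                              f = all$factor[queryHits(hits)]))
    tab <- table(factor(pair$r, levels = seq_along(regions)))
    n[] <- as.integer(tab)
  }
  n
}

#' Write an occupancy matrix and its correlation table
#'
#' @param om An [OccupancyMatrix-class].
#' @param matrixPath,correlationPath,orderPath Output paths; any may be
#'   `NULL` to skip.
#' @return Invisibly, the [pairwiseCorrelation()] result.
#' @export
writeOccupancy <- function(om, matrixPath = NULL, correlationPath = NULL,
                           orderPath = NULL) {
  sites <- SummarizedExperiment::rowRanges(om)
  m <- SummarizedExperiment::assay(om, "occupancy")
  if (!is.null(matrixPath))
    writeTsv(data.frame(chrom = as.character(seqnames(sites)),
                        start = bedStart(sites), end = bedEnd(sites),
                        anchor = sites$anchor, m, check.names = FALSE),
             matrixPath)
  pc <- pairwiseCorrelation(om)
  if (!is.null(correlationPath))
    writeTsv(data.frame(factor = rownames(pc$r), pc$r, check.names = FALSE),
             correlationPath)
  if (!is.null(orderPath)) writeLines(pc$order, orderPath)
  invisible(pc)
}
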