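#' Remove peaks inside TSS exclusion zones
#'
#' Drops every peak whose interval is *fully contained* within
#' `[tss - tssExclusion, tss + tssExclusion)` of any transcription start
#' site; peaks that only partially overlap a zone are retained. Applied to
#' constituent peaks before stitching (ROSE `-t` semantics) so that promoter
#' signal does not inflate stitched enhancer regions.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges` (transcript level; every TSS counts).
#' @param tssExclusion Zone half-width in bp; `0` disables the filter.
#' @return Filtered peak `GRanges`, order preserved.
#' @export
excludeTssPeaks <- function(peaks, genes, tssExclusion = 2500) {
  stopifnot(tssExclusion >= 0)
  if (tssExclusion == 0 || !length(peaks) || !length(genes)) return(peaks)
  checkChromVocabulary(peaks, genes, c("peaks", "genes"))
  ## 0-based zone [tss - E, tss + E) -> 1-based [tss - E + 1, tss + E]
  zones <- GRanges(seqnames(genes),
                   IRanges(pmax(genes$tss - tssExclusion + 1, 1),
                           genes$tss + tssExclusion))
  drop <- overlapsAny(peaks, zones, type = "within")
  if (any(drop))
    message(sum(drop), " peak(s) removed in TSS exclusion zones")
  peaks[!drop]
}

#' Stitch nearby peaks into candidate enhancer regions
#'
#' Single-linkage merge per chromosome: two peaks belong to the same
#' stitched region iff the gap between their intervals (end of the earlier
#' to start of the later) is at most `stitchDistance`. Output regions are
#' disjoint, pairwise separated by more than `stitchDistance`, sorted by
#' position, and independent of input order. Each region records the sum of
#' its constituent peak signals.
#'
#' @param peaks Non-empty peak `GRanges` with a `signal` column.
#' @param stitchDistance Maximum gap in bp (default 12,500).
#' @return `GRanges` of stitched regions with metadata columns
#'   `totalSignal` and `nPeaks`.
#' @export
stitchPeaks <- function(peaks, stitchDistance = 12500) {
  if (!length(peaks)) stop("stitchPeaks: empty peak set")
  if (is.null(peaks$signal)) stop("stitchPeaks: peaks need a 'signal' column")
  regions <- reduce(granges(peaks), min.gapwidth = stitchDistance + 1)
  hits <- findOverlaps(peaks, regions)
  stopifnot(length(hits) == length(peaks))   # every peak lands in one region
  idx <- subjectHits(hits)
  regions$totalSignal <- as.numeric(
    rowsum(peaks$signal[queryHits(hits)], idx)[, 1L])
  regions$nPeaks <- as.integer(tabulate(idx, length(regions)))
  ## deterministic genome order regardless of input chromosome order
  regions <- GenomeInfoDb::sortSeqlevels(regions)
  sort(regions, ignore.strand = TRUE)
}

#' Rank stitched regions and place the elbow cutoff
#'
#' Regions are sorted by ascending total signal; rank and signal are both
#' rescaled to the unit interval (x and y) and the cutoff index is the
#' point maximizing `x - y` -- the slope-1 tangent point of the convex
#' ranked-signal curve, i.e. the ROSE elbow criterion. Regions with total
#' signal strictly above the cutoff signal are super-enhancers (a region
#' tied with the cutoff is typical).
#'
#' @param regions `GRanges` from [stitchPeaks()] (at least 3 regions with
#'   non-constant signal).
#' @return An [SECallResult-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges((1:10) * 1e5,
#'                                                       width = 1000))
#' gr$totalSignal <- c(rep(1, 8), 40, 60); gr$nPeaks <- 1L
#' rankAndCutoff(gr)   # calls the top 2 regions super-enhancers
#' @export
rankAndCutoff <- function(regions) {
  n <- length(regions)
  if (n < 3L) stop("rankAndCutoff: insufficient data (need >= 3 regions)")
  s <- regions$totalSignal
  if (diff(range(s)) == 0)
    stop("rankAndCutoff: degenerate rank curve (all signals equal, no elbow)")
  o <- radixOrder(s)          # stable: position order within ties
  r <- regions[o]
  ss <- s[o]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (ss - ss[1L]) / (ss[n] - ss[1L])
  idx <- which.max(x - y)
  cut <- ss[idx]
  r$rank <- seq_len(n)
  r$isSE <- r$totalSignal > cut
  r$x <- x
  r$y <- y
  new("SECallResult", regions = r, cutoffSignal = cut,
      cutoffIndex = as.integer(idx))
}

#' Call super-enhancers from a signal-scored peak set
#'
#' Convenience wrapper running the full SE-calling chain: TSS exclusion of
#' constituent peaks, stitching, and the ranked-signal elbow cutoff.
#'
#' @param peaks Peak `GRanges` with `signal`.
#' @param genes Gene-model `GRanges` (for TSS exclusion).
#' @param config A [pipelineConfig()].
#' @return An [SECallResult-class].
#' @export
callSuperEnhancers <- function(peaks, genes, config = pipelineConfig()) {
  kept <- excludeTssPeaks(peaks, genes, config$tssExclusion)
  rankAndCutoff(stitchPeaks(kept, config$stitchDistance))
}

#' Associate super-enhancers with genes
#'
#' An SE is associated with every gene whose extended span (gene body
#' extended by `networkWindow` on both sides) intersects it; an SE matching
#' no extended span falls back to the single gene with the smallest distance
#' between the SE midpoint and a TSS (ties: lexicographically smaller
#' symbol). SEs on chromosomes without any gene are logged and excluded.
#'
#' @param result An [SECallResult-class], or a `GRanges` of regions.
#' @param genes Gene-model `GRanges`; collapsed to one transcript per
#'   symbol via [canonicalTranscripts()].
#' @param networkWindow Extension in bp (default 20,000).
#' @return `data.frame` with columns `se` (region name), `chrom`, `start`,
#'   `end` (0-based half-open), `gene`, `mode` ("overlap" or "nearest").
#'   The unique values of `gene` are the SE-associated genes.
#' @export
associateSeGenes <- function(result, genes, networkWindow = 20000) {
  se <- if (is(result, "SECallResult")) superEnhancers(result) else result
  g <- canonicalTranscripts(genes)
  if (!length(se))
    return(data.frame(se = character(), chrom = character(),
                      start = integer(), end = integer(),
                      gene = character(), mode = character()))
  if (!length(g)) stop("associateSeGenes: no gene models supplied")
  checkChromVocabulary(se, g, c("super-enhancers", "genes"))
  ext <- GRanges(seqnames(g),
                 IRanges(pmax(GenomicRanges::start(g) - networkWindow, 1),
                         GenomicRanges::end(g) + networkWindow))
  hits <- findOverlaps(se, ext, ignore.strand = TRUE)
  seName <- if (!is.null(se$name)) se$name else sprintf("SE_%d", seq_along(se))
  rows <- data.frame(i = queryHits(hits),
                     gene = g$symbol[subjectHits(hits)],
                     mode = rep("overlap", length(hits)),
                     stringsAsFactors = FALSE)
  unmatched <- setdiff(seq_along(se), unique(queryHits(hits)))
  for (i in unmatched) {
    chr <- as.character(seqnames(se))[i]
    onChr <- which(as.character(seqnames(g)) == chr)
    if (!length(onChr)) {
      message("super-enhancer ", seName[i], " on ", chr,
              " has no gene on its chromosome; excluded")
      next
    }
    mid <- floor((bedStart(se)[i] + bedEnd(se)[i]) / 2)
    d <- abs(mid - g$tss[onChr])
    cand <- onChr[d == min(d)]
    pick <- cand[radixOrder(g$symbol[cand])[1L]]
    rows <- rbind(rows, data.frame(i = i, gene = g$symbol[pick],
                                   mode = "nearest",
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[radixOrder(rows$i, rows$gene), , drop = FALSE]
  out <- data.frame(se = seName[rows$i],
                    chrom = as.character(seqnames(se))[rows$i],
                    start = bedStart(se)[rows$i],
                    end = bedEnd(se)[rows$i],
                    gene = rows$gene, mode = rows$mode,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write SE-calling outputs
#'
#' Writes the region BED-like table (chrom, start, end, name, totalSignal,
#' rank, isSE) and the scaled rank curve.
#'
#' @param result An [SECallResult-class].
#' @param regionPath,curvePath Output paths (either may be `NULL` to skip).
#' @return Invisibly, the region table as a `data.frame`.
#' @export
writeSeCalls <- function(result, regionPath = NULL, curvePath = NULL) {
  r <- seRegions(result)
  df <- data.frame(chrom = as.character(seqnames(r)),
                   start = bedStart(r), end = bedEnd(r),
                   name = sprintf("region_%04d", r$rank),
                   total_signal = r$totalSignal, n_peaks = r$nPeaks,
                   rank = r$rank, is_SE = as.integer(r$isSE))
  if (!is.null(regionPath)) writeTsv(df, regionPath)
  if (!is.null(curvePath))
    writeTsv(data.frame(rank = r$rank, total_signal = r$totalSignal,
                        x = r$x, y = r$y), curvePath)
  invisible(df)
}
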