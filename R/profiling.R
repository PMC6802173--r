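#' Read single-position read placements from BED3
#'
#' Sequenced fragments are consumed as single representative coordinates
#' (the BED start of each record), keeping the module agnostic of the
#' alignment format.
#'
#' @param path BED3+ file of placements.
#' @return `data.frame` with columns `chrom`, `position` (0-based).
#' @export
readReadPlacements <- function(path) {
  gr <- readBedIntervals(path)
  data.frame(chrom = as.character(seqnames(gr)), position = bedStart(gr),
             stringsAsFactors = FALSE)
}

#' Averaged read-density profile around peak centers
#'
#' For each center, reads with offset in `[-profileHalfwidth,
#' profileHalfwidth)` are tallied into `profileBin`-bp half-open bins;
#' summed bin counts are depth-normalized to reads-per-million
#' (divided by total reads / 1e6) and averaged over centers. Duplicating
#' the read multiset leaves the profile unchanged (normalization cancels).
#'
#' @param reads `data.frame` with `chrom` and `position` (0-based), e.g.
#'   from [readReadPlacements()]; must be non-empty.
#' @param centers `data.frame` with `chrom` and `position` (0-based peak
#'   centers); at least one.
#' @param profileHalfwidth Profile half-width in bp (default 3000).
#' @param profileBin Bin width in bp (default 100).
#' @return `data.frame` with `offset` (left bin edge relative to the
#'   center) and `score` (mean depth-normalized reads per bin).
#' @export
profileAroundCenters <- function(reads, centers, profileHalfwidth = 3000,
                                 profileBin = 100) {
  N <- nrow(reads)
  if (!N) stop("profileAroundCenters: zero reads (cannot depth-normalize)")
  if (!nrow(centers)) stop("profileAroundCenters: no centers supplied")
  H <- profileHalfwidth; B <- profileBin
  nBins <- as.integer(2 * H / B)
  counts <- numeric(nBins)
  bychrom <- split(reads$position, reads$chrom)
  bychrom <- lapply(bychrom, sort)
  for (i in seq_len(nrow(centers))) {
    pos <- bychrom[[as.character(centers$chrom[i])]]
    if (is.null(pos)) next
    c0 <- centers$position[i]
    lo <- findInterval(c0 - H - 0.5, pos) + 1L     # first pos >= c0 - H
    hi <- findInterval(c0 + H - 0.5, pos)          # last pos <= c0 + H - 1
    if (hi < lo) next
    off <- pos[lo:hi] - c0
    b <- floor((off + H) / B) + 1L
    counts <- counts + tabulate(b, nBins)
  }
  data.frame(offset = seq(-H, H - B, by = B),
             score = counts * 1e6 / N / nrow(centers))
}

#' Depth-normalized occupancy score of a region
#'
#' Count of read positions inside the 0-based half-open region, divided by
#' total reads per million.
#'
#' @param reads `data.frame` with `chrom`, `position`.
#' @param region A length-1 `GRanges`, or a list/vector with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return Occupancy score in reads per million.
#' @export
regionOccupancyScore <- function(reads, region) {
  N <- nrow(reads)
  if (!N) stop("regionOccupancyScore: zero reads (cannot depth-normalize)")
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    region <- list(chrom = as.character(seqnames(region)),
                   start = bedStart(region), end = bedEnd(region))
  }
  s <- as.numeric(region$start); e <- as.numeric(region$end)
  if (e <= s) stop("regionOccupancyScore: zero-length region")
  k <- sum(reads$chrom == region$chrom & reads$position >= s &
             reads$position < e)
  k * 1e6 / N
}

#' Relative occupancy between two states
#'
#' `log2((a + pseudocount) / (b + pseudocount))`, computed as a difference
#' of logs so that swapping the two states negates the result exactly.
#'
#' @param scoreA,scoreB Occupancy scores (e.g. dTSC vs TSC states).
#' @param pseudocount Positive pseudocount.
#' @return log2 ratio.
#' @export
relativeOccupancy <- function(scoreA, scoreB, pseudocount = 1.0) {
  stopifnot(pseudocount > 0)
  log2(scoreA + pseudocount) - log2(scoreB + pseudocount)
}
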