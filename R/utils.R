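#' @import methods
#' @importFrom stats cor cutree dist hclust rexp rnorm runif rbinom setNames
#' @importFrom utils read.table write.table packageVersion
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges IRangesList start end width findOverlaps overlapsAny
#' @importFrom GenomicRanges GRanges granges reduce seqnames strand strand<- sort
#' @importFrom GenomeInfoDb seqlevels seqlevelsInUse seqnames<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
NULL

## Interval fields are exchanged with BED-style files, which are 0-based
## half-open; GRanges is 1-based closed. These helpers are the single place
## where the conversion happens.
bedStart <- function(x) GenomicRanges::start(x) - 1L

bedEnd <- function(x) GenomicRanges::end(x)

grFromBed <- function(chrom, start, end, ...) {
  GRanges(chrom, IRanges(start + 1L, end), ...)
}

## One-bp GRanges at a 0-based position, for point-in-interval overlap tests.
pointGR <- function(chrom, pos) {
  GRanges(chrom, IRanges(pos + 1L, pos + 1L))
}

#' Peak centers
#'
#' Geometric center of each interval on the 0-based coordinate scale:
#' `floor((start + end) / 2)` of the 0-based half-open interval. Summit
#' columns, where present in the input, are ignored.
#'
#' @param x A `GRanges` of peaks (or any intervals).
#' @return Integer vector of 0-based center positions.
#' @export
peakCenters <- function(x) {
  as.integer(floor((bedStart(x) + bedEnd(x)) / 2))
}

## Byte-wise (locale-independent) ordering, used everywhere a deterministic
## lexicographic tie-break is promised.
radixOrder <- function(...) order(..., method = "radix")

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream. All synthetic-data generators run through this, which is what
## makes them pure functions of (spec, seed).
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Warn when two inputs use disjoint chromosome vocabularies (e.g. "chr1"
## vs "1"); matching is otherwise exact string equality.
checkChromVocabulary <- function(a, b, what = c("inputs", "inputs")) {
  ca <- unique(as.character(seqnames(a)))
  cb <- unique(as.character(seqnames(b)))
  if (length(ca) && length(cb) && !length(intersect(ca, cb)))
    warning(sprintf(
      "disjoint chromosome vocabularies between %s (%s...) and %s (%s...)",
      what[1L], ca[1L], what[2L], cb[1L]))
  invisible(NULL)
}

## Numeric formatting for TSV/BED writers: full double precision so that a
## write/read round trip is bit-exact.
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  ## trim to the shortest representation that still round-trips
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], fmtNum)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
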