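#' Read a signal-scored peak file (BED or narrowPeak)
#'
#' Peaks are returned as a `GRanges` carrying the signal score, the factor
#' (e.g. a transcription factor or cofactor such as p300) and the cell state
#' the track was profiled in. File coordinates are BED-style 0-based
#' half-open; the derived `center` column stays on that scale
#' (`floor((start + end) / 2)`). Input order is preserved.
#'
#' @param path Path to a tab-separated BED3+ or narrowPeak file. Lines
#'   starting with `track`, `browser` or `#` are skipped.
#' @param factor Factor name attached to every peak.
#' @param cellState Cell-state label attached to every peak (e.g. "TSC").
#' @param signalColumn 1-based column holding the signal. Default: column 7
#'   (signalValue) for 10-column narrowPeak, column 5 (score) otherwise.
#' @param minSignal Peaks with signal strictly below this value are dropped
#'   (optional weak-peak filter; default `0`, i.e. off).
#' @return `GRanges` with metadata columns `name`, `signal`, `factor`,
#'   `cellState`, `center`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk\t7.5", tf)
#' readPeaks(tf, factor = "p300", cellState = "TSC")
#' @export
readPeaks <- function(path, factor, cellState = NA_character_,
                      signalColumn = NULL, minSignal = 0) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("no peaks in '", path, "'")
    return(emptyPeaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop(sprintf("parse error at line %d of '%s': fewer than 3 columns",
                 lineNo[which(ncols < 3L)[1L]], path))
  sigCol <- if (!is.null(signalColumn)) as.integer(signalColumn)
            else if (all(ncols == 10L)) 7L else 5L
  if (any(ncols < sigCol))
    stop(sprintf("format error in '%s': missing signal column %d (line %d)",
                 path, sigCol, lineNo[which(ncols < sigCol)[1L]]))
  getCol <- function(i) vapply(fields, `[[`, character(1L), i)
  chrom <- getCol(1L)
  start <- suppressWarnings(as.integer(getCol(2L)))
  end <- suppressWarnings(as.integer(getCol(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s': non-integer coordinates",
                 lineNo[bad[1L]], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s': start >= end (%d >= %d)",
                 lineNo[bad[1L]], path, start[bad[1L]], end[bad[1L]]))
  if (any(start < 0L))
    stop(sprintf("parse error at line %d of '%s': negative start",
                 lineNo[which(start < 0L)[1L]], path))
  signal <- suppressWarnings(as.numeric(getCol(sigCol)))
  bad <- which(is.na(signal))
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s': non-numeric signal",
                 lineNo[bad[1L]], path))
  if (any(signal < 0))
    stop(sprintf("parse error at line %d of '%s': negative signal",
                 lineNo[which(signal < 0)[1L]], path))
  name <- if (all(ncols >= 4L)) getCol(4L)
          else sprintf("peak_%d", seq_along(chrom))
  gr <- grFromBed(chrom, start, end)
  mcols(gr) <- DataFrame(name = name, signal = signal,
                         factor = as.character(factor),
                         cellState = as.character(cellState))
  gr$center <- peakCenters(gr)
  if (minSignal > 0) {
    drop <- gr$signal < minSignal
    if (any(drop))
      message(sum(drop), " peak(s) below minimum signal ", minSignal,
              " removed")
    gr <- gr[!drop]
  }
  gr
}

emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(name = character(), signal = numeric(),
                         factor = character(), cellState = character(),
                         center = integer())
  gr
}

#' Write peaks as BED5
#'
#' Inverse of [readPeaks()]: coordinates go back to 0-based half-open and
#' signals are printed at full double precision, so a write/read round trip
#' reproduces coordinates, signals and order exactly.
#'
#' @param peaks `GRanges` from [readPeaks()] or a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = bedStart(peaks), end = bedEnd(peaks),
                   name = if (!is.null(peaks$name)) peaks$name
                          else sprintf("peak_%d", seq_along(peaks)),
                   signal = fmtNum(peaks$signal))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a refFlat file
#'
#' Parses the UCSC 11-column refFlat dialect (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) into a
#' transcript-level `GRanges`. The transcription start site is derived
#' strand-aware on the 0-based scale: `txStart` on `+`, `txEnd - 1` on `-`.
#' Duplicate gene symbols are retained (distinct transcripts); gene-level
#' operations pick one via [canonicalTranscripts()].
#'
#' @param path Path to a refFlat file (no header).
#' @return `GRanges` with metadata columns `symbol`, `txName`, `tss`
#'   (0-based) and `exons` (an `IRangesList`, 1-based closed).
#' @export
readRefFlat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    warning("no gene models in '", path, "'")
    return(emptyGenes())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L))
    stop(sprintf("parse error at line %d of '%s': expected 11 columns",
                 which(lengths(fields) < 11L)[1L], path))
  getCol <- function(i) vapply(fields, `[[`, character(1L), i)
  symbol <- getCol(1L); txName <- getCol(2L); chrom <- getCol(3L)
  strand <- getCol(4L)
  strand[strand == "−"] <- "-"   # tolerate typographic minus
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s': unknown strand '%s'",
                 bad[1L], path, strand[bad[1L]]))
  txStart <- suppressWarnings(as.integer(getCol(5L)))
  txEnd <- suppressWarnings(as.integer(getCol(6L)))
  exonCount <- suppressWarnings(as.integer(getCol(9L)))
  bad <- which(is.na(txStart) | is.na(txEnd) | is.na(exonCount) |
                 txStart >= txEnd)
  if (length(bad))
    stop(sprintf("parse error at line %d of '%s': bad transcript coordinates",
                 bad[1L], path))
  splitInts <- function(s) as.integer(strsplit(sub(",+$", "", s), ",")[[1L]])
  exStarts <- lapply(getCol(10L), splitInts)
  exEnds <- lapply(getCol(11L), splitInts)
  bad <- which(lengths(exStarts) != exonCount | lengths(exEnds) != exonCount)
  if (length(bad))
    stop(sprintf(
      "parse error at line %d of '%s': exonCount %d inconsistent with exon list",
      bad[1L], path, exonCount[bad[1L]]))
  for (i in seq_along(exStarts)) {
    s <- exStarts[[i]]; e <- exEnds[[i]]
    if (any(s >= e) || is.unsorted(s, strictly = TRUE) ||
        any(s[-1L] < e[-length(e)]) ||
        s[1L] < txStart[i] || e[length(e)] > txEnd[i])
      stop(sprintf(
        "parse error at line %d of '%s': exons not sorted/disjoint within transcript",
        i, path))
  }
  gr <- GRanges(chrom, IRanges(txStart + 1L, txEnd), strand = strand)
  mcols(gr) <- DataFrame(
    symbol = symbol, txName = txName,
    tss = ifelse(strand == "+", txStart, txEnd - 1L),
    exons = IRangesList(mapply(function(s, e) IRanges(s + 1L, e),
                               exStarts, exEnds, SIMPLIFY = FALSE))
  )
  gr
}

emptyGenes <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(symbol = character(), txName = character(),
                         tss = integer(), exons = IRangesList())
  gr
}

#' Write gene models as refFlat
#'
#' @param genes `GRanges` as returned by [readRefFlat()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRefFlat <- function(genes, path) {
  exS <- vapply(genes$exons, function(e)
    paste0(paste(start(e) - 1L, collapse = ","), ","), character(1L))
  exE <- vapply(genes$exons, function(e)
    paste0(paste(end(e), collapse = ","), ","), character(1L))
  df <- data.frame(genes$symbol, genes$txName,
                   as.character(seqnames(genes)),
                   as.character(strand(genes)),
                   bedStart(genes), bedEnd(genes),
                   bedStart(genes), bedEnd(genes),
                   lengths(genes$exons), exS, exE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read plain genomic intervals from a BED3+ file
#'
#' Used for repeat masks and other interval lists.
#'
#' @param path Path to a BED file.
#' @return `GRanges` (no metadata columns).
#' @export
readBedIntervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop(sprintf("parse error at line %d of '%s': fewer than 3 columns",
                 which(lengths(fields) < 3L)[1L], path))
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
  if (anyNA(start) || anyNA(end) || any(start >= end))
    stop(sprintf("parse error in '%s': bad interval coordinates", path))
  grFromBed(vapply(fields, `[[`, character(1L), 1L), start, end)
}

#' Remove peaks falling in repeat-masked regions
#'
#' Drops every peak whose center lies inside any repeat interval, mirroring
#' the removal of peaks in simple redundant regions of the genome. An empty
#' repeat set is the identity; the operation is idempotent and preserves
#' order.
#'
#' @param peaks Peak `GRanges`.
#' @param repeats `GRanges` of repeat intervals (may be empty).
#' @return Filtered peak `GRanges`.
#' @export
filterRepeatRegions <- function(peaks, repeats) {
  if (!length(repeats) || !length(peaks)) return(peaks)
  hit <- overlapsAny(pointGR(seqnames(peaks), peakCenters(peaks)), repeats)
  message(sum(hit), " peak(s) removed in repeat regions")
  peaks[!hit]
}

#' Canonical transcript per gene symbol
#'
#' Where several transcripts share a symbol, gene-level operations use the
#' transcript with the widest span; ties are broken lexicographically by
#' transcript name.
#'
#' @param genes Transcript-level gene `GRanges`.
#' @return `GRanges` with one row per symbol.
#' @export
canonicalTranscripts <- function(genes) {
  if (!length(genes)) return(genes)
  o <- radixOrder(genes$symbol, -width(genes), genes$txName)
  g <- genes[o]
  g[!duplicated(g$symbol)]
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated with a header; first column holds gene symbols, remaining
#' columns one sample each.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, genes in rows.
#' @export
readExpressionTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("expression table '", path, "' has duplicate gene symbols")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("expression table '", path, "' is not numeric")
  if (any(m < 0)) stop("expression table '", path, "' has negative values")
  rownames(m) <- df[[1L]]
  m
}

#' Write a gene-by-sample expression table
#'
#' @param expr Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  writeTsv(df, path)
}

#' Read a two-column ortholog table
#'
#' @param path TSV with header and two columns (e.g. mouse_symbol,
#'   human_symbol).
#' @return Named character vector mapping column 1 to column 2.
#' @export
readOrthologMap <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog table '", path, "' needs two columns")
  setNames(as.character(df[[2L]]), df[[1L]])
}
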