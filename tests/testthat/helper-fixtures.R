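suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## peaks from 0-based half-open coordinates
makePeaks <- function(starts, ends, signal = 1, chrom = "chr1",
                      factor = "p300", cellState = "TSC", name = NULL) {
  n <- length(starts)
  gr <- GRanges(rep_len(chrom, n), IRanges(starts + 1L, ends))
  mcols(gr) <- DataFrame(
    name = name %||% sprintf("pk%d", seq_len(n)),
    signal = rep_len(signal, n),
    factor = rep_len(factor, n), cellState = rep_len(cellState, n))
  gr$center <- peakCenters(gr)
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## one gene model row from 0-based coordinates; exons as list of c(start, end)
makeGene <- function(symbol, txStart, txEnd, strand = "+", chrom = "chr1",
                     exons = NULL, txName = paste0(symbol, "_tx1")) {
  if (is.null(exons)) exons <- list(c(txStart, txEnd))
  gr <- GRanges(chrom, IRanges(txStart + 1L, txEnd), strand = strand)
  mcols(gr) <- DataFrame(
    symbol = symbol, txName = txName,
    tss = if (strand == "+") as.integer(txStart) else as.integer(txEnd - 1L),
    exons = IRangesList(IRanges(vapply(exons, `[`, numeric(1), 1) + 1L,
                                vapply(exons, `[`, numeric(1), 2))))
  gr
}

## --- independent oracles (plain loops, no package internals) -------------

## O(n^2) transitive closure of the stitching gap relation
stitchOracle <- function(chrom, s, e, signal, dist) {
  n <- length(s)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (chrom[i] != chrom[j]) next
    gap <- max(s[i], s[j]) - min(e[i], e[j])
    adj[i, j] <- gap <= dist
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    if (!changed) break
  }
  ids <- unique(comp)
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), total = numeric())
  for (k in ids) {
    m <- comp == k
    out <- rbind(out, data.frame(chrom = chrom[m][1], start = min(s[m]),
                                 end = max(e[m]), total = sum(signal[m])))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

## exhaustive elbow evaluation on a signal vector
elbowOracle <- function(sig) {
  ss <- sort(sig)
  n <- length(ss)
  best <- -Inf; idx <- NA
  for (i in seq_len(n)) {
    v <- (i - 1) / (n - 1) - (ss[i] - ss[1]) / (ss[n] - ss[1])
    if (v > best) { best <- v; idx <- i }
  }
  list(cutoffIndex = idx, cutoffSignal = ss[idx], nSE = sum(sig > ss[idx]))
}

## brute-force feature precedence per peak center: enumerate every
## (gene, feature) pair, take the precedence maximum, then the smallest
## symbol among genes granting it
featureOracle <- function(center, chrom, genes, ph = 2000, um = 20000) {
  featOf <- integer(0); symOf <- character(0)
  for (i in seq_along(genes)) {
    if (as.character(seqnames(genes))[i] != chrom) next
    tss <- genes$tss[i]
    strand <- as.character(strand(genes))[i]
    s <- start(genes)[i] - 1L; e <- end(genes)[i]
    feats <- integer()
    if (abs(center - tss) <= ph) feats <- c(feats, 1L)
    d <- if (strand == "+") tss - center else center - tss
    if (d > ph && d <= um) feats <- c(feats, 2L)
    if (center >= s && center < e) {
      ex <- genes$exons[[i]]
      inEx <- any(center + 1L >= start(ex) & center + 1L <= end(ex))
      feats <- c(feats, if (inEx) 4L else 3L)
    }
    if (length(feats)) {
      featOf <- c(featOf, min(feats))
      symOf <- c(symOf, genes$symbol[i])
    }
  }
  if (!length(featOf))
    return(list(feature = "intergenic", gene = NA_character_))
  best <- min(featOf)
  list(feature = c("promoter", "upstream", "intron", "exon")[best],
       gene = min(symOf[featOf == best]))
}

## exhaustive motif enumeration from a logical adjacency matrix
motifOracle <- function(A) {
  k <- nrow(A)
  auto <- which(diag(A))
  Ao <- A; diag(Ao) <- FALSE
  fb <- 0L; ff <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && Ao[i, j] && Ao[j, i]) fb <- fb + 1L
  }
  for (a in seq_len(k)) for (b in seq_len(k)) for (cc in seq_len(k)) {
    if (a != b && b != cc && a != cc && Ao[a, b] && Ao[b, cc] && Ao[a, cc])
      ff <- ff + 1L
  }
  list(nAuto = length(auto), nFeedback = fb, nFeedforward = ff)
}
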