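#' Classify peaks into genomic features by the annotation hierarchy
#'
#' Each peak is judged by its center against every transcript and receives
#' the highest-precedence feature under the hierarchy
#' promoter > upstream > intron > exon > intergenic:
#' * promoter: center within `promoterHalfwidth` of a TSS (either side);
#' * upstream: center strictly more than `promoterHalfwidth` and at most
#'   `upstreamMax` bp 5' of a TSS on the gene's strand;
#' * intron: center inside a gene body but in no exon of that transcript;
#' * exon: center inside an exon;
#' * intergenic: none of the above (no gene assigned).
#'
#' Among genes granting the winning feature, the lexicographically smallest
#' symbol is reported.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Transcript-level gene `GRanges` from [readRefFlat()].
#' @param config A [pipelineConfig()].
#' @return `data.frame` with one row per peak: `feature` (factor with the
#'   five levels in precedence order) and `gene` (`NA` for intergenic).
#' @export
classifyPeakFeatures <- function(peaks, genes, config = pipelineConfig()) {
  ph <- config$promoterHalfwidth
  um <- config$upstreamMax
  stopifnot(ph < um)
  lv <- c("promoter", "upstream", "intron", "exon", "intergenic")
  n <- length(peaks)
  if (!n)
    return(data.frame(feature = factor(character(), levels = lv),
                      gene = character()))
  if (length(genes)) checkChromVocabulary(peaks, genes, c("peaks", "genes"))
  centers <- peakCenters(peaks)
  pts <- pointGR(seqnames(peaks), centers)
  best <- rep(5L, n)                 # precedence index into lv
  bestGene <- rep(NA_character_, n)

  claim <- function(level, hits, geneIdx) {
    ## hits: Hits peaks->zones ; geneIdx maps zone -> gene row
    if (!length(hits)) return()
    p <- queryHits(hits)
    gsym <- genes$symbol[geneIdx[subjectHits(hits)]]
    o <- radixOrder(p, gsym)
    p <- p[o]; gsym <- gsym[o]
    first <- !duplicated(p)          # smallest symbol per peak
    p <- p[first]; gsym <- gsym[first]
    upd <- level < best[p]
    best[p[upd]] <<- level
    bestGene[p[upd]] <<- gsym[upd]
  }

  if (length(genes)) {
    tss <- genes$tss
    chr <- seqnames(genes)
    plus <- as.character(strand(genes)) == "+"
    ## promoter: |center - tss| <= ph  (0-based positions)
    prom <- GRanges(chr, IRanges(pmax(tss - ph + 1, 1), tss + ph + 1))
    ## upstream: ph < d <= um, d = strand-aware distance 5' of the TSS
    upS <- ifelse(plus, tss - um, tss + ph + 1)
    upE <- ifelse(plus, tss - ph - 1, tss + um)
    up <- GRanges(chr, IRanges(pmax(upS + 1, 1), pmax(upE + 1, 0)))
    body <- granges(genes)
    exons <- genes$exons
    exFlat <- unlist(exons, use.names = FALSE)
    exGene <- rep(seq_along(genes), lengths(exons))
    exGR <- GRanges(rep(chr, lengths(exons)), exFlat)

    ## exon (4) and intron (3) first, then upstream (2), promoter (1):
    ## later claims overwrite on strictly higher precedence only.
    claim(4L, findOverlaps(pts, exGR, ignore.strand = TRUE), exGene)
    bodyHits <- findOverlaps(pts, body, ignore.strand = TRUE)
    if (length(bodyHits)) {
      ## intron = in body but not in an exon of that same transcript
      pairInExon <- logical(length(bodyHits))
      for (k in seq_along(bodyHits)) {
        gi <- subjectHits(bodyHits)[k]
        pos1 <- GenomicRanges::start(pts)[queryHits(bodyHits)[k]]
        ex <- exons[[gi]]
        pairInExon[k] <- any(pos1 >= start(ex) & pos1 <= end(ex))
      }
      claim(3L, bodyHits[!pairInExon], seq_along(genes))
    }
    claim(2L, findOverlaps(pts, up, ignore.strand = TRUE), seq_along(genes))
    claim(1L, findOverlaps(pts, prom, ignore.strand = TRUE), seq_along(genes))
  }
  data.frame(feature = factor(lv[best], levels = lv),
             gene = bestGene, stringsAsFactors = FALSE)
}

#' Count enhancers associated with each gene
#'
#' An enhancer counts for a gene iff its center lies within `upstreamMax`
#' bp 5' of the TSS (strand-aware) or inside the gene body. One enhancer may
#' count for several genes; genes without enhancers map to 0. Transcripts
#' are collapsed to one per symbol ([canonicalTranscripts()]).
#'
#' @param peaks Enhancer peak `GRanges` (e.g. p300 binding sites).
#' @param genes Gene-model `GRanges`.
#' @param config A [pipelineConfig()]; `upstreamMax` is the upstream reach.
#' @return Named integer vector over all gene symbols.
#' @export
mapEnhancersToGenes <- function(peaks, genes, config = pipelineConfig()) {
  g <- canonicalTranscripts(genes)
  counts <- setNames(integer(length(g)), g$symbol)
  if (!length(peaks) || !length(g)) return(counts)
  um <- config$upstreamMax
  centers <- peakCenters(peaks)
  pts <- pointGR(seqnames(peaks), centers)
  plus <- as.character(strand(g)) == "+"
  tss <- g$tss
  ## upstream reach: 0 < d <= um  (center strictly 5' of the TSS)
  upS <- ifelse(plus, tss - um, tss + 1)
  upE <- ifelse(plus, tss - 1, tss + um)
  zones <- c(GRanges(seqnames(g), IRanges(pmax(upS + 1, 1), pmax(upE + 1, 0))),
             granges(g))
  zoneGene <- c(seq_along(g), seq_along(g))
  hits <- findOverlaps(pts, zones, ignore.strand = TRUE)
  if (length(hits)) {
    pair <- unique(data.frame(p = queryHits(hits),
                              g = zoneGene[subjectHits(hits)]))
    tab <- table(factor(pair$g, levels = seq_along(g)))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Assign peaks to target genes
#'
#' A peak targets every gene whose body, extended by `networkWindow` bp on
#' both sides, contains the peak center. A peak matching no extended span
#' falls back to the single nearest gene on its chromosome by
#' center-to-TSS distance; ties are broken by the smaller distance to the
#' gene-body boundary, then by lexicographic symbol. Transcripts are
#' collapsed to one per symbol.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges` (at least one on each peak's
#'   chromosome; otherwise an error names the offending chromosome).
#' @param config A [pipelineConfig()].
#' @return List (one element per peak) of target gene symbol vectors;
#'   fallback assignments have length 1.
#' @export
assignTargetGenes <- function(peaks, genes, config = pipelineConfig()) {
  g <- canonicalTranscripts(genes)
  if (!length(g)) stop("assignTargetGenes: no gene models supplied")
  w <- config$networkWindow
  centers <- peakCenters(peaks)
  pts <- pointGR(seqnames(peaks), centers)
  ext <- GRanges(seqnames(g),
                 IRanges(pmax(GenomicRanges::start(g) - w, 1),
                         GenomicRanges::end(g) + w))
  hits <- findOverlaps(pts, ext, ignore.strand = TRUE)
  out <- vector("list", length(peaks))
  if (length(hits)) {
    sp <- split(g$symbol[subjectHits(hits)], queryHits(hits))
    for (k in names(sp))
      out[[as.integer(k)]] <- sort(unique(sp[[k]]), method = "radix")
  }
  gChr <- as.character(seqnames(g))
  gS <- bedStart(g); gE <- bedEnd(g)
  for (i in which(lengths(out) == 0L)) {
    chr <- as.character(seqnames(peaks))[i]
    onChr <- which(gChr == chr)
    if (!length(onChr))
      stop("assignTargetGenes: no gene on chromosome ", chr)
    c0 <- centers[i]
    dTss <- abs(c0 - g$tss[onChr])
    cand <- onChr[dTss == min(dTss)]
    if (length(cand) > 1L) {
      dBody <- pmax(0, gS[cand] - c0, c0 - (gE[cand] - 1L))
      cand <- cand[dBody == min(dBody)]
      cand <- cand[radixOrder(g$symbol[cand])]
    }
    out[[i]] <- g$symbol[cand[1L]]
  }
  out
}

#' Write per-peak feature annotation
#'
#' @param peaks Peak `GRanges`.
#' @param calls Output of [classifyPeakFeatures()] for `peaks`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCalls <- function(peaks, calls, path) {
  writeTsv(data.frame(chrom = as.character(seqnames(peaks)),
                      start = bedStart(peaks), end = bedEnd(peaks),
                      factor = peaks$factor,
                      feature = as.character(calls$feature),
                      gene = ifelse(is.na(calls$gene), ".", calls$gene)),
           path)
}
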