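#' Specification of a synthetic enhancer landscape
#'
#' Describes the fixture genome the generators emulate: a peak landscape of
#' sparse typical enhancers plus dense, high-signal planted clusters that a
#' correct super-enhancer caller must recover, against a background gene
#' annotation. Defaults follow the study conditions used throughout the
#' package's recovery tests: 200 typical singleton peaks with exponential
#' signal of mean 5 and 10 clusters of 8 peaks with exponential signal of
#' mean 50, on one 15-Mb chromosome with a 400-gene annotation.
#'
#' @param nChroms Number of chromosomes (`chr1`, `chr2`, ...).
#' @param chromLength Length of each chromosome in bp.
#' @param nGenes Number of genes (non-overlapping, random strand, 2--6
#'   exons).
#' @param nTypical Number of isolated typical enhancer peaks, pairwise
#'   separated by more than `stitchDistance`.
#' @param typicalSignalMean Mean of the exponential signal of typical
#'   peaks.
#' @param nSeClusters Number of planted super-enhancer clusters.
#' @param peaksPerCluster Peaks per planted cluster.
#' @param clusterSpan Span (bp) within which a cluster's peaks fall; must
#'   be below `stitchDistance` so each cluster stitches into one region.
#' @param seSignalMean Mean of the exponential per-peak signal inside
#'   clusters; must exceed `typicalSignalMean`.
#' @param stitchDistance,tssExclusion The SE-calling parameters the
#'   placement respects: entities are spaced more than `stitchDistance`
#'   apart and clusters avoid TSS exclusion zones.
#' @param seed Integer RNG seed; all generators are pure functions of
#'   (spec, seed).
#' @return A validated `SyntheticLandscapeSpec` (named list).
#' @export
syntheticLandscapeSpec <- function(nChroms = 1L, chromLength = 15e6,
                                   nGenes = 400L, nTypical = 200L,
                                   typicalSignalMean = 5,
                                   nSeClusters = 10L, peaksPerCluster = 8L,
                                   clusterSpan = 10000, seSignalMean = 50,
                                   stitchDistance = 12500,
                                   tssExclusion = 2500, seed = 1L) {
  spec <- list(nChroms = as.integer(nChroms),
               chromLength = as.numeric(chromLength),
               nGenes = as.integer(nGenes), nTypical = as.integer(nTypical),
               typicalSignalMean = typicalSignalMean,
               nSeClusters = as.integer(nSeClusters),
               peaksPerCluster = as.integer(peaksPerCluster),
               clusterSpan = as.numeric(clusterSpan),
               seSignalMean = seSignalMean,
               stitchDistance = as.numeric(stitchDistance),
               tssExclusion = as.numeric(tssExclusion),
               seed = as.integer(seed))
  if (spec$seSignalMean <= spec$typicalSignalMean)
    stop("spec: seSignalMean must exceed typicalSignalMean")
  if (spec$clusterSpan >= spec$stitchDistance)
    stop("spec: clusterSpan must be below stitchDistance")
  if (spec$nChroms < 1L || spec$chromLength <= 0)
    stop("spec: need at least one chromosome of positive length")
  structure(spec, class = "SyntheticLandscapeSpec")
}

## deal n items across k groups as evenly as possible
dealAcross <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Generate a synthetic gene annotation
#'
#' Places `nGenes` non-overlapping genes (length 2--10 kb, random strand,
#' 2--6 exons with refFlat-style first/last exon boundaries at the
#' transcript ends) uniformly over the chromosomes. Deterministic given the
#' spec seed; an annotation that cannot fit raises a capacity error.
#'
#' @param spec A [syntheticLandscapeSpec()].
#' @return Gene-model `GRanges` in [readRefFlat()] layout.
#' @export
generateAnnotation <- function(spec) {
  withSeed(spec$seed, {
    footprint <- 12000
    perChrom <- dealAcross(spec$nGenes, spec$nChroms)
    nSlots <- floor(spec$chromLength / footprint)
    if (any(perChrom > nSlots))
      stop("capacity error: ", spec$nGenes, " genes do not fit ",
           spec$nChroms, " chromosome(s) of ", spec$chromLength, " bp")
    rows <- list()
    for (ch in seq_len(spec$nChroms)) {
      ng <- perChrom[ch]
      if (!ng) next
      slots <- sort(sample.int(nSlots, ng))
      for (i in seq_len(ng)) {
        len <- sample(2000:10000, 1L)
        s <- (slots[i] - 1) * footprint + sample.int(footprint - len, 1L) - 1L
        nEx <- sample(2:6, 1L)
        inner <- sort(sample((s + 1):(s + len - 1), 2L * nEx - 2L))
        bounds <- c(s, inner, s + len)
        exS <- bounds[seq(1L, 2L * nEx, by = 2L)]
        exE <- bounds[seq(2L, 2L * nEx, by = 2L)]
        rows[[length(rows) + 1L]] <- list(
          chrom = paste0("chr", ch), strand = sample(c("+", "-"), 1L),
          s = s, e = s + len, exS = exS, exE = exE)
      }
    }
    if (!length(rows)) return(emptyGenes())
    chrom <- vapply(rows, `[[`, character(1L), "chrom")
    strand <- vapply(rows, `[[`, character(1L), "strand")
    s <- vapply(rows, function(r) r$s, numeric(1L))
    e <- vapply(rows, function(r) r$e, numeric(1L))
    symbol <- sprintf("Gene%04d", seq_along(rows))
    gr <- GRanges(chrom, IRanges(s + 1, e), strand = strand)
    mcols(gr) <- DataFrame(
      symbol = symbol, txName = paste0(symbol, "_tx1"),
      tss = as.integer(ifelse(strand == "+", s, e - 1)),
      exons = IRangesList(lapply(rows, function(r)
        IRanges(r$exS + 1, r$exE))))
    gr
  })
}

#' Generate a synthetic enhancer landscape with planted SE clusters
#'
#' Emulates the hockey-stick ranked-signal geometry of a real enhancer
#' landscape: `nTypical` isolated peaks with Exponential(mean
#' `typicalSignalMean`) signal, pairwise separated by more than the stitch
#' distance, plus `nSeClusters` clusters of `peaksPerCluster` peaks within
#' `clusterSpan` bp each, Exponential(mean `seSignalMean`) per-peak signal.
#' Clusters are placed more than `stitchDistance` from any other peak and
#' more than `tssExclusion` from every TSS, so a planted cluster always
#' stitches into exactly one region surviving TSS exclusion. Placement uses
#' fixed-width genome slots, so feasibility is checked up front (capacity
#' error instead of unbounded rejection).
#'
#' @param spec A [syntheticLandscapeSpec()].
#' @param genes Annotation from [generateAnnotation()] (for TSS
#'   avoidance); may be empty.
#' @return List with `peaks` (`GRanges`, factor `"p300"`, cell state
#'   `"TSC"`) and `truth` -- a list whose `plantedSeIntervals` `GRanges`
#'   records each cluster's stitched extent.
#' @export
generateEnhancerLandscape <- function(spec, genes = GRanges()) {
  withSeed(spec$seed + 1L, {
    slotW <- spec$stitchDistance + spec$clusterSpan + 2000
    entW <- spec$clusterSpan + 1000       # entity confined to slot start
    nSlots <- floor(spec$chromLength / slotW)
    perChrom <- dealAcross(spec$nTypical + spec$nSeClusters, spec$nChroms)
    clustPer <- dealAcross(spec$nSeClusters, spec$nChroms)
    if (any(perChrom > nSlots))
      stop("capacity error: ", spec$nTypical + spec$nSeClusters,
           " peak entities do not fit the genome at the required spacing")
    chromV <- character(); sV <- numeric(); eV <- numeric()
    sigV <- numeric(); nameV <- character()
    tChrom <- character(); tS <- numeric(); tE <- numeric()
    for (ch in seq_len(spec$nChroms)) {
      chrom <- paste0("chr", ch)
      nEnt <- perChrom[ch]; nClu <- clustPer[ch]
      if (!nEnt) next
      tssOnChrom <- if (length(genes))
        genes$tss[as.character(seqnames(genes)) == chrom] else numeric()
      slotFree <- function(slot) {
        a <- (slot - 1) * slotW - spec$tssExclusion
        b <- (slot - 1) * slotW + entW + spec$tssExclusion
        !any(tssOnChrom >= a & tssOnChrom <= b)
      }
      slots <- sample.int(nSlots, nEnt)
      if (nClu) {
        ## clusters take TSS-free slots; swap in fresh slots when needed
        pool <- setdiff(sample.int(nSlots), slots)
        for (k in seq_len(nClu)) {
          tries <- 0L
          while (!slotFree(slots[k])) {
            if (!length(pool) || tries > 1000L)
              stop("capacity error: cannot place cluster clear of TSSs")
            slots[k] <- pool[1L]; pool <- pool[-1L]
            tries <- tries + 1L
          }
        }
      }
      base <- (slots - 1) * slotW
      for (k in seq_len(nEnt)) {
        if (k <= nClu) {
          npk <- spec$peaksPerCluster
          ctr <- sort(sample.int(spec$clusterSpan, npk)) + base[k]
          w <- sample(200:600, npk, replace = TRUE)
          s <- pmax(ctr - w %/% 2, 0); e <- s + w
          chromV <- c(chromV, rep(chrom, npk))
          sV <- c(sV, s); eV <- c(eV, e)
          sigV <- c(sigV, rexp(npk, 1 / spec$seSignalMean))
          nameV <- c(nameV, sprintf("%s_clu%d_pk%d", chrom, k, seq_len(npk)))
          tChrom <- c(tChrom, chrom)
          tS <- c(tS, min(s)); tE <- c(tE, max(e))
        } else {
          w <- sample(200:1000, 1L)
          s <- base[k] + sample.int(1000L, 1L) - 1L
          chromV <- c(chromV, chrom)
          sV <- c(sV, s); eV <- c(eV, s + w)
          sigV <- c(sigV, rexp(1L, 1 / spec$typicalSignalMean))
          nameV <- c(nameV, sprintf("%s_typ%d", chrom, k))
        }
      }
    }
    peaks <- grFromBed(chromV, sV, eV)
    mcols(peaks) <- DataFrame(name = nameV, signal = sigV,
                              factor = "p300", cellState = "TSC")
    peaks$center <- peakCenters(peaks)
    truth <- list(
      plantedSeIntervals = if (length(tChrom)) grFromBed(tChrom, tS, tE)
                           else GRanges(),
      spec = spec)
    list(peaks = peaks, truth = truth)
  })
}

#' Generate multi-factor peak sets with controlled co-occupancy
#'
#' Builds a universe of shared binding sites at which each factor binds
#' independently with probability `cooccupancyRate` (peak centers jittered
#' uniformly within +/-100 bp of the site anchor), plus factor-private
#' sites. Site anchors are spaced far enough apart that distinct sites
#' never merge under the default 500-bp overlap window.
#'
#' @param nFactors Number of factors (named `TF01`, `TF02`, ...).
#' @param nSharedSites Number of shared anchor sites.
#' @param cooccupancyRate Binding probability per (factor, shared site);
#'   scalar or one value per factor.
#' @param privateSitesPerFactor Private sites per factor.
#' @param seed Integer seed.
#' @param chromLength Genome length used for anchor placement (single
#'   chromosome `chr1`).
#' @param anchors Optional explicit 0-based anchor positions for the
#'   shared sites (overrides placement; must be pairwise farther apart
#'   than the overlap window plus jitter).
#' @return List with `peaksets` (named list of `GRanges`) and `truth`
#'   (`anchors`, binary `indicator` site-by-factor matrix,
#'   `cooccupancyRate`).
#' @export
generateTfPeakSets <- function(nFactors, nSharedSites = 500,
                               cooccupancyRate = 0.7,
                               privateSitesPerFactor = 50, seed = 1L,
                               chromLength = 5e7, anchors = NULL) {
  stopifnot(all(cooccupancyRate >= 0), all(cooccupancyRate <= 1))
  rate <- rep_len(cooccupancyRate, nFactors)
  withSeed(seed, {
    factors <- sprintf("TF%02d", seq_len(nFactors))
    nPriv <- nFactors * privateSitesPerFactor
    spacing <- 2000
    if (is.null(anchors)) {
      nSlots <- floor(chromLength / spacing)
      if (nSharedSites + nPriv > nSlots)
        stop("capacity error: too many sites for chromLength")
      pos <- (sample.int(nSlots, nSharedSites + nPriv) - 1) * spacing + 500
      anchors <- pos[seq_len(nSharedSites)]
      privAnchors <- pos[nSharedSites + seq_len(nPriv)]
    } else {
      stopifnot(length(anchors) == nSharedSites)
      nSlots <- floor(chromLength / spacing)
      if (nPriv > nSlots - nSharedSites)
        stop("capacity error: too many private sites for chromLength")
      cand <- (sample.int(nSlots, nPriv + nSharedSites) - 1) * spacing + 500
      ## keep private anchors clear of the supplied shared anchors
      far <- vapply(cand, function(p) all(abs(p - anchors) > 1000),
                    logical(1L))
      privAnchors <- cand[far][seq_len(nPriv)]
    }
    indicator <- matrix(0L, nSharedSites, nFactors,
                        dimnames = list(NULL, factors))
    for (j in seq_len(nFactors))
      if (nSharedSites)
        indicator[, j] <- rbinom(nSharedSites, 1L, rate[j])
    peaksets <- list()
    for (j in seq_len(nFactors)) {
      bound <- which(indicator[, j] == 1L)
      ctr <- c(if (length(bound)) anchors[bound] +
                 sample(-100:100, length(bound), replace = TRUE),
               if (privateSitesPerFactor)
                 privAnchors[(j - 1) * privateSitesPerFactor +
                               seq_len(privateSitesPerFactor)])
      ctr <- as.numeric(ctr)
      gr <- grFromBed(rep("chr1", length(ctr)), pmax(ctr - 150, 0),
                      pmax(ctr - 150, 0) + 300)
      mcols(gr) <- DataFrame(
        name = sprintf("%s_pk%d", factors[j], seq_along(gr)),
        signal = rexp(length(gr), 1 / 10),
        factor = factors[j], cellState = "TSC")
      gr$center <- peakCenters(gr)
      peaksets[[factors[j]]] <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    }
    list(peaksets = peaksets,
         truth = list(anchors = anchors, indicator = indicator,
                      cooccupancyRate = rate))
  })
}

#' Generate time-course expression from four archetype classes
#'
#' Genes are drawn from four positive mean curves over normalized time --
#' class 1 biphasic (high, low mid, high; 4-fold), class 2 monotone
#' decreasing (4-fold), class 3 monotone increasing (4-fold), class 4 flat
#' -- scaled by a per-gene lognormal baseline, with multiplicative
#' lognormal noise of log-scale s.d. `noiseSd`.
#'
#' @param nGenesPerClass Genes per class.
#' @param nTimepoints Number of timepoints (>= 4).
#' @param noiseSd Log-scale standard deviation of the multiplicative
#'   noise; `0` gives exact archetype curves.
#' @param seed Integer seed.
#' @return List with `expr` (gene-by-timepoint matrix, columns `t0`,
#'   `t1`, ...) and `truth` (`classLabels`, named integer vector).
#' @export
generateTimecourseExpression <- function(nGenesPerClass = 50,
                                         nTimepoints = 7, noiseSd = 0.1,
                                         seed = 1L) {
  stopifnot(nTimepoints >= 4)
  withSeed(seed, {
    tn <- seq(0, 1, length.out = nTimepoints)
    curves <- rbind(2^(2 * (4 * (tn - 0.5)^2) - 1),   # biphasic
                    2^(1 - 2 * tn),                   # decreasing
                    2^(2 * tn - 1),                   # increasing
                    rep(1, nTimepoints))              # flat
    n <- 4L * nGenesPerClass
    labels <- rep(1:4, each = nGenesPerClass)
    expr <- matrix(0, n, nTimepoints,
                   dimnames = list(sprintf("Tcg%04d", seq_len(n)),
                                   paste0("t", seq_len(nTimepoints) - 1L)))
    for (i in seq_len(n)) {
      baseline <- 2^runif(1, 4, 9)
      expr[i, ] <- baseline * curves[labels[i], ] *
        exp(rnorm(nTimepoints, 0, noiseSd))
    }
    list(expr = expr,
         truth = list(classLabels = setNames(labels, rownames(expr))))
  })
}

#' Generate case/control expression datasets with planted dysregulation
#'
#' Each dataset draws per-sample expression `2^(mu + N(0, noiseSd))`
#' around gene baselines `mu ~ N(6, 1)` (log2 units); planted genes have
#' their case-arm mean shifted by `+/- effectLog2fc`. The planted
#' up/down identities are shared across datasets, emulating a consistent
#' disease signature screened across independent cohorts.
#'
#' @param nDatasets Number of datasets.
#' @param nGenes Genes per dataset.
#' @param nPlantedUp,nPlantedDown Planted up-/down-regulated gene counts
#'   (ignored when `plantedUp`/`plantedDown` are given). The planted total
#'   must stay below `extremeFraction * nGenes`.
#' @param effectLog2fc Planted case-vs-control shift in log2 units.
#' @param noiseSd Per-sample log2-scale noise s.d.
#' @param nSamplesPerArm Samples per arm (case and control).
#' @param seed Integer seed.
#' @param geneNames Optional explicit gene symbols (length `nGenes`).
#' @param plantedUp,plantedDown Optional explicit planted gene symbols.
#' @param extremeFraction Tail fraction used for the feasibility check.
#' @return List with `datasets` (list of `list(expr, condition)`) and
#'   `truth` (`direction`: named "up"/"down" vector over planted genes).
#' @export
generateCaseControlDatasets <- function(nDatasets = 5, nGenes = 1000,
                                        nPlantedUp = 20, nPlantedDown = 20,
                                        effectLog2fc = 2, noiseSd = 0.2,
                                        nSamplesPerArm = 6, seed = 1L,
                                        geneNames = NULL, plantedUp = NULL,
                                        plantedDown = NULL,
                                        extremeFraction = 0.10) {
  withSeed(seed, {
    if (is.null(geneNames)) geneNames <- sprintf("GENE%04d", seq_len(nGenes))
    stopifnot(length(geneNames) == nGenes, !anyDuplicated(geneNames))
    if (is.null(plantedUp) || is.null(plantedDown)) {
      pick <- sample(geneNames, nPlantedUp + nPlantedDown)
      if (is.null(plantedUp)) plantedUp <- pick[seq_len(nPlantedUp)]
      if (is.null(plantedDown))
        plantedDown <- setdiff(pick, plantedUp)[seq_len(nPlantedDown)]
    }
    stopifnot(all(c(plantedUp, plantedDown) %in% geneNames),
              !length(intersect(plantedUp, plantedDown)))
    if (length(plantedUp) + length(plantedDown) >= extremeFraction * nGenes)
      stop("configuration error: planted genes (",
           length(plantedUp) + length(plantedDown),
           ") must stay below extremeFraction * nGenes (",
           extremeFraction * nGenes, ")")
    shift <- setNames(numeric(nGenes), geneNames)
    shift[plantedUp] <- effectLog2fc
    shift[plantedDown] <- -effectLog2fc
    baseline <- setNames(rnorm(nGenes, 6, 1), geneNames)
    datasets <- vector("list", nDatasets)
    for (d in seq_len(nDatasets)) {
      draw <- function(mu) 2^(mu + rnorm(length(mu), 0, noiseSd))
      ca <- vapply(seq_len(nSamplesPerArm), function(i)
        draw(baseline + shift), numeric(nGenes))
      co <- vapply(seq_len(nSamplesPerArm), function(i)
        draw(baseline), numeric(nGenes))
      expr <- cbind(ca, co)
      dimnames(expr) <- list(geneNames,
                             c(sprintf("case_%d", seq_len(nSamplesPerArm)),
                               sprintf("control_%d", seq_len(nSamplesPerArm))))
      datasets[[d]] <- list(expr = expr,
                            condition = rep(c("case", "control"),
                                            each = nSamplesPerArm))
    }
    truth <- list(direction = setNames(
      c(rep("up", length(plantedUp)), rep("down", length(plantedDown))),
      c(plantedUp, plantedDown)))
    list(datasets = datasets, truth = truth)
  })
}
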