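#' Run the full analysis pipeline from a configuration file
#'
#' Executes the selected stages in dependency order -- `se_calling`,
#' `annotation`, `cooccupancy`, `network`, `expression`, `profiling` --
#' reading inputs named in the YAML configuration and writing one TSV per
#' result into `outDir`, plus a run manifest (`manifest.yaml`) recording
#' the configuration snapshot, per-stage timings, record counts and an md5
#' digest of every output file. Stages fail fast, naming the stage, when a
#' required input is missing.
#'
#' The configuration has two blocks: `params:` ([pipelineConfig()] keys)
#' and `inputs:` with paths `enhancerPeaks` (signal-scored BED for the
#' enhancer-defining cofactor track), `genes` (refFlat), optional
#' `repeats` (BED), `tfPeaks` (factor -> BED map), `tfGeneMap`
#' (factor -> gene symbol map), `expressionA`/`expressionB` (two-condition
#' expression TSVs), `timecourse` (expression TSV, columns in time order),
#' `caseControl` (list of `expr` + `condition` TSV pairs), `orthologs`
#' (two-column TSV) and `reads`/`readsB` (BED3 read placements for one or
#' two cell states).
#'
#' @param configPath Path to the YAML configuration.
#' @param outDir Output directory (created if needed).
#' @param stages Character subset of stages to run (default: all).
#' @return Invisibly, a list with `manifest` and `results` (the in-memory
#'   stage outputs).
#' @export
runPipeline <- function(configPath, outDir,
                        stages = c("se_calling", "annotation", "cooccupancy",
                                   "network", "expression", "profiling")) {
  stages <- match.arg(stages, several.ok = TRUE)
  raw <- yaml::read_yaml(configPath)
  cfg <- do.call(pipelineConfig,
                 raw$params[intersect(names(raw$params),
                                      names(formals(pipelineConfig)))])
  inp <- raw$inputs
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  base <- dirname(normalizePath(configPath))
  resolve <- function(p) {
    if (is.null(p)) return(p)
    bp <- file.path(base, p)
    if (file.exists(bp)) bp else p
  }

  need <- function(stage, keys) {
    for (k in keys) {
      v <- inp[[k]]
      if (is.null(v))
        stop("stage '", stage, "': missing required input '", k, "'")
      paths <- if (k %in% c("tfPeaks")) unlist(v)
               else if (k == "caseControl") unlist(v)
               else if (k == "tfGeneMap") character() else unlist(v)
      for (p in paths)
        if (is.character(p) && !file.exists(resolve(p)))
          stop("stage '", stage, "': input file not found: ", p)
    }
  }
  reqs <- list(
    se_calling = c("enhancerPeaks", "genes"),
    annotation = c("enhancerPeaks", "genes"),
    cooccupancy = c("tfPeaks"),
    network = c("tfPeaks", "genes", "tfGeneMap"),
    expression = c("expressionA", "expressionB", "timecourse",
                   "caseControl", "enhancerPeaks", "genes"),
    profiling = c("reads", "enhancerPeaks", "genes"))
  for (st in stages) need(st, reqs[[st]])

  res <- list()
  timings <- list()
  outputs <- character()
  out <- function(name) {
    p <- file.path(outDir, name)
    outputs <<- c(outputs, p)
    p
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }

  loadEnhancers <- local({
    cache <- NULL
    function() {
      if (!is.null(cache)) return(cache)
      pk <- readPeaks(resolve(inp$enhancerPeaks),
                      factor = inp$enhancerFactor %||% "p300",
                      cellState = inp$cellState %||% "TSC",
                      minSignal = cfg$minSignal)
      if (!is.null(inp$repeats))
        pk <- filterRepeatRegions(pk, readBedIntervals(resolve(inp$repeats)))
      cache <<- pk
      pk
    }
  })
  loadGenes <- local({
    cache <- NULL
    function() {
      if (is.null(cache)) cache <<- readRefFlat(resolve(inp$genes))
      cache
    }
  })
  loadTfPeaks <- function() {
    ps <- lapply(inp$tfPeaks, function(p)
      readPeaks(resolve(p), factor = "tmp"))
    for (nm in names(ps)) if (length(ps[[nm]])) ps[[nm]]$factor <- nm
    ps
  }

  if ("se_calling" %in% stages) timed("se_calling", {
    peaks <- loadEnhancers()
    genes <- loadGenes()
    message("se_calling: ", length(peaks), " peaks in")
    se <- callSuperEnhancers(peaks, genes, cfg)
    writeSeCalls(se, out("se_regions.tsv"), out("se_rank_curve.tsv"))
    assoc <- associateSeGenes(se, genes, cfg$networkWindow)
    writeTsv(assoc, out("se_genes.tsv"))
    message("se_calling: ", sum(seRegions(se)$isSE), " SEs, ",
            length(unique(assoc$gene)), " SE-associated genes")
    res$se <- se
    res$seGenes <- assoc
  })

  if ("annotation" %in% stages) timed("annotation", {
    peaks <- loadEnhancers()
    genes <- loadGenes()
    calls <- classifyPeakFeatures(peaks, genes, cfg)
    writeFeatureCalls(peaks, calls, out("peak_features.tsv"))
    counts <- mapEnhancersToGenes(peaks, genes, cfg)
    writeTsv(data.frame(gene = names(counts), n_enhancers = unname(counts)),
             out("enhancer_gene_counts.tsv"))
    message("annotation: ", nrow(calls), " peaks classified")
    res$featureCalls <- calls
    res$enhancerCounts <- counts
  })

  if ("cooccupancy" %in% stages) timed("cooccupancy", {
    ps <- loadTfPeaks()
    om <- buildUnionSites(ps, cfg$overlapWindow)
    pc <- writeOccupancy(om, out("occupancy_matrix.tsv"),
                         out("correlation.tsv"),
                         out("dendrogram_order.txt"))
    res$occupancy <- om
    res$correlation <- pc
    if (!is.null(res$se)) {
      seGr <- superEnhancers(res$se)
      nf <- countFactorsPerRegion(seGr, ps)
      writeTsv(data.frame(chrom = as.character(seqnames(seGr)),
                          start = bedStart(seGr), end = bedEnd(seGr),
                          n_factors = nf),
               out("se_factor_counts.tsv"))
      res$seFactorCounts <- nf
      message(sprintf(
        "cooccupancy: %.1f%% of SEs co-occupied by >%d factors",
        100 * mean(nf > cfg$cooccupancySeThreshold),
        cfg$cooccupancySeThreshold))
    }
  })

  if ("network" %in% stages) timed("network", {
    ps <- loadTfPeaks()
    genes <- loadGenes()
    trn <- buildTRN(ps, genes, unlist(inp$tfGeneMap), cfg)
    exportEdgeList(trn, out("network_edges.tsv"))
    circ <- findCircuitry(trn)
    writeTsv(data.frame(
      motif = c(rep("autoregulation", length(circ$autoregulators)),
                rep("feedback", nrow(circ$feedbackPairs)),
                rep("feedforward", nrow(circ$feedforwardTriads))),
      members = c(circ$autoregulators,
                  apply(circ$feedbackPairs, 1L, paste, collapse = ","),
                  apply(circ$feedforwardTriads, 1L, paste, collapse = ","))),
      out("circuitry.tsv"))
    thr <- cfg$cooccupancyGeneThreshold
    coreg <- coregulatedGeneSet(trn, thr)
    writeTsv(data.frame(gene = coreg), out("coregulated_genes.tsv"))
    message("network: ", nrow(networkEdges(trn)), " edges, ",
            length(coreg), " genes co-occupied by >", thr, " factors")
    res$trn <- trn
    res$circuitry <- circ
    res$coregulated <- coreg
  })

  if ("expression" %in% stages) timed("expression", {
    genes <- loadGenes()
    counts <- res$enhancerCounts %||%
      mapEnhancersToGenes(loadEnhancers(), genes, cfg)
    exprA <- readExpressionTable(resolve(inp$expressionA))
    exprB <- readExpressionTable(resolve(inp$expressionB))
    ma <- movingAverageEnhancerCounts(exprA, exprB, counts,
                                      window = cfg$maWindow,
                                      pseudocount = cfg$pseudocount)
    writeTsv(ma, out("moving_average.tsv"))
    writeTsv(attr(ma, "ranking"), out("relative_expression_rank.tsv"))
    tc <- readExpressionTable(resolve(inp$timecourse))
    classes <- classifyTimecourse(tc, cfg$nClasses)
    writeTsv(data.frame(gene = names(classes$classOf),
                        class = unname(classes$classOf)),
             out("timecourse_classes.tsv"))
    ## re-entrant: fall back to the se_calling stage's written output
    seAssoc <- res$seGenes
    if (is.null(seAssoc)) {
      sePath <- file.path(outDir, "se_genes.tsv")
      if (!file.exists(sePath))
        stop("stage 'expression': needs se_calling results (run the ",
             "se_calling stage first or keep its se_genes.tsv in outDir)")
      seAssoc <- read.table(sePath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    }
    seGenes <- unique(seAssoc$gene)
    orth <- if (!is.null(inp$orthologs))
      readOrthologMap(resolve(inp$orthologs)) else NULL
    cc <- lapply(inp$caseControl, function(d) {
      cond <- read.table(resolve(d$condition), sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
      list(expr = readExpressionTable(resolve(d$expr)),
           condition = cond[[2L]])
    })
    screen <- crossdatasetDysregulated(cc, seGenes, orth,
                                       cfg$extremeFraction,
                                       cfg$minDatasetHits, cfg$pseudocount)
    writeTsv(screen, out("dysregulated_genes.tsv"))
    message("expression: ", nrow(screen), " dysregulated SE-gene orthologs")
    res$movingAverage <- ma
    res$classes <- classes
    res$screen <- screen
  })

  if ("profiling" %in% stages) timed("profiling", {
    reads <- readReadPlacements(resolve(inp$reads))
    peaks <- loadEnhancers()
    centers <- data.frame(chrom = as.character(seqnames(peaks)),
                          position = peakCenters(peaks))
    prof <- profileAroundCenters(reads, centers, cfg$profileHalfwidth,
                                 cfg$profileBin)
    writeTsv(prof, out("signal_profile.tsv"))
    res$profile <- prof
    if (!is.null(inp$readsB) && !is.null(res$se)) {
      readsB <- readReadPlacements(resolve(inp$readsB))
      seGr <- superEnhancers(res$se)
      relOcc <- vapply(seq_along(seGr), function(i) {
        a <- regionOccupancyScore(readsB, seGr[i])
        b <- regionOccupancyScore(reads, seGr[i])
        relativeOccupancy(a, b, cfg$pseudocount)
      }, numeric(1L))
      writeTsv(data.frame(chrom = as.character(seqnames(seGr)),
                          start = bedStart(seGr), end = bedEnd(seGr),
                          log2_relative_occupancy = relOcc),
               out("relative_occupancy.tsv"))
      res$relativeOccupancy <- relOcc
    }
  })

  manifest <- list(
    tool = "seCircuit",
    version = as.character(packageVersion("seCircuit")),
    rngSeed = cfg$rngSeed,
    params = unclass(cfg),
    stages = timings,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(list(manifest = manifest, results = res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on generated data and score it against truth
#'
#' Generates a complete synthetic fixture suite (enhancer landscape with
#' planted SE clusters, 27 TF peak sets anchored inside the planted SEs,
#' two-condition and time-course expression, five case/control datasets
#' with planted dysregulated SE-gene orthologs, and read placements for
#' two cell states), writes the fixtures and a configuration under
#' `outDir/inputs`, runs [runPipeline()] on them, and writes a recovery
#' report comparing the outputs with the generator truth. Fully
#' deterministic given `seed`.
#'
#' @param seed Integer seed driving every generator.
#' @param outDir Output directory.
#' @param nFactors Number of synthetic TF tracks (default 27).
#' @return Invisibly, a list with `manifest`, `results`, `truth` and
#'   `report` (named numeric recovery metrics).
#' @export
runDemo <- function(seed = 1L, outDir, nFactors = 27L) {
  dir.create(file.path(outDir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  ## fixture files are written under outDir but referenced relative to the
  ## config, so two runs into different directories stay byte-identical
  ip <- function(name) file.path(outDir, "inputs", name)
  rp <- function(name) file.path("inputs", name)
  spec <- syntheticLandscapeSpec(seed = seed)
  genes <- generateAnnotation(spec)
  land <- generateEnhancerLandscape(spec, genes)
  writePeaks(land$peaks, ip("p300_TSC.bed"))
  writeRefFlat(genes, ip("genes.refflat"))

  ## TF tracks: 3 anchors inside each planted SE + background shared sites
  planted <- land$truth$plantedSeIntervals
  inSe <- withSeed(seed + 2L, unlist(lapply(seq_along(planted), function(i) {
    s <- bedStart(planted)[i]; e <- bedEnd(planted)[i]
    sort(sample(seq(s + 200, e - 200, by = 400), 3L))
  })))
  bg <- withSeed(seed + 20L,
                 (sample.int(floor(spec$chromLength / 2500), 150L) - 1) *
                   2500 + 1250)
  bg <- bg[vapply(bg, function(p) all(abs(p - inSe) > 1000), logical(1L))]
  anchors <- as.numeric(c(inSe, bg))
  tf <- generateTfPeakSets(nFactors = nFactors,
                           nSharedSites = length(anchors),
                           cooccupancyRate = 0.8,
                           privateSitesPerFactor = 20, seed = seed + 3L,
                           chromLength = spec$chromLength, anchors = anchors)
  tfPaths <- list()
  for (nm in names(tf$peaksets)) {
    writePeaks(tf$peaksets[[nm]], ip(paste0(nm, "_TSC.bed")))
    tfPaths[[nm]] <- rp(paste0(nm, "_TSC.bed"))
  }

  ## SE-associated genes name the TF genes (SE-predicted TFs)
  seTmp <- callSuperEnhancers(land$peaks, genes, pipelineConfig())
  assocTmp <- associateSeGenes(seTmp, genes)
  seGeneSyms <- unique(assocTmp$gene)
  tfGenes <- rep_len(c(seGeneSyms,
                       setdiff(genes$symbol, seGeneSyms)), nFactors)
  tfGeneMap <- as.list(setNames(tfGenes, names(tf$peaksets)))

  ## two-condition expression coupled to enhancer counts
  counts <- mapEnhancersToGenes(land$peaks, genes, pipelineConfig())
  exprTables <- withSeed(seed + 4L, {
    b <- 2^rnorm(length(counts), 6, 1)
    a <- b * 2^(0.25 * counts + rnorm(length(counts), 0, 0.3))
    list(a = setNames(a, names(counts)), b = setNames(b, names(counts)))
  })
  writeExpressionTable(matrix(exprTables$a, ncol = 1,
                              dimnames = list(names(counts), "TSC")),
                       ip("expression_TSC.tsv"))
  writeExpressionTable(matrix(exprTables$b, ncol = 1,
                              dimnames = list(names(counts), "ESC")),
                       ip("expression_ESC.tsv"))

  tc <- generateTimecourseExpression(nGenesPerClass = 50, nTimepoints = 7,
                                     noiseSd = 0.1, seed = seed + 5L)
  writeExpressionTable(tc$expr, ip("timecourse.tsv"))

  ## case/control: plant dysregulation among SE-gene orthologs
  human <- toupper(genes$symbol)
  writeTsv(data.frame(mouse_symbol = genes$symbol, human_symbol = human),
           ip("orthologs.tsv"))
  seHuman <- sort(toupper(seGeneSyms), method = "radix")
  nPlant <- min(4L, length(seHuman) %/% 2L)
  plantedUp <- seHuman[seq_len(nPlant)]
  plantedDown <- seHuman[nPlant + seq_len(nPlant)]
  cc <- generateCaseControlDatasets(
    nDatasets = 5, nGenes = length(human), effectLog2fc = 2, noiseSd = 0.2,
    seed = seed + 6L, geneNames = sort(human, method = "radix"),
    plantedUp = plantedUp, plantedDown = plantedDown)
  ccInputs <- list()
  for (d in seq_along(cc$datasets)) {
    writeExpressionTable(cc$datasets[[d]]$expr,
                         ip(sprintf("case_control_%d.tsv", d)))
    writeTsv(data.frame(sample = colnames(cc$datasets[[d]]$expr),
                        condition = cc$datasets[[d]]$condition),
             ip(sprintf("case_control_%d_conditions.tsv", d)))
    ccInputs[[d]] <- list(expr = rp(sprintf("case_control_%d.tsv", d)),
                          condition = rp(sprintf(
                            "case_control_%d_conditions.tsv", d)))
  }

  ## read placements: TSC covers all planted SEs, dTSC loses half of them
  readPaths <- withSeed(seed + 7L, {
    clusterCenters <- peakCenters(land$peaks)[grepl("_clu",
                                                    land$peaks$name)]
    mk <- function(keepFrac) {
      keep <- clusterCenters[seq_len(floor(length(clusterCenters) *
                                             keepFrac))]
      fg <- round(rnorm(15000, sample(keep, 15000, replace = TRUE), 400))
      bgr <- round(runif(5000, 0, spec$chromLength - 1))
      pos <- pmax(c(fg, bgr), 0)
      data.frame(chrom = "chr1", position = sort(pos))
    }
    list(TSC = mk(1), dTSC = mk(0.5))
  })
  for (st in names(readPaths)) {
    df <- readPaths[[st]]
    write.table(data.frame(df$chrom, df$position, df$position + 1),
                ip(paste0("reads_", st, ".bed")), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }

  config <- list(
    params = unclass(pipelineConfig(rngSeed = seed)),
    inputs = list(
      enhancerPeaks = rp("p300_TSC.bed"), enhancerFactor = "p300",
      cellState = "TSC", genes = rp("genes.refflat"),
      tfPeaks = tfPaths, tfGeneMap = tfGeneMap,
      expressionA = rp("expression_TSC.tsv"),
      expressionB = rp("expression_ESC.tsv"),
      timecourse = rp("timecourse.tsv"),
      caseControl = ccInputs, orthologs = rp("orthologs.tsv"),
      reads = rp("reads_TSC.bed"), readsB = rp("reads_dTSC.bed")))
  configPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, configPath)

  run <- runPipeline(configPath, outDir)
  truth <- list(landscape = land$truth, tf = tf$truth,
                timecourse = tc$truth, caseControl = cc$truth)
  report <- scoreDemo(run$results, truth, pipelineConfig())
  writeTsv(data.frame(metric = names(report), value = unname(report)),
           file.path(outDir, "recovery_report.tsv"))
  invisible(list(manifest = run$manifest, results = run$results,
                 truth = truth, report = report))
}

## Score pipeline outputs against generator truth.
scoreDemo <- function(res, truth, cfg) {
  se <- superEnhancers(res$se)
  planted <- truth$landscape$plantedSeIntervals
  key <- function(gr) paste(seqnames(gr), bedStart(gr), bedEnd(gr))
  plantedCalled <- mean(key(planted) %in% key(se))
  sePrecision <- mean(key(se) %in% key(planted))
  acc <- mean(res$classes$classOf[names(truth$timecourse$classLabels)] ==
                truth$timecourse$classLabels)
  called <- res$screen$gene
  trueSet <- names(truth$caseControl$direction)
  tp <- intersect(called, trueSet)
  dirOk <- all(res$screen$direction[match(tp, called)] ==
                 truth$caseControl$direction[tp])
  c(n_stitched_regions = length(seRegions(res$se)),
    n_superenhancers = length(se),
    planted_se_recovery = plantedCalled,
    se_precision = sePrecision,
    n_se_genes = length(unique(res$seGenes$gene)),
    frac_se_cooccupied = mean(res$seFactorCounts >
                                cfg$cooccupancySeThreshold),
    n_network_edges = nrow(networkEdges(res$trn)),
    n_coregulated_genes = length(res$coregulated),
    n_autoregulators = length(res$circuitry$autoregulators),
    n_feedback_pairs = nrow(res$circuitry$feedbackPairs),
    n_feedforward_triads = nrow(res$circuitry$feedforwardTriads),
    timecourse_accuracy = acc,
    screen_precision = if (length(called))
      length(tp) / length(called) else NA_real_,
    screen_recall = length(tp) / length(trueSet),
    screen_direction_ok = as.numeric(dirOk),
    moving_average_spearman = cor(res$movingAverage$rank,
                                  res$movingAverage$meanEnhancers,
                                  method = "spearman"))
}
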