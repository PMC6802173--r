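test_that("feature hierarchy resolves promoter, upstream and precedence", {
  geneA <- makeGene("GeneA", 100000, 150000, "+",
                    exons = list(c(100000, 101000), c(149000, 150000)))
  geneB <- makeGene("GeneB", 95000, 99000, "+")
  genes <- c(geneA, geneB)
  cfg <- pipelineConfig()

  ## center 99000: |99000 - 100000| = 1000 -> promoter of GeneA
  ## center 85000: 15000 bp 5' of GeneA tss -> upstream
  ## center 120000: inside GeneA body, no exon -> intron
  ## center 100500: promoter wins over exon (precedence)
  p <- makePeaks(c(98900, 84900, 119900, 100400, 300000),
                 c(99100, 85100, 120100, 100600, 300100))
  calls <- classifyPeakFeatures(p, genes, cfg)
  expect_equal(as.character(calls$feature),
               c("promoter", "upstream", "intron", "promoter", "intergenic"))
  expect_equal(calls$gene[1:4], c("GeneA", "GeneA", "GeneA", "GeneA"))
  expect_true(is.na(calls$gene[5]))

  ## strand-aware upstream: 5' of a minus-strand gene is to the right
  gm <- makeGene("GeneM", 100000, 150000, "-")    # tss 149999
  up <- makePeaks(160000, 160200)                 # 10 kb 5' on '-'
  expect_equal(as.character(classifyPeakFeatures(up, gm, cfg)$feature),
               "upstream")
  down <- makePeaks(90000, 90200)                 # 3' of the '-' gene
  expect_equal(as.character(classifyPeakFeatures(down, gm, cfg)$feature),
               "intergenic")
})

test_that("feature classification matches the brute-force oracle", {
  spec <- syntheticLandscapeSpec(nGenes = 50, seed = 17)
  genes <- generateAnnotation(spec)
  set.seed(18)
  n <- 300
  st <- sample.int(spec$chromLength - 1000, n)
  p <- makePeaks(st, st + sample(200:800, n, replace = TRUE))
  calls <- classifyPeakFeatures(p, genes, pipelineConfig())
  centers <- peakCenters(p)
  for (i in seq_len(n)) {
    o <- featureOracle(centers[i], "chr1", genes)
    expect_equal(as.character(calls$feature[i]), o$feature)
    if (o$feature != "intergenic") expect_equal(calls$gene[i], o$gene)
  }
})

test_that("enhancer-to-gene counts follow upstream+body rule and oracle", {
  gp <- makeGene("GeneP", 100000, 120000, "+")
  cfg <- pipelineConfig()
  ## 10 kb upstream counts; 10 kb downstream of tx_end does not; body does
  p <- makePeaks(c(89900, 129900, 110000), c(90100, 130100, 110200))
  counts <- mapEnhancersToGenes(p, gp, cfg)
  expect_equal(unname(counts["GeneP"]), 2L)

  ## quadratic oracle over a random fixture
  spec <- syntheticLandscapeSpec(nGenes = 30, seed = 19)
  genes <- generateAnnotation(spec)
  set.seed(20)
  st <- sample.int(spec$chromLength - 1000, 200)
  pk <- makePeaks(st, st + 400)
  counts <- mapEnhancersToGenes(pk, genes, cfg)
  centers <- peakCenters(pk)
  g <- canonicalTranscripts(genes)
  oracle <- setNames(integer(length(g)), g$symbol)
  for (i in seq_along(g)) {
    tss <- g$tss[i]; s <- start(g)[i] - 1L; e <- end(g)[i]
    plus <- as.character(strand(g))[i] == "+"
    for (c0 in centers) {
      d <- if (plus) tss - c0 else c0 - tss
      if ((d > 0 && d <= 20000) || (c0 >= s && c0 < e))
        oracle[i] <- oracle[i] + 1L
    }
  }
  expect_identical(counts[names(oracle)], oracle)
})

test_that("target-gene assignment uses extended span then nearest fallback", {
  genes <- c(makeGene("GeneA", 100000, 110000, "+"),
             makeGene("GeneB", 300000, 310000, "+"))
  cfg <- pipelineConfig()
  expect_equal(assignTargetGenes(makePeaks(105000, 105200), genes, cfg),
               list("GeneA"))                    # inside body
  ## 30 kb from GeneA's span, 160 kb from GeneB's -> nearest fallback to A
  expect_equal(assignTargetGenes(makePeaks(139900, 140100), genes, cfg),
               list("GeneA"))
  ## within both extended spans -> both targets
  genes2 <- c(makeGene("GeneA", 100000, 110000, "+"),
              makeGene("GeneB", 115000, 125000, "+"))
  expect_equal(assignTargetGenes(makePeaks(112000, 112400), genes2, cfg),
               list(c("GeneA", "GeneB")))
  ## equidistant TSSs (50 kb) and tied body distances -> lexicographic
  ## tie-break picks the smaller symbol
  twins <- c(makeGene("GeneZ", 50000, 60000, "+"),     # tss 50000
             makeGene("GeneY", 140001, 150001, "-"))   # tss 150000
  pick <- assignTargetGenes(makePeaks(99900, 100100), twins,
                            pipelineConfig(networkWindow = 100))
  expect_equal(pick, list("GeneY"))
  suppressWarnings(
    expect_error(assignTargetGenes(makePeaks(1, 100, chrom = "chrZ"),
                                   genes, cfg), "no gene on chromosome"))
})
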