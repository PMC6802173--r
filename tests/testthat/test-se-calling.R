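test_that("TSS exclusion drops only fully contained peaks", {
  g <- makeGene("GeneA", 50000, 60000, "+")      # tss 50000
  p <- makePeaks(c(48000, 46000, 49000), c(52000, 49000, 53000))
  expect_message(kept <- excludeTssPeaks(p, g, 2500), "1 peak")
  ## [48000,52000) contained in [47500,52500) -> removed;
  ## [46000,49000) and [49000,53000) only partially overlap -> retained
  expect_identical(kept$name, c("pk2", "pk3"))
  expect_identical(excludeTssPeaks(p, g, 0), p)   # zero zone = identity
})

test_that("stitching merges by gap and matches the closure oracle", {
  p <- makePeaks(c(1000, 10000), c(1600, 10600))   # gap 8400 <= 12500
  r <- stitchPeaks(p, 12500)
  expect_length(r, 1)
  expect_equal(c(GenomicRanges::start(r), GenomicRanges::end(r)),
               c(1001, 10600))
  expect_equal(r$totalSignal, 2)

  p2 <- makePeaks(c(0, 20000), c(500, 20500))      # gap 19500 > 12500
  expect_length(stitchPeaks(p2, 12500), 2)
  expect_error(stitchPeaks(makePeaks(numeric(), numeric())), "empty")

  ## 50 random peaks vs O(n^2) transitive-closure oracle, several seeds
  for (s in 1:5) {
    set.seed(s)
    n <- 50
    st <- sample.int(3e5, n)
    en <- st + sample(100:5000, n, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    sig <- rexp(n, 1 / 5)
    p <- makePeaks(st, en, signal = sig, chrom = chrom)
    r <- stitchPeaks(p, 12500)
    o <- stitchOracle(chrom, st, en, sig, 12500)
    expect_equal(as.character(seqnames(r)), o$chrom)
    expect_equal(GenomicRanges::start(r) - 1L, o$start)
    expect_equal(GenomicRanges::end(r), o$end)
    expect_equal(r$totalSignal, o$total)
  }
})

test_that("stitching is idempotent and order-invariant", {
  set.seed(9)
  n <- 80
  st <- sample.int(5e5, n)
  p <- makePeaks(st, st + 300, signal = rexp(n))
  r <- stitchPeaks(p, 12500)
  ## re-feed regions as peaks
  r2in <- r
  r2in$signal <- r$totalSignal
  r2 <- stitchPeaks(r2in, 12500)
  expect_equal(granges(r2), granges(r))
  expect_equal(r2$totalSignal, r$totalSignal)
  ## permutation invariance
  perm <- sample(n)
  rp <- stitchPeaks(p[perm], 12500)
  expect_equal(granges(rp), granges(r))
  expect_equal(rp$totalSignal, r$totalSignal)
  ## conservation of signal
  expect_equal(sum(r$totalSignal), sum(p$signal))
})

test_that("elbow cutoff reproduces the worked example and oracle", {
  sig <- c(rep(1, 8), 40, 60)
  gr <- makePeaks((0:9) * 1e5, (0:9) * 1e5 + 1000)
  gr$totalSignal <- sig
  gr$nPeaks <- 1L
  res <- rankAndCutoff(gr)
  expect_equal(sum(seRegions(res)$isSE), 2)       # top 2 are SEs
  expect_equal(cutoffSignal(res), 1)
  expect_equal(cutoffIndex(res), 8L)

  flat <- gr
  flat$totalSignal <- rep(5, 10)
  expect_error(rankAndCutoff(flat), "degenerate")
  expect_error(rankAndCutoff(gr[1:2]), "insufficient")
})

test_that("SE partition is consistent: every SE outranks every typical", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:80, 1)
    gr <- makePeaks((seq_len(n) - 1) * 1e5, (seq_len(n) - 1) * 1e5 + 500)
    gr$totalSignal <- c(rexp(n - 3, 1 / 5), rexp(3, 1 / 80))
    gr$nPeaks <- 1L
    res <- rankAndCutoff(gr)
    se <- superEnhancers(res); ty <- typicalEnhancers(res)
    expect_true(length(se) >= 1)
    if (length(ty))
      expect_gt(min(se$totalSignal), max(ty$totalSignal))
    o <- elbowOracle(gr$totalSignal)
    expect_equal(length(se), o$nSE)
  }
})

test_that("appending a region below the minimum never shrinks the SE set", {
  for (s in 1:50) {
    set.seed(s)
    sig <- c(rexp(30, 1 / 5), rexp(5, 1 / 50))
    n1 <- elbowOracle(sig)$nSE
    gr <- makePeaks((seq_along(sig) - 1) * 1e5,
                    (seq_along(sig) - 1) * 1e5 + 500)
    gr$totalSignal <- sig; gr$nPeaks <- 1L
    expect_equal(sum(seRegions(rankAndCutoff(gr))$isSE), n1)
    sig2 <- c(sig, min(sig) / 2)
    gr2 <- makePeaks((seq_along(sig2) - 1) * 1e5,
                     (seq_along(sig2) - 1) * 1e5 + 500)
    gr2$totalSignal <- sig2; gr2$nPeaks <- 1L
    expect_gte(sum(seRegions(rankAndCutoff(gr2))$isSE), n1)
  }
})

test_that("SE-gene association covers overlap, fallback and many-to-many", {
  genes <- c(makeGene("GeneA", 125000, 140000, "+"),
             makeGene("GeneB", 200000, 210000, "+"),
             makeGene("GeneC", 118000, 123000, "-"))
  se <- GRanges("chr1", IRanges(100001, 130000))  # bed [100000, 130000)
  a <- associateSeGenes(se, genes, 20000)
  expect_setequal(a$gene, c("GeneA", "GeneC"))    # both extended spans hit

  ## nearest-TSS fallback
  far <- GRanges("chr1", IRanges(500001, 510000))
  b <- associateSeGenes(far, genes, 20000)
  expect_equal(b$gene, "GeneB")                   # tss 200000 is nearest
  expect_equal(b$mode, "nearest")

  ## SE on a geneless chromosome warns on the disjoint vocabulary and is
  ## excluded with a message
  lost <- GRanges("chrX", IRanges(1, 1000))
  ws <- capture_warnings(
    expect_message(z <- associateSeGenes(lost, genes), "no gene on"))
  expect_match(ws, "disjoint chromosome", all = FALSE)
  expect_equal(nrow(z), 0)
})

test_that("full SE call conserves signal through stitching", {
  spec <- syntheticLandscapeSpec(nGenes = 60, seed = 13)
  g <- generateAnnotation(spec)
  land <- generateEnhancerLandscape(spec, g)
  suppressMessages(kept <- excludeTssPeaks(land$peaks, g, 2500))
  r <- stitchPeaks(kept, 12500)
  expect_equal(sum(r$totalSignal), sum(kept$signal))
})
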