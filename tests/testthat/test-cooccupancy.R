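test_that("center overlap is a strict 500-bp window on one chromosome", {
  a <- makePeaks(0, 200)                      # center 100
  expect_true(centersOverlap(a, makePeaks(450, 650)))     # centers 100/550
  expect_false(centersOverlap(a, makePeaks(600, 800)))    # delta 600
  expect_true(centersOverlap(a, makePeaks(0, 200)))       # identical
  expect_false(centersOverlap(a, makePeaks(0, 200, chrom = "chr2")))
  expect_false(centersOverlap(a, makePeaks(400, 800)))    # delta exactly 500
})

test_that("union sites merge identical sets into all-ones rows", {
  p <- makePeaks(c(1000, 5000, 9000), c(1400, 5400, 9400))
  om <- buildUnionSites(list(A = p, B = p))
  m <- SummarizedExperiment::assay(om, "occupancy")
  expect_equal(dim(m), c(3L, 2L))
  expect_true(all(m == 1L))

  ## different chromosomes give disjoint (block) structure
  q <- makePeaks(c(1000, 5000), c(1400, 5400), chrom = "chr2")
  om2 <- buildUnionSites(list(A = p, B = q))
  m2 <- SummarizedExperiment::assay(om2, "occupancy")
  expect_equal(nrow(m2), 5L)
  expect_true(all(rowSums(m2) == 1L))
})

test_that("union sites match the pairwise-closure oracle and ignore order", {
  for (s in 1:5) {
    set.seed(s)
    mk <- function(f) {
      st <- sample.int(20000, 30)
      makePeaks(st, st + 200, factor = f)
    }
    ps <- list(A = mk("A"), B = mk("B"), C = mk("C"))
    om <- buildUnionSites(ps, 500)
    m <- SummarizedExperiment::assay(om, "occupancy")

    ## oracle: transitive closure of |center_i - center_j| < 500
    all <- c(ps$A, ps$B, ps$C)
    ctr <- peakCenters(all)
    n <- length(all)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n))
        if (abs(ctr[i] - ctr[j]) < 500 && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      if (!changed) break
    }
    sites <- sort(unique(vapply(split(ctr, comp), min, numeric(1))))
    expect_equal(nrow(m), length(sites))
    oracleRows <- t(vapply(split(seq_len(n), comp), function(idx)
      as.integer(c("A", "B", "C") %in% all$factor[idx]), integer(3)))
    oracleRows <- oracleRows[order(vapply(split(ctr, comp), min,
                                          numeric(1))), , drop = FALSE]
    expect_equal(unname(m), unname(oracleRows))

    ## invariance to list order and within-set shuffling
    ps2 <- list(C = ps$C[sample(30)], A = ps$A[sample(30)],
                B = ps$B[sample(30)])
    om2 <- buildUnionSites(ps2, 500)
    expect_equal(SummarizedExperiment::assay(om2, "occupancy"), m)
    expect_equal(granges(SummarizedExperiment::rowRanges(om2)),
                 granges(SummarizedExperiment::rowRanges(om)))
  }
})

test_that("pairwise correlation handles identity, opposition and NAs", {
  p <- makePeaks(c(1000, 5000, 9000, 13000), c(1200, 5200, 9200, 13200))
  q <- makePeaks(c(20000, 24000), c(20200, 24200))
  ## identical peak lists correlate at exactly 1 (universe widened by a
  ## third factor; over their own union alone both columns are constant
  ## and r is undefined)
  om <- buildUnionSites(list(A = p, B = p, C = q))
  pc <- pairwiseCorrelation(om)
  expect_equal(pc$r["A", "B"], 1)
  expect_equal(diag(pc$r), c(A = 1, B = 1, C = 1))

  ## complementary binding: TF1 on sites 1-2, TF2 on sites 3-4 -> r = -1
  om2 <- buildUnionSites(list(TF1 = p[1:2], TF2 = p[3:4]))
  pc2 <- pairwiseCorrelation(om2)
  expect_equal(pc2$r["TF1", "TF2"], -1)

  ## a factor bound everywhere has zero variance -> NA, excluded from order
  om3 <- buildUnionSites(list(A = p, B = p[1:2], D = p[3:4]))
  m3 <- SummarizedExperiment::assay(om3, "occupancy")
  expect_true(all(m3[, "A"] == 1L))
  pc3 <- pairwiseCorrelation(om3)
  expect_true(is.na(pc3$r["A", "B"]))
  expect_false(is.na(pc3$r["B", "D"]))
  ## correlation table is symmetric with entries in [-1, 1]
  expect_equal(pc3$r, t(pc3$r))
  expect_true(all(abs(pc3$r[!is.na(pc3$r)]) <= 1))
})

test_that("correlated factors cluster closer than uncorrelated ones", {
  wins <- 0L
  for (s in 1:20) {
    tf <- generateTfPeakSets(3, 200, c(0.9, 0.9, 0.1), 5, seed = s)
    pc <- pairwiseCorrelation(buildUnionSites(tf$peaksets))
    if (pc$r["TF01", "TF02"] > pc$r["TF01", "TF03"]) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("factor counting per region counts distinct factors only", {
  region <- GRanges("chr1", IRanges(1, 10000))
  ps <- list(A = makePeaks(c(1000, 2000, 3000), c(1100, 2100, 3100),
                           factor = "A"),
             B = makePeaks(5000, 5100, factor = "B"),
             C = makePeaks(20000, 20100, factor = "C"))
  expect_equal(countFactorsPerRegion(region, ps), 2L)  # A counted once
  expect_equal(countFactorsPerRegion(GRanges("chr1", IRanges(50000, 60000)),
                                     ps), 0L)
})
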