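test_that("moving average slides over the ranked count sequence", {
  a <- c(g1 = 8, g2 = 4, g3 = 2, g4 = 1)
  b <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)
  counts <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  ma <- movingAverageEnhancerCounts(a, b, counts, window = 3)
  expect_equal(ma$meanEnhancers, c(2, 3))
  expect_equal(attr(ma, "ranking")$gene, c("g1", "g2", "g3", "g4"))

  ## constant counts give a constant series
  mac <- movingAverageEnhancerCounts(a, b, c(g1 = 5, g2 = 5, g3 = 5, g4 = 5),
                                     window = 2)
  expect_true(all(mac$meanEnhancers == 5))
  expect_error(movingAverageEnhancerCounts(a, b, counts, window = 5),
               "window")

  ## depends only on the ranked count sequence, not on gene labels
  a2 <- setNames(a, c("x1", "x2", "x3", "x4"))
  b2 <- setNames(b, names(a2)); c2 <- setNames(counts, names(a2))
  expect_equal(movingAverageEnhancerCounts(a2, b2, c2, 3)$meanEnhancers,
               ma$meanEnhancers)
})

test_that("rank ties break lexicographically by symbol", {
  a <- c(zz = 2, aa = 2, mm = 2)
  b <- c(zz = 1, aa = 1, mm = 1)
  r <- rankRelativeExpression(a, b)
  expect_equal(r$gene, c("aa", "mm", "zz"))
})

test_that("enhancer-rich genes surface at the top of the ranking", {
  ## genes generated with counts increasing in true relative expression:
  ## windowed means must decrease along the ranking (strong negative rank
  ## correlation), mirroring the enhancer-number/activity coupling
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    counts <- setNames(rpois(n, 2) + round(seq(0, 8, length.out = n)),
                       sprintf("g%03d", seq_len(n)))
    b <- setNames(2^rnorm(n, 6, 1), names(counts))
    a <- b * 2^(0.4 * counts + rnorm(n, 0, 0.3))
    ma <- movingAverageEnhancerCounts(a, b, counts, window = 50)
    cor(ma$rank, ma$meanEnhancers, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos < -0.9))
})

test_that("relative time-course rows average to one", {
  m <- rbind(flat = c(2, 2, 2, 2), ramp = c(0, 4, 0, 4))
  r <- relativeTimecourse(m)
  expect_equal(unname(r["flat", ]), c(1, 1, 1, 1))
  expect_equal(unname(rowMeans(r)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(relativeTimecourse(rbind(g = c(0, 4)))[1, ]), c(0, 2))
  m2 <- rbind(ok = c(1, 2), dead = c(0, 0))
  expect_warning(r2 <- relativeTimecourse(m2), "all-zero")
  expect_equal(rownames(r2), "ok")
  set.seed(1)
  big <- matrix(rexp(700), 100, 7,
                dimnames = list(sprintf("g%d", 1:100), NULL))
  expect_true(all(abs(rowMeans(relativeTimecourse(big)) - 1) < 1e-9))
})

test_that("noiseless archetypes classify into their own labelled classes", {
  g <- generateTimecourseExpression(1, 7, noiseSd = 0, seed = 1)
  cls <- classifyTimecourse(g$expr, 4)
  expect_equal(unname(cls$classOf[names(g$truth$classLabels)]),
               unname(g$truth$classLabels))
  one <- classifyTimecourse(g$expr, 1)
  expect_true(all(one$classOf == 1L))
  expect_error(classifyTimecourse(g$expr[1:2, ], 4), "fewer genes")
  ## correlation distance refuses zero-variance (flat) profiles by name
  expect_error(classifyTimecourse(g$expr, 4, distance = "correlation"),
               "degenerate")
})

test_that("noisy archetype classes are recovered against truth", {
  for (s in 1:3) {
    g <- generateTimecourseExpression(30, 7, noiseSd = 0.1, seed = s)
    cls <- classifyTimecourse(g$expr, 4)
    acc <- mean(cls$classOf[names(g$truth$classLabels)] ==
                  g$truth$classLabels)
    expect_gte(acc, 0.95)
  }
})

test_that("dysregulation screen applies decile and hit-count rules", {
  ## hand-built: 20 genes, 10% tails -> 2 genes per tail per dataset.
  ## gA tops 3 of 5 datasets (selected, up); gB tops only 2 (dropped);
  ## gC bottoms 4 of 5 (selected, down).
  genes <- sprintf("g%02d", 1:20)
  mkds <- function(topGenes, bottomGenes) {
    ratio <- setNames(rep(1, 20), genes)
    ratio[topGenes] <- c(9, 8)[seq_along(topGenes)]
    ratio[bottomGenes] <- 0.1
    expr <- cbind(case = 100 * ratio, control = rep(100, 20))
    rownames(expr) <- genes
    list(expr = expr, condition = c("case", "control"))
  }
  ds <- list(mkds(c("g01", "g02"), "g03"),   # gA=g01, gB=g02, gC=g03
             mkds(c("g01", "g02"), "g03"),
             mkds(c("g01", "g04"), "g03"),
             mkds(c("g05", "g06"), "g03"),
             mkds(c("g07", "g08"), "g09"))
  out <- crossdatasetDysregulated(ds, seGenes = genes, minHits = 3)
  expect_true("g01" %in% out$gene)
  expect_equal(out$direction[out$gene == "g01"], "up")
  expect_false("g02" %in% out$gene)
  expect_true("g03" %in% out$gene)
  expect_equal(out$direction[out$gene == "g03"], "down")

  ## monotone: raising minHits never adds a gene
  out4 <- crossdatasetDysregulated(ds, seGenes = genes, minHits = 4)
  expect_true(all(out4$gene %in% out$gene))
  ## gene not SE-associated is never reported
  outNoSe <- crossdatasetDysregulated(ds, seGenes = c("g02"), minHits = 3)
  expect_equal(nrow(outNoSe), 0)
  expect_error(crossdatasetDysregulated(ds[1:2], genes, minHits = 3),
               "fewer datasets")
  expect_warning(
    crossdatasetDysregulated(ds, "gX", orthologs = c(gY = "gY"),
                             minHits = 3),
    "no SE-associated genes")
})

test_that("ortholog mapping routes SE genes into the datasets' namespace", {
  g <- generateCaseControlDatasets(5, 200, 5, 5, effectLog2fc = 2,
                                   noiseSd = 0.1, seed = 6)
  planted <- names(g$truth$direction)
  mouse <- paste0("m_", planted)
  orth <- setNames(planted, mouse)
  out <- crossdatasetDysregulated(g$datasets, seGenes = mouse,
                                  orthologs = orth, minHits = 3)
  expect_setequal(out$gene, planted)
  expect_equal(setNames(out$direction, out$gene)[planted],
               g$truth$direction[planted])
})
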