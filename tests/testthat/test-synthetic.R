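test_that("generators are pure functions of (spec, seed)", {
  spec <- syntheticLandscapeSpec(nGenes = 40, seed = 11)
  g1 <- generateAnnotation(spec); g2 <- generateAnnotation(spec)
  expect_identical(g1, g2)
  l1 <- generateEnhancerLandscape(spec, g1)
  l2 <- generateEnhancerLandscape(spec, g1)
  expect_identical(l1, l2)
  t1 <- generateTfPeakSets(3, 50, 0.5, 10, seed = 2)
  t2 <- generateTfPeakSets(3, 50, 0.5, 10, seed = 2)
  expect_identical(t1, t2)
  e1 <- generateTimecourseExpression(5, 7, 0.1, seed = 3)
  e2 <- generateTimecourseExpression(5, 7, 0.1, seed = 3)
  expect_identical(e1, e2)
  c1 <- generateCaseControlDatasets(2, 100, 3, 3, seed = 4)
  c2 <- generateCaseControlDatasets(2, 100, 3, 3, seed = 4)
  expect_identical(c1, c2)
  ## generators leave the caller's RNG stream untouched
  set.seed(99); before <- .Random.seed
  invisible(generateAnnotation(spec))
  expect_identical(.Random.seed, before)
})

test_that("annotation generator respects counts and capacity", {
  expect_length(generateAnnotation(syntheticLandscapeSpec(nGenes = 0)), 0)
  spec <- syntheticLandscapeSpec(nGenes = 25, seed = 8)
  g <- generateAnnotation(spec)
  expect_length(g, 25)
  ## non-overlapping, exons inside transcripts
  expect_false(any(countOverlaps(g, g) > 1))
  for (i in seq_along(g)) {
    ex <- g$exons[[i]]
    expect_true(all(start(ex) >= start(g)[i] & end(ex) <= end(g)[i]))
    expect_true(all(diff(start(ex)) > 0))
  }
  tiny <- syntheticLandscapeSpec(nGenes = 1000, chromLength = 1e5)
  expect_error(generateAnnotation(tiny), "capacity")
})

test_that("landscape generator plants the advertised structure", {
  spec <- syntheticLandscapeSpec(nGenes = 40, seed = 21)
  g <- generateAnnotation(spec)
  land <- generateEnhancerLandscape(spec, g)
  expect_length(land$peaks, 200 + 10 * 8)
  expect_length(land$truth$plantedSeIntervals, 10)
  ## clusters clear of every TSS exclusion zone
  planted <- land$truth$plantedSeIntervals
  for (i in seq_along(planted)) {
    d <- abs(g$tss - floor((start(planted)[i] + end(planted)[i]) / 2))
    near <- g$tss >= start(planted)[i] - 1 - spec$tssExclusion &
      g$tss <= end(planted)[i] + spec$tssExclusion
    expect_false(any(near))
  }
  none <- generateEnhancerLandscape(
    syntheticLandscapeSpec(nGenes = 0, nSeClusters = 0, seed = 1))
  expect_length(none$truth$plantedSeIntervals, 0)
})

test_that("cluster peaks outscore typical peaks across seeded draws", {
  ## Monte-Carlo check of the 10x signal separation
  wins <- 0L
  for (s in 1:100) {
    spec <- syntheticLandscapeSpec(nGenes = 0, nTypical = 50,
                                   nSeClusters = 3, seed = s)
    land <- generateEnhancerLandscape(spec)
    clu <- grepl("_clu", land$peaks$name)
    if (mean(land$peaks$signal[clu]) > mean(land$peaks$signal[!clu]))
      wins <- wins + 1L
  }
  expect_gte(wins, 99L)
})

test_that("TF peak sets honor the co-occupancy rate", {
  full <- generateTfPeakSets(4, 50, 1, 0, seed = 1)
  expect_true(all(full$truth$indicator == 1L))
  expect_true(all(lengths(full$peaksets) == 50L))
  none <- generateTfPeakSets(4, 50, 0, 5, seed = 1)
  expect_true(all(none$truth$indicator == 0L))
  expect_true(all(lengths(none$peaksets) == 5L))   # only private peaks
  ## binomial oracle: empirical binding fraction within 3 s.e. of 0.7
  big <- generateTfPeakSets(1, 1000, 0.7, 0, seed = 7)
  phat <- mean(big$truth$indicator[, 1])
  se3 <- 3 * sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(phat - 0.7), se3)
  ## jitter stays within +/-100 bp of the anchor
  bound <- which(big$truth$indicator[, 1] == 1L)
  ctr <- peakCenters(big$peaksets[[1]])
  expect_true(all(abs(sort(ctr) - sort(big$truth$anchors[bound])) <= 100))
})

test_that("time-course archetypes behave as labelled when noiseless", {
  g <- generateTimecourseExpression(2, 6, noiseSd = 0, seed = 1)
  lab <- g$truth$classLabels
  flat <- g$expr[names(lab)[lab == 4][1], ]
  expect_true(all(flat == flat[1]))
  down <- g$expr[names(lab)[lab == 2][1], ]
  expect_true(all(diff(down) < 0))
  up <- g$expr[names(lab)[lab == 3][1], ]
  expect_true(all(diff(up) > 0))
  bi <- g$expr[names(lab)[lab == 1][1], ]
  expect_true(bi[1] > min(bi) && bi[6] > min(bi) &&
                which.min(bi) %in% 2:5)
})

test_that("case/control generator plants recoverable extremes", {
  ## noiseless: planted-up genes occupy the global top of the ratio
  g0 <- generateCaseControlDatasets(1, 200, 5, 5, effectLog2fc = 2,
                                    noiseSd = 0, seed = 2)
  ds <- g0$datasets[[1]]
  ratio <- rowMeans(ds$expr[, ds$condition == "case"]) /
    rowMeans(ds$expr[, ds$condition == "control"])
  up <- names(g0$truth$direction)[g0$truth$direction == "up"]
  expect_setequal(names(sort(ratio, decreasing = TRUE))[1:5], up)
  ## rank oracle at noise 0.2: every planted gene in its extreme decile
  ## in all 5 datasets (two seeds here; the acceptance suite runs ten)
  for (s in 1:2) {
    g <- generateCaseControlDatasets(5, 500, 10, 10, effectLog2fc = 2,
                                     noiseSd = 0.2, seed = s)
    m <- floor(0.1 * 500)
    for (ds in g$datasets) {
      ratio <- rowMeans(ds$expr[, ds$condition == "case"]) /
        rowMeans(ds$expr[, ds$condition == "control"])
      o <- names(sort(ratio, decreasing = TRUE))
      dir <- g$truth$direction
      expect_true(all(names(dir)[dir == "up"] %in% head(o, m)))
      expect_true(all(names(dir)[dir == "down"] %in% tail(o, m)))
    }
  }
  expect_error(
    generateCaseControlDatasets(2, 100, 6, 6, extremeFraction = 0.1),
    "configuration error")
})
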