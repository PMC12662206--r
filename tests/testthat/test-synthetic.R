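test_that("capsule mask matches analytic geometry", {
  # straight capsule: centerline on the central row
  org <- makeOrganoidMask(SimParams(lengthPx = 400, widthPx = 100))
  tm <- trueMidline(org)
  expect_true(all(tm[, 1L] == tm[1L, 1L]))
  expect_equal(max(tm[, 2L]) - min(tm[, 2L]), 400)

  # pixel area within 2% of the analytic capsule area, bent and straight
  for (curv in c(0, 0.002)) {
    p <- SimParams(lengthPx = 400, widthPx = 100, curvature = curv)
    o <- makeOrganoidMask(p)
    analytic <- (400 - 100) * 100 + pi * 50^2
    expect_lt(abs(sum(maskGrid(o)) - analytic) / analytic, 0.02)
  }

  # not elongated -> rejected
  expect_error(makeOrganoidMask(SimParams(lengthPx = 100, widthPx = 100)),
               "elongated")
  # explicit grid too small -> sizing error
  expect_error(
    makeOrganoidMask(SimParams(gridRows = 50, gridCols = 50)),
    "exceeds")
})

test_that("true centerline lies inside the mask with unit sampling", {
  for (curv in c(0, 0.001, 0.002)) {
    org <- makeOrganoidMask(SimParams(curvature = curv))
    tm <- trueMidline(org)
    expect_true(all(maskGrid(org)[cbind(round(tm[, 1L]), round(tm[, 2L]))]))
    steps <- sqrt(diff(tm[, 1L])^2 + diff(tm[, 2L])^2)
    expect_true(all(steps <= 1))
  }
})

test_that("scatterCells samples uniformly with ground-truth positions", {
  org <- makeOrganoidMask(smallParams())
  expect_equal(nrow(scatterCells(org, 0)), 0L)
  expect_error(scatterCells(org, -1), ">= 0")

  c1 <- scatterCells(org, 100, seed = 5L)
  c2 <- scatterCells(org, 100, seed = 5L)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  # centroids on true pixels; s_true in [0, 1]
  expect_true(all(maskGrid(org)[cbind(round(c1$row), round(c1$col))]))
  expect_true(all(c1$s_true >= 0 & c1$s_true <= 1))

  # uniform sampling on a straight capsule: mean s_true near 0.5
  big <- makeOrganoidMask(SimParams())
  cells <- scatterCells(big, 500, seed = 2L)
  expect_lt(abs(mean(cells$s_true) - 0.5), 0.05)
})

test_that("s_true is the arc fraction of the nearest centerline point", {
  org <- makeOrganoidMask(smallParams())
  cells <- scatterCells(org, 40, seed = 9L)
  tm <- trueMidline(org)
  manual <- vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (tm[, 1L] - cells$row[i])^2 + (tm[, 2L] - cells$col[i])^2
    (which.min(d2) - 1) / (nrow(tm) - 1)  # ties to the lower index
  }, numeric(1L))
  expect_equal(cells$s_true, manual)
})

test_that("simulated counts follow the stated gradient means", {
  org <- makeOrganoidMask(SimParams(nCells = 1000))
  cells <- scatterCells(org, 1000, seed = 4L)

  # beta = 0: all genes exchangeable; set means within 3 SE of background
  p0 <- SimParams(nCells = 1000, effectSize = 0, baseRate = 2)
  sce0 <- simulateCounts(cells, params = p0, seed = 21L)
  cts0 <- SummarizedExperiment::assay(sce0, "counts")
  sets <- SummarizedExperiment::rowData(sce0)$geneSet
  mSet <- mean(cts0[sets != "background", ])
  mBg <- mean(cts0[sets == "background", ])
  seComb <- sqrt(stats::var(as.numeric(cts0[sets != "background", ])) /
                   sum(sets != "background") / 1000 +
                 stats::var(as.numeric(cts0[sets == "background", ])) /
                   sum(sets == "background") / 1000)
  expect_lt(abs(mSet - mBg), 3 * seComb)

  # grand mean near baseRate
  gm <- mean(cts0)
  se <- stats::sd(as.numeric(cts0)) / sqrt(length(cts0))
  expect_lt(abs(gm - 2), 3 * se)

  # total counts within 4 SD of the Poisson expectation
  expTotal <- 2 * length(cts0)
  expect_lt(abs(sum(cts0) - expTotal), 4 * sqrt(expTotal))

  # beta = 4: chondrogenic counts higher at the proximal quarter
  p4 <- SimParams(nCells = 1000, effectSize = 4, baseRate = 2)
  sce4 <- simulateCounts(cells, params = p4, proximalEnd = "first",
                         seed = 22L)
  cts4 <- SummarizedExperiment::assay(sce4, "counts")
  chon <- sets == "chondrogenic"
  prox <- cells$s_true < 0.25
  dist <- cells$s_true > 0.75
  expect_gt(mean(cts4[chon, prox]), mean(cts4[chon, dist]))
  fib <- sets == "fibroblast"
  expect_gt(mean(cts4[fib, dist]), mean(cts4[fib, prox]))

  # overlapping gene sets are rejected
  expect_error(
    simulateCounts(cells, list(chondrogenic = c("A", "B"),
                               fibroblast = c("B", "C")), p4, seed = 1L),
    "overlap")
})

test_that("negative binomial dispersion inflates the variance", {
  org <- makeOrganoidMask(smallParams())
  cells <- scatterCells(org, 400, seed = 3L)
  pNB <- SimParams(nCells = 400, effectSize = 0, baseRate = 5,
                   dispersion = 1)
  sce <- simulateCounts(cells, params = pNB, seed = 8L)
  cts <- SummarizedExperiment::assay(sce, "counts")
  bg <- cts[SummarizedExperiment::rowData(sce)$geneSet == "background", ]
  # variance = mu + dispersion * mu^2 = 30 versus Poisson's 5
  expect_gt(stats::var(as.numeric(bg)), 3 * mean(bg))
})

test_that("the generator is deterministic given the seed", {
  a <- simulateOrganoid(smallParams())
  b <- simulateOrganoid(smallParams())
  expect_identical(maskGrid(a), maskGrid(b))
  expect_identical(as.data.frame(cellTable(a)), as.data.frame(cellTable(b)))
  expect_identical(
    SummarizedExperiment::assay(expressionData(a), "counts"),
    SummarizedExperiment::assay(expressionData(b), "counts"))
  expect_identical(trueOrientation(a), trueOrientation(b))
  d <- simulateOrganoid(smallParams(seed = 12L))
  expect_false(identical(
    SummarizedExperiment::assay(expressionData(a), "counts"),
    SummarizedExperiment::assay(expressionData(d), "counts")))
})

test_that("intensity images ramp along the axis", {
  org <- makeOrganoidMask(smallParams())
  flat <- makeIntensityImage(org, gradient = 0)
  expect_true(all(flat[maskGrid(org)] == 0.5))
  expect_true(all(flat[!maskGrid(org)] == 0))

  img <- makeIntensityImage(org, gradient = 1)
  tm <- trueMidline(org)
  first <- img[round(tm[1L, 1L]), round(tm[1L, 2L])]
  last <- img[round(tm[nrow(tm), 1L]), round(tm[nrow(tm), 2L])]
  expect_gt(last, first)
  # gradient 1 over the unit axis spans [0, 1] up to rasterization error
  vals <- img[maskGrid(org)]
  expect_lt(min(vals), 1 / simParams(org)@lengthPx)
  expect_gt(max(vals), 1 - 1 / simParams(org)@lengthPx)
})
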