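test_that("normalization scales cells to the target sum then logs", {
  cts <- matrix(c(1, 1, 2, 2), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  # cells are columns: c1 = (1, 1) sums to 2, c2 = (2, 2) sums to 4;
  # with target 4 both scale to (2, 2) and log1p gives log(3) everywhere
  norm <- normalizeExpression(cts, targetSum = 4)
  expect_equal(unname(norm), matrix(log(3), 2, 2))

  set.seed(1)
  big <- matrix(rpois(300, 3), 20, 15,
                dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:15)))
  big[big < 0] <- 0
  nb <- normalizeExpression(big, targetSum = 1e4)
  expect_true(all(nb[big == 0] == 0))  # zeros stay zero
  preLog <- expm1(nb)
  expect_equal(unname(colSums(preLog)), rep(1e4, 15), tolerance = 1e-8)

  expect_error(normalizeExpression(matrix(0, 3, 3)), "zero")
  sce <- toySCE(big)
  nsce <- normalizeExpression(sce)
  expect_true("lognorm" %in%
                SummarizedExperiment::assayNames(nsce))
})

test_that("gene-set scores vanish on constant and shifted panels", {
  genes <- sprintf("g%02d", 1:40)
  const <- matrix(3, 2, 40, dimnames = list(NULL, genes))
  s <- geneSetScore(const, genes[1:4], nBins = 10, ctrlSize = 5, seed = 1)
  expect_equal(unname(s), c(0, 0))

  set.seed(2)
  prof <- matrix(runif(80), 2, 40, dimnames = list(NULL, genes))
  s1 <- geneSetScore(prof, genes[5:8], nBins = 10, ctrlSize = 5, seed = 3)
  s2 <- geneSetScore(prof + 7, genes[5:8], nBins = 10, ctrlSize = 5,
                     seed = 3)
  expect_equal(s1, s2)  # additive shifts cancel in the difference of means

  expect_error(geneSetScore(prof, c("nope1", "nope2")), "none")
  expect_warning(
    geneSetScore(prof, c(genes[1], "nope"), nBins = 10, ctrlSize = 5,
                 seed = 1), "missing")
})

test_that("a constructed offset panel scores exactly delta", {
  # background genes constant at 2; set genes equal their expression-
  # matched controls plus delta
  delta <- 0.37
  genes <- c(sprintf("bg%02d", 1:30), "setA", "setB")
  prof <- matrix(2, 3, 32, dimnames = list(NULL, genes))
  prof[, 31:32] <- 2 + delta
  s <- geneSetScore(prof, c("setA", "setB"), nBins = 8, ctrlSize = 10,
                    seed = 5)
  expect_equal(unname(s), rep(delta, 3))
})

test_that("expression-matched random sets score about zero", {
  # one independent panel per draw so the replicate mean is unbiased
  scores <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    prof <- matrix(rgamma(4 * 131, shape = 2, rate = 0.5), 4, 131,
                   dimnames = list(NULL, sprintf("g%03d", 1:131)))
    mean(geneSetScore(prof, sample(colnames(prof), 6), seed = i))
  }, numeric(1L))
  se <- stats::sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 2 * se)
})

test_that("polarization truth table covers all boundary combinations", {
  lo <- 0.005; at <- 0.01; hi <- 0.02
  expect_equal(classifyPolarization(hi, hi), "polarized")
  expect_equal(classifyPolarization(lo, lo), "invalid")
  expect_equal(classifyPolarization(hi, lo), "nonpolarized")
  expect_equal(classifyPolarization(lo, hi), "nonpolarized")
  expect_equal(classifyPolarization(at, hi), "nonpolarized")
  expect_equal(classifyPolarization(hi, at), "nonpolarized")
  expect_equal(classifyPolarization(at, lo), "nonpolarized")
  expect_equal(classifyPolarization(lo, at), "nonpolarized")
  expect_equal(classifyPolarization(at, at), "nonpolarized")
  expect_error(classifyPolarization(NaN, 1), "finite")
})

test_that("halves split at 0.5 with the boundary going distal", {
  expect_equal(splitHalves(0), "proximal")
  expect_equal(splitHalves(0.5), "distal")
  expect_equal(splitHalves(c(0.49, 0.51)), c("proximal", "distal"))
})

test_that("orientation recovers the simulated proximal end", {
  org <- simulateOrganoid(SimParams(seed = 101L))
  seg <- segmentStructure(maskGrid(org))
  ml <- extractMidline(seg)
  cells <- filterCellsInStructure(cellTable(org), seg)
  proj <- projectCells(cells, ml)
  norm <- normalizeExpression(expressionData(org)[, proj@cellId])
  res <- orientAndScale(proj, norm)
  expect_true(orientationRecovered(org, ml, res$scores))
  expect_equal(polarizationClass(res$scores), "polarized")

  # oriented positions live on [0, 1]; the midline coordinate scale
  # itself spans exactly [0, 1]
  s <- axialPosition(res$projection)
  expect_true(all(s >= 0 & s <= 1))
  f <- arcLength(ml) / max(arcLength(ml))
  expect_equal(range(f), c(0, 1))

  # swapping the two gene sets flips the orientation
  swapped <- orientAndScale(proj, norm,
                            geneSets = list(
                              chondrogenic = defaultGeneSets()$fibroblast,
                              fibroblast = defaultGeneSets()$chondrogenic))
  expect_false(axisOrientation(swapped$scores) ==
                 axisOrientation(res$scores))
  expect_equal(axialPosition(swapped$projection),
               1 - axialPosition(res$projection))

  # domains match the split rule
  expect_identical(unname(res$domains),
                   splitHalves(unname(axialPosition(res$projection))))
})

test_that("uniform cells split into nearly equal halves", {
  org <- makeOrganoidMask(SimParams())
  cells <- scatterCells(org, 500, seed = 55L)
  dom <- splitHalves(cells$s_true)
  tab <- table(dom)
  expect_lte(abs(tab[["proximal"]] - tab[["distal"]]) / sum(tab), 0.05)
})
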