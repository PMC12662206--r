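domainFixture <- function(beta = 4, seeds = 1:2, condition = "cond") {
  lapply(seeds, function(s) {
    org <- simulateOrganoid(SimParams(seed = s, nCells = 200,
                                      effectSize = beta,
                                      lengthPx = 200, widthPx = 60))
    norm <- normalizeExpression(expressionData(org))
    firstProx <- trueOrientation(org) == "first-is-proximal"
    sTrue <- cellTable(org)$s_true
    dom <- splitHalves(if (firstProx) sTrue else 1 - sTrue)
    names(dom) <- cellTable(org)$cell_id
    summarizeDomains(norm, dom,
                     sampleId = paste0(condition, "_s", s),
                     condition = condition)
  })
}

test_that("sample QC keeps exactly the samples at or above the cutoff", {
  mk <- function(nDetected, nGenes = 300) {
    m <- matrix(0, nGenes, 4,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)), NULL))
    if (nDetected > 0) m[seq_len(nDetected), 1L] <- 1
    m
  }
  mats <- list(low = mk(179), at = mk(180), high = mk(250), zero = mk(0))
  kept <- qcFilterSamples(mats, minGenes = 180)
  expect_identical(names(kept), c("at", "high"))
  expect_equal(unname(attr(kept, "detectedGenes")), c(179, 180, 250, 0))

  # monotone: adding counts to a kept sample never excludes it
  more <- mats$at
  more[, 2L] <- 5
  expect_true("s" %in% names(qcFilterSamples(list(s = more), 180)))
})

test_that("domain summaries average the normalized layer", {
  norm <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  s1 <- summarizeDomains(norm, c(c1 = "proximal", c2 = "proximal"))
  expect_equal(
    unname(SummarizedExperiment::assay(s1, "meanExpr")[, 1L]),
    c(2.5, 3.5, 4.5))
  expect_message(
    summarizeDomains(norm, c(c1 = "proximal", c2 = "proximal")),
    "omitting")

  single <- summarizeDomains(norm[, 1L, drop = FALSE], c(c1 = "distal"))
  expect_equal(
    unname(SummarizedExperiment::assay(single, "meanExpr")[, 1L]),
    c(1, 2, 3))
  expect_error(summarizeDomains(norm, c(c1 = "proximal")), "domain label")
})

test_that("simulated gradients show up in the domain summaries", {
  summ <- combineSummaries(domainFixture(beta = 4, seeds = 1L))
  me <- SummarizedExperiment::assay(summ, "meanExpr")
  cd <- SummarizedExperiment::colData(summ)
  chon <- defaultGeneSets()$chondrogenic
  expect_gt(mean(me[chon, cd$domain == "proximal"]),
            mean(me[chon, cd$domain == "distal"]))
})

test_that("PCA centroid distance separates gradient from null conditions", {
  set.seed(7)
  s4 <- domainFixture(beta = 4, seeds = 1:3, condition = "grad")
  s0 <- domainFixture(beta = 0, seeds = 4:6, condition = "null")
  summ <- combineSummaries(c(s4, s0))
  res <- pcaDomains(summ)
  expect_true(all(diff(res$explainedVariance) <= 1e-9))
  expect_gt(res$centroidDistance[["grad"]], res$centroidDistance[["null"]])
  expect_true(all(res$centroidDistance >= 0))

  # identical proximal and distal summaries -> centroid distance 0
  dup <- combineSummaries(list(s4[[1L]], s4[[2L]], s4[[3L]]))
  me <- SummarizedExperiment::assay(dup, "meanExpr")
  cdd <- SummarizedExperiment::colData(dup)
  me[, cdd$domain == "distal"] <- me[, cdd$domain == "proximal"]
  SummarizedExperiment::assay(dup, "meanExpr") <- me
  cdd$condition <- "dup"
  SummarizedExperiment::colData(dup) <- cdd
  resDup <- pcaDomains(dup)
  expect_equal(unname(resDup$centroidDistance[["dup"]]), 0,
               tolerance = 1e-8)
})

test_that("PCA embedding is invariant to sample order up to sign", {
  s <- c(domainFixture(beta = 4, seeds = 1:2, condition = "a"),
         domainFixture(beta = 0, seeds = 3:4, condition = "b"))
  full <- combineSummaries(s)
  perm <- combineSummaries(s[c(3, 1, 4, 2)])
  r1 <- pcaDomains(full)
  r2 <- pcaDomains(perm)
  e1 <- r1$embedding[rownames(r2$embedding), , drop = FALSE]
  for (k in 1:2) {
    agree <- min(max(abs(e1[, k] - r2$embedding[, k])),
                 max(abs(e1[, k] + r2$embedding[, k])))
    expect_lt(agree, 1e-6)
  }
  expect_equal(r1$centroidDistance[sort(names(r1$centroidDistance))],
               r2$centroidDistance[sort(names(r2$centroidDistance))],
               tolerance = 1e-8)
})

test_that("the detection filter drops rarely expressed genes", {
  sets <- defaultGeneSets()
  # two summaries where one gene is expressed in a single cell of 200
  org <- simulateOrganoid(SimParams(seed = 9L, nCells = 200,
                                    lengthPx = 200, widthPx = 60))
  sce <- expressionData(org)
  cts <- SummarizedExperiment::assay(sce, "counts")
  cts["Bg001", ] <- 0
  cts["Bg001", 1L] <- 1  # detected in 0.5% of cells
  SummarizedExperiment::assay(sce, "counts") <- cts
  norm <- normalizeExpression(sce)
  dom <- splitHalves(cellTable(org)$s_true)
  names(dom) <- cellTable(org)$cell_id
  summ <- combineSummaries(list(
    summarizeDomains(norm, dom, "s1", "c"),
    summarizeDomains(norm, dom, "s2", "c")))
  res <- pcaDomains(summ, minCellFraction = 0.01)
  expect_false("Bg001" %in% res$keptGenes)
  expect_true("Sox9" %in% res$keptGenes)
})

test_that("marker tables average per domain and test differences", {
  s <- domainFixture(beta = 4, seeds = 1:3)
  summ <- combineSummaries(s)
  tab <- domainMarkerTable(summ, c("Sox9", "Col1a1"), test = TRUE)
  expect_equal(rownames(tab), c("Sox9", "Col1a1"))
  expect_gt(tab["Sox9", "cond.proximal"], tab["Sox9", "cond.distal"])
  expect_gt(tab["Col1a1", "cond.distal"], tab["Col1a1", "cond.proximal"])
  expect_true(all(tab$p.adj >= tab$p.value - 1e-12))

  expect_warning(domainMarkerTable(summ, c("Sox9", "NotAGene")), "absent")
  expect_error(domainMarkerTable(summ, character(0)), "empty")

  # markers = whole panel reproduces the per-domain means
  all <- domainMarkerTable(summ, rownames(summ))
  me <- SummarizedExperiment::assay(summ, "meanExpr")
  cd <- SummarizedExperiment::colData(summ)
  manual <- rowMeans(me[, cd$domain == "proximal", drop = FALSE])
  expect_equal(all[, "cond.proximal"], unname(manual))
})
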