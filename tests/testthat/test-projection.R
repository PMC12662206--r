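test_that("cells outside the structure are removed, inside kept", {
  g <- matrix(FALSE, 40, 40)
  g[10:30, 10:30] <- TRUE
  mask <- OrganoidAxis:::OrganoidMask(g)
  cells <- S4Vectors::DataFrame(
    cell_id = c("a", "b", "c"),
    row = c(15.2, 5.0, 20.0), col = c(15.8, 5.0, 29.6))
  kept <- filterCellsInStructure(cells, mask)
  expect_identical(kept$cell_id, c("a", "c"))

  # all inside -> size preserved
  inside <- S4Vectors::DataFrame(cell_id = c("x", "y"),
                                 row = c(12, 25), col = c(12, 25))
  expect_equal(nrow(filterCellsInStructure(inside, mask)), 2L)

  # out-of-grid centroids are dropped with a warning, not an error
  off <- S4Vectors::DataFrame(cell_id = "z", row = 99, col = 99)
  expect_warning(res <- filterCellsInStructure(off, mask), "outside")
  expect_equal(nrow(res), 0L)

  # pad offset shifts coordinates into the padded frame
  padded <- OrganoidAxis:::OrganoidMask(g, c(5L, 5L))
  shifted <- filterCellsInStructure(
    S4Vectors::DataFrame(cell_id = "a", row = 10, col = 10), padded)
  expect_equal(shifted$row, 15)
})

test_that("projection at alpha 0 equals the nearest-coordinate oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    # random 8-connected path of 50 coordinates
    path <- cbind(cumsum(c(50L, sample(-1:1, 49L, TRUE))),
                  seq(10L, 59L))
    ml <- Midline(path)
    cells <- S4Vectors::DataFrame(
      cell_id = sprintf("c%03d", 1:100),
      row = stats::runif(100, 1, 100), col = stats::runif(100, 1, 100))
    proj <- projectCells(cells, ml, alpha = 0)
    expect_identical(unname(assignedIndex(proj)),
                     nearestCoordOracle(cells, path))
    expect_equal(sum(occupancy(proj)), 100L)
  }
})

test_that("the crowding penalty reassigns the hand-worked example", {
  # midline of three coordinates, two cells on the same spot, alpha = 5:
  # the first cell takes the nearest coordinate; for the second,
  # 1 * exp(5) ~ 148.4 beats sqrt(2) ~ 1.414, so it moves to the next
  ml <- Midline(cbind(c(1L, 1L, 1L), c(1L, 2L, 3L)))
  cells <- S4Vectors::DataFrame(cell_id = c("a", "b"),
                                row = c(2, 2), col = c(1, 1))
  proj <- projectCells(cells, ml, alpha = 5)
  expect_identical(unname(assignedIndex(proj)), c(1L, 2L))
  expect_identical(occupancy(proj), c(1L, 1L, 0L))
  expect_error(projectCells(cells, ml, alpha = -1), ">= 0")
})

test_that("argmin ties break toward the smaller midline index", {
  ml <- Midline(cbind(c(1L, 1L, 1L), c(1L, 2L, 3L)))
  # a cell equidistant from coordinates 1 and 2
  cells <- S4Vectors::DataFrame(cell_id = "a", row = 5, col = 1.5)
  proj <- projectCells(cells, ml, alpha = 0)
  expect_identical(unname(assignedIndex(proj)), 1L)
})

test_that("occupancy is conserved and deterministic across runs", {
  fx <- makeCrowdedFixture()
  for (a in c(0, 0.01, 0.1)) {
    p <- projectCells(fx$cells, fx$midline, alpha = a)
    expect_equal(sum(occupancy(p)), nrow(fx$cells))
  }
  p1 <- projectCells(fx$cells, fx$midline, alpha = 0.01)
  p2 <- projectCells(fx$cells, fx$midline, alpha = 0.01)
  expect_identical(assignedIndex(p1), assignedIndex(p2))
})

test_that("the crowding penalty lowers the maximum occupancy", {
  fx <- makeCrowdedFixture()  # 200 cells clustered at one end, seed 7
  curve <- crowdingCurve(fx$cells, fx$midline, alphas = c(0, 0.01))
  expect_lt(curve$maxOccupancy[curve$alpha == 0.01],
            curve$maxOccupancy[curve$alpha == 0])

  # alpha = 0 column equals the nearest-neighbor occupancy histogram
  nn <- nearestCoordOracle(as.data.frame(fx$cells),
                           midlinePath(fx$midline))
  expect_equal(curve$maxOccupancy[curve$alpha == 0],
               max(tabulate(nn, nrow(midlinePath(fx$midline)))))

  single <- S4Vectors::DataFrame(cell_id = "a", row = 50, col = 31)
  c1 <- crowdingCurve(single, fx$midline, alphas = c(0, 0.01, 1))
  expect_true(all(c1$maxOccupancy == 1L))
  expect_error(crowdingCurve(single, fx$midline, numeric(0)), "alpha")
})

test_that("order dependence of the sequential scheme is bounded", {
  # reversing the processing order must leave the projection essentially
  # unchanged: occupancy profiles nearly identical and almost every cell
  # within one coordinate of its forward-order index
  fx <- makeCrowdedFixture()
  fwd <- projectCells(fx$cells, fx$midline, alpha = 0.01)
  rev <- fx$cells
  rev$cell_id <- sprintf("cell_%05d", base::rev(seq_len(nrow(rev))))
  bwd <- projectCells(rev, fx$midline, alpha = 0.01)
  shift <- abs(assignedIndex(fwd)[fx$cells$cell_id] -
                 assignedIndex(bwd)[rev$cell_id])
  expect_gte(mean(shift <= 1), 0.90)
  expect_lte(sum(abs(occupancy(fwd) - occupancy(bwd))),
             0.1 * nrow(fx$cells))
})
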