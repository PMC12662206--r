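#' Remove cells outside the structure segmentation
#'
#' Keeps cells whose rounded centroid pixel is foreground in the segmented
#' mask. Coordinates are first shifted by the mask's \code{padOffset} (set
#' \code{applyPadOffset = FALSE} if they already are in the padded frame).
#' Cells whose centroid falls outside the grid bounds are dropped with a
#' warning rather than an error.
#'
#' @param cells a \code{DataFrame}/\code{data.frame} with \code{cell_id},
#'   \code{row}, \code{col} (px, original image frame).
#' @param structMask an [OrganoidMask].
#' @param applyPadOffset shift coordinates by the mask's padding first.
#' @return the filtered cell table with coordinates in the mask frame.
#' @export
filterCellsInStructure <- function(cells, structMask,
                                   applyPadOffset = TRUE) {
  grid <- .asMaskGrid(structMask)
  off <- if (applyPadOffset) .padOffsetOf(structMask) else c(0L, 0L)
  cells <- as(cells, "DataFrame")
  if (anyDuplicated(cells$cell_id)) stop("cell ids must be unique")
  if (any(!is.finite(cells$row)) || any(!is.finite(cells$col)))
    stop("cell centroids must be finite")
  r <- cells$row + off[1L]
  c <- cells$col + off[2L]
  ri <- round(r); ci <- round(c)
  inGrid <- ri >= 1 & ri <= nrow(grid) & ci >= 1 & ci <= ncol(grid)
  if (any(!inGrid))
    warning(sum(!inGrid), " cell(s) outside the grid bounds were dropped",
            " (coordinate frame mismatch?)")
  keep <- inGrid
  keep[inGrid] <- grid[cbind(ri[inGrid], ci[inGrid])]
  out <- cells[keep, , drop = FALSE]
  out$row <- r[keep]
  out$col <- c[keep]
  out
}

#' Project cells onto the midline with a crowding penalty
#'
#' Cells are processed sequentially in ascending \code{cell_id} order; each
#' cell c is assigned the midline coordinate i minimizing the penalized
#' distance D(i,c) * exp(alpha * N(i)), where D is the Euclidean distance
#' between the centroid and the midline pixel and N(i) is the number of
#' cells already assigned to i. The winning coordinate's occupancy is then
#' incremented. With \code{alpha = 0} this reduces to plain
#' nearest-coordinate projection; the default \code{alpha = 0.01} spreads
#' piled-up cells along the axis. Ties in the argmin go to the smaller
#' midline index.
#'
#' @param cells filtered cell table (see [filterCellsInStructure()]).
#' @param midline a [Midline].
#' @param alpha crowding penalty scale, must be >= 0.
#' @return a [ProjectionResult]; positions \code{s} are \code{NA} until the
#'   midline is oriented with [orientAndScale()].
#' @examples
#' fx <- makeCrowdedFixture()
#' projectCells(fx$cells, fx$midline, alpha = 0.01)
#' @export
projectCells <- function(cells, midline, alpha = 0.01) {
  if (alpha < 0) stop("alpha must be >= 0")
  path <- midlinePath(midline)
  if (!nrow(path)) stop("midline is empty")
  cells <- as(cells, "DataFrame")
  n <- nrow(cells)
  m <- nrow(path)
  ord <- order(cells$cell_id)
  D <- sqrt(outer(cells$row, path[, 1L], "-")^2 +
              outer(cells$col, path[, 2L], "-")^2)
  N <- integer(m)
  idx <- integer(n)
  for (i in ord) {
    dprime <- D[i, ] * exp(alpha * N)
    j <- which.min(dprime)  # first minimum: ties go to the smaller index
    idx[i] <- j
    N[j] <- N[j] + 1L
  }
  new("ProjectionResult", cellId = as.character(cells$cell_id),
      index = idx, occupancy = N, alpha = alpha,
      s = rep(NA_real_, n), arclen = arcLength(midline))
}

#' Maximum occupancy as a function of the crowding penalty
#'
#' Runs one projection per alpha and reports the maximum number of cells
#' assigned to any single midline coordinate, a diagnostic for how strongly
#' the penalty spreads crowded cells.
#'
#' @param cells,midline as in [projectCells()].
#' @param alphas numeric vector of penalty scales.
#' @return \code{data.frame} with columns \code{alpha} and
#'   \code{maxOccupancy}.
#' @export
crowdingCurve <- function(cells, midline, alphas = c(0, 0.01)) {
  if (!length(alphas)) stop("at least one alpha is required")
  data.frame(
    alpha = alphas,
    maxOccupancy = vapply(alphas, function(a) {
      occ <- occupancy(projectCells(cells, midline, alpha = a))
      if (length(occ)) max(occ) else 0L
    }, integer(1L))
  )
}
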