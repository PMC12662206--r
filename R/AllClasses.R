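#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("SCEOrNULL", c("SingleCellExperiment", "NULL"))

#' Simulation parameters for synthetic organoids
#'
#' Container for the parameters of the synthetic bent-capsule organoid
#' generator. The defaults describe the standard simulated section used
#' throughout the package: a 400 x 100 px capsule carrying 600 cells whose
#' chondrogenic and fibroblast transcripts form opposing monotone gradients
#' along the true axis.
#'
#' @slot lengthPx total pole-to-pole capsule length in pixels (must exceed
#'   \code{widthPx}; an organoid is elongated by construction).
#' @slot widthPx capsule width (cap diameter) in pixels.
#' @slot curvature centerline curvature in 1/px; 0 gives a straight capsule.
#' @slot nCells number of cells scattered uniformly over the mask.
#' @slot nBackgroundGenes number of flat background genes added to the two
#'   gradient gene sets (default 123, giving a 131-gene panel with the
#'   default sets).
#' @slot baseRate mean counts per gene per cell for background genes.
#' @slot effectSize gradient strength beta >= 0: gradient-set genes have mean
#'   \code{baseRate * (1 + beta * g)} where g runs from 0 to 1 along the axis.
#' @slot dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 degenerates to Poisson.
#' @slot seed integer seed; one global generator drives every stochastic draw.
#' @slot marginPx background margin around the capsule in pixels.
#' @slot gridRows,gridCols optional fixed grid size; when supplied the capsule
#'   (plus margin) must fit or construction fails.
#'
#' @seealso [SimParams()] for the user-facing constructor.
#' @export
setClass("SimParams",
  representation(
    lengthPx = "numeric", widthPx = "numeric", curvature = "numeric",
    nCells = "numeric", nBackgroundGenes = "numeric", baseRate = "numeric",
    effectSize = "numeric", dispersion = "numeric", seed = "integer",
    marginPx = "numeric", gridRows = "numeric", gridCols = "numeric"
  )
)

setValidity("SimParams", function(object) {
  msg <- NULL
  if (length(object@lengthPx) != 1L || length(object@widthPx) != 1L)
    msg <- c(msg, "lengthPx and widthPx must be scalars")
  if (object@widthPx <= 0)
    msg <- c(msg, "widthPx must be positive")
  if (object@lengthPx <= object@widthPx)
    msg <- c(msg, "capsule must be elongated: lengthPx > widthPx required")
  if (object@curvature < 0)
    msg <- c(msg, "curvature must be >= 0 (mirror the mask for the other bend)")
  if (object@curvature > 0 &&
      (object@lengthPx / 2) * object@curvature > pi / 2)
    msg <- c(msg, "curvature too strong: centerline would exceed a half circle")
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  if (object@nBackgroundGenes < 0) msg <- c(msg, "nBackgroundGenes must be >= 0")
  if (object@baseRate <= 0) msg <- c(msg, "baseRate must be positive")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@marginPx < 0) msg <- c(msg, "marginPx must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param lengthPx,widthPx,curvature,nCells,nBackgroundGenes,baseRate,effectSize,dispersion,seed,marginPx,gridRows,gridCols
#'   see the corresponding slots.
#' @return a validated \code{SimParams} object.
#' @examples
#' SimParams(curvature = 0.002, seed = 7L)
#' @rdname SimParams-class
#' @export
SimParams <- function(lengthPx = 400, widthPx = 100, curvature = 0,
                      nCells = 600, nBackgroundGenes = 123, baseRate = 2,
                      effectSize = 4, dispersion = 0, seed = 1L,
                      marginPx = 60, gridRows = numeric(0),
                      gridCols = numeric(0)) {
  new("SimParams", lengthPx = lengthPx, widthPx = widthPx,
      curvature = curvature, nCells = nCells,
      nBackgroundGenes = nBackgroundGenes, baseRate = baseRate,
      effectSize = effectSize, dispersion = dispersion,
      seed = as.integer(seed), marginPx = marginPx,
      gridRows = gridRows, gridCols = gridCols)
}

#' Segmented organoid mask
#'
#' A 2-D boolean pixel grid (row-major, origin top-left, 1-based indices as
#' usual in R) together with the padding applied during segmentation, so that
#' cell coordinates recorded in the original image frame can be shifted
#' consistently.
#'
#' @slot grid logical matrix; \code{TRUE} marks organoid pixels.
#' @slot padOffset integer vector (rows, cols) added to the top/left during
#'   segmentation; \code{c(0L, 0L)} when no padding was triggered.
#' @export
setClass("OrganoidMask",
  representation(grid = "matrix", padOffset = "integer")
)

setValidity("OrganoidMask", function(object) {
  msg <- NULL
  if (!is.logical(object@grid)) msg <- c(msg, "grid must be a logical matrix")
  if (!any(object@grid)) msg <- c(msg, "mask has no foreground pixels")
  if (length(object@padOffset) != 2L || any(object@padOffset < 0L))
    msg <- c(msg, "padOffset must be two non-negative integers")
  if (is.null(msg)) TRUE else msg
})

#' @param grid,padOffset see the slots above.
#' @return an \code{OrganoidMask}.
#' @rdname OrganoidMask-class
#' @export
OrganoidMask <- function(grid, padOffset = c(0L, 0L)) {
  new("OrganoidMask", grid = grid, padOffset = as.integer(padOffset))
}

#' Morphological midline
#'
#' An ordered 8-connected pixel path through the organoid mask with its
#' cumulative arc length (diagonal steps count sqrt(2) px). The first and
#' last path points are the two corner anchors.
#'
#' @slot path integer matrix (n x 2) of (row, col) pixel coordinates;
#'   consecutive points are 8-neighbors.
#' @slot arclen cumulative arc length per point in pixels, starting at 0.
#' @slot padOffset padding carried over from [segmentStructure()] so cell
#'   coordinates can be mapped into the midline frame.
#' @export
setClass("Midline",
  representation(path = "matrix", arclen = "numeric", padOffset = "integer")
)

setValidity("Midline", function(object) {
  msg <- NULL
  p <- object@path
  if (nrow(p) < 2L) msg <- c(msg, "midline must have at least 2 points")
  if (ncol(p) != 2L) msg <- c(msg, "path must be an n x 2 matrix")
  if (length(object@arclen) != nrow(p))
    msg <- c(msg, "arclen must have one value per path point")
  if (nrow(p) >= 2L) {
    cheb <- pmax(abs(diff(p[, 1L])), abs(diff(p[, 2L])))
    if (any(cheb != 1L))
      msg <- c(msg, "consecutive path points must be 8-neighbors")
    if (any(diff(object@arclen) <= 0))
      msg <- c(msg, "arclen must be strictly increasing")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param path n x 2 matrix of (row, col) coordinates of an 8-connected
#'   pixel path.
#' @param arclen optional cumulative arc length (computed from the path
#'   when omitted).
#' @param padOffset see the slot above.
#' @return a \code{Midline}.
#' @rdname Midline-class
#' @export
Midline <- function(path, arclen = NULL, padOffset = c(0L, 0L)) {
  path <- matrix(as.integer(round(path)), ncol = 2L,
                 dimnames = list(NULL, c("row", "col")))
  if (is.null(arclen)) {
    step <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2)
    arclen <- c(0, cumsum(step))
  }
  new("Midline", path = path, arclen = arclen,
      padOffset = as.integer(padOffset))
}

#' Synthetic organoid with ground truth
#'
#' Bundles a generated capsule mask, the analytic pole-to-pole centerline it
#' was built around, the orientation of the simulated proximal-distal
#' gradient, scattered cells, and (optionally) simulated counts.
#'
#' @slot mask logical matrix, the capsule mask.
#' @slot trueMidline numeric matrix (m x 2) of (row, col) centerline
#'   coordinates sampled at 0.5 px arc spacing, ordered pole to pole.
#' @slot trueOrientation \code{"first-is-proximal"} or
#'   \code{"last-is-proximal"}: which centerline end carries the chondrogenic
#'   (proximal) gradient maximum. Empty until counts are simulated.
#' @slot cells \code{DataFrame} with columns \code{cell_id}, \code{row},
#'   \code{col}, \code{s_true} (arc-length fraction of the nearest centerline
#'   point, measured from the first point).
#' @slot counts \code{SingleCellExperiment} (genes x cells) or \code{NULL}.
#' @slot params the generating [SimParams].
#' @export
setClass("SyntheticOrganoid",
  representation(
    mask = "matrix", trueMidline = "matrix", trueOrientation = "character",
    cells = "DataFrame", counts = "SCEOrNULL", params = "SimParams"
  )
)

setValidity("SyntheticOrganoid", function(object) {
  msg <- NULL
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  tm <- object@trueMidline
  if (nrow(tm) > 0L) {
    ri <- round(tm[, 1L]); ci <- round(tm[, 2L])
    inside <- ri >= 1 & ri <= nrow(object@mask) &
      ci >= 1 & ci <= ncol(object@mask)
    if (!all(inside) ||
        !all(object@mask[cbind(ri[inside], ci[inside])]))
      msg <- c(msg, "true midline must lie entirely within the mask")
  }
  cl <- object@cells
  if (nrow(cl) > 0L) {
    if (anyDuplicated(cl$cell_id))
      msg <- c(msg, "cell ids must be unique")
    px <- cbind(round(cl$row), round(cl$col))
    if (!all(object@mask[px]))
      msg <- c(msg, "every cell centroid must lie on a mask pixel")
  }
  if (!is.null(object@counts)) {
    cts <- SummarizedExperiment::assay(object@counts, "counts")
    if (ncol(cts) != nrow(cl))
      msg <- c(msg, "counts must have one column per cell")
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(object@trueOrientation) &&
      !object@trueOrientation %in% c("first-is-proximal", "last-is-proximal"))
    msg <- c(msg, "trueOrientation must be 'first-is-proximal' or 'last-is-proximal'")
  if (is.null(msg)) TRUE else msg
})

#' Normalized major-axis intensity profile
#'
#' Fluorescence intensity along the mask's major axis, min-max normalized and
#' averaged into 200 bins of width 0.005 on the normalized organoid length.
#'
#' @slot positions the 200 bin centers on [0, 1].
#' @slot values per-bin mean normalized gray value on [0, 1]; all zero when
#'   \code{degenerate}.
#' @slot nContributing number of line samples averaged into each bin; 0 marks
#'   bins filled by interpolation.
#' @slot degenerate TRUE when the masked image had zero dynamic range
#'   (max gray = min gray), in which case values are a documented all-zero
#'   convention.
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", values = "numeric",
                 nContributing = "integer", degenerate = "logical")
)

setValidity("IntensityProfile", function(object) {
  msg <- NULL
  n <- length(object@positions)
  if (length(object@values) != n || length(object@nContributing) != n)
    msg <- c(msg, "positions, values and nContributing must share length")
  if (!object@degenerate &&
      (any(object@values < -1e-9) || any(object@values > 1 + 1e-9)))
    msg <- c(msg, "values must lie in [0, 1] unless degenerate")
  if (is.null(msg)) TRUE else msg
})

#' Cell-to-midline projection
#'
#' Result of the crowding-penalized projection: the midline coordinate index
#' assigned to each cell, the per-coordinate occupancy, and (after
#' orientation) the scaled axial position s in [0, 1] with 0 at the proximal
#' end.
#'
#' @slot cellId character, projected cell identifiers.
#' @slot index integer midline coordinate index (1-based) per cell.
#' @slot occupancy integer per-midline-coordinate cell count; sums to the
#'   number of projected cells.
#' @slot alpha the crowding penalty scale used.
#' @slot s oriented scaled position per cell (NA before orientation).
#' @slot arclen the midline arc lengths, kept so positions can be scaled.
#' @export
setClass("ProjectionResult",
  representation(cellId = "character", index = "integer",
                 occupancy = "integer", alpha = "numeric", s = "numeric",
                 arclen = "numeric")
)

setValidity("ProjectionResult", function(object) {
  msg <- NULL
  n <- length(object@cellId)
  if (length(object@index) != n || length(object@s) != n)
    msg <- c(msg, "index and s must have one entry per cell")
  if (n > 0L && (any(object@index < 1L) ||
                 any(object@index > length(object@occupancy))))
    msg <- c(msg, "assigned indices must be valid midline indices")
  if (any(object@occupancy < 0L))
    msg <- c(msg, "occupancy must be non-negative")
  if (sum(object@occupancy) != n)
    msg <- c(msg, "occupancy must sum to the number of projected cells")
  if (length(object@alpha) != 1L || object@alpha < 0)
    msg <- c(msg, "alpha must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' Proximal/distal polarity scores
#'
#' Gene-set enrichment scores of the two midline halves and the resulting
#' three-way polarization class.
#'
#' @slot proximalScore chondrogenic enrichment score of the proximal half.
#' @slot distalScore fibroblast enrichment score of the distal half.
#' @slot classLabel one of \code{"polarized"}, \code{"nonpolarized"},
#'   \code{"invalid"}.
#' @slot orientation \code{"first-is-proximal"} or \code{"last-is-proximal"}:
#'   which midline end was called proximal.
#' @slot binScores numeric matrix of per-axis-bin gene-set scores
#'   (bins x sets), kept for diagnostics.
#' @slot flags character vector of anomalies (e.g. empty axis bins).
#' @export
setClass("PolarityScores",
  representation(proximalScore = "numeric", distalScore = "numeric",
                 classLabel = "character", orientation = "character",
                 binScores = "matrix", flags = "character")
)

setValidity("PolarityScores", function(object) {
  msg <- NULL
  if (!object@classLabel %in% c("polarized", "nonpolarized", "invalid"))
    msg <- c(msg, "classLabel must be polarized/nonpolarized/invalid")
  if (object@classLabel != "invalid" &&
      !length(object@orientation))
    msg <- c(msg, "orientation must be set for non-invalid classes")
  if (is.null(msg)) TRUE else msg
})
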