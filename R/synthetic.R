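#' Default proximal/distal gene sets
#'
#' The chondrogenic (proximal) and fibroblast (distal) marker sets used to
#' orient the midline: Sox9, Acan, Col2a1, Col9a1, Col9a2, Col11a1 versus
#' Col1a1, Col3a1.
#'
#' @return named list with elements \code{chondrogenic} and \code{fibroblast}.
#' @examples defaultGeneSets()
#' @export
defaultGeneSets <- function() {
  list(
    chondrogenic = c("Sox9", "Acan", "Col2a1", "Col9a1", "Col9a2", "Col11a1"),
    fibroblast = c("Col1a1", "Col3a1")
  )
}

# analytic capsule geometry: centerline samples (pole to pole, 0.5 px arc
# spacing) relative to an internal reference frame, plus a distance function.
.capsuleGeometry <- function(params) {
  L <- params@lengthPx
  W <- params@widthPx
  kappa <- params@curvature
  Ls <- L - W  # spine between the cap centers
  step <- 0.5
  tt <- seq(0, L, by = step)
  if (tt[length(tt)] < L) tt <- c(tt, L)
  if (kappa == 0) {
    mid <- cbind(rep(0, length(tt)), tt - L / 2)
    distFun <- function(r, c) {
      cc <- pmin(pmax(c, -Ls / 2), Ls / 2)
      sqrt(r^2 + (c - cc)^2)
    }
  } else {
    R <- 1 / kappa
    phiF <- (L / 2) / R   # half-angle of the full centerline
    phiS <- (Ls / 2) / R  # half-angle of the spine
    phi <- tt / R - phiF
    # circle center at the origin; apex of the arc points "up" (-row)
    mid <- cbind(-R * cos(phi), R * sin(phi))
    distFun <- function(r, c) {
      rho <- sqrt(r^2 + c^2)
      ang <- atan2(c, -r)
      onArc <- abs(ang) <= phiS
      d <- abs(rho - R)
      eA <- c(-R * cos(phiS), -R * sin(phiS))
      eB <- c(-R * cos(phiS), R * sin(phiS))
      dEnd <- pmin(sqrt((r - eA[1L])^2 + (c - eA[2L])^2),
                   sqrt((r - eB[1L])^2 + (c - eB[2L])^2))
      ifelse(onArc, d, dEnd)
    }
  }
  list(mid = mid, distFun = distFun)
}

#' Generate a synthetic bent-capsule organoid mask
#'
#' Rasterizes a solid, hole-free capsule (a rectangle with semicircular
#' caps) whose centerline follows a circular arc of the given curvature, and
#' records the analytic pole-to-pole centerline as ground truth. The mask is
#' the set of pixels within width/2 of the capsule spine, computed from the
#' exact point-to-arc distance, so the pixel area matches the analytic
#' capsule area up to rasterization error.
#'
#' @param params a [SimParams] object.
#' @return a [SyntheticOrganoid] with mask and true centerline filled in;
#'   cells and counts are added by [scatterCells()] / [simulateCounts()] or
#'   in one step by [simulateOrganoid()].
#' @examples
#' org <- makeOrganoidMask(SimParams(lengthPx = 120, widthPx = 40))
#' sum(maskGrid(org))
#' @export
makeOrganoidMask <- function(params) {
  validObject(params)
  geo <- .capsuleGeometry(params)
  W <- params@widthPx
  m <- params@marginPx
  rmin <- min(geo$mid[, 1L]) - W / 2
  rmax <- max(geo$mid[, 1L]) + W / 2
  cmin <- min(geo$mid[, 2L]) - W / 2
  cmax <- max(geo$mid[, 2L]) + W / 2
  nr <- ceiling(rmax - rmin) + 2 * m
  nc <- ceiling(cmax - cmin) + 2 * m
  if (length(params@gridRows) && length(params@gridCols)) {
    if (nr > params@gridRows || nc > params@gridCols)
      stop("capsule plus margin (", nr, " x ", nc,
           " px) exceeds the requested grid (", params@gridRows, " x ",
           params@gridCols, " px)")
    nr <- params@gridRows
    nc <- params@gridCols
  }
  roff <- m - rmin + 1  # reference frame -> 1-based pixel rows
  coff <- m - cmin + 1
  rr <- matrix(seq_len(nr), nr, nc) - roff
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - coff
  mask <- geo$distFun(as.numeric(rr), as.numeric(cc)) <= W / 2
  mask <- matrix(mask, nr, nc)
  mid <- cbind(geo$mid[, 1L] + roff, geo$mid[, 2L] + coff)
  colnames(mid) <- c("row", "col")
  # pole pixels can round a fraction of a pixel beyond the analytic
  # boundary; absorb them so the centerline lies in the mask exactly
  mask[cbind(round(mid[, 1L]), round(mid[, 2L]))] <- TRUE
  new("SyntheticOrganoid", mask = mask, trueMidline = mid,
      trueOrientation = character(0),
      cells = DataFrame(cell_id = character(0), row = numeric(0),
                        col = numeric(0), s_true = numeric(0)),
      counts = NULL, params = params)
}

#' Scatter cells uniformly over an organoid mask
#'
#' Samples cell centroids uniformly over the true mask pixels and assigns
#' each cell its true axial position \code{s_true}: the arc-length fraction
#' of the nearest centerline point, with ties broken toward the lower
#' arc-length index.
#'
#' @param organoid a [SyntheticOrganoid] with a mask.
#' @param nCells number of cells; 0 yields an empty table, negative errors.
#' @param seed optional seed; when \code{NULL} the current RNG stream is
#'   used (as [simulateOrganoid()] does, drawing everything from one
#'   generator).
#' @return a \code{DataFrame} with columns \code{cell_id}, \code{row},
#'   \code{col}, \code{s_true}.
#' @examples
#' org <- makeOrganoidMask(SimParams(lengthPx = 120, widthPx = 40))
#' head(scatterCells(org, 10, seed = 1))
#' @export
scatterCells <- function(organoid, nCells = simParams(organoid)@nCells,
                         seed = NULL) {
  .stopIfEmptyMask(organoid@mask)
  if (nCells < 0) stop("nCells must be >= 0")
  nCells <- as.integer(nCells)
  if (nCells == 0L)
    return(DataFrame(cell_id = character(0), row = numeric(0),
                     col = numeric(0), s_true = numeric(0)))
  px <- which(organoid@mask)
  draw <- .withSeed(seed, sample(length(px), nCells, replace = TRUE))
  lin <- px[draw]
  nr <- nrow(organoid@mask)
  r <- (lin - 1L) %% nr + 1L
  c <- (lin - 1L) %/% nr + 1L
  np <- .nearestPoint(cbind(r, c), organoid@trueMidline)
  M <- nrow(organoid@trueMidline)
  sTrue <- (np$index - 1) / (M - 1)
  DataFrame(cell_id = sprintf("cell_%05d", seq_len(nCells)),
            row = as.numeric(r), col = as.numeric(c), s_true = sTrue)
}

#' Simulate in situ counts with opposing axial gradients
#'
#' Draws a cell-by-gene count matrix in which chondrogenic genes follow a
#' mean of \code{baseRate * (1 + beta * (1 - p))}, fibroblast genes
#' \code{baseRate * (1 + beta * p)}, and background genes a flat
#' \code{baseRate}, where p is the proximal-to-distal coordinate of each
#' cell (p = 0 at the proximal end, so the chondrogenic set peaks
#' proximally). Counts are Poisson, or negative binomial with variance
#' \code{mu + dispersion * mu^2} when \code{dispersion > 0}.
#'
#' @param cells a cell table with an \code{s_true} column.
#' @param geneSets list with \code{chondrogenic} and \code{fibroblast}
#'   members; the two sets must not overlap.
#' @param params a [SimParams].
#' @param proximalEnd \code{"first"} or \code{"last"}: which centerline end
#'   is proximal, i.e. p = s_true or p = 1 - s_true.
#' @param seed optional seed (see [scatterCells()]).
#' @return a \code{SingleCellExperiment} (genes x cells) with a
#'   \code{counts} assay, cell metadata in \code{colData} and the gene-set
#'   membership in \code{rowData}.
#' @export
simulateCounts <- function(cells, geneSets = defaultGeneSets(), params,
                           proximalEnd = c("first", "last"), seed = NULL) {
  proximalEnd <- match.arg(proximalEnd)
  if (!nrow(cells)) stop("no cells to simulate counts for")
  if (is.null(cells$s_true) || anyNA(cells$s_true))
    stop("every cell must have an s_true axial position")
  if (length(intersect(geneSets$chondrogenic, geneSets$fibroblast)))
    stop("gene sets overlap: ",
         paste(intersect(geneSets$chondrogenic, geneSets$fibroblast),
               collapse = ", "))
  nBg <- as.integer(params@nBackgroundGenes)
  genes <- c(geneSets$chondrogenic, geneSets$fibroblast,
             if (nBg > 0L) sprintf("Bg%03d", seq_len(nBg)))
  setOf <- c(rep("chondrogenic", length(geneSets$chondrogenic)),
             rep("fibroblast", length(geneSets$fibroblast)),
             rep("background", nBg))
  p <- if (proximalEnd == "first") cells$s_true else 1 - cells$s_true
  beta <- params@effectSize
  base <- params@baseRate
  mu <- matrix(base, length(genes), nrow(cells),
               dimnames = list(genes, cells$cell_id))
  mu[setOf == "chondrogenic", ] <-
    matrix(base * (1 + beta * (1 - p)), sum(setOf == "chondrogenic"),
           nrow(cells), byrow = TRUE)
  mu[setOf == "fibroblast", ] <-
    matrix(base * (1 + beta * p), sum(setOf == "fibroblast"),
           nrow(cells), byrow = TRUE)
  counts <- .withSeed(seed, {
    if (params@dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
             dimnames = dimnames(mu))
    } else {
      matrix(stats::rnbinom(length(mu), size = 1 / params@dispersion,
                            mu = mu),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    }
  })
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = as(cells, "DataFrame"),
    rowData = DataFrame(gene = genes, geneSet = setOf),
    metadata = list(proximalEnd = proximalEnd)
  )
}

#' Generate a complete synthetic organoid
#'
#' Runs mask construction, cell scattering, a seeded coin flip for the
#' proximal end, and count simulation from a single global generator, so
#' that identical parameters (including seed) reproduce the organoid
#' bit-identically.
#'
#' @param params a [SimParams].
#' @param geneSets gradient gene sets, see [simulateCounts()].
#' @return a [SyntheticOrganoid] with mask, centerline, orientation, cells
#'   and counts.
#' @examples
#' org <- simulateOrganoid(SimParams(lengthPx = 120, widthPx = 40,
#'                                   nCells = 50, seed = 3L))
#' trueOrientation(org)
#' @export
simulateOrganoid <- function(params, geneSets = defaultGeneSets()) {
  org <- makeOrganoidMask(params)
  .withSeed(params@seed, {
    cells <- scatterCells(org, params@nCells, seed = NULL)
    proximalEnd <- sample(c("first", "last"), 1L)
    counts <- simulateCounts(cells, geneSets, params,
                             proximalEnd = proximalEnd, seed = NULL)
    org@cells <- cells
    org@counts <- counts
    org@trueOrientation <- paste0(proximalEnd, "-is-proximal")
  })
  validObject(org)
  org
}

#' Synthetic fluorescence image with an axial intensity gradient
#'
#' Pixel intensity inside the mask is an affine function of the axial
#' position a (arc-length fraction of the nearest centerline point):
#' \code{0.5 + gradient * (a - 0.5)}, so \code{gradient = 0} gives a
#' constant 0.5 and \code{gradient = 1} spans [0, 1] from the first to the
#' last centerline pole. Pixels outside the mask are 0.
#'
#' @param organoid a [SyntheticOrganoid].
#' @param gradient slope of the intensity ramp over the unit-scaled axis.
#' @return numeric matrix of the same size as the mask.
#' @export
makeIntensityImage <- function(organoid, gradient = 1) {
  .stopIfEmptyMask(organoid@mask)
  px <- which(organoid@mask, arr.ind = TRUE)
  np <- .nearestPoint(px, organoid@trueMidline)
  a <- (np$index - 1) / (nrow(organoid@trueMidline) - 1)
  img <- matrix(0, nrow(organoid@mask), ncol(organoid@mask))
  img[organoid@mask] <- 0.5 + gradient * (a - 0.5)
  img
}

#' Crowded projection fixture
#'
#' A fixed test instance for the crowding penalty: a straight 100-point
#' midline with cells clustered isotropically (sd 3 px) around its first
#' coordinate, so that nearest-coordinate projection piles most cells onto
#' a handful of indices.
#'
#' @param nCells number of cells (default 200).
#' @param sd cluster standard deviation in px.
#' @param seed seed for the cell cloud (default 7).
#' @return list with elements \code{midline} (a [Midline]) and \code{cells}
#'   (a \code{DataFrame} with \code{cell_id}, \code{row}, \code{col}).
#' @export
makeCrowdedFixture <- function(nCells = 200L, sd = 3, seed = 7L) {
  path <- cbind(rep(50L, 100L), 30L + 0:99)
  ml <- Midline(path)
  cells <- .withSeed(seed, DataFrame(
    cell_id = sprintf("cell_%05d", seq_len(nCells)),
    row = 50 + stats::rnorm(nCells, 0, sd),
    col = 30 + stats::rnorm(nCells, 0, sd)
  ))
  list(midline = ml, cells = cells)
}
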