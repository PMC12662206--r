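#' Segment the organoid structure from a binarized cell mask
#'
#' Morphological closing (disc radius 50), hole filling, then opening
#' (disc radius 20); only the largest 8-connected component is kept. When
#' any foreground pixel lies within \code{borderTrigger} px of the image
#' boundary the grid is first padded by \code{pad} px on all sides; the
#' padding is retained and recorded in the result's \code{padOffset} so
#' that cell coordinates can be shifted consistently.
#'
#' @param cellMask binarized cell segmentation (logical/numeric matrix or
#'   [OrganoidMask]).
#' @param closeRadius,openRadius disc radii in px for closing and opening.
#' @param pad padding in px added on all sides when triggered.
#' @param borderTrigger distance to the boundary (px) that triggers padding.
#' @return an [OrganoidMask] holding the single-component structure mask.
#' @export
segmentStructure <- function(cellMask, closeRadius = 50L, openRadius = 20L,
                             pad = 100L, borderTrigger = 50L) {
  grid <- .asMaskGrid(cellMask)
  .stopIfEmptyMask(grid, "cell mask")
  px <- which(grid, arr.ind = TRUE)
  nearBorder <- any(px[, 1L] <= borderTrigger) ||
    any(px[, 1L] > nrow(grid) - borderTrigger) ||
    any(px[, 2L] <= borderTrigger) ||
    any(px[, 2L] > ncol(grid) - borderTrigger)
  off <- c(0L, 0L)
  if (nearBorder) {
    padded <- matrix(FALSE, nrow(grid) + 2L * pad, ncol(grid) + 2L * pad)
    padded[pad + seq_len(nrow(grid)), pad + seq_len(ncol(grid))] <- grid
    grid <- padded
    off <- c(pad, pad)
  }
  # morphology runs on the foreground bounding box (plus clearance for the
  # closing dilation) and is re-embedded, which leaves results unchanged
  cr <- .cropToMask(grid, pad = closeRadius + openRadius + 4L)
  img <- cr$grid * 1
  img <- EBImage::closing(img, EBImage::makeBrush(2L * closeRadius + 1L,
                                                  "disc"))
  img <- EBImage::fillHull(img)
  img <- EBImage::opening(img, EBImage::makeBrush(2L * openRadius + 1L,
                                                  "disc"))
  sub <- matrix(as.logical(img > 0.5), nrow(cr$grid), ncol(cr$grid))
  if (!any(sub)) stop("segmentation is empty after opening")
  sub <- .largestComponent8(sub)
  out <- matrix(FALSE, nrow(grid), ncol(grid))
  out[cr$offset[1L] + seq_len(nrow(sub)),
      cr$offset[2L] + seq_len(ncol(sub))] <- sub
  OrganoidMask(out, off)
}

# least-cost 8-connected path between two pixels over a cost map, with
# geometric step weighting: each move costs dist * (cost[a] + cost[b]) / 2.
# The path is confined to `allowed` pixels.
.leastCostPath <- function(cost, allowed, from, to) {
  nr <- nrow(cost); nc <- ncol(cost)
  px <- which(allowed)
  id <- integer(length(allowed))
  id[px] <- seq_along(px)
  ri <- (px - 1L) %% nr + 1L
  ci <- (px - 1L) %/% nr + 1L
  cst <- cost[px]
  eFrom <- integer(0); eTo <- integer(0); eW <- numeric(0)
  for (sh in list(c(1L, 0L, 1), c(0L, 1L, 1),
                  c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
    r2 <- ri + sh[1L]; c2 <- ci + sh[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    sel <- id[nb] > 0L
    a <- id[px[ok]][sel]; b <- id[nb][sel]
    eFrom <- c(eFrom, a); eTo <- c(eTo, b)
    eW <- c(eW, sh[3L] * (cst[a] + cst[b]) / 2)
  }
  g <- igraph::make_graph(rbind(eFrom, eTo), n = length(px),
                          directed = FALSE)
  fromId <- id[(from[2L] - 1L) * nr + from[1L]]
  toId <- id[(to[2L] - 1L) * nr + to[1L]]
  if (fromId == 0L || toId == 0L)
    stop("path endpoints must lie inside the mask")
  sp <- igraph::shortest_paths(g, from = fromId, to = toId, weights = eW,
                               output = "vpath")
  v <- as.integer(sp$vpath[[1L]])
  if (!length(v)) stop("no finite-cost path between the two corners")
  cbind(row = ri[v], col = ci[v])
}

#' Extract the morphological midline of a segmented mask
#'
#' The midline is the least-cost path along the crest of the mask's
#' Euclidean distance transform: (1) the distance transform is computed;
#' (2) its ridge is enhanced with the Meijering neuriteness filter (bright
#' ridges, response in [0, 1]); (3) Harris corner candidates are detected
#' on the mask; (4) the two candidates closest to the two endpoints of the
#' moment-ellipse major axis become the midline ends, so the midline
#' follows the major-axis direction; (5) the minimum-cost 8-connected path
#' between them is traced over the cost map 1 - ridge with geometric step
#' weighting (diagonal moves allowed).
#'
#' @param structMask an [OrganoidMask] from [segmentStructure()] (a single
#'   8-connected component), or a plain mask.
#' @param ridgeSigmas scales (px) of the ridge filter; the response is the
#'   pixel-wise maximum across scales. Default \code{c(1, 3, 5, 7)}: the
#'   EDT crest width tracks organoid thickness, so several scales are
#'   pooled.
#' @param harrisK Harris sensitivity (default 0.05).
#' @param harrisSigma Gaussian sigma of the Harris structure tensor.
#' @param peakMinDistance minimum distance between corner candidates (px).
#' @param peakThresholdRel relative response threshold for candidates.
#' @return a [Midline]; its \code{padOffset} is inherited from the mask.
#' @export
extractMidline <- function(structMask, ridgeSigmas = c(1, 3, 5, 7),
                           harrisK = 0.05, harrisSigma = 1,
                           peakMinDistance = 10L, peakThresholdRel = 0.01) {
  full <- .asMaskGrid(structMask)
  .stopIfEmptyMask(full)
  # all filters are local, so work on the bounding box plus clearance
  cr <- .cropToMask(full, pad = as.integer(ceiling(4 * max(ridgeSigmas))) +
                      peakMinDistance + 2L)
  grid <- cr$grid
  edt <- .edt(grid)
  ridge <- .meijeringRidge(edt, ridgeSigmas)
  rng <- range(ridge)
  if (rng[2L] > rng[1L]) ridge <- (ridge - rng[1L]) / (rng[2L] - rng[1L])
  resp <- .harrisResponse(grid * 1, k = harrisK, sigma = harrisSigma)
  peaks <- .cornerPeaks(resp, minDistance = peakMinDistance,
                        thresholdRel = peakThresholdRel)
  if (nrow(peaks) < 2L)
    stop("fewer than 2 corner candidates detected")
  mom <- .maskMoments(grid)
  major <- 4 * sqrt(mom$eigenvalues[1L])
  e1 <- mom$centroid + major / 2 * mom$majorVector
  e2 <- mom$centroid - major / 2 * mom$majorVector
  d1 <- (peaks[, 1L] - e1[1L])^2 + (peaks[, 2L] - e1[2L])^2
  d2 <- (peaks[, 1L] - e2[1L])^2 + (peaks[, 2L] - e2[2L])^2
  iA <- which.min(d1)
  iB <- which.min(d2)
  if (iA == iB) {
    d2[iA] <- Inf
    iB <- which.min(d2)
  }
  cA <- .snapToMask(peaks[iA, ], grid)
  cB <- .snapToMask(peaks[iB, ], grid)
  path <- .leastCostPath(1 - ridge, grid, cA, cB)
  path[, 1L] <- path[, 1L] + cr$offset[1L]
  path[, 2L] <- path[, 2L] + cr$offset[2L]
  Midline(path, padOffset = .padOffsetOf(structMask))
}

# Euclidean distance transform of the foreground (distance to nearest
# background pixel, center to center).
.edt <- function(grid) {
  d <- EBImage::distmap(grid * 1, metric = "euclidean")
  matrix(as.numeric(d), nrow(grid), ncol(grid))
}

# snap a pixel to the nearest mask pixel (corner responses can peak just
# outside the foreground)
.snapToMask <- function(p, grid) {
  if (grid[p[1L], p[2L]]) return(p)
  px <- which(grid, arr.ind = TRUE)
  j <- which.min((px[, 1L] - p[1L])^2 + (px[, 2L] - p[2L])^2)
  px[j, ]
}

#' Mean deviation of a midline from a reference curve
#'
#' Mean over midline path points of the Euclidean distance to the nearest
#' reference point; the recovery metric used to score extracted midlines
#' against the analytic centerline of synthetic organoids.
#'
#' @param midline a [Midline] or an n x 2 coordinate matrix.
#' @param reference an m x 2 coordinate matrix (or [Midline]).
#' @return mean deviation in pixels.
#' @export
midlineDeviation <- function(midline, reference) {
  p <- if (is(midline, "Midline")) midlinePath(midline) else midline
  r <- if (is(reference, "Midline")) midlinePath(reference) else reference
  if (!nrow(p) || !nrow(r)) stop("midline and reference must be non-empty")
  mean(.nearestPoint(p, r)$dist)
}
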