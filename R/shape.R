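#' Mask morphometrics: area and moment-ellipse axes
#'
#' Computes the pixel area and the major/minor axis lengths of the ellipse
#' with the same normalized second central moments as the mask (the
#' standard region-properties definition), plus the minor/major axis ratio
#' and the three-class elongation call.
#'
#' @param mask a logical matrix, [OrganoidMask] or [SyntheticOrganoid].
#' @return one-row \code{data.frame} with columns \code{area},
#'   \code{majorAxis}, \code{minorAxis}, \code{axisRatio},
#'   \code{orientation} (radians of the major axis from the row axis) and
#'   \code{elongationClass}.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
#' computeShapeMetrics(m)
#' @export
computeShapeMetrics <- function(mask) {
  grid <- .asMaskGrid(mask)
  .stopIfEmptyMask(grid)
  mom <- .maskMoments(grid)
  major <- 4 * sqrt(mom$eigenvalues[1L])
  minor <- 4 * sqrt(mom$eigenvalues[2L])
  ratio <- if (major > 0) minor / major else 1
  data.frame(
    area = sum(grid),
    majorAxis = major,
    minorAxis = minor,
    axisRatio = ratio,
    orientation = atan2(mom$majorVector[2L], mom$majorVector[1L]),
    elongationClass = classifyElongation(min(max(ratio, .Machine$double.eps), 1)),
    stringsAsFactors = FALSE
  )
}

#' Three-class elongation call from the axis ratio
#'
#' Minor/major axis ratios of at least 0.85 are called \code{"none"}, ratios
#' in (0.75, 0.85) \code{"short"}, and ratios of at most 0.75 \code{"long"}.
#' The 0.75 boundary goes to \code{"long"}.
#'
#' @param axisRatio minor/major axis ratio(s) in (0, 1]; vectorized.
#' @return character vector of \code{"none"}, \code{"short"}, \code{"long"}.
#' @examples
#' classifyElongation(c(0.9, 0.8, 0.75))
#' @export
classifyElongation <- function(axisRatio) {
  if (any(!is.finite(axisRatio)) || any(axisRatio <= 0) ||
      any(axisRatio > 1))
    stop("axis ratio must lie in (0, 1]")
  ifelse(axisRatio >= 0.85, "none",
         ifelse(axisRatio <= 0.75, "long", "short"))
}

#' Area fold change between two masks
#'
#' Ratio of the later mask's pixel area to the earlier one's, a proxy for
#' growth from initial aggregate to final structure.
#'
#' @param maskT0,maskT1 masks at the two time points (any form accepted by
#'   [computeShapeMetrics()]).
#' @return a single number, area(t1) / area(t0).
#' @export
areaFoldChange <- function(maskT0, maskT1) {
  g0 <- .asMaskGrid(maskT0)
  g1 <- .asMaskGrid(maskT1)
  .stopIfEmptyMask(g0, "mask at t0")
  .stopIfEmptyMask(g1, "mask at t1")
  sum(g1) / sum(g0)
}

# bilinear interpolation of img at fractional (row, col) positions
.bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  nr <- nrow(img); nc <- ncol(img)
  cl <- function(x, n) pmin(pmax(x, 1L), n)
  v00 <- img[cbind(cl(r0, nr), cl(c0, nc))]
  v10 <- img[cbind(cl(r0 + 1, nr), cl(c0, nc))]
  v01 <- img[cbind(cl(r0, nr), cl(c0 + 1, nc))]
  v11 <- img[cbind(cl(r0 + 1, nr), cl(c0 + 1, nc))]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Normalized intensity profile along the mask's major axis
#'
#' Samples the image along the line through the mask centroid in the
#' major-axis direction at unit-pixel steps with bilinear interpolation
#' (emulating a 1-px line-profile tool), keeps samples whose pixel lies in
#' the mask, min-max normalizes gray values and positions to [0, 1], and
#' averages the samples into 200 bins of width 0.005. Empty bins are filled
#' by linear interpolation from their neighbors and flagged with
#' \code{nContributing = 0}.
#'
#' The line direction is canonicalized (positive column component) so that
#' mirroring the organoid reverses the profile.
#'
#' @param mask mask as in [computeShapeMetrics()].
#' @param image numeric matrix of the same size.
#' @param nBins number of bins (default 200).
#' @return an [IntensityProfile]. When the masked image has no dynamic
#'   range the profile is flagged degenerate and its values are all 0.
#' @export
intensityProfile <- function(mask, image, nBins = 200L) {
  grid <- .asMaskGrid(mask)
  .stopIfEmptyMask(grid)
  if (!all(dim(grid) == dim(image)))
    stop("mask and image must have the same dimensions")
  mom <- .maskMoments(grid)
  u <- mom$majorVector
  px <- which(grid, arr.ind = TRUE)
  tAll <- (px[, 1L] - mom$centroid[1L]) * u[1L] +
    (px[, 2L] - mom$centroid[2L]) * u[2L]
  tSeq <- seq(floor(min(tAll)), ceiling(max(tAll)), by = 1)
  r <- mom$centroid[1L] + tSeq * u[1L]
  c <- mom$centroid[2L] + tSeq * u[2L]
  ri <- round(r); ci <- round(c)
  inside <- ri >= 1 & ri <= nrow(grid) & ci >= 1 & ci <= ncol(grid)
  inside[inside] <- grid[cbind(ri[inside], ci[inside])]
  if (sum(inside) < 2L)
    stop("major-axis line intersects fewer than 2 mask pixels")
  vals <- .bilinear(image, r[inside], c[inside])
  pos <- tSeq[inside]
  pos <- (pos - min(pos)) / (max(pos) - min(pos))
  degenerate <- max(vals) == min(vals)
  if (degenerate) {
    return(new("IntensityProfile",
               positions = (seq_len(nBins) - 0.5) / nBins,
               values = rep(0, nBins),
               nContributing = rep(0L, nBins), degenerate = TRUE))
  }
  vals <- (vals - min(vals)) / (max(vals) - min(vals))
  bin <- pmin(floor(pos * nBins) + 1L, nBins)
  n <- tabulate(bin, nBins)
  sums <- rep(0, nBins)
  agg <- tapply(vals, bin, sum)
  sums[as.integer(names(agg))] <- agg
  centers <- (seq_len(nBins) - 0.5) / nBins
  means <- ifelse(n > 0L, sums / n, NA_real_)
  if (anyNA(means)) {
    filled <- stats::approx(centers[n > 0L], means[n > 0L], xout = centers,
                            rule = 2)$y
    means[n == 0L] <- filled[n == 0L]
  }
  new("IntensityProfile", positions = centers, values = means,
      nContributing = as.integer(n), degenerate = FALSE)
}

#' Average intensity profiles across organoids
#'
#' Per-bin mean over the non-degenerate profiles; degenerate profiles are
#' excluded, and averaging only degenerate profiles is an error.
#'
#' @param profiles list of [IntensityProfile] objects.
#' @return an [IntensityProfile] whose \code{nContributing} counts the
#'   profiles contributing samples to each bin.
#' @export
averageProfiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  ok <- !vapply(profiles, isDegenerate, logical(1L))
  if (!any(ok)) stop("all profiles are degenerate")
  profiles <- profiles[ok]
  vals <- vapply(profiles, profileValues,
                 numeric(length(profileValues(profiles[[1L]]))))
  nc <- vapply(profiles, function(p) as.integer(p@nContributing > 0L),
               integer(length(profileValues(profiles[[1L]]))))
  new("IntensityProfile",
      positions = profilePositions(profiles[[1L]]),
      values = rowMeans(vals),
      nContributing = as.integer(rowSums(nc)),
      degenerate = FALSE)
}
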