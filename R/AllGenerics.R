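#' @name accessors
#' @title Accessors for OrganoidAxis classes
#' @description Slot accessors for the package's S4 containers; use these
#'   rather than \code{@}.
#' @param x an OrganoidAxis object.
#' @return the slot contents (see the individual class pages).
NULL

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname accessors
#' @export
setGeneric("padOffset", function(x) standardGeneric("padOffset"))
#' @rdname accessors
#' @export
setGeneric("midlinePath", function(x) standardGeneric("midlinePath"))
#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setGeneric("endpoints", function(x) standardGeneric("endpoints"))
#' @rdname accessors
#' @export
setGeneric("trueMidline", function(x) standardGeneric("trueMidline"))
#' @rdname accessors
#' @export
setGeneric("trueOrientation", function(x) standardGeneric("trueOrientation"))
#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))
#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
#' @rdname accessors
#' @export
setGeneric("assignedIndex", function(x) standardGeneric("assignedIndex"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("axialPosition", function(x) standardGeneric("axialPosition"))
#' @rdname accessors
#' @export
setGeneric("proximalScore", function(x) standardGeneric("proximalScore"))
#' @rdname accessors
#' @export
setGeneric("distalScore", function(x) standardGeneric("distalScore"))
#' @rdname accessors
#' @export
setGeneric("polarizationClass", function(x) standardGeneric("polarizationClass"))
#' @rdname accessors
#' @export
setGeneric("axisOrientation", function(x) standardGeneric("axisOrientation"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
setMethod("maskGrid", "OrganoidMask", function(x) x@grid)
#' @rdname accessors
setMethod("maskGrid", "SyntheticOrganoid", function(x) x@mask)
#' @rdname accessors
setMethod("padOffset", "OrganoidMask", function(x) x@padOffset)
#' @rdname accessors
setMethod("padOffset", "Midline", function(x) x@padOffset)
#' @rdname accessors
setMethod("midlinePath", "Midline", function(x) x@path)
#' @rdname accessors
setMethod("arcLength", "Midline", function(x) x@arclen)
#' @rdname accessors
setMethod("endpoints", "Midline", function(x)
  x@path[c(1L, nrow(x@path)), , drop = FALSE])
#' @rdname accessors
setMethod("trueMidline", "SyntheticOrganoid", function(x) x@trueMidline)
#' @rdname accessors
setMethod("trueOrientation", "SyntheticOrganoid", function(x) x@trueOrientation)
#' @rdname accessors
setMethod("cellTable", "SyntheticOrganoid", function(x) x@cells)
#' @rdname accessors
setMethod("expressionData", "SyntheticOrganoid", function(x) x@counts)
#' @rdname accessors
setMethod("simParams", "SyntheticOrganoid", function(x) x@params)
#' @rdname accessors
setMethod("assignedIndex", "ProjectionResult", function(x)
  stats::setNames(x@index, x@cellId))
#' @rdname accessors
setMethod("occupancy", "ProjectionResult", function(x) x@occupancy)
#' @rdname accessors
setMethod("axialPosition", "ProjectionResult", function(x)
  stats::setNames(x@s, x@cellId))
#' @rdname accessors
setMethod("proximalScore", "PolarityScores", function(x) x@proximalScore)
#' @rdname accessors
setMethod("distalScore", "PolarityScores", function(x) x@distalScore)
#' @rdname accessors
setMethod("polarizationClass", "PolarityScores", function(x) x@classLabel)
#' @rdname accessors
setMethod("axisOrientation", "PolarityScores", function(x) x@orientation)
#' @rdname accessors
setMethod("profileValues", "IntensityProfile", function(x) x@values)
#' @rdname accessors
setMethod("profilePositions", "IntensityProfile", function(x) x@positions)
#' @rdname accessors
setMethod("isDegenerate", "IntensityProfile", function(x) x@degenerate)

setMethod("show", "SimParams", function(object) {
  cat("SimParams: capsule", object@lengthPx, "x", object@widthPx,
      "px, curvature", object@curvature, "/px\n")
  cat("  cells:", object@nCells,
      "| genes: 2 gradient sets +", object@nBackgroundGenes, "background\n")
  cat("  baseRate:", object@baseRate, "| effectSize:", object@effectSize,
      "| dispersion:", object@dispersion, "| seed:", object@seed, "\n")
})

setMethod("show", "OrganoidMask", function(object) {
  cat("OrganoidMask:", nrow(object@grid), "x", ncol(object@grid),
      "px,", sum(object@grid), "foreground px, padOffset (",
      object@padOffset[1L], ",", object@padOffset[2L], ")\n")
})

setMethod("show", "Midline", function(object) {
  cat("Midline:", nrow(object@path), "points, arc length",
      round(max(object@arclen), 1), "px\n")
  ep <- endpoints(object)
  cat("  endpoints: (", ep[1, 1], ",", ep[1, 2], ") -> (",
      ep[2, 1], ",", ep[2, 2], ")\n")
})

setMethod("show", "SyntheticOrganoid", function(object) {
  cat("SyntheticOrganoid:", nrow(object@mask), "x", ncol(object@mask),
      "px mask,", sum(object@mask), "foreground px\n")
  cat("  centerline:", nrow(object@trueMidline), "points | cells:",
      nrow(object@cells), "| counts:",
      if (is.null(object@counts)) "none" else
        paste(dim(object@counts), collapse = " x "), "\n")
  if (length(object@trueOrientation))
    cat("  true orientation:", object@trueOrientation, "\n")
})

setMethod("show", "ProjectionResult", function(object) {
  cat("ProjectionResult:", length(object@cellId), "cells on",
      length(object@occupancy), "midline coordinates (alpha =",
      object@alpha, ")\n")
  cat("  max occupancy:", if (length(object@occupancy)) max(object@occupancy)
      else 0L,
      "| oriented:", !all(is.na(object@s)), "\n")
})

setMethod("show", "PolarityScores", function(object) {
  cat("PolarityScores:", object@classLabel, "\n")
  cat("  proximal (chondrogenic):", signif(object@proximalScore, 4),
      "| distal (fibroblast):", signif(object@distalScore, 4), "\n")
  if (length(object@orientation))
    cat("  orientation:", object@orientation, "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "IntensityProfile", function(object) {
  cat("IntensityProfile:", length(object@values), "bins",
      if (object@degenerate) "(degenerate)" else "", "\n")
})
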