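# fixtures built in code; nothing is stored on disk

smallParams <- function(seed = 11L, ...) {
  SimParams(lengthPx = 120, widthPx = 40, nCells = 80, seed = seed, ...)
}

discMask <- function(radius, size = 2L * radius + 11L,
                     center = c(size / 2, size / 2)) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  (rr - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

ellipseMask <- function(a, b, size = 2L * max(a, b) + 11L) {
  ctr <- size / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  ((cc - ctr) / a)^2 + ((rr - ctr) / b)^2 <= 1
}

squareMask <- function(side, size = side + 10L, at = c(6L, 6L)) {
  m <- matrix(FALSE, size, size)
  m[at[1L]:(at[1L] + side - 1L), at[2L]:(at[2L] + side - 1L)] <- TRUE
  m
}

# small panel SCE: genes x cells with named genes
toySCE <- function(counts) {
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

# brute-force nearest-coordinate oracle for projection at alpha = 0
nearestCoordOracle <- function(cells, path) {
  vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (path[, 1L] - cells$row[i])^2 + (path[, 2L] - cells$col[i])^2
    which.min(d2)
  }, integer(1L))
}

# brute-force all-pairs mean nearest distance (midlineDeviation oracle)
bruteDeviation <- function(p, ref) {
  mean(vapply(seq_len(nrow(p)), function(i)
    sqrt(min((ref[, 1L] - p[i, 1L])^2 + (ref[, 2L] - p[i, 2L])^2)),
    numeric(1L)))
}

# orientation recovery helper: TRUE when the predicted proximal midline end
# is closer to the true proximal pole than to the true distal pole
orientationRecovered <- function(org, midline, scores) {
  ep <- endpoints(midline)
  tm <- trueMidline(org)
  pred <- if (axisOrientation(scores) == "first-is-proximal") ep[1L, ]
    else ep[2L, ]
  firstProx <- trueOrientation(org) == "first-is-proximal"
  tp <- if (firstProx) tm[1L, ] else tm[nrow(tm), ]
  td <- if (firstProx) tm[nrow(tm), ] else tm[1L, ]
  sum((pred - tp)^2) < sum((pred - td)^2)
}
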