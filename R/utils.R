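# shared internal helpers

# coerce OrganoidMask / numeric / logical matrix to a logical grid
.asMaskGrid <- function(x) {
  if (is(x, "OrganoidMask")) return(x@grid)
  if (is(x, "SyntheticOrganoid")) return(x@mask)
  if (is.matrix(x)) {
    if (is.logical(x)) return(x)
    return(x > 0)
  }
  stop("cannot interpret object of class ", class(x)[1L], " as a mask")
}

.padOffsetOf <- function(x) {
  if (is(x, "OrganoidMask") || is(x, "Midline")) return(x@padOffset)
  c(0L, 0L)
}

# nearest reference point for each query point; ties go to the lower index.
# Chunked so that n_query x n_ref never materializes at full size.
.nearestPoint <- function(query, ref, chunk = 4096L) {
  nq <- nrow(query)
  idx <- integer(nq)
  dst <- numeric(nq)
  rr <- ref[, 1L]; rc <- ref[, 2L]
  for (start in seq(1L, nq, by = chunk)) {
    end <- min(start + chunk - 1L, nq)
    qr <- query[start:end, 1L]; qc <- query[start:end, 2L]
    d2 <- outer(qr, rr, "-")^2 + outer(qc, rc, "-")^2
    j <- max.col(-d2, ties.method = "first")
    idx[start:end] <- j
    dst[start:end] <- sqrt(d2[cbind(seq_along(j), j)])
  }
  list(index = idx, dist = dst)
}

# evaluate expr with a temporary RNG state seeded by `seed`;
# the caller's RNG stream is restored afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# biased second central moments of a mask; returns centroid, eigenvalues
# (decreasing) and the major-axis unit vector with a fixed sign convention
# (positive column component, ties broken toward positive row).
.maskMoments <- function(grid) {
  px <- which(grid, arr.ind = TRUE)
  r <- px[, 1L]; c <- px[, 2L]
  r0 <- mean(r); c0 <- mean(c)
  mu20 <- mean((r - r0)^2); mu02 <- mean((c - c0)^2)
  mu11 <- mean((r - r0) * (c - c0))
  e <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2L), symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (v[2L] < 0 || (v[2L] == 0 && v[1L] < 0)) v <- -v
  list(centroid = c(r0, c0), eigenvalues = pmax(e$values, 0),
       majorVector = v)
}

# largest 8-connected component of a logical grid (EBImage::bwlabel is
# 4-connected, so components are built on the pixel adjacency graph).
.largestComponent8 <- function(grid) {
  px <- which(grid)
  if (!length(px)) stop("empty mask")
  nr <- nrow(grid)
  nc <- ncol(grid)
  id <- integer(length(grid))
  id[px] <- seq_along(px)
  # column-major linear index shifts for the 4 forward neighbors
  edges <- list()
  k <- 1L
  ri <- (px - 1L) %% nr + 1L
  ci <- (px - 1L) %/% nr + 1L
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- ri + sh[1L]; c2 <- ci + sh[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    sel <- id[nb] > 0L
    if (any(sel)) {
      edges[[k]] <- rbind(id[px[ok]][sel], id[nb][sel])
      k <- k + 1L
    }
  }
  g <- igraph::make_graph(if (length(edges)) c(do.call(cbind, edges)) else
    integer(0), n = length(px), directed = FALSE)
  comp <- igraph::components(g)
  keep <- px[comp$membership == which.max(comp$csize)]
  out <- matrix(FALSE, nr, nc)
  out[keep] <- TRUE
  out
}

# crop a grid to the foreground bounding box plus `pad` background pixels;
# returns the cropped grid and the (row, col) offset such that
# full = cropped + offset
.cropToMask <- function(grid, pad) {
  px <- which(grid, arr.ind = TRUE)
  r1 <- max(1L, min(px[, 1L]) - pad)
  r2 <- min(nrow(grid), max(px[, 1L]) + pad)
  c1 <- max(1L, min(px[, 2L]) - pad)
  c2 <- min(ncol(grid), max(px[, 2L]) + pad)
  list(grid = grid[r1:r2, c1:c2, drop = FALSE],
       offset = c(r1 - 1L, c1 - 1L))
}

.stopIfEmptyMask <- function(grid, what = "mask") {
  if (!any(grid)) stop(what, " has no foreground pixels")
  invisible(TRUE)
}
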