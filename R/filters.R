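# Ridge and corner filters used by midline extraction.
#
# These are faithful ports of the standard algorithms: the Meijering
# neuriteness measure (modified-Hessian eigenvalues, per-scale max
# normalization, pixel-wise max across scales) and the Harris corner
# response (Sobel structure tensor, det - k * trace^2) with
# minimum-distance corner peak picking. Unit tests pin them against
# frozen values from an independent reference implementation.

# sampled Gaussian (order 0) or Gaussian first-derivative (order 1) kernel;
# the order-0 kernel is normalized to unit sum before differentiation.
.gaussKernel1d <- function(sigma, order = 0L, truncate = 8) {
  radius <- as.integer(floor(truncate * sigma + 0.5))
  x <- seq(-radius, radius)
  g <- exp(-(x^2) / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) g else -x / sigma^2 * g
}

# 2-D separable filtering with replicate borders; `kr` runs along rows.
.filterSep <- function(img, kr, kc) {
  EBImage::filter2(img, outer(kr, kc), boundary = "replicate")
}

# Hessian of a Gaussian-smoothed image at scale sigma, computed as two
# successive first-order Gaussian derivative passes at sigma / sqrt(2).
.hessianGaussian <- function(img, sigma, truncate = 8) {
  s <- sigma / sqrt(2)
  # keep kernels smaller than the image so FFT filtering stays valid
  maxr <- (min(dim(img)) - 1L) %/% 2L
  trunc <- min(truncate, max(1, (maxr - 1) / s))
  g0 <- .gaussKernel1d(s, 0L, trunc)
  g1 <- .gaussKernel1d(s, 1L, trunc)
  dr <- .filterSep(img, g1, g0)   # d/drow, smoothed along cols
  dc <- .filterSep(img, g0, g1)
  list(
    rr = .filterSep(dr, g1, g0),
    rc = .filterSep(dr, g0, g1),
    cc = .filterSep(dc, g0, g1)
  )
}

# Meijering neuriteness response, bright ridges, in [0, 1].
.meijeringRidge <- function(img, sigmas = c(1, 3, 5, 7)) {
  img <- -img  # detect bright ridges via the black-ridge formulation
  out <- matrix(0, nrow(img), ncol(img))
  for (sigma in sigmas) {
    H <- .hessianGaussian(img, sigma)
    tr <- H$rr + H$cc
    disc <- sqrt(pmax((H$rr - H$cc)^2 + 4 * H$rc^2, 0))
    e1 <- (tr + disc) / 2  # decreasing order: e1 >= e2
    e2 <- (tr - disc) / 2
    v1 <- e1 + e2 / 3      # modified eigenvalues, alpha = 1/3 in 2-D
    v2 <- e2 + e1 / 3
    vals <- ifelse(abs(v1) >= abs(v2), v1, v2)
    vals <- pmax(vals, 0)
    mx <- max(vals)
    if (mx > 0) vals <- vals / mx
    out <- pmax(out, vals)
  }
  out
}

# Sobel derivative along rows (axis = 1) or columns (axis = 2), zero padding.
.sobel <- function(img, axis) {
  d <- c(1, 0, -1); s <- c(1, 2, 1)
  k <- if (axis == 1L) outer(d, s) else outer(s, d)
  pad <- matrix(0, nrow(img) + 2L, ncol(img) + 2L)
  pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  out <- EBImage::filter2(pad, k, boundary = "replicate")
  out[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)]
}

# Gaussian smoothing with zero ("constant") borders, scipy-style truncate 4.
.gaussSmoothConstant <- function(img, sigma, truncate = 4) {
  radius <- as.integer(floor(truncate * sigma + 0.5))
  g <- .gaussKernel1d(sigma, 0L, truncate)
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2L * radius, nc + 2L * radius)
  pad[radius + seq_len(nr), radius + seq_len(nc)] <- img
  out <- .filterSep(pad, g, g)
  out[radius + seq_len(nr), radius + seq_len(nc)]
}

# Harris corner response det(A) - k * trace(A)^2 from the Sobel structure
# tensor smoothed with a Gaussian of the given sigma.
.harrisResponse <- function(img, k = 0.05, sigma = 1) {
  gr <- .sobel(img, 1L)
  gc <- .sobel(img, 2L)
  arr <- .gaussSmoothConstant(gr * gr, sigma)
  arc <- .gaussSmoothConstant(gr * gc, sigma)
  acc <- .gaussSmoothConstant(gc * gc, sigma)
  (arr * acc - arc^2) - k * (arr + acc)^2
}

# Corner peaks: local maxima of the response above a relative threshold,
# thinned so kept peaks are at least minDistance apart (strongest first).
# Returns an n x 2 matrix of (row, col); peaks within minDistance of the
# image border are excluded, as is conventional.
.cornerPeaks <- function(resp, minDistance = 10L, thresholdRel = 0.01) {
  mx <- max(resp)
  if (mx <= 0) return(matrix(integer(0), 0L, 2L))
  thr <- thresholdRel * mx
  win <- 2L * minDistance + 1L
  localMax <- EBImage::dilate(resp, EBImage::makeBrush(win, "box"))
  cand <- which(resp == localMax & resp > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(integer(0), 0L, 2L))
  inb <- cand[, 1L] > minDistance & cand[, 1L] <= nrow(resp) - minDistance &
    cand[, 2L] > minDistance & cand[, 2L] <= ncol(resp) - minDistance
  cand <- cand[inb, , drop = FALSE]
  if (!nrow(cand)) return(matrix(integer(0), 0L, 2L))
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!nrow(keep) ||
        all((keep[, 1L] - p[1L])^2 + (keep[, 2L] - p[2L])^2 >=
            minDistance^2))
      keep <- rbind(keep, p)
  }
  dimnames(keep) <- list(NULL, c("row", "col"))
  keep
}
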