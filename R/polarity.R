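#' Total-count normalization and log transform
#'
#' Scales each cell's counts to a fixed target sum (default 1e4) and
#' applies log(1 + x). Cells with zero total counts are left at zero with
#' a warning; an all-zero matrix is an error.
#'
#' @param x a \code{SingleCellExperiment} with a \code{counts} assay, or a
#'   genes x cells count matrix.
#' @param targetSum per-cell count sum after scaling.
#' @return the same type as \code{x}; a \code{SingleCellExperiment} gains a
#'   \code{lognorm} assay, a matrix is returned transformed.
#' @examples
#' normalizeExpression(matrix(c(1, 1, 2, 2), 2,
#'                     dimnames = list(c("a", "b"), NULL)), targetSum = 4)
#' @export
normalizeExpression <- function(x, targetSum = 1e4) {
  cts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  tot <- colSums(cts)
  if (all(tot == 0)) stop("all cells have zero total counts")
  if (any(tot == 0))
    warning(sum(tot == 0), " cell(s) with zero total counts left at zero")
  sf <- ifelse(tot > 0, targetSum / tot, 0)
  norm <- log1p(sweep(cts, 2L, sf, "*"))
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "lognorm") <- norm
    x
  } else {
    norm
  }
}

#' Gene-set enrichment score with expression-matched controls
#'
#' For each profile (row), the score is the mean normalized expression of
#' the set genes minus the mean of control genes drawn, with a fixed seed,
#' from the expression bin of each set gene: all panel genes are ranked by
#' average expression and divided into \code{nBins} equal-size bins, and
#' \code{ctrlSize} controls are sampled from the bin of every set gene
#' (excluding set genes themselves). When a set gene's bin holds no
#' eligible control genes - possible on small panels where a set
#' monopolizes the top bin - the \code{ctrlSize} nearest-ranked eligible
#' genes are used instead.
#'
#' @param profiles numeric matrix, profiles x genes, with gene column
#'   names; a single profile may be given as a named vector.
#' @param geneSet character vector of set genes; members missing from the
#'   panel are dropped with a warning.
#' @param nBins number of expression bins (default 25).
#' @param ctrlSize number of control genes per set gene (default 50).
#' @param seed seed for the control draw (default 0 for reproducibility).
#' @return numeric vector, one score per profile row.
#' @export
geneSetScore <- function(profiles, geneSet, nBins = 25L, ctrlSize = 50L,
                         seed = 0L) {
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, 1L, dimnames = list(NULL, names(profiles)))
  genes <- colnames(profiles)
  if (is.null(genes)) stop("profiles must have gene column names")
  set <- intersect(geneSet, genes)
  if (!length(set))
    stop("none of the set genes are present in the panel")
  if (length(set) < length(geneSet))
    warning(length(geneSet) - length(set),
            " set gene(s) missing from the panel were dropped")
  avg <- colMeans(profiles, na.rm = TRUE)
  ord <- order(avg)
  rank <- integer(length(genes))
  rank[ord] <- seq_along(ord)
  binOf <- integer(length(genes))
  binOf[ord] <- ceiling(seq_along(ord) * nBins / length(ord))
  eligible <- !(genes %in% set)
  controls <- .withSeed(seed, {
    unlist(lapply(set, function(g) {
      gi <- match(g, genes)
      pool <- which(binOf == binOf[gi] & eligible)
      if (!length(pool)) {
        elig <- which(eligible)
        pool <- elig[order(abs(rank[elig] - rank[gi]))]
        pool <- pool[seq_len(min(ctrlSize, length(pool)))]
        return(pool)
      }
      pool[sample.int(length(pool), ctrlSize,
                      replace = length(pool) < ctrlSize)]
    }))
  })
  if (!length(controls)) stop("no control genes available")
  rowMeans(profiles[, set, drop = FALSE]) -
    rowMeans(profiles[, controls, drop = FALSE])
}

#' Classify tissue polarization from the two domain scores
#'
#' Both scores above the threshold: \code{"polarized"}; both below:
#' \code{"invalid"}; anything else (including scores exactly at the
#' threshold): \code{"nonpolarized"}.
#'
#' @param proximalScore,distalScore the chondrogenic score of the proximal
#'   half and the fibroblast score of the distal half.
#' @param threshold decision threshold (default 0.01).
#' @return one of \code{"polarized"}, \code{"nonpolarized"},
#'   \code{"invalid"}.
#' @examples
#' classifyPolarization(0.02, 0.03)
#' classifyPolarization(0.001, 0.002)
#' @export
classifyPolarization <- function(proximalScore, distalScore,
                                 threshold = 0.01) {
  if (!is.finite(proximalScore) || !is.finite(distalScore))
    stop("scores must be finite")
  if (proximalScore > threshold && distalScore > threshold) "polarized"
  else if (proximalScore < threshold && distalScore < threshold) "invalid"
  else "nonpolarized"
}

#' Split oriented positions into proximal and distal domains
#'
#' Cells with scaled position s < 0.5 are proximal, s >= 0.5 distal (the
#' midpoint goes to the distal half).
#'
#' @param s oriented scaled positions in [0, 1].
#' @return character vector of \code{"proximal"} / \code{"distal"}.
#' @export
splitHalves <- function(s) {
  ifelse(s < 0.5, "proximal", "distal")
}

#' Orient the midline and scale cell positions to [0, 1]
#'
#' Cells are partitioned into \code{nAxisBins} equidistant arc-length bins
#' along the midline and mean normalized expression profiles are computed
#' per bin. The chondrogenic enrichment score of each midline half (the
#' mean of its bins' profiles) decides the orientation: the half with the
#' higher chondrogenic score is proximal. Positions are the arc-length
#' fractions of the assigned coordinates, reversed if needed so that s = 0
#' is the proximal end, and the proximal score (chondrogenic, proximal
#' half) and distal score (fibroblast, distal half) feed the 0.01
#' polarization rule.
#'
#' @param projection a [ProjectionResult].
#' @param expr a \code{SingleCellExperiment} with a \code{lognorm} assay
#'   (see [normalizeExpression()]) whose column names match the projected
#'   cell ids, or a genes x cells normalized matrix.
#' @param geneSets list with \code{chondrogenic}/\code{fibroblast} members.
#' @param nAxisBins number of equidistant axis bins (default 4).
#' @param threshold polarization threshold (default 0.01).
#' @param scoreOn \code{"halves"} (default) scores each half profile;
#'   \code{"whole"} scores the whole-organoid mean profile instead (the
#'   orientation is still decided on the halves).
#' @param seed control-gene seed passed to [geneSetScore()].
#' @return list with elements \code{scores} (a [PolarityScores]),
#'   \code{projection} (the input with oriented \code{s} filled in) and
#'   \code{domains} (per-cell proximal/distal labels from [splitHalves()]).
#' @export
orientAndScale <- function(projection, expr, geneSets = defaultGeneSets(),
                           nAxisBins = 4L, threshold = 0.01,
                           scoreOn = c("halves", "whole"), seed = 0L) {
  scoreOn <- match.arg(scoreOn)
  if (nAxisBins < 2L || nAxisBins %% 2L != 0L)
    stop("nAxisBins must be an even number >= 2")
  norm <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "lognorm") else expr
  if (is.null(colnames(norm)))
    stop("normalized matrix must have cell ids as column names")
  if (!all(projection@cellId %in% colnames(norm)))
    stop("projection and expression matrix share no consistent cell ids")
  norm <- norm[, projection@cellId, drop = FALSE]
  arclen <- projection@arclen
  f <- arclen[projection@index] / max(arclen)
  bin <- pmin(floor(f * nAxisBins) + 1L, nAxisBins)
  flags <- character(0)
  counts <- tabulate(bin, nAxisBins)
  if (any(counts == 0L))
    flags <- c(flags, paste0("empty axis bin(s): ",
                             paste(which(counts == 0L), collapse = ",")))
  # per-bin mean profiles (bins x genes); empty bins stay NA
  binProf <- matrix(NA_real_, nAxisBins, nrow(norm),
                    dimnames = list(NULL, rownames(norm)))
  for (b in which(counts > 0L))
    binProf[b, ] <- rowMeans(norm[, bin == b, drop = FALSE])
  half <- rep(1:2, each = nAxisBins / 2L)
  halves <- rbind(
    colMeans(binProf[half == 1L, , drop = FALSE], na.rm = TRUE),
    colMeans(binProf[half == 2L, , drop = FALSE], na.rm = TRUE)
  )
  if (anyNA(halves)) stop("one midline half contains no cells")
  chondro <- geneSetScore(halves, geneSets$chondrogenic, seed = seed)
  fibro <- geneSetScore(halves, geneSets$fibroblast, seed = seed)
  proximalHalf <- which.max(chondro)
  orientation <- if (proximalHalf == 1L) "first-is-proximal" else
    "last-is-proximal"
  s <- if (proximalHalf == 1L) f else 1 - f
  if (scoreOn == "halves") {
    pScore <- chondro[proximalHalf]
    dScore <- fibro[3L - proximalHalf]
  } else {
    whole <- matrix(rowMeans(norm), 1L, dimnames = list(NULL, rownames(norm)))
    pScore <- geneSetScore(whole, geneSets$chondrogenic, seed = seed)
    dScore <- geneSetScore(whole, geneSets$fibroblast, seed = seed)
  }
  binScores <- cbind(
    chondrogenic = geneSetScore(ifelse(is.na(binProf), 0, binProf),
                                geneSets$chondrogenic, seed = seed),
    fibroblast = geneSetScore(ifelse(is.na(binProf), 0, binProf),
                              geneSets$fibroblast, seed = seed)
  )
  scores <- new("PolarityScores",
                proximalScore = unname(pScore), distalScore = unname(dScore),
                classLabel = classifyPolarization(pScore, dScore, threshold),
                orientation = orientation, binScores = binScores,
                flags = flags)
  projection@s <- s
  list(scores = scores, projection = projection,
       domains = stats::setNames(splitHalves(s), projection@cellId))
}
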