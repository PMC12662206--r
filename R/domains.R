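#' Sample-level detected-gene QC filter
#'
#' A sample is kept iff the number of genes detected (at least one count
#' across all cells) reaches \code{minGenes}; samples below the cutoff are
#' excluded from further analysis. The filter is monotone: adding counts to
#' a kept sample can never exclude it.
#'
#' @param matrices named list of per-sample count matrices (genes x cells)
#'   or \code{SingleCellExperiment}s.
#' @param minGenes detection cutoff (default 180; "lower than 180" is
#'   excluded, so exactly 180 detected genes is kept).
#' @return the list restricted to kept samples, with an attribute
#'   \code{detectedGenes} giving the per-sample detected-gene counts.
#' @export
qcFilterSamples <- function(matrices, minGenes = 180L) {
  detected <- vapply(matrices, function(m) {
    cts <- if (is(m, "SummarizedExperiment"))
      SummarizedExperiment::assay(m, "counts") else m
    sum(rowSums(cts > 0) > 0)
  }, numeric(1L))
  kept <- matrices[detected >= minGenes]
  attr(kept, "detectedGenes") <- detected
  kept
}

#' Per-domain mean expression summaries
#'
#' Averages the normalized expression layer over the cells of each domain
#' (proximal / distal, optionally the whole sample), producing one summary
#' column per (sample, domain). The number of cells expressing each gene is
#' kept alongside so that pooled detection fractions can be computed later.
#'
#' @param expr \code{SingleCellExperiment} with \code{counts} and
#'   \code{lognorm} assays, or a genes x cells normalized matrix (in which
#'   case detection counts are derived from \code{lognorm > 0}).
#' @param domains per-cell domain labels (\code{"proximal"} /
#'   \code{"distal"}), named by cell id or aligned with the columns.
#' @param sampleId sample identifier recorded in the summary.
#' @param condition optional condition label.
#' @param includeWhole also emit a \code{"whole"} summary over all cells.
#' @return a \code{SummarizedExperiment} with assays \code{meanExpr} and
#'   \code{nExpressing} (genes x summaries) and colData columns
#'   \code{sample_id}, \code{condition}, \code{domain}, \code{n_cells}.
#'   Empty domains are omitted (with a message).
#' @export
summarizeDomains <- function(expr, domains, sampleId = "sample1",
                             condition = NA_character_,
                             includeWhole = FALSE) {
  if (is(expr, "SummarizedExperiment")) {
    norm <- SummarizedExperiment::assay(expr, "lognorm")
    det <- SummarizedExperiment::assay(expr, "counts") > 0
  } else {
    norm <- expr
    det <- norm > 0
  }
  if (!is.null(names(domains))) {
    if (!all(colnames(norm) %in% names(domains)))
      stop("every cell must have a domain label")
    domains <- domains[colnames(norm)]
  } else if (length(domains) != ncol(norm)) {
    stop("every cell must have a domain label")
  }
  groups <- list(proximal = which(domains == "proximal"),
                 distal = which(domains == "distal"))
  if (includeWhole) groups$whole <- seq_len(ncol(norm))
  present <- vapply(groups, length, integer(1L)) > 0L
  if (any(!present))
    message("omitting empty domain(s): ",
            paste(names(groups)[!present], collapse = ", "))
  groups <- groups[present]
  meanExpr <- vapply(groups, function(i)
    rowMeans(norm[, i, drop = FALSE]), numeric(nrow(norm)))
  nExpr <- vapply(groups, function(i)
    rowSums(det[, i, drop = FALSE]), numeric(nrow(norm)))
  colnames(meanExpr) <- colnames(nExpr) <-
    paste(sampleId, names(groups), sep = ".")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(meanExpr = meanExpr, nExpressing = nExpr),
    rowData = S4Vectors::DataFrame(gene = rownames(norm),
                                   row.names = rownames(norm)),
    colData = S4Vectors::DataFrame(
      sample_id = sampleId,
      condition = condition,
      domain = names(groups),
      n_cells = vapply(groups, length, integer(1L)),
      row.names = paste(sampleId, names(groups), sep = ".")
    )
  )
}

#' Combine domain summaries across samples
#'
#' Column-binds summaries produced by [summarizeDomains()], aligning genes
#' by name; genes absent from a sample become missing values (later mean
#' imputed by [pcaDomains()]).
#'
#' @param summaries list of \code{SummarizedExperiment}s from
#'   [summarizeDomains()].
#' @return a combined \code{SummarizedExperiment}.
#' @export
combineSummaries <- function(summaries) {
  if (!length(summaries)) stop("no summaries supplied")
  genes <- Reduce(union, lapply(summaries, rownames))
  align <- function(s, what) {
    m <- matrix(NA_real_, length(genes), ncol(s),
                dimnames = list(genes, colnames(s)))
    m[rownames(s), ] <- SummarizedExperiment::assay(s, what)
    m
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(
      meanExpr = do.call(cbind, lapply(summaries, align, "meanExpr")),
      nExpressing = do.call(cbind, lapply(summaries, align, "nExpressing"))
    ),
    colData = do.call(rbind, lapply(summaries,
                                    SummarizedExperiment::colData))
  )
}

#' PCA of domain summaries with centroid distances
#'
#' Reproduces the averaged-expression PCA comparison: genes expressed in
#' fewer than \code{minCellFraction} of all cells (pooled over summaries)
#' are excluded, missing values are imputed with per-gene means, each gene
#' is standardized to zero mean and unit variance, and the samples are
#' projected onto principal components. For every condition with both
#' domains present, the Euclidean distance between the centroids of its
#' proximal and distal summaries is computed in the first
#' \code{nComponents} components (or the full space with
#' \code{useAllComponents = TRUE}).
#'
#' @param summaries combined summaries (see [combineSummaries()]).
#' @param minCellFraction detection-fraction cutoff for genes
#'   (default 0.01, i.e. 1 percent of cells).
#' @param nComponents components used for the centroid distance.
#' @param useAllComponents compute centroid distances in the full PC space.
#' @return list with \code{embedding} (summaries x components),
#'   \code{explainedVariance} (fractions, non-increasing),
#'   \code{centroidDistance} (named by condition), and
#'   \code{keptGenes}.
#' @export
pcaDomains <- function(summaries, minCellFraction = 0.01,
                       nComponents = 2L, useAllComponents = FALSE) {
  if (ncol(summaries) < 3L) stop("need at least 3 summaries for PCA")
  me <- SummarizedExperiment::assay(summaries, "meanExpr")
  cd <- SummarizedExperiment::colData(summaries)
  ne <- SummarizedExperiment::assay(summaries, "nExpressing")
  totalCells <- sum(cd$n_cells[cd$domain != "whole"])
  # pooled detection fraction per gene; "whole" summaries would double
  # count their sample's cells, so they are excluded from the pool
  nonWhole <- cd$domain != "whole"
  frac <- rowSums(ne[, nonWhole, drop = FALSE], na.rm = TRUE) /
    max(totalCells, 1L)
  keep <- frac >= minCellFraction
  if (!any(keep)) stop("no genes pass the detection filter")
  X <- t(me[keep, , drop = FALSE])
  # mean imputation of missing summary values, per gene
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2L, stats::sd)
  zeroVar <- sds == 0 | !is.finite(sds)
  if (any(zeroVar)) {
    message("dropping ", sum(zeroVar), " zero-variance gene(s) before ",
            "standardization")
    X <- X[, !zeroVar, drop = FALSE]
  }
  if (!ncol(X)) stop("no genes left after the zero-variance drop")
  Z <- scale(X)
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  emb <- p$x
  conds <- unique(cd$condition[!is.na(cd$condition)])
  useK <- if (useAllComponents) ncol(emb) else min(nComponents, ncol(emb))
  centroidDistance <- vapply(conds, function(cnd) {
    sel <- !is.na(cd$condition) & cd$condition == cnd
    ep <- emb[sel & cd$domain == "proximal", seq_len(useK), drop = FALSE]
    ed <- emb[sel & cd$domain == "distal", seq_len(useK), drop = FALSE]
    if (!nrow(ep) || !nrow(ed)) return(NA_real_)
    sqrt(sum((colMeans(ep) - colMeans(ed))^2))
  }, numeric(1L))
  names(centroidDistance) <- conds
  list(embedding = emb, explainedVariance = ev,
       centroidDistance = centroidDistance[!is.na(centroidDistance)],
       keptGenes = colnames(X))
}

#' Per-domain marker expression table
#'
#' Average normalized expression of a marker list within the proximal and
#' distal domains (per condition when conditions are recorded), suitable
#' for heatmap export. Optionally adds a two-sided Wilcoxon rank-sum test
#' of proximal versus distal per-sample domain means with
#' Benjamini-Hochberg correction.
#'
#' @param summaries combined summaries (see [combineSummaries()]).
#' @param markers character vector of marker genes; markers absent from the
#'   panel are omitted with a warning, an empty list is an error.
#' @param test add Wilcoxon p-values (needs at least two samples per
#'   domain).
#' @return \code{data.frame}, one row per marker, one column per
#'   (condition, domain) group mean, plus \code{p.value} / \code{p.adj}
#'   when tested.
#' @export
domainMarkerTable <- function(summaries, markers, test = FALSE) {
  if (!length(markers)) stop("marker list is empty")
  me <- SummarizedExperiment::assay(summaries, "meanExpr")
  cd <- SummarizedExperiment::colData(summaries)
  missing <- setdiff(markers, rownames(me))
  if (length(missing))
    warning("marker(s) absent from the panel omitted: ",
            paste(missing, collapse = ", "))
  markers <- intersect(markers, rownames(me))
  if (!length(markers)) stop("no markers present in the panel")
  sel <- cd$domain %in% c("proximal", "distal")
  grp <- paste(ifelse(is.na(cd$condition), "all", cd$condition),
               cd$domain, sep = ".")[sel]
  sub <- me[markers, sel, drop = FALSE]
  out <- vapply(unique(grp), function(g)
    rowMeans(sub[, grp == g, drop = FALSE], na.rm = TRUE),
    numeric(length(markers)))
  out <- as.data.frame(out)
  if (test) {
    pd <- cd$domain[sel]
    p <- vapply(markers, function(g) {
      x <- sub[g, pd == "proximal"]
      y <- sub[g, pd == "distal"]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, numeric(1L))
    out$p.value <- p
    out$p.adj <- stats::p.adjust(p, method = "BH")
  }
  out
}
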