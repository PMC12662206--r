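# plain-file interchange: TIFF masks/images, CSV tables, MTX matrices,
# YAML gene sets, JSON sidecars

#' Read and write masks and intensity images as TIFF
#'
#' Masks round-trip as 8-bit TIFF (foreground 1), intensity images as
#' 16-bit; matrices are (row, col) with the origin top-left.
#'
#' @param path file path.
#' @param mask logical matrix (or [OrganoidMask]; padding is not stored in
#'   the file).
#' @return \code{readMask} returns a logical matrix; \code{readImage} a
#'   numeric matrix in [0, 1].
#' @name mask-io
NULL

#' @rdname mask-io
#' @export
writeMask <- function(mask, path) {
  grid <- .asMaskGrid(mask)
  tiff::writeTIFF(grid * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname mask-io
#' @export
readMask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' @rdname mask-io
#' @param image numeric matrix scaled to [0, 1].
#' @export
writeIntensityImage <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname mask-io
#' @export
readIntensityImage <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Cell table CSV round-trip
#'
#' Columns \code{cell_id,row,col[,s_true]}.
#'
#' @param cells cell table; \code{path} file path.
#' @return \code{readCellTable} returns a \code{DataFrame}.
#' @name cell-io
NULL

#' @rdname cell-io
#' @param path file path.
#' @export
writeCellTable <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cell-io
#' @export
readCellTable <- function(path) {
  as(utils::read.csv(path, stringsAsFactors = FALSE), "DataFrame")
}

#' Count matrix interchange (MatrixMarket triplet)
#'
#' Writes \code{matrix.mtx} (genes x cells), \code{genes.tsv} and
#' \code{cells.tsv} into a directory, and reads them back into a
#' \code{SingleCellExperiment}.
#'
#' @param x \code{SingleCellExperiment} or genes x cells matrix.
#' @param dir directory (created if missing).
#' @return \code{readCountsMTX} returns a \code{SingleCellExperiment} with
#'   a \code{counts} assay.
#' @name mtx-io
NULL

#' @rdname mtx-io
#' @export
writeCountsMTX <- function(x, dir) {
  cts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(cts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cts), file.path(dir, "genes.tsv"))
  writeLines(colnames(cts), file.path(dir, "cells.tsv"))
  if (is(x, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    utils::write.csv(cd, file.path(dir, "cell_metadata.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname mtx-io
#' @export
readCountsMTX <- function(dir) {
  cts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  if (all(cts == round(cts))) storage.mode(cts) <- "integer"
  rownames(cts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(cts) <- readLines(file.path(dir, "cells.tsv"))
  cd <- NULL
  metaPath <- file.path(dir, "cell_metadata.csv")
  if (file.exists(metaPath))
    cd <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cts),
    colData = if (is.null(cd)) S4Vectors::DataFrame(row.names = colnames(cts))
      else S4Vectors::DataFrame(cd, row.names = colnames(cts))
  )
}

#' Midline CSV round-trip
#'
#' Columns \code{index,row,col,arclen} (and the pad offset as a header
#' comment is avoided; the offset travels in the run manifest).
#'
#' @param midline a [Midline]; \code{path} file path.
#' @return \code{readMidlineCSV} returns a [Midline] (padOffset zero).
#' @name midline-io
NULL

#' @rdname midline-io
#' @param path file path.
#' @export
writeMidlineCSV <- function(midline, path) {
  p <- midlinePath(midline)
  utils::write.csv(data.frame(index = seq_len(nrow(p)), row = p[, 1L],
                              col = p[, 2L], arclen = arcLength(midline)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname midline-io
#' @export
readMidlineCSV <- function(path) {
  d <- utils::read.csv(path)
  Midline(cbind(d$row, d$col), arclen = d$arclen)
}

#' Gene sets YAML round-trip
#'
#' @param geneSets named list of character vectors; \code{path} file path.
#' @return \code{readGeneSets} returns the named list.
#' @name genesets-io
NULL

#' @rdname genesets-io
#' @param path file path.
#' @export
writeGeneSets <- function(geneSets, path) {
  yaml::write_yaml(geneSets, path)
  invisible(path)
}

#' @rdname genesets-io
#' @export
readGeneSets <- function(path) {
  gs <- yaml::read_yaml(path)
  lapply(gs, as.character)
}

#' Write a synthetic organoid to plain files
#'
#' Mask as TIFF, cells as CSV, counts as MTX triplet, and a JSON sidecar
#' recording the simulation parameters and the true orientation.
#'
#' @param organoid a [SyntheticOrganoid].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeOrganoid <- function(organoid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMask(organoid@mask, file.path(dir, "mask.tiff"))
  writeCellTable(organoid@cells, file.path(dir, "cells.csv"))
  if (!is.null(organoid@counts))
    writeCountsMTX(organoid@counts, file.path(dir, "counts"))
  utils::write.csv(
    data.frame(index = seq_len(nrow(organoid@trueMidline)),
               row = organoid@trueMidline[, 1L],
               col = organoid@trueMidline[, 2L]),
    file.path(dir, "true_midline.csv"), row.names = FALSE)
  p <- organoid@params
  jsonlite::write_json(
    list(params = list(lengthPx = p@lengthPx, widthPx = p@widthPx,
                       curvature = p@curvature, nCells = p@nCells,
                       nBackgroundGenes = p@nBackgroundGenes,
                       baseRate = p@baseRate, effectSize = p@effectSize,
                       dispersion = p@dispersion, seed = p@seed,
                       marginPx = p@marginPx),
         trueOrientation = if (length(organoid@trueOrientation))
           organoid@trueOrientation else NULL),
    file.path(dir, "simulation.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
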