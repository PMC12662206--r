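#' Build a pipeline run configuration
#'
#' Collects every stage parameter with the standard analysis constants as
#' defaults: closing/opening disc radii 50/20 px, padding 100 px with a
#' 50 px border trigger, crowding penalty alpha 0.01, polarization
#' threshold 0.01, 4 axis bins, 200 profile bins, QC cutoff 180 detected
#' genes, 1 percent PCA gene filter. Inputs are either file paths (mask,
#' cells CSV, counts MTX directory) or a simulation request.
#'
#' @param simulate run on a simulated organoid instead of input files.
#' @param maskFile,cellsFile,countsDir input paths (ignored when
#'   simulating).
#' @param lengthPx,widthPx,curvature,nCells,nBackgroundGenes,baseRate,effectSize,dispersion
#'   simulation parameters, see [SimParams()].
#' @param seed global seed.
#' @param closeRadius,openRadius,pad,borderTrigger segmentation parameters.
#' @param ridgeSigmas ridge filter scales.
#' @param alpha crowding penalty scale.
#' @param threshold polarization threshold.
#' @param nAxisBins axis bins for orientation.
#' @param nProfileBins intensity profile bins.
#' @param minGenes QC detected-genes cutoff.
#' @param minCellFraction PCA gene detection fraction.
#' @param targetSum normalization target sum.
#' @param outDir output directory.
#' @return a named list of class \code{RunConfig}; serializes losslessly
#'   through [writeRunConfig()] / [readRunConfig()].
#' @export
makeRunConfig <- function(simulate = TRUE, maskFile = NULL,
                          cellsFile = NULL, countsDir = NULL,
                          lengthPx = 400, widthPx = 100, curvature = 0,
                          nCells = 600, nBackgroundGenes = 123,
                          baseRate = 2, effectSize = 4, dispersion = 0,
                          seed = 1L, closeRadius = 50L, openRadius = 20L,
                          pad = 100L, borderTrigger = 50L,
                          ridgeSigmas = c(1, 3, 5, 7), alpha = 0.01,
                          threshold = 0.01, nAxisBins = 4L,
                          nProfileBins = 200L, minGenes = 180L,
                          minCellFraction = 0.01, targetSum = 1e4,
                          outDir = "organoid-axis-run") {
  cfg <- list(simulate = simulate, maskFile = maskFile,
              cellsFile = cellsFile, countsDir = countsDir,
              lengthPx = lengthPx, widthPx = widthPx,
              curvature = curvature, nCells = nCells,
              nBackgroundGenes = nBackgroundGenes, baseRate = baseRate,
              effectSize = effectSize, dispersion = dispersion,
              seed = as.integer(seed), closeRadius = closeRadius,
              openRadius = openRadius, pad = pad,
              borderTrigger = borderTrigger, ridgeSigmas = ridgeSigmas,
              alpha = alpha, threshold = threshold,
              nAxisBins = nAxisBins, nProfileBins = nProfileBins,
              minGenes = minGenes, minCellFraction = minCellFraction,
              targetSum = targetSum, outDir = outDir)
  class(cfg) <- c("RunConfig", "list")
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks every parameter before any stage runs; invalid settings (e.g. a
#' negative crowding penalty) fail here.
#'
#' @param config a \code{RunConfig}.
#' @return the config, invisibly, or an error.
#' @export
validateRunConfig <- function(config) {
  stopifnot(is.list(config))
  if (config$alpha < 0) stop("invalid config: alpha must be >= 0")
  if (config$threshold < 0) stop("invalid config: threshold must be >= 0")
  if (config$closeRadius < 0 || config$openRadius < 0)
    stop("invalid config: morphology radii must be >= 0")
  if (config$nAxisBins < 2) stop("invalid config: nAxisBins must be >= 2")
  if (config$targetSum <= 0) stop("invalid config: targetSum must be > 0")
  if (!config$simulate) {
    for (f in c("maskFile", "cellsFile")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("invalid config: missing input file for ", f)
    }
    if (is.null(config$countsDir) || !dir.exists(config$countsDir))
      stop("invalid config: missing countsDir")
  }
  invisible(config)
}

#' @rdname makeRunConfig
#' @param config a \code{RunConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname makeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$ridgeSigmas <- as.numeric(unlist(cfg$ridgeSigmas))
  class(cfg) <- c("RunConfig", "list")
  validateRunConfig(cfg)
  cfg
}

#' Run the full axis-quantification pipeline
#'
#' Executes simulate/load, structure segmentation, midline extraction,
#' cell filtering and crowding-penalized projection, normalization,
#' orientation and polarization scoring, and per-domain summarization, in
#' order, writing every intermediate artifact plus a manifest of all
#' parameter values to the output directory. Outputs are deterministic
#' given the configuration (including seed).
#'
#' @param config a \code{RunConfig} from [makeRunConfig()] or
#'   [readRunConfig()].
#' @param geneSets orientation gene sets (default [defaultGeneSets()]).
#' @param writeOutputs write stage artifacts to \code{config$outDir}
#'   (set \code{FALSE} to run in memory only).
#' @return (invisibly) a list with the stage results: \code{organoid} (when
#'   simulated), \code{structMask}, \code{midline}, \code{projection},
#'   \code{scores}, \code{domains}, \code{summary}, \code{shape}.
#' @export
runPipeline <- function(config, geneSets = defaultGeneSets(),
                        writeOutputs = TRUE) {
  validateRunConfig(config)
  outDir <- config$outDir
  if (writeOutputs && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  stage <- "input"
  res <- list()
  tryCatch({
    if (config$simulate) {
      params <- SimParams(lengthPx = config$lengthPx,
                          widthPx = config$widthPx,
                          curvature = config$curvature,
                          nCells = config$nCells,
                          nBackgroundGenes = config$nBackgroundGenes,
                          baseRate = config$baseRate,
                          effectSize = config$effectSize,
                          dispersion = config$dispersion,
                          seed = config$seed)
      org <- simulateOrganoid(params, geneSets)
      res$organoid <- org
      mask <- org@mask
      cells <- org@cells
      counts <- org@counts
    } else {
      mask <- readMask(config$maskFile)
      cells <- readCellTable(config$cellsFile)
      counts <- readCountsMTX(config$countsDir)
    }

    stage <- "shape"
    res$shape <- computeShapeMetrics(mask)

    stage <- "segment"
    struct <- segmentStructure(mask, closeRadius = config$closeRadius,
                               openRadius = config$openRadius,
                               pad = config$pad,
                               borderTrigger = config$borderTrigger)
    res$structMask <- struct

    stage <- "midline"
    ml <- extractMidline(struct, ridgeSigmas = config$ridgeSigmas)
    res$midline <- ml

    stage <- "project"
    inCells <- filterCellsInStructure(cells, struct)
    proj <- projectCells(inCells, ml, alpha = config$alpha)

    stage <- "polarity"
    counts <- counts[, colnames(counts) %in% proj@cellId, drop = FALSE]
    norm <- normalizeExpression(counts, targetSum = config$targetSum)
    ori <- orientAndScale(proj, norm, geneSets,
                          nAxisBins = config$nAxisBins,
                          threshold = config$threshold)
    res$projection <- ori$projection
    res$scores <- ori$scores
    res$domains <- ori$domains

    stage <- "domains"
    res$summary <- summarizeDomains(norm, ori$domains,
                                    sampleId = "run",
                                    includeWhole = TRUE)

    if (writeOutputs) {
      stage <- "write"
      if (config$simulate) writeOrganoid(org, file.path(outDir, "input"))
      writeMask(struct@grid, file.path(outDir, "structure_mask.tiff"))
      writeMidlineCSV(ml, file.path(outDir, "midline.csv"))
      utils::write.csv(res$shape, file.path(outDir, "shape_metrics.csv"),
                       row.names = FALSE)
      prj <- res$projection
      utils::write.csv(
        data.frame(cell_id = prj@cellId, index = prj@index, s = prj@s,
                   domain = res$domains[prj@cellId]),
        file.path(outDir, "cell_positions.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(proximalScore = proximalScore(res$scores),
             distalScore = distalScore(res$scores),
             polarizationClass = polarizationClass(res$scores),
             orientation = axisOrientation(res$scores)),
        file.path(outDir, "polarity.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        as.data.frame(SummarizedExperiment::assay(res$summary, "meanExpr")),
        file.path(outDir, "domain_means.csv"))
      manifest <- c(unclass(config),
                    list(package = "OrganoidAxis",
                         version = as.character(
                           utils::packageVersion("OrganoidAxis")),
                         padOffset = as.integer(struct@padOffset)))
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
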