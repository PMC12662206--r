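# OrganoidAxis

Axis quantification for elongated organoid sections profiled with
targeted in situ transcriptomics.

Mesodermal organoids that break symmetry elongate into capsule-shaped
structures with a cartilage-forming (chondrogenic, *proximal*) pole and a
fibroblast-like (*distal*) pole. Sections of such organoids arrive as a
segmentation mask, per-cell centroids, and a cell-by-gene count matrix —
but no shared coordinate system. OrganoidAxis builds one:

1. **Structure segmentation** — closing (disc r = 50 px), hole filling,
   opening (disc r = 20 px), largest 8-connected component; images near
   the border are padded by 100 px with bookkeeping.
2. **Morphological midline** — the minimum-cost 8-connected path over
   `1 − ridge`, where `ridge` is the Meijering neuriteness response of the
   mask's Euclidean distance transform; the ends are Harris corner
   candidates closest to the moment-ellipse major-axis endpoints.
3. **Crowding-penalized projection** — each cell is assigned the midline
   coordinate *i* minimizing

   D′<sub>i,c</sub> = D<sub>i,c</sub> · e<sup>α·N<sub>i</sub></sup>,  α = 0.01,

   where N<sub>i</sub> counts cells already assigned to *i*, spreading
   pile-ups along the axis.
4. **Orientation and polarization** — four arc-length bins; the midline
   half with the higher chondrogenic gene-set enrichment score (Sox9,
   Acan, Col2a1, Col9a1, Col9a2, Col11a1; controls matched by expression
   bin) is proximal; positions are scaled to [0, 1]; sections with both
   the proximal (chondrogenic) and distal (fibroblast: Col1a1, Col3a1)
   scores above 0.01 are *polarized*, both below *invalid*, otherwise
   *nonpolarized*.
5. **Domain summaries** — proximal/distal split at s = 0.5, per-domain
   mean expression, sample QC (≥ 180 detected genes), and a PCA with
   per-condition proximal–distal centroid distances (< 1% detection
   filter, mean imputation, standardization).

Mask morphometrics (moment-ellipse axes; elongation classes none / short
/ long at axis-ratio thresholds 0.85 and 0.75; 200-bin normalized
major-axis intensity profiles) and a synthetic organoid generator with
full ground truth (bent-capsule masks, uniform cells, opposing Poisson /
negative-binomial expression gradients) are included — every stage is
testable offline.

## Worked example

```r
library(OrganoidAxis)

org     <- simulateOrganoid(SimParams(curvature = 0.001, seed = 42L))
struct  <- segmentStructure(maskGrid(org))
midline <- extractMidline(struct)
cells   <- filterCellsInStructure(cellTable(org), struct)
proj    <- projectCells(cells, midline, alpha = 0.01)
norm    <- normalizeExpression(expressionData(org)[, proj@cellId])
res     <- orientAndScale(proj, norm)
res$scores
#> PolarityScores: polarized
#>   proximal (chondrogenic): 1.006 | distal (fibroblast): 1.091
#>   orientation: last-is-proximal
```

The section is called **polarized**: both domain scores are far above the
0.01 threshold. `orientation` refers to the extracted path's own
direction (here the path happens to start at the geometric end that the
generator labelled distal — the recovered proximal pole coincides with
the true one). Recovery against ground truth:

```r
round(midlineDeviation(midline, trueMidline(org)), 2)
#> [1] 2.76                      # px from the analytic centerline
table(res$domains)
#>   distal proximal
#>      276      324
summ <- summarizeDomains(norm, res$domains, sampleId = "demo")
round(SummarizedExperiment::assay(summ, "meanExpr")[
  c("Sox9", "Col1a1", "Bg001"), ], 2)
#>        demo.proximal demo.distal
#> Sox9            5.43        4.61   # chondrogenic marker: proximal-high
#> Col1a1          4.57        5.49   # fibroblast marker: distal-high
#> Bg001           3.74        3.61   # background gene: flat
```

A thin command-line wrapper with `run` / `simulate` / `shape` /
`midline` / `project` / `polarity` subcommands is installed at
`inst/scripts/organoid-axis.R`, and `runPipeline(makeRunConfig(...))`
executes the whole chain with every intermediate artifact and a
parameter manifest written to disk.

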