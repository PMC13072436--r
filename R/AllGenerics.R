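#' @rdname IMSDataset
#' @param x an object.
#' @export
setGeneric("mzAxis", function(x) standardGeneric("mzAxis"))

#' @rdname IMSDataset
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname IMSDataset
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname IMSDataset
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))

#' @rdname IMSDataset
#' @export
setGeneric("originUm", function(x) standardGeneric("originUm"))

#' @rdname IMSDataset
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname AntibodyPanel
#' @param x an object.
#' @export
setGeneric("panelTable", function(x) standardGeneric("panelTable"))

#' Predict class probabilities from a fitted model
#'
#' The narrow interface the attribution stage relies on: any model exposing
#' a `predictProba` method (returning an `n x n_classes` matrix of
#' probabilities, or any per-class model output) can be interpreted. A plain
#' R `function(X) -> matrix` is accepted as a model.
#'
#' @param object a fitted model.
#' @param X numeric matrix of feature rows.
#' @return numeric matrix, one row per row of `X`, one column per class.
#' @export
setGeneric("predictProba", function(object, X) standardGeneric("predictProba"))

## ---- accessors ----

#' @rdname IMSDataset
#' @export
setMethod("mzAxis", "IMSDataset", function(x) rowData(x)$mz)

#' @rdname IMSDataset
#' @export
setMethod("pixelCoords", "IMSDataset", function(x)
  data.frame(row = colData(x)$row, col = colData(x)$col))

#' @rdname IMSDataset
#' @export
setMethod("roiIds", "IMSDataset", function(x) colData(x)$roi_id)

#' @rdname IMSDataset
#' @export
setMethod("pitchUm", "IMSDataset", function(x) metadata(x)$pitch_um)

#' @rdname IMSDataset
#' @export
setMethod("originUm", "IMSDataset", function(x) metadata(x)$origin_um)

#' @rdname IMSDataset
#' @export
setMethod("intensityMatrix", "IMSDataset", function(x) {
  m <- t(assay(x, "intensities"))
  dimnames(m) <- list(NULL, mzLabel(mzAxis(x)))
  m
})

#' @rdname AntibodyPanel
#' @export
setMethod("panelTable", "AntibodyPanel", function(x) x@entries)

#' @rdname MxIFImage
#' @param x an MxIFImage.
#' @export
setMethod("pitchUm", "MxIFImage", function(x) x@pitchUm)

#' @rdname MxIFImage
#' @export
setMethod("originUm", "MxIFImage", function(x) x@originUm)

#' @rdname MxIFImage
#' @export
setMethod("panelTable", "MxIFImage", function(x) x@panel@entries)

#' Channel raster array of an MxIF image
#' @param x an [MxIFImage-class].
#' @return numeric array `H x W x n_channels`.
#' @export
channelArray <- function(x) x@channels

#' Channel names of an MxIF image (antibody targets, in channel order)
#' @param x an [MxIFImage-class].
#' @return character vector.
#' @export
channelNames <- function(x) x@panel@entries$target

## ---- show methods ----

setMethod("show", "MxIFImage", function(object) {
  d <- dim(object@channels)
  cat(sprintf("MxIFImage: %d x %d pixels, %d channels, pitch %g um\n",
              d[1], d[2], d[3], object@pitchUm))
  cat(" channels:", paste(channelNames(object), collapse = ", "), "\n")
})

setMethod("show", "AntibodyPanel", function(object) {
  e <- object@entries
  cat(sprintf("AntibodyPanel: %d antibodies across %d cycles\n",
              nrow(e), max(e$cycle)))
  print(e[, c("target", "cycle", "fluorophore", "conjugation")])
})

setMethod("show", "RegistrationTransform", function(object) {
  cat(sprintf("RegistrationTransform (%s)\n", object@direction))
  cat(" linear part:\n")
  print(object@matrix)
  cat(sprintf(" offset: (%.4g, %.4g) um\n",
              object@offset[1], object@offset[2]))
})

setMethod("show", "SegmentationResult", function(object) {
  n <- sum(!is.na(object@labels))
  cat(sprintf("SegmentationResult: k = %d over %d in-ROI pixels (WSS %.4g)\n",
              object@k, n, object@wss))
  sz <- tabulate(object@labels[!is.na(object@labels)], object@k)
  for (i in seq_len(object@k))
    cat(sprintf("  segment %d: %7d px  %s\n", i, sz[i], object@cellTypes[i]))
})

setMethod("show", "LabeledIMSTable", function(object) {
  cat(sprintf("LabeledIMSTable: %d labeled IMS pixels, %d features, %d excluded\n",
              nrow(object@table), length(object@mz), nrow(object@excluded)))
})

setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf("ClassifierResult: %d classes, %d CV folds\n",
              length(object@classes), max(object@folds)))
  print(classMetrics(object))
})

setMethod("show", "AttributionResult", function(object) {
  cat(sprintf("AttributionResult: %d classes x %d features (%s, %d pixels)\n",
              length(object@classes), length(object@mz),
              object@meta$method, length(object@evaluated)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d x %d cell map, %d cell types, %d features, seed %d\n",
              nrow(object@cellMap), ncol(object@cellMap),
              length(object@cellTypes), ncol(object@lipidMatrix), object@seed))
})

## ---- plain accessors for result classes ----

#' Per-segment classifier metrics (fold mean and SD)
#' @param x a [ClassifierResult-class].
#' @return data.frame with `segment`, `metric`, `mean`, `sd`.
#' @export
classMetrics <- function(x) x@metrics

#' Confusion matrix summed over held-out folds
#' @param x a [ClassifierResult-class].
#' @return matrix (rows = truth, cols = predicted).
#' @export
confusionMatrix <- function(x) x@confusion

#' Global SHAP scores (classes x features)
#' @param x an [AttributionResult-class].
#' @return non-negative numeric matrix.
#' @export
globalScores <- function(x) x@globalScore

#' Correlation-direction signs (classes x features)
#' @param x an [AttributionResult-class].
#' @return matrix with entries in -1/0/+1.
#' @export
directions <- function(x) x@direction

#' Ranked features per class (by descending global score)
#' @param x an [AttributionResult-class].
#' @return named list of integer feature orderings.
#' @export
rankings <- function(x) x@ranking

#' Labeled-pixel table of a LabeledIMSTable
#' @param x a [LabeledIMSTable-class].
#' @return data.frame.
#' @export
labeledTable <- function(x) x@table

#' Intensity matrix aligned with the labeled-pixel table
#' @param x a [LabeledIMSTable-class].
#' @return numeric matrix.
#' @export
labeledIntensities <- function(x) x@intensities

#' Segment labels as a raster matrix in the MxIF frame
#' @param x a [SegmentationResult-class].
#' @param dim dimensions `c(H, W)` of the MxIF raster.
#' @return integer matrix with NA outside the measurement regions.
#' @export
segmentRaster <- function(x, dim) matrix(x@labels, dim[1], dim[2])
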