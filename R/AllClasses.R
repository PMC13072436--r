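#' IMSDataset: a picked-peak imaging mass spectrometry dataset
#'
#' Pixels on a regular grid (rows = m/z features, columns = pixels in the
#' underlying [SummarizedExperiment::SummarizedExperiment]). `rowData` holds
#' the m/z axis, `colData` the 0-based `(row, col)` grid coordinates and the
#' per-pixel ROI (glomerulus) id, `metadata` the physical pixel pitch and the
#' physical coordinate of the corner of pixel `(0, 0)` in micrometres.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [IMSDataset()], [readIMS()], [writeIMS()]
#' @export
setClass("IMSDataset", contains = "SummarizedExperiment")

setValidity("IMSDataset", function(object) {
  msg <- character()
  mz <- rowData(object)$mz
  if (is.null(mz)) msg <- c(msg, "rowData must contain an 'mz' column")
  else {
    if (length(mz) != nrow(object))
      msg <- c(msg, "length(mz) must equal the number of features")
    if (length(mz) > 1L && any(diff(mz) <= 0))
      msg <- c(msg, "m/z axis must be strictly increasing")
  }
  cd <- colData(object)
  for (f in c("row", "col", "roi_id"))
    if (is.null(cd[[f]])) msg <- c(msg, sprintf("colData must contain '%s'", f))
  if (!is.null(cd$row) && !is.null(cd$col)) {
    key <- paste(cd$row, cd$col)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      msg <- c(msg, sprintf("duplicate pixel grid coordinate (row col) = (%s)", d))
    }
  }
  a <- assay(object)
  if (any(!is.finite(a)) || any(a < 0))
    msg <- c(msg, "intensities must be finite and non-negative")
  md <- metadata(object)
  if (is.null(md$pitch_um) || md$pitch_um <= 0)
    msg <- c(msg, "metadata$pitch_um must be a positive pitch in um")
  if (is.null(md$origin_um) || length(md$origin_um) != 2L)
    msg <- c(msg, "metadata$origin_um must be a length-2 physical origin")
  if (length(msg)) msg else TRUE
})

#' Construct an IMSDataset
#'
#' @param intensities numeric matrix, pixels in rows and features in columns
#'   (the natural orientation of a peak table); stored transposed internally.
#' @param mz strictly increasing numeric m/z axis, one value per feature.
#' @param coords integer matrix/data.frame with 0-based `row` and `col` grid
#'   coordinates, one row per pixel.
#' @param roiId integer per-pixel ROI id, 0 meaning outside any ROI.
#' @param pitchUm physical pixel pitch in micrometres (default 5, the pitch
#'   used for high spatial resolution glomerular lipid imaging).
#' @param originUm physical coordinate (x, y) of the corner of pixel (0, 0).
#' @return an [IMSDataset-class] object.
#' @examples
#' ims <- IMSDataset(matrix(1:4, 2), mz = c(703.575, 810.600),
#'                   coords = cbind(row = 0:1, col = c(0L, 0L)))
#' mzAxis(ims)
#' @export
IMSDataset <- function(intensities, mz, coords, roiId = NULL, pitchUm = 5,
                       originUm = c(0, 0)) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) == 0L) stop("no pixels", call. = FALSE)
  coords <- as.data.frame(coords)
  if (is.null(roiId)) roiId <- integer(nrow(intensities))
  cd <- DataFrame(row = as.integer(coords$row), col = as.integer(coords$col),
                  roi_id = as.integer(roiId))
  se <- SummarizedExperiment(
    assays = list(intensities = t(intensities)),
    rowData = DataFrame(mz = as.numeric(mz)),
    colData = cd)
  metadata(se) <- list(pitch_um = pitchUm, origin_um = as.numeric(originUm))
  new("IMSDataset", se)
}

#' AntibodyPanel: the MxIF antibody panel
#'
#' A thin S4 wrapper around a data.frame with one row per antibody:
#' `target`, `cell_structures`, `cycle`, `fluorophore`, `conjugation`
#' (direct/indirect) and `expected_segments` (a list column of canonical
#' cell-type tags the target marks, e.g. podocalyxin -> "podocyte").
#'
#' @slot entries data.frame as described above.
#' @seealso [readPanel()], [glomerularPanel()]
#' @export
setClass("AntibodyPanel", representation(entries = "data.frame"))

setValidity("AntibodyPanel", function(object) {
  e <- object@entries
  need <- c("target", "cell_structures", "cycle", "fluorophore",
            "conjugation", "expected_segments")
  if (!all(need %in% names(e)))
    return(paste("panel must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$target))
    return(sprintf("duplicate antibody target '%s'",
                   e$target[duplicated(e$target)][1L]))
  if (any(e$cycle < 1)) return("cycle must be >= 1")
  if (!all(e$conjugation %in% c("direct", "indirect")))
    return("conjugation must be 'direct' or 'indirect'")
  TRUE
})

#' MxIFImage: a multichannel immunofluorescence raster
#'
#' @slot channels numeric array `H x W x n_channels`, non-negative.
#' @slot pitchUm microscopy pixel pitch in micrometres.
#' @slot originUm physical coordinate (x, y) of the corner of pixel (0, 0).
#' @slot panel [AntibodyPanel-class]; one entry per channel, in channel order.
#' @seealso [MxIFImage()], [readMxIF()], [writeMxIF()]
#' @export
setClass("MxIFImage",
         representation(channels = "array", pitchUm = "numeric",
                        originUm = "numeric", panel = "AntibodyPanel"))

setValidity("MxIFImage", function(object) {
  d <- dim(object@channels)
  if (length(d) != 3L) return("channels must be an H x W x C array")
  if (d[3L] != nrow(object@panel@entries))
    return(sprintf("channel count (%d) does not match panel entry count (%d)",
                   d[3L], nrow(object@panel@entries)))
  if (any(object@channels < 0)) return("fluorescence intensities must be >= 0")
  if (object@pitchUm <= 0) return("pitchUm must be > 0")
  if (length(object@originUm) != 2L) return("originUm must be length 2")
  TRUE
})

#' Construct an MxIFImage
#'
#' @param channels numeric array `H x W x n_channels`.
#' @param panel [AntibodyPanel-class] with one entry per channel.
#' @param pitchUm pixel pitch in micrometres (default 1).
#' @param originUm physical (x, y) of the corner of pixel (0, 0).
#' @return an [MxIFImage-class].
#' @export
MxIFImage <- function(channels, panel, pitchUm = 1, originUm = c(0, 0)) {
  new("MxIFImage", channels = channels, pitchUm = pitchUm,
      originUm = as.numeric(originUm), panel = panel)
}

#' ROIMask: glomerular measurement regions and their depth classes
#'
#' @slot labels integer matrix in the MxIF frame; 0 = outside any ROI,
#'   positive integers identify glomeruli.
#' @slot pitchUm raster pitch in micrometres.
#' @slot originUm physical (x, y) of the corner of pixel (0, 0).
#' @slot depth data.frame with `roi_id` and `depth_class`
#'   (deep / superficial / unknown), one row per ROI.
#' @export
setClass("ROIMask",
         representation(labels = "matrix", pitchUm = "numeric",
                        originUm = "numeric", depth = "data.frame"))

setValidity("ROIMask", function(object) {
  if (any(object@labels < 0)) return("ROI ids must be non-negative integers")
  if (nrow(object@depth)) {
    if (!all(c("roi_id", "depth_class") %in% names(object@depth)))
      return("depth table needs 'roi_id' and 'depth_class'")
    if (!all(object@depth$depth_class %in% c("deep", "superficial", "unknown")))
      return("depth_class must be deep/superficial/unknown")
  }
  TRUE
})

#' Construct an ROIMask
#' @param labels integer label matrix (0 = background).
#' @param pitchUm raster pitch in micrometres.
#' @param originUm physical (x, y) of the raster corner.
#' @param depth optional data.frame (`roi_id`, `depth_class`).
#' @return an [ROIMask-class].
#' @export
ROIMask <- function(labels, pitchUm = 1, originUm = c(0, 0),
                    depth = data.frame()) {
  mode(labels) <- "integer"
  new("ROIMask", labels = labels, pitchUm = pitchUm,
      originUm = as.numeric(originUm), depth = depth)
}

#' RegistrationTransform: affine map between the two physical frames
#'
#' Maps physical micrometre coordinates of one modality into the other:
#' `y = A x + b` with `A` the 2x2 linear part and `b` the offset.
#'
#' @slot matrix 2x2 linear part (must be invertible).
#' @slot offset length-2 offset in micrometres.
#' @slot direction which frame maps into which, e.g. `"mxif->ims"`.
#' @seealso [estimateAffine()], [transformPoints()], [invertTransform()]
#' @export
setClass("RegistrationTransform",
         representation(matrix = "matrix", offset = "numeric",
                        direction = "character"))

setValidity("RegistrationTransform", function(object) {
  if (!all(dim(object@matrix) == c(2L, 2L))) return("linear part must be 2x2")
  if (abs(det(object@matrix)) <= 1e-12)
    return("linear part must be invertible (|det| > 1e-12)")
  if (length(object@offset) != 2L) return("offset must be length 2")
  TRUE
})

#' Construct a RegistrationTransform
#' @param matrix 2x2 linear part.
#' @param offset length-2 offset (micrometres).
#' @param direction direction tag, default `"mxif->ims"`.
#' @return a [RegistrationTransform-class].
#' @export
RegistrationTransform <- function(matrix = diag(2), offset = c(0, 0),
                                  direction = "mxif->ims") {
  new("RegistrationTransform", matrix = unname(base::as.matrix(matrix)),
      offset = unname(as.numeric(offset)), direction = direction)
}

#' PixelAssociation: membership of MxIF pixels in IMS pixel footprints
#'
#' For every IMS pixel, the MxIF pixels whose transformed centers fall in its
#' half-open square footprint, plus the per-channel mean MxIF intensity over
#' those members. `memberOf` maps each MxIF pixel (column-major over the
#' raster) to the index of the IMS pixel that owns it (0 = none), so each
#' MxIF pixel is assigned to at most one IMS pixel by construction.
#'
#' @slot memberOf integer vector over MxIF pixels (0 = unassigned).
#' @slot counts integer vector over IMS pixels: contributing MxIF pixels.
#' @slot channelMeans matrix `n_ims_pixels x n_channels` of aggregated means
#'   (NA rows for empty footprints).
#' @slot emptyFootprint logical vector over IMS pixels.
#' @export
setClass("PixelAssociation",
         representation(memberOf = "integer", counts = "integer",
                        channelMeans = "matrix", emptyFootprint = "logical"))

setValidity("PixelAssociation", function(object) {
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (length(object@counts) != nrow(object@channelMeans))
    return("counts and channelMeans disagree on the number of IMS pixels")
  if (max(c(0L, object@memberOf)) > length(object@counts))
    return("memberOf refers to an IMS pixel that does not exist")
  TRUE
})

#' SegmentationResult: subglomerular segments from MxIF clustering
#'
#' @slot labels integer vector over all MxIF pixels (column-major), cluster
#'   id in `1..k` for in-ROI pixels and NA outside the measurement regions.
#' @slot clusterProfiles matrix `k x n_selected_channels`: mean standardized
#'   intensity profile of each cluster.
#' @slot cellTypes character of length `k`: canonical cell-type tag per
#'   cluster, `"substructure (unassigned)"` when no type matches.
#' @slot selectedChannels channels used for clustering.
#' @slot k number of clusters.
#' @slot seed seed used for k-means initialization.
#' @slot wss best total within-cluster sum of squares.
#' @slot wssTrace per-iteration objective of the winning restart.
#' @export
setClass("SegmentationResult",
         representation(labels = "integer", clusterProfiles = "matrix",
                        cellTypes = "character", selectedChannels = "character",
                        k = "integer", seed = "integer", wss = "numeric",
                        wssTrace = "numeric"))

setValidity("SegmentationResult", function(object) {
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
    return("labels must lie in 1..k")
  if (any(!is.finite(object@clusterProfiles)))
    return("cluster profiles must be finite")
  if (length(object@cellTypes) != object@k)
    return("cell-type assignment must cover all k clusters")
  TRUE
})

#' LabeledIMSTable: IMS pixels carrying transferred segment labels
#'
#' @slot table data.frame with one row per retained IMS pixel: `pixel`
#'   (index into the source IMSDataset), `row`, `col`, `roi_id`,
#'   `depth_class`, `segment`, `n_members`.
#' @slot intensities matrix of ion intensities aligned with `table` rows.
#' @slot mz numeric m/z axis for the intensity columns.
#' @slot excluded data.frame of dropped pixels with a `reason` code
#'   (e.g. `sparse_footprint`, `unlabeled`).
#' @export
setClass("LabeledIMSTable",
         representation(table = "data.frame", intensities = "matrix",
                        mz = "numeric", excluded = "data.frame"))

setValidity("LabeledIMSTable", function(object) {
  if (nrow(object@table) != nrow(object@intensities))
    return("table and intensities must have one row per retained pixel")
  if (ncol(object@intensities) != length(object@mz))
    return("intensity columns must match the m/z axis")
  if (nrow(object@table) && any(object@table$segment < 1L))
    return("segment labels must be positive")
  TRUE
})

#' ClassifierResult: cross-validated segment classifier and its metrics
#'
#' @slot metrics data.frame: one row per (segment, metric) with fold `mean`
#'   and `sd`; metrics are one-vs-rest balanced accuracy, F1, precision and
#'   recall.
#' @slot confusion confusion matrix summed over held-out folds
#'   (rows = truth, cols = predicted).
#' @slot folds integer fold id per training row.
#' @slot model the final model refit on all rows (for attribution).
#' @slot classes segment labels in model class order.
#' @slot featureNames feature (m/z) column labels.
#' @slot spec list of classifier settings actually used.
#' @export
setClass("ClassifierResult",
         representation(metrics = "data.frame", confusion = "matrix",
                        folds = "integer", model = "ANY",
                        classes = "character", featureNames = "character",
                        spec = "list"))

setValidity("ClassifierResult", function(object) {
  m <- object@metrics
  ok <- is.finite(m$mean) & m$mean >= -1e-9 & m$mean <= 1 + 1e-9
  if (!all(ok)) return("metric fold means must lie in [0, 1]")
  TRUE
})

#' AttributionResult: Shapley interpretation of a fitted segment classifier
#'
#' @slot shapValues list (one matrix `n_evaluated_pixels x n_features` per
#'   class) of signed attributions on the class-probability scale.
#' @slot baseline per-class expected model output over the background set.
#' @slot globalScore matrix `n_classes x n_features`: mean |attribution|
#'   over all evaluated pixels (the global SHAP score).
#' @slot direction matrix of signs in -1/0/+1 from the correlation between
#'   feature intensity and its attribution (0 when |r| below the dead zone).
#' @slot ranking list per class: feature indices by descending global score,
#'   ties broken by ascending m/z.
#' @slot mz m/z axis of the features.
#' @slot classes class (segment) names.
#' @slot evaluated indices of the evaluated pixels in the source table.
#' @slot meta list: method, background size, seed, attribution scale.
#' @export
setClass("AttributionResult",
         representation(shapValues = "list", baseline = "numeric",
                        globalScore = "matrix", direction = "matrix",
                        ranking = "list", mz = "numeric", classes = "character",
                        evaluated = "integer", meta = "list"))

setValidity("AttributionResult", function(object) {
  if (any(object@globalScore < 0)) return("global scores must be >= 0")
  nf <- length(object@mz)
  for (r in object@ranking)
    if (!identical(sort(r), seq_len(nf)))
      return("each ranking must be a permutation of the features")
  if (!all(object@direction %in% c(-1, 0, 1)))
    return("directions must be in {-1, 0, +1}")
  TRUE
})

#' SyntheticTruth: planted ground truth of a simulated paired dataset
#'
#' @slot cellMap integer matrix at MxIF resolution; values index `cellTypes`.
#' @slot cellTypes canonical cell-type names (level order of `cellMap`).
#' @slot expressionMatrix `n_cell_types x n_channels` mean fluorescence.
#' @slot lipidMatrix `n_cell_types x n_features` mean ion intensity.
#' @slot plantedMarkers data.frame: `cell_type`, `feature`, `mz`, `sign` —
#'   the features planted to discriminate each cell type.
#' @slot depthEffects data.frame: `feature`, `mz`, `fold` — features
#'   multiplicatively shifted in deep glomeruli.
#' @slot trueTransform the affine misalignment applied between the frames.
#' @slot seed integer seed the dataset was generated under.
#' @export
setClass("SyntheticTruth",
         representation(cellMap = "matrix", cellTypes = "character",
                        expressionMatrix = "matrix", lipidMatrix = "matrix",
                        plantedMarkers = "data.frame",
                        depthEffects = "data.frame",
                        trueTransform = "RegistrationTransform",
                        seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (any(object@expressionMatrix < 0) || any(object@lipidMatrix < 0))
    return("expression and lipid matrices must be >= 0")
  TRUE
})
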