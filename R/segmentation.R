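## MxIF pixel clustering into subglomerular segments, cell-type naming of
## clusters, and transfer of segment labels onto coregistered IMS pixels.

#' The default channel subset used for segmentation
#'
#' The six glomerular structure/cell-type channels used to delineate
#' subglomerular segments.
#' @return character vector of panel targets.
#' @export
defaultSegmentationChannels <- function()
  c("Tensin", "Podocalyxin", "Fibronectin", "CD31", "Synaptopodin", "Nestin")

#' Z-score channels over the clustered pixel population
#'
#' Standardizes each channel to mean 0 and (population) variance 1 over the
#' supplied pixels. Channels with zero variance carry no contrast and are
#' dropped with a warning.
#'
#' @param X numeric matrix, pixels x channels (>= 2 pixels).
#' @return the standardized matrix (possibly fewer columns); dropped
#'   channel names in attribute `"dropped"`.
#' @export
standardizeChannels <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 pixels to standardize", call. = FALSE)
  mu <- colMeans(X)
  sdp <- sqrt(colMeans(sweep(X, 2L, mu)^2))   # population SD
  drop <- sdp == 0
  if (all(drop))
    stop("all channels have zero variance", call. = FALSE)
  if (any(drop))
    warning("dropping zero-variance channel(s): ",
            paste(colnames(X)[drop] %||% which(drop), collapse = ", "),
            call. = FALSE)
  Z <- sweep(sweep(X[, !drop, drop = FALSE], 2L, mu[!drop]), 2L, sdp[!drop], "/")
  attr(Z, "dropped") <- colnames(X)[drop]
  Z
}

#' Cluster pixel signatures with k-means (Lloyd + k-means++)
#'
#' Lloyd's algorithm with k-means++ initialization, best of `nInit`
#' restarts by total within-cluster sum of squares. An empty cluster at an
#' update step is re-seeded at the point farthest from its assigned center
#' (logged). Final labels are renumbered by descending cluster size (ties
#' by descending centroid norm) so cluster ids are reproducible.
#'
#' @param X numeric matrix, pixels x channels (standardized upstream).
#' @param k number of clusters (>= 2, <= number of pixels).
#' @param seed integer seed for initialization.
#' @param nInit number of k-means++ restarts (default 10).
#' @param maxIter Lloyd iteration cap (default 100).
#' @param tol relative objective-change convergence tolerance.
#' @return list: `labels` (1..k per pixel), `centers` (k x channels),
#'   `wss` (best objective), `wssTrace` (per-iteration objective of the
#'   winning restart, non-increasing).
#' @export
clusterPixels <- function(X, k, seed = 1, nInit = 10, maxIter = 100,
                          tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k pixels", call. = FALSE)
  best <- NULL
  for (r in seq_len(nInit)) {
    fit <- withr::with_seed(as.integer(seed) + r - 1L,
                            .lloydOnce(X, k, maxIter, tol))
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  ## renumber by descending size, ties by descending centroid norm
  size <- tabulate(best$labels, k)
  nrm <- sqrt(rowSums(best$centers^2))
  ord <- order(-size, -nrm)
  relab <- integer(k); relab[ord] <- seq_len(k)
  list(labels = relab[best$labels], centers = best$centers[ord, , drop = FALSE],
       wss = best$wss, wssTrace = best$wssTrace)
}

.sqDistToCenters <- function(X, C) {
  matrix(rowSums(X^2), nrow(X), nrow(C)) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE) -
    2 * X %*% t(C)
}

.kmeansPPInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

.lloydOnce <- function(X, k, maxIter, tol) {
  C <- .kmeansPPInit(X, k)
  labels <- integer(nrow(X))
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    d2 <- .sqDistToCenters(X, C)
    labels <- max.col(-d2, ties.method = "first")
    mind2 <- pmax(d2[cbind(seq_len(nrow(X)), labels)], 0)
    empty <- setdiff(seq_len(k), unique(labels))
    if (length(empty)) {
      message(sprintf("clusterPixels: re-seeding %d empty cluster(s) at farthest point",
                      length(empty)))
      for (e in empty) {
        far <- which.max(mind2)
        C[e, ] <- X[far, ]
        labels[far] <- e
        mind2[far] <- 0
      }
      d2 <- .sqDistToCenters(X, C)
      labels <- max.col(-d2, ties.method = "first")
      mind2 <- pmax(d2[cbind(seq_len(nrow(X)), labels)], 0)
    }
    wss <- sum(mind2)
    trace <- c(trace, wss)
    Cn <- rowsum(X, labels, reorder = TRUE)
    cnt <- tabulate(labels, k)
    C <- Cn / cnt
    if (is.finite(prev) && prev - wss <= tol * max(prev, 1)) break
    prev <- wss
  }
  list(labels = labels, centers = C, wss = trace[length(trace)],
       wssTrace = trace)
}

#' Name clusters by cell type from their standardized profiles
#'
#' For each cluster, the cosine similarity between its mean standardized
#' intensity profile and each cell type's expectation vector (+1 on
#' channels whose panel `expected_segments` include the type, -1 on the
#' other selected channels) is computed; the best-matching type is assigned
#' when the similarity reaches `threshold`, otherwise the cluster is left
#' as `"substructure (unassigned)"`. Several clusters may share a type.
#'
#' Only cell types with at least one positive expected channel among the
#' selected ones are candidates: a type marked exclusively by unselected
#' channels would otherwise have an all-negative expectation vector and
#' spuriously capture any uniformly dim cluster. For the same reason a
#' type is only assigned when the cluster is actually elevated (mean
#' standardized intensity > 0) on that type's marker channels; uniformly
#' dim clusters stay unassigned rather than matching the expectation
#' vector with the fewest positive entries.
#'
#' @param clusterProfiles matrix k x selected channels (standardized means);
#'   column names must be panel targets.
#' @param panel an [AntibodyPanel-class].
#' @param threshold minimum cosine similarity (default 0.3).
#' @return character vector of length k.
#' @export
assignCellTypes <- function(clusterProfiles, panel, threshold = 0.3) {
  EV <- expectationVectors(panel, colnames(clusterProfiles))
  EV <- EV[rowSums(EV > 0) > 0, , drop = FALSE]
  if (nrow(EV) == 0L)
    return(rep("substructure (unassigned)", nrow(clusterProfiles)))
  out <- character(nrow(clusterProfiles))
  for (i in seq_len(nrow(clusterProfiles))) {
    p <- clusterProfiles[i, ]
    np <- sqrt(sum(p^2))
    if (np == 0) { out[i] <- "substructure (unassigned)"; next }
    sim <- as.numeric(EV %*% p) / (np * sqrt(rowSums(EV^2)))
    elevated <- vapply(seq_len(nrow(EV)), function(t)
      mean(p[EV[t, ] > 0]) > 0, logical(1))
    sim[!elevated] <- -Inf
    j <- which.max(sim)
    out[i] <- if (is.finite(sim[j]) && sim[j] >= threshold) rownames(EV)[j]
              else "substructure (unassigned)"
  }
  out
}

#' Segment MxIF pixels inside the measurement regions
#'
#' Standardizes the selected channels over the in-ROI pixels, clusters them
#' with [clusterPixels()], computes per-cluster standardized mean profiles
#' and names each cluster with [assignCellTypes()].
#'
#' @param mxif an [MxIFImage-class].
#' @param roi an [ROIMask-class] on the same raster grid.
#' @param channels channel subset (default
#'   [defaultSegmentationChannels()]).
#' @param k number of segments (default 6).
#' @param seed,nInit,maxIter,tol passed to [clusterPixels()].
#' @param similarityThreshold passed to [assignCellTypes()].
#' @return a [SegmentationResult-class].
#' @export
segmentMxIF <- function(mxif, roi, channels = defaultSegmentationChannels(),
                        k = 6, seed = 1, nInit = 10, maxIter = 100,
                        tol = 1e-8, similarityThreshold = 0.3) {
  arr <- channelArray(mxif)
  if (!all(dim(roi@labels) == dim(arr)[1:2]))
    stop("ROI mask raster does not match the MxIF raster", call. = FALSE)
  chIdx <- match(channels, channelNames(mxif))
  if (anyNA(chIdx))
    stop("channels not present in panel: ",
         paste(channels[is.na(chIdx)], collapse = ", "), call. = FALSE)
  pixmat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3L])
  colnames(pixmat) <- channelNames(mxif)
  inRoi <- as.vector(roi@labels) > 0L
  Z <- standardizeChannels(pixmat[inRoi, chIdx, drop = FALSE])
  fit <- clusterPixels(Z, k, seed = seed, nInit = nInit, maxIter = maxIter,
                       tol = tol)
  labels <- rep(NA_integer_, nrow(pixmat))
  labels[inRoi] <- fit$labels
  profiles <- rowsum(Z, fit$labels) / tabulate(fit$labels, k)
  rownames(profiles) <- paste0("segment_", seq_len(k))
  cellTypes <- assignCellTypes(profiles, mxif@panel,
                               threshold = similarityThreshold)
  new("SegmentationResult", labels = labels, clusterProfiles = profiles,
      cellTypes = cellTypes, selectedChannels = colnames(Z),
      k = as.integer(k), seed = as.integer(seed), wss = fit$wss,
      wssTrace = fit$wssTrace)
}

#' Transfer segment labels to IMS pixels by footprint majority vote
#'
#' Each IMS pixel takes the modal cluster id among the labeled MxIF pixels
#' in its footprint (ties: lowest id wins). Pixels with fewer than
#' `minCount` labeled members are excluded with reason
#' `"sparse_footprint"`; pixels with no labeled member with reason
#' `"unlabeled"`.
#'
#' @param association a [PixelAssociation-class] from [associatePixels()].
#' @param segmentation a [SegmentationResult-class] (or an integer vector
#'   of per-MxIF-pixel labels, NA where unlabeled).
#' @param ims the [IMSDataset-class] the association was computed against.
#' @param roi optional [ROIMask-class]; its depth table annotates
#'   `depth_class` via the IMS pixels' ROI ids.
#' @param minCount minimum labeled members per retained pixel (default 5,
#'   of the 25 possible at the 5:1 pitch ratio).
#' @return a [LabeledIMSTable-class].
#' @export
labelIMSPixels <- function(association, segmentation, ims, roi = NULL,
                           minCount = 5) {
  stopifnot(minCount >= 1)
  mxifLabels <- if (is(segmentation, "SegmentationResult"))
    segmentation@labels else as.integer(segmentation)
  if (length(mxifLabels) != length(association@memberOf))
    stop("segmentation labels do not match the association's MxIF raster",
         call. = FALSE)
  nIms <- length(association@counts)
  k <- max(mxifLabels, na.rm = TRUE)
  votes <- matrix(0L, nIms, k)
  for (lab in seq_len(k)) {
    sel <- !is.na(mxifLabels) & mxifLabels == lab & association@memberOf > 0L
    votes[, lab] <- tabulate(association@memberOf[sel], nIms)
  }
  nLabeled <- rowSums(votes)
  segment <- max.col(votes, ties.method = "first")  # ties -> lowest id
  co <- pixelCoords(ims)
  depth <- rep("unknown", nIms)
  if (!is.null(roi) && nrow(roi@depth)) {
    m <- match(roiIds(ims), roi@depth$roi_id)
    depth[!is.na(m)] <- roi@depth$depth_class[m[!is.na(m)]]
  }
  tab <- data.frame(pixel = seq_len(nIms), row = co$row, col = co$col,
                    roi_id = roiIds(ims), depth_class = depth,
                    segment = segment, n_members = nLabeled)
  keep <- nLabeled >= minCount
  reason <- ifelse(nLabeled == 0L, "unlabeled", "sparse_footprint")
  excluded <- data.frame(pixel = which(!keep), reason = reason[!keep])
  new("LabeledIMSTable", table = tab[keep, , drop = FALSE],
      intensities = intensityMatrix(ims)[keep, , drop = FALSE],
      mz = mzAxis(ims), excluded = excluded)
}
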