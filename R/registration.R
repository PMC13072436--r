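## Affine coregistration of the MxIF and IMS physical frames, and the
## association of MxIF pixels to the IMS pixel footprints that contain them.

#' Apply an affine transform to physical points
#'
#' @param transform a [RegistrationTransform-class].
#' @param xy numeric matrix/2-column object of (x, y) in micrometres.
#' @return transformed coordinates, same shape.
#' @export
transformPoints <- function(transform, xy) {
  xy <- as.matrix(xy)
  out <- xy %*% t(transform@matrix)
  out[, 1L] <- out[, 1L] + transform@offset[1L]
  out[, 2L] <- out[, 2L] + transform@offset[2L]
  colnames(out) <- c("x", "y")
  out
}

#' Invert an affine transform
#' @param transform a [RegistrationTransform-class].
#' @return the inverse [RegistrationTransform-class].
#' @export
invertTransform <- function(transform) {
  Ai <- solve(transform@matrix)
  dir <- strsplit(transform@direction, "->", fixed = TRUE)[[1L]]
  RegistrationTransform(Ai, -as.numeric(Ai %*% transform@offset),
                        direction = paste(rev(dir), collapse = "->"))
}

#' Compose two affine transforms (apply `first`, then `second`)
#' @param second,first [RegistrationTransform-class] objects.
#' @return the composed transform.
#' @export
composeTransforms <- function(second, first) {
  RegistrationTransform(second@matrix %*% first@matrix,
                        as.numeric(second@matrix %*% first@offset) + second@offset,
                        direction = first@direction)
}

#' Estimate the MxIF-to-IMS affine transform from landmark pairs
#'
#' Least-squares affine fit minimizing the summed squared residuals of the
#' mapped MxIF landmarks against their IMS counterparts.
#'
#' @param landmarksMxif,landmarksIms matrices/data.frames of matched (x, y)
#'   landmark coordinates in physical micrometres; at least 3 non-collinear
#'   pairs.
#' @return a [RegistrationTransform-class] with the residual RMS (um)
#'   attached as attribute `"rms"`.
#' @export
estimateAffine <- function(landmarksMxif, landmarksIms) {
  P <- as.matrix(landmarksMxif); Q <- as.matrix(landmarksIms)
  if (nrow(P) != nrow(Q)) stop("landmark sets differ in size", call. = FALSE)
  if (nrow(P) < 3L)
    stop("at least 3 landmark pairs are required", call. = FALSE)
  X <- cbind(P[, 1L], P[, 2L], 1)
  if (qr(X)$rank < 3L)
    stop("degenerate landmark configuration (collinear landmarks)",
         call. = FALSE)
  B <- qr.solve(X, Q)                      # 3 x 2: [a11 a21; a12 a22; b1 b2]
  A <- t(B[1:2, , drop = FALSE])
  b <- as.numeric(B[3L, ])
  res <- X %*% B - Q
  tr <- RegistrationTransform(A, b, direction = "mxif->ims")
  attr(tr, "rms") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Read landmark pairs from CSV
#'
#' Columns: `x_mxif_um`, `y_mxif_um`, `x_ims_um`, `y_ims_um`.
#' @param path CSV path.
#' @return list with elements `mxif` and `ims` (matrices of coordinates).
#' @export
readLandmarks <- function(path) {
  d <- read.csv(path)
  need <- c("x_mxif_um", "y_mxif_um", "x_ims_um", "y_ims_um")
  if (!all(need %in% names(d)))
    stop("landmark CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  list(mxif = as.matrix(d[, need[1:2]]), ims = as.matrix(d[, need[3:4]]))
}

#' Serialize / restore a transform as JSON
#' @param transform a [RegistrationTransform-class].
#' @param path JSON path.
#' @return `path` (write) or the transform (read).
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = transform@matrix, offset = transform@offset,
         direction = transform@direction),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.matrix(j$matrix)) j$matrix
       else matrix(unlist(j$matrix), 2, 2, byrow = TRUE)
  RegistrationTransform(m, as.numeric(j$offset), j$direction)
}

#' Associate MxIF pixels with the IMS pixels whose footprints contain them
#'
#' Each MxIF pixel center is mapped through `transform` into the IMS
#' physical frame and assigned to the IMS pixel in whose half-open square
#' footprint `[x - p/2, x + p/2) x [y - p/2, y + p/2)` it lands (p = IMS
#' pitch, left/top edges inclusive). Membership is therefore deterministic,
#' order-free, and each MxIF pixel belongs to at most one IMS pixel.
#' Per-channel means are aggregated over the members of each footprint;
#' IMS pixels with no members are flagged, not dropped.
#'
#' @param mxif an [MxIFImage-class].
#' @param ims an [IMSDataset-class].
#' @param transform [RegistrationTransform-class] mapping MxIF physical
#'   coordinates into the IMS physical frame (identity by default).
#' @return a [PixelAssociation-class].
#' @export
associatePixels <- function(mxif, ims, transform = RegistrationTransform()) {
  arr <- channelArray(mxif)
  h <- dim(arr)[1L]; w <- dim(arr)[2L]; nch <- dim(arr)[3L]
  px <- expand.grid(row = 0:(h - 1L), col = 0:(w - 1L))  # column-major order
  centers <- pixelCenters(px$row, px$col, pitchUm(mxif), originUm(mxif))
  mapped <- transformPoints(transform, centers)
  p <- pitchUm(ims); o <- originUm(ims)
  gc_ <- floor((mapped[, 1L] - o[1L]) / p)
  gr_ <- floor((mapped[, 2L] - o[2L]) / p)
  co <- pixelCoords(ims)
  width <- max(co$col, gc_[is.finite(gc_)]) + 2
  keyIms <- co$row * width + co$col
  keyMx <- gr_ * width + gc_
  keyMx[gr_ < 0 | gc_ < 0] <- -1
  memberOf <- match(keyMx, keyIms, nomatch = 0L)
  nIms <- nrow(co)
  counts <- tabulate(memberOf, nbins = nIms)
  pixmat <- matrix(arr, h * w, nch)
  keep <- memberOf > 0L
  sums <- rowsum(pixmat[keep, , drop = FALSE], memberOf[keep], reorder = FALSE)
  means <- matrix(NA_real_, nIms, nch)
  idx <- as.integer(rownames(sums))
  means[idx, ] <- sums / counts[idx]
  colnames(means) <- channelNames(mxif)
  new("PixelAssociation", memberOf = as.integer(memberOf),
      counts = as.integer(counts), channelMeans = means,
      emptyFootprint = counts == 0L)
}
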