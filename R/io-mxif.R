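## MxIF multichannel TIFF and ROI label-mask input/output.
##
## TIFF pages are written as 32-bit float scaled into [0, 1]; the scale,
## pixel pitch, physical origin and channel names travel in a JSON sidecar
## (`<path>.meta.json`) because baseline TIFF tags cannot carry them.

.sidecar <- function(path) paste0(path, ".meta.json")

#' Read a multichannel MxIF TIFF
#'
#' @param path TIFF path (one page per channel). A `<path>.meta.json`
#'   sidecar written by [writeMxIF()] restores intensity scale, pitch and
#'   origin; without it intensities are taken as stored.
#' @param panel an [AntibodyPanel-class]; entry count must equal the page
#'   count and defines channel order.
#' @param pitchUm,originUm used when no sidecar is present.
#' @return an [MxIFImage-class].
#' @export
readMxIF <- function(path, panel, pitchUm = 1, originUm = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(pages)
  npanel <- nrow(panelTable(panel))
  if (nch != npanel)
    stop(sprintf("channel count mismatch: TIFF has %d pages, panel has %d entries",
                 nch, npanel), call. = FALSE)
  scale <- 1
  if (file.exists(.sidecar(path))) {
    meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
    scale <- meta$scale
    pitchUm <- meta$pitch_um
    originUm <- as.numeric(meta$origin_um)
  }
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  arr <- array(0, c(h, w, nch))
  for (i in seq_len(nch)) arr[, , i] <- pages[[i]] * scale
  arr[arr < 0] <- 0  # clip float32 round-off below zero
  MxIFImage(arr, panel, pitchUm = pitchUm, originUm = originUm)
}

#' Write a multichannel MxIF TIFF (+ JSON sidecar)
#'
#' @param img an [MxIFImage-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeMxIF <- function(img, path) {
  arr <- channelArray(img)
  scale <- max(arr, 1e-300)
  if (scale <= 1) scale <- 1
  pages <- lapply(seq_len(dim(arr)[3L]), function(i) arr[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(scale = scale, pitch_um = pitchUm(img),
         origin_um = originUm(img), channels = channelNames(img)),
    .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI label mask (label TIFF + optional depth sidecar table)
#'
#' @param path label TIFF written by [writeROIMask()] (16-bit integer
#'   labels).
#' @param depthPath optional CSV with columns `roi_id`, `depth_class`.
#' @param pitchUm,originUm raster geometry; overridden by the JSON sidecar
#'   when present.
#' @return an [ROIMask-class].
#' @export
readROIMask <- function(path, depthPath = NULL, pitchUm = 1,
                        originUm = c(0, 0)) {
  m <- tiff::readTIFF(path)
  labels <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  if (file.exists(.sidecar(path))) {
    meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
    pitchUm <- meta$pitch_um
    originUm <- as.numeric(meta$origin_um)
  }
  depth <- if (!is.null(depthPath)) {
    d <- read.csv(depthPath, stringsAsFactors = FALSE)
    if (!all(c("roi_id", "depth_class") %in% names(d)))
      stop("depth table needs columns roi_id, depth_class", call. = FALSE)
    d
  } else data.frame()
  ROIMask(labels, pitchUm = pitchUm, originUm = originUm, depth = depth)
}

#' Write an ROI label mask as a 16-bit label TIFF (+ JSON sidecar)
#'
#' @param mask an [ROIMask-class] (label values must be < 65536).
#' @param path output TIFF path.
#' @param depthPath optional CSV path for the depth sidecar table.
#' @return `path`, invisibly.
#' @export
writeROIMask <- function(mask, path, depthPath = NULL) {
  if (max(mask@labels) > 65535L)
    stop("label TIFF supports ROI ids up to 65535", call. = FALSE)
  tiff::writeTIFF(mask@labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(pitch_um = mask@pitchUm, origin_um = mask@originUm),
    .sidecar(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(depthPath) && nrow(mask@depth))
    write.csv(mask@depth, depthPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}
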