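## IMS peak-table input/output: a documented CSV dialect and minimal
## processed-mode (picked-peak) imzML.
##
## CSV dialect (bit-exact, frozen): header `row,col,roi_id` followed by one
## column per m/z feature named by its value printed with 3 decimals
## (e.g. `703.575`); one row per pixel; 0-based grid coordinates.

#' Read an IMS peak-intensity table
#'
#' @param path file path; for imzML, the `.imzML` XML file (the binary
#'   `.ibd` companion must sit next to it).
#' @param dialect `"csv"` (documented dialect, see Details) or `"imzml"`
#'   (processed-mode picked peaks with a shared m/z axis; 64-bit float,
#'   uncompressed).
#' @param pitchUm physical pixel pitch in micrometres; used when the file
#'   carries none (default 5).
#' @param originUm physical (x, y) of the corner of pixel (0, 0); used when
#'   the file carries none.
#' @details The CSV dialect has columns `row`, `col`, `roi_id` and then one
#'   column per feature named by its m/z with exactly 3 decimals. Grid
#'   coordinates are 0-based, row-major.
#' @return an [IMSDataset-class].
#' @export
readIMS <- function(path, dialect = c("csv", "imzml"), pitchUm = 5,
                    originUm = c(0, 0)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") .readIMScsv(path, pitchUm, originUm)
  else .readImzML(path, pitchUm, originUm)
}

#' Write an IMS peak-intensity table
#'
#' @param ims an [IMSDataset-class].
#' @param path output path (`.csv`, or `.imzML`; the `.ibd` is written next
#'   to it).
#' @param dialect `"csv"` or `"imzml"`.
#' @return `path`, invisibly.
#' @export
writeIMS <- function(ims, path, dialect = c("csv", "imzml")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") .writeIMScsv(ims, path) else .writeImzML(ims, path)
  invisible(path)
}

.readIMScsv <- function(path, pitchUm, originUm) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("row", "col", "roi_id")
  if (!all(need %in% names(df)[1:3]))
    stop("CSV dialect requires leading columns row, col, roi_id", call. = FALSE)
  if (nrow(df) == 0L) stop("no pixels", call. = FALSE)
  mzcols <- setdiff(names(df), need)
  mz <- suppressWarnings(as.numeric(mzcols))
  if (any(is.na(mz)))
    stop("feature columns must be named by numeric m/z values", call. = FALSE)
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("m/z header is not strictly increasing", call. = FALSE)
  key <- paste(df$row, df$col)
  if (anyDuplicated(key))
    stop(sprintf("duplicate pixel grid coordinate (row col) = (%s)",
                 key[duplicated(key)][1L]), call. = FALSE)
  IMSDataset(as.matrix(df[, mzcols, drop = FALSE]), mz = mz,
             coords = df[, c("row", "col")], roiId = df$roi_id,
             pitchUm = pitchUm, originUm = originUm)
}

.writeIMScsv <- function(ims, path) {
  co <- pixelCoords(ims)
  df <- data.frame(row = co$row, col = co$col, roi_id = roiIds(ims))
  m <- intensityMatrix(ims)
  colnames(m) <- mzLabel(mzAxis(ims))
  out <- cbind(df, as.data.frame(m, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

## ---- minimal processed-mode imzML ----
## Feature-aligned picked peaks only: every spectrum must carry the same
## m/z axis. 64-bit little-endian floats, no compression. Grid positions
## follow the imzML convention (1-based x = col + 1, y = row + 1).

.ibdPath <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

.writeImzML <- function(ims, path) {
  m <- intensityMatrix(ims)
  mz <- mzAxis(ims)
  co <- pixelCoords(ims)
  n <- nrow(m); d <- length(mz)
  ibd <- .ibdPath(path)
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(1:16), con)                 # ibd UUID (fixed)
  offs <- matrix(0, n, 2L)
  pos <- 16
  for (i in seq_len(n)) {
    offs[i, 1L] <- pos
    writeBin(as.double(mz), con, size = 8, endian = "little")
    pos <- pos + 8 * d
    offs[i, 2L] <- pos
    writeBin(as.double(m[i, ]), con, size = 8, endian = "little")
    pos <- pos + 8 * d
  }
  spectra <- vapply(seq_len(n), function(i) {
    paste0(
      '<spectrum index="', i - 1L, '" id="spectrum=', i, '" defaultArrayLength="', d, '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="', co$col[i] + 1L, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="', co$row[i] + 1L, '"/>',
      '<userParam name="roi_id" value="', roiIds(ims)[i], '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', sprintf("%.0f", offs[i, 1L]), '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', d, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * d, '"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', sprintf("%.0f", offs[i, 2L]), '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', d, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * d, '"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixel x" value="', max(co$col) + 1L, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixel y" value="', max(co$row) + 1L, '"/>',
    '<userParam name="pitch_um" value="', pitchUm(ims), '"/>',
    '<userParam name="origin_x_um" value="', originUm(ims)[1], '"/>',
    '<userParam name="origin_y_um" value="', originUm(ims)[2], '"/>',
    '</scanSettings></scanSettingsList>',
    '<run id="run1"><spectrumList count="', n, '">',
    paste(spectra, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, useBytes = TRUE)
}

.readImzML <- function(path, pitchUm, originUm) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  fmt <- xml2::xml_find_all(doc, "//referenceableParamGroup/cvParam[@accession='MS:1000521']")
  if (length(fmt))
    stop("only 64-bit float imzML binaries are supported", call. = FALSE)
  comp <- xml2::xml_find_all(doc, "//referenceableParamGroup/cvParam[@accession='MS:1000574']")
  if (length(comp))
    stop("compressed imzML binaries are not supported", call. = FALSE)
  ss <- xml2::xml_find_first(doc, "//scanSettings")
  getUser <- function(node, name, default) {
    v <- xml2::xml_attr(
      xml2::xml_find_first(node, sprintf("userParam[@name='%s']", name)), "value")
    if (is.na(v)) default else as.numeric(v)
  }
  if (!inherits(ss, "xml_missing")) {
    pitchUm <- getUser(ss, "pitch_um", pitchUm)
    originUm <- c(getUser(ss, "origin_x_um", originUm[1]),
                  getUser(ss, "origin_y_um", originUm[2]))
  }
  specs <- xml2::xml_find_all(doc, "//spectrum")
  if (length(specs) == 0L) stop("no pixels", call. = FALSE)
  cv <- function(node, acc)
    xml2::xml_attr(xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", acc)), "value")
  ibd <- .ibdPath(path)
  if (!file.exists(ibd)) stop("missing .ibd companion: ", ibd, call. = FALSE)
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  n <- length(specs)
  rowv <- colv <- roiv <- integer(n)
  mzRef <- NULL
  inten <- NULL
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    colv[i] <- as.integer(cv(sp, "IMS:1000050")) - 1L
    rowv[i] <- as.integer(cv(sp, "IMS:1000051")) - 1L
    roi <- xml2::xml_attr(
      xml2::xml_find_first(sp, ".//userParam[@name='roi_id']"), "value")
    roiv[i] <- if (is.na(roi)) 0L else as.integer(roi)
    arrs <- xml2::xml_find_all(sp, ".//binaryDataArray")
    if (length(arrs) != 2L)
      stop("each spectrum must have an m/z and an intensity array", call. = FALSE)
    isMz <- vapply(arrs, function(a) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, "referenceableParamGroupRef"), "ref")
      identical(ref, "mzArray") ||
        length(xml2::xml_find_all(a, "cvParam[@accession='MS:1000514']")) > 0
    }, logical(1))
    readArr <- function(a) {
      off <- as.numeric(cv(a, "IMS:1000102"))
      len <- as.integer(cv(a, "IMS:1000103"))
      seek(con, off)
      readBin(con, "double", n = len, size = 8, endian = "little")
    }
    mzi <- readArr(arrs[[which(isMz)[1L]]])
    iti <- readArr(arrs[[which(!isMz)[1L]]])
    if (is.null(mzRef)) {
      mzRef <- mzi
      inten <- matrix(0, n, length(mzRef))
    } else if (length(mzi) != length(mzRef) ||
               max(abs(mzi - mzRef)) > 1e-9 * max(1, max(abs(mzRef)))) {
      stop("spectra do not share a common picked-peak m/z axis; ",
           "feature-aligned processed imzML is required", call. = FALSE)
    }
    inten[i, ] <- iti
  }
  if (length(mzRef) > 1L && any(diff(mzRef) <= 0))
    stop("m/z axis is not strictly increasing", call. = FALSE)
  key <- paste(rowv, colv)
  if (anyDuplicated(key))
    stop(sprintf("duplicate pixel grid coordinate (row col) = (%s)",
                 key[duplicated(key)][1L]), call. = FALSE)
  IMSDataset(inten, mz = mzRef, coords = data.frame(row = rowv, col = colv),
             roiId = roiv, pitchUm = pitchUm, originUm = originUm)
}
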