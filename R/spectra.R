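## Per-segment average mass spectra and between-segment difference spectra.

#' Average mass spectrum of a segment group
#'
#' Unweighted mean intensity per m/z feature over the IMS pixels belonging
#' to any segment in `segments`, with the standard error of the mean
#' (SD / sqrt(n); 0 for a single pixel).
#'
#' @param labeled a [LabeledIMSTable-class].
#' @param segments integer vector of segment ids to pool (e.g. `c(4, 6)`
#'   to combine two podocyte-dominated segments).
#' @return data.frame: `mz`, `mean`, `se`, with attributes `n` (pixel
#'   count) and `segments`.
#' @export
meanSpectrum <- function(labeled, segments) {
  sel <- labeled@table$segment %in% segments
  n <- sum(sel)
  if (n == 0L)
    stop("empty segment group: ", paste(segments, collapse = ","),
         call. = FALSE)
  M <- labeled@intensities[sel, , drop = FALSE]
  mu <- colMeans(M)
  se <- if (n > 1L) apply(M, 2L, sd) / sqrt(n) else rep(0, ncol(M))
  out <- data.frame(mz = labeled@mz, mean = mu, se = se)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "segments") <- segments
  out
}

#' Signed difference spectrum between two segment groups
#'
#' Per-feature `mean_A - mean_B`; antisymmetric in its arguments. The two
#' spectra must share an identical m/z axis.
#'
#' @param spectrumA,spectrumB outputs of [meanSpectrum()].
#' @return data.frame: `mz`, `difference`, plus both group means.
#' @export
differenceSpectrum <- function(spectrumA, spectrumB) {
  if (nrow(spectrumA) != nrow(spectrumB) ||
      any(spectrumA$mz != spectrumB$mz))
    stop("m/z axes of the two spectra do not match", call. = FALSE)
  data.frame(mz = spectrumA$mz, difference = spectrumA$mean - spectrumB$mean,
             mean_a = spectrumA$mean, mean_b = spectrumB$mean)
}

#' All per-segment average spectra as one long table
#'
#' @param labeled a [LabeledIMSTable-class].
#' @return data.frame with `segment`, `mz`, `mean`, `se`, `n`.
#' @export
segmentSpectra <- function(labeled) {
  segs <- sort(unique(labeled@table$segment))
  do.call(rbind, lapply(segs, function(s) {
    sp <- meanSpectrum(labeled, s)
    data.frame(segment = s, sp, n = attr(sp, "n"))
  }))
}
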