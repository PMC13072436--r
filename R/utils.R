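## small shared helpers

utils::globalVariables(c("mz_label", "segment", "score", "correlation"))

#' Derive a per-stage seed from the pipeline's global seed
#'
#' One global seed expands deterministically into per-stage seeds so a stage
#' can be re-run in isolation with the same stream it saw inside a full run.
#' The derivation is `(seed * 7919 + sum(utf8(stage))) mod (2^31 - 1)`.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  as.integer((as.double(seed) * 7919 + sum(utf8ToInt(stage))) %% 2147483647)
}

## physical center of pixel (r, c): origin + (c + 1/2, r + 1/2) * pitch,
## with x along columns and y along rows; (r, c) are 0-based.
pixelCenters <- function(row, col, pitchUm, originUm) {
  cbind(x = originUm[1] + (col + 0.5) * pitchUm,
        y = originUm[2] + (row + 0.5) * pitchUm)
}

## format an m/z value the way the CSV dialect names feature columns
mzLabel <- function(mz) sprintf("%.3f", mz)

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

## modal value of a positive-integer vector, ties broken by the lowest id
.modalId <- function(ids) {
  tab <- tabulate(ids)
  which.max(tab) # which.max returns the first (lowest id) maximum
}
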