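## Antibody panel configuration.

#' Read an antibody panel configuration
#'
#' The config is YAML (or JSON) with a top-level `panel:` list, one record
#' per antibody carrying `target`, `cell_structures`, `cycle`, `fluorophore`,
#' `conjugation` and `expected_segments` (the canonical cell-type tags the
#' target marks; may be empty for targets outside the glomerular tuft such
#' as aSMA or AQP1). Entry order defines channel order.
#'
#' @param path config path.
#' @return an [AntibodyPanel-class].
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  recs <- if (!is.null(cfg$panel)) cfg$panel else cfg
  if (!length(recs)) stop("panel config has no entries", call. = FALSE)
  df <- data.frame(
    target = vapply(recs, function(r) as.character(r$target), character(1)),
    cell_structures = vapply(recs, function(r)
      as.character(r$cell_structures %||% ""), character(1)),
    cycle = vapply(recs, function(r) as.integer(r$cycle), integer(1)),
    fluorophore = vapply(recs, function(r) as.character(r$fluorophore),
                         character(1)),
    conjugation = tolower(vapply(recs, function(r) as.character(r$conjugation),
                                 character(1))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$target))
    stop(sprintf("duplicate antibody target '%s'",
                 df$target[duplicated(df$target)][1L]), call. = FALSE)
  df$expected_segments <- lapply(recs, function(r)
    as.character(unlist(r$expected_segments)))
  new("AntibodyPanel", entries = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged 10-antibody glomerular MxIF panel
#'
#' The three-cycle, 10-antibody panel used to map glomerular cell types and
#' structures (podocytes via podocalyxin/synaptopodin/nestin, mesangial
#' cells via tensin/fibronectin/collagen IV a1-2, endothelial cells via
#' CD31, the glomerular basement membrane via collagen IV a5, plus aSMA and
#' AQP1 for extraglomerular context), shipped as a YAML fixture.
#'
#' @return an [AntibodyPanel-class] with 10 entries.
#' @examples
#' p <- glomerularPanel()
#' nrow(panelTable(p))
#' @export
glomerularPanel <- function() {
  readPanel(system.file("extdata", "glomerular_panel.yaml",
                        package = "glomint", mustWork = TRUE))
}

#' Cell-type expectation vectors over a channel subset
#'
#' For every canonical cell type tagged anywhere in the panel, builds the
#' expectation vector used to name clusters: +1 on channels whose
#' `expected_segments` include the type, -1 on the other selected channels.
#'
#' @param panel an [AntibodyPanel-class].
#' @param channels character subset of panel targets (default all).
#' @return numeric matrix, cell types x selected channels.
#' @export
expectationVectors <- function(panel, channels = NULL) {
  e <- panelTable(panel)
  if (is.null(channels)) channels <- e$target
  miss <- setdiff(channels, e$target)
  if (length(miss))
    stop("channels not in panel: ", paste(miss, collapse = ", "), call. = FALSE)
  types <- sort(unique(unlist(e$expected_segments)))
  out <- matrix(-1, length(types), length(channels),
                dimnames = list(types, channels))
  for (j in seq_along(channels)) {
    tags <- e$expected_segments[[match(channels[j], e$target)]]
    out[types %in% tags, j] <- 1
  }
  out
}
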