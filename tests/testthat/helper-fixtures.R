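## shared fixtures, all generated in code

## tiny 2-pixel IMS dataset around the two exemplar lipid features
tinyIMS <- function() {
  IMSDataset(matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE),
             mz = c(703.575, 810.600),
             coords = data.frame(row = c(0L, 0L), col = 0:1),
             roiId = c(1L, 1L), pitchUm = 5, originUm = c(0, 0))
}

## small paired simulation; cheap enough for many tests
smallSim <- function(over = list(), seed = 5) {
  base <- list(n_glomeruli = 4, radius_um = 45)
  suppressMessages(simulateGlomeruli(utils::modifyList(base, over), seed))
}

## map each segment to the planted cell type dominating its MxIF pixels
segmentTruthTypes <- function(seg, truth) {
  lv <- cellTypeLevels()
  inseg <- !is.na(seg@labels)
  tt <- lv[as.vector(truth@cellMap)][inseg]
  tab <- table(seg@labels[inseg], tt)
  apply(tab, 1L, function(r) colnames(tab)[which.max(r)])
}

## hand-built pixel association: memberOf maps MxIF pixel -> IMS pixel index
toyAssociation <- function(memberOf, nIms, channelMeans = NULL) {
  counts <- tabulate(memberOf[memberOf > 0L], nIms)
  if (is.null(channelMeans)) channelMeans <- matrix(0, nIms, 1L)
  new("PixelAssociation", memberOf = as.integer(memberOf),
      counts = as.integer(counts), channelMeans = channelMeans,
      emptyFootprint = counts == 0L)
}

## labeled IMS table built directly from components
toyLabeled <- function(intensities, segment, roi, depth = NULL,
                       mz = seq_len(ncol(intensities)) + 600) {
  n <- nrow(intensities)
  if (is.null(depth)) depth <- rep("unknown", n)
  tab <- data.frame(pixel = seq_len(n), row = 0L, col = seq_len(n) - 1L,
                    roi_id = roi, depth_class = depth, segment = segment,
                    n_members = 25L)
  new("LabeledIMSTable", table = tab, intensities = as.matrix(intensities),
      mz = mz, excluded = data.frame())
}
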