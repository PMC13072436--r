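test_that("layouts are deterministic under a fixed seed", {
  a <- generateLayout(2, radiusUm = 45, seed = 9)
  b <- generateLayout(2, radiusUm = 45, seed = 9)
  expect_identical(a$cellMap, b$cellMap)
  expect_identical(a$roi@labels, b$roi@labels)
})

test_that("60 glomeruli at equal depth fractions give exactly 30 deep + 30 superficial", {
  lay <- generateLayout(60, radiusUm = 40, pitchUm = 2, seed = 1)
  expect_equal(sum(lay$roi@depth$depth_class == "deep"), 30L)
  expect_equal(sum(lay$roi@depth$depth_class == "superficial"), 30L)
})

test_that("a single glomerulus contains all five in-glomerulus cell types", {
  lay <- generateLayout(1, radiusUm = 45, seed = 3)
  expect_equal(sort(unique(as.vector(lay$roi@labels))), c(0L, 1L))
  present <- cellTypeLevels()[sort(unique(as.vector(lay$cellMap)))]
  expect_true(all(c("podocyte", "mesangial", "endothelial",
                    "basement_membrane", "other_substructure") %in% present))
})

test_that("impossible geometry is rejected", {
  expect_error(generateLayout(1, radiusUm = 25), "radius too small")
  expect_error(generateLayout(1, radiusUm = 10, pitchUm = 4),
               "must exceed 3x")
})

test_that("zero-noise MxIF rendering reproduces the expression matrix exactly", {
  lay <- generateLayout(1, radiusUm = 45, seed = 3)
  img <- renderMxIF(lay$cellMap, glomerularPanel(), noiseCv = 0,
                    backgroundLevel = 0, seed = 1)
  E <- defaultExpressionMatrix()
  arr <- channelArray(img)
  lv <- cellTypeLevels()
  for (t in unique(as.vector(lay$cellMap))) {
    sel <- lay$cellMap == t
    for (ch in c(4, 6)) # podocalyxin, CD31
      expect_true(all(arr[, , ch][sel] == E[lv[t], ch]))
  }
  expect_error(renderMxIF(lay$cellMap, glomerularPanel(), noiseCv = -1),
               "noise_cv")
})

test_that("noisy MxIF channel means match expression within 3 standard errors", {
  cm <- matrix(2L, 120, 120)  # all podocyte
  cv <- 0.3
  img <- renderMxIF(cm, glomerularPanel(), noiseCv = cv,
                    backgroundLevel = 0, seed = 7)
  E <- defaultExpressionMatrix()
  vals <- channelArray(img)[, , 4]  # podocalyxin
  mu <- E["podocyte", "Podocalyxin"]
  se <- mu * cv / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mu), 3 * se)
})

test_that("IMS footprints mix cell-type lipid profiles by area", {
  L <- rbind(matrix(0, 1, 5), matrix(10, 1, 5), matrix(30, 1, 5),
             matrix(0, 3, 5))
  rownames(L) <- cellTypeLevels()
  mz <- seq(700, 704)
  ## footprint entirely one cell type
  cm <- matrix(2L, 10, 10)  # podocyte everywhere
  ims <- suppressMessages(renderIMS(cm, L, mz, imsPitchUm = 5,
                                    noiseModel = list(type = "none")))
  expect_true(all(intensityMatrix(ims) == 10))
  ## 50/50 straddling footprint: arithmetic mean of the two rows
  cm2 <- cbind(matrix(2L, 10, 5), matrix(3L, 10, 5))
  ims2 <- suppressMessages(renderIMS(cm2, L, mz, imsPitchUm = 10,
                                     noiseModel = list(type = "none")))
  expect_true(all(intensityMatrix(ims2) == 20))
})

test_that("deep-glomerulus features are shifted by the planted fold", {
  cm <- matrix(2L, 80, 80)
  roiLab <- cbind(matrix(1L, 80, 40), matrix(2L, 80, 40))
  roi <- ROIMask(roiLab, depth = data.frame(
    roi_id = 1:2, depth_class = c("deep", "superficial")))
  L <- matrix(100, 6, 8, dimnames = list(cellTypeLevels(), NULL))
  de <- data.frame(feature = 3L, mz = 702, fold = 2)
  ims <- suppressMessages(renderIMS(cm, L, mz = seq(700, 707), imsPitchUm = 5,
                                    noiseModel = list(type = "poisson", scale = 2),
                                    depthEffects = de, roiMask = roi, seed = 2))
  m <- intensityMatrix(ims)
  deepSel <- roiIds(ims) == 1L
  ratio <- mean(m[deepSel, 3]) / mean(m[!deepSel, 3])
  expect_lt(abs(ratio - 2), 0.1)
  ratioOther <- mean(m[deepSel, 4]) / mean(m[!deepSel, 4])
  expect_lt(abs(ratioOther - 1), 0.1)
})

test_that("each planted marker is its cell type's largest standardized effect", {
  lip <- defaultLipidMatrix(40, seed = 1)
  L <- lip$lipidMatrix
  ## enrichment of type t on feature j relative to the other types
  enrich <- function(t, j) {
    rest <- L[setdiff(rownames(L), t), j]
    L[t, j] / mean(rest)
  }
  for (i in seq_len(nrow(lip$plantedMarkers))) {
    t <- lip$plantedMarkers$cell_type[i]
    eff <- vapply(seq_len(ncol(L)), function(j) enrich(t, j), numeric(1))
    ## planted markers are positive-sign: dominance in positive enrichment
    expect_equal(which.max(log(eff)), lip$plantedMarkers$feature[i],
                 ignore_attr = TRUE)
  }
  expect_true(all(L >= 0))
  ## the exemplar pair is planted with the documented signs
  jPod <- match(703.575, lip$mz); jEnd <- match(810.600, lip$mz)
  expect_equal(lip$plantedMarkers$feature[lip$plantedMarkers$cell_type == "podocyte"], jPod)
  expect_gt(L["endothelial", jEnd], 2 * median(L[, jEnd]))
  expect_lt(L["podocyte", jEnd], median(L[, jEnd]))
})

test_that("the full simulation is deterministic under a fixed seed", {
  a <- smallSim(list(n_glomeruli = 1, radius_um = 40), seed = 11)
  b <- smallSim(list(n_glomeruli = 1, radius_um = 40), seed = 11)
  expect_identical(a$truth@cellMap, b$truth@cellMap)
  expect_equal(channelArray(a$mxif), channelArray(b$mxif))
  expect_equal(intensityMatrix(a$ims), intensityMatrix(b$ims))
})
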