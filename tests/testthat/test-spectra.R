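test_that("mean spectra follow the closed forms on tiny groups", {
  X <- rbind(c(1, 2, 3), c(5, 6, 7), c(9, 10, 11))
  lab <- toyLabeled(X, segment = c(1L, 1L, 2L), roi = c(1L, 1L, 2L))
  one <- meanSpectrum(lab, 2)
  expect_equal(one$mean, c(9, 10, 11))
  expect_equal(one$se, c(0, 0, 0))
  two <- meanSpectrum(lab, 1)
  expect_equal(two$mean, c(3, 4, 5))
  expect_error(meanSpectrum(lab, 7), "empty segment group: 7")
})

test_that("group means agree with a naive accumulation oracle", {
  withr::local_seed(12)
  X <- matrix(rexp(200), 20, 10)
  seg <- sample(1:3, 20, replace = TRUE)
  lab <- toyLabeled(X, segment = seg, roi = rep(1:4, 5))
  for (s in 1:3) {
    acc <- rep(0, 10); n <- 0
    for (i in which(seg == s)) { acc <- acc + X[i, ]; n <- n + 1 }
    expect_equal(meanSpectrum(lab, s)$mean, acc / n, tolerance = 1e-12)
  }
})

test_that("difference spectra are antisymmetric and require matching axes", {
  withr::local_seed(3)
  X <- matrix(rexp(60), 6, 10)
  lab <- toyLabeled(X, segment = rep(1:2, 3), roi = rep(1:2, 3))
  a <- meanSpectrum(lab, 1); b <- meanSpectrum(lab, 2)
  expect_equal(differenceSpectrum(a, a)$difference, rep(0, 10))
  expect_equal(differenceSpectrum(a, b)$difference,
               -differenceSpectrum(b, a)$difference)
  bBad <- b; bBad$mz <- bBad$mz + 1
  expect_error(differenceSpectrum(a, bBad), "do not match")
})

test_that("segment means conserve the grand mean", {
  sim <- smallSim(list(n_glomeruli = 2, radius_um = 45), seed = 8)
  assoc <- associatePixels(sim$mxif, sim$ims, sim$truth@trueTransform)
  seg <- segmentMxIF(sim$mxif, sim$roi, seed = 3)
  lab <- labelIMSPixels(assoc, seg, sim$ims, sim$roi)
  sp <- segmentSpectra(lab)
  pooled <- vapply(sort(unique(sp$mz)), function(m) {
    rows <- sp[sp$mz == m, ]
    sum(rows$mean * rows$n) / sum(rows$n)
  }, numeric(1))
  grand <- colMeans(labeledIntensities(lab))
  expect_equal(unname(pooled), unname(grand[order(lab@mz)]), tolerance = 1e-9)
})

test_that("podocyte-vs-endothelial differences carry the planted lipid signs", {
  sim <- smallSim(list(n_glomeruli = 4, radius_um = 50, noise_cv = 0.1),
                  seed = 2)
  assoc <- associatePixels(sim$mxif, sim$ims, sim$truth@trueTransform)
  seg <- segmentMxIF(sim$mxif, sim$roi, seed = 6)
  types <- segmentTruthTypes(seg, sim$truth)
  lab <- labelIMSPixels(assoc, seg, sim$ims, sim$roi)
  podSeg <- as.integer(names(types)[types == "podocyte"])
  endSeg <- as.integer(names(types)[types == "endothelial"])
  expect_gt(length(podSeg), 0); expect_gt(length(endSeg), 0)
  d <- differenceSpectrum(meanSpectrum(lab, podSeg),
                          meanSpectrum(lab, endSeg))
  expect_gt(d$difference[d$mz == 703.575], 0)
  expect_lt(d$difference[d$mz == 810.600], 0)
})
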