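fastSpec <- function(...) classifierSpec(nrounds = 60, ...)

## two segments with disjoint feature supports across several glomeruli
separableLabeled <- function(nPerSeg = 60, nRois = 6) {
  withr::local_seed(31)
  ## discrete levels so held-out values match the training support
  X1 <- cbind(matrix(sample(c(60, 80, 100), nPerSeg * 3, TRUE), nPerSeg),
              matrix(0, nPerSeg, 3))
  X2 <- cbind(matrix(0, nPerSeg, 3),
              matrix(sample(c(60, 80, 100), nPerSeg * 3, TRUE), nPerSeg))
  toyLabeled(rbind(X1, X2), segment = rep(1:2, each = nPerSeg),
             roi = rep(rep(seq_len(nRois), length.out = nPerSeg), 2))
}

test_that("a separable two-segment toy scores 1.0 on all four metrics", {
  lab <- separableLabeled()
  res <- trainSegmentClassifier(lab, fastSpec(folds = 3))
  m <- classMetrics(res)
  expect_equal(nrow(m), 8L)  # 2 segments x 4 metrics
  expect_true(all(m$mean == 1))
  expect_true(all(confusionMatrix(res)[row(confusionMatrix(res)) !=
                                       col(confusionMatrix(res))] == 0))
})

test_that("confusion-matrix row sums equal class test counts", {
  lab <- separableLabeled()
  res <- trainSegmentClassifier(lab, fastSpec(folds = 3))
  expect_equal(unname(rowSums(confusionMatrix(res))),
               unname(as.integer(table(labeledTable(lab)$segment))))
})

test_that("metrics agree with a hand-rolled implementation on toy confusion matrices", {
  cm <- matrix(c(40, 5, 3, 2, 50, 4, 1, 6, 60), 3, 3, byrow = TRUE,
               dimnames = list(1:3, 1:3))
  got <- metricsFromConfusion(cm)
  for (i in 1:3) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- sum(cm) - tp - fn - fp
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(got$precision[i], prec)
    expect_equal(got$recall[i], rec)
    expect_equal(got$f1[i], 2 * prec * rec / (prec + rec))
    expect_equal(got$balanced_accuracy[i], (rec + tn / (tn + fp)) / 2)
  }
})

test_that("grouped CV never lets a glomerulus span folds", {
  lab <- separableLabeled(nPerSeg = 80, nRois = 10)
  res <- trainSegmentClassifier(lab, fastSpec(folds = 5))
  byRoi <- tapply(res@folds, labeledTable(lab)$roi_id,
                  function(f) length(unique(f)))
  expect_true(all(byRoi == 1L))
})

test_that("shuffled null labels give balanced accuracy near one half", {
  withr::local_seed(77)
  n <- 400
  X <- matrix(rexp(n * 10), n)
  lab <- toyLabeled(X, segment = sample(rep(1:2, each = n / 2)),
                    roi = rep(1:10, each = n / 10))
  res <- trainSegmentClassifier(lab, fastSpec(folds = 5))
  ba <- classMetrics(res)
  ba <- ba[ba$metric == "balanced_accuracy", ]
  expect_true(all(abs(ba$mean - 0.5) <= pmax(3 * ba$sd, 0.1)))
})

test_that("segments smaller than the fold count are dropped with a warning", {
  lab <- separableLabeled()
  tb <- labeledTable(lab)
  tb$segment[1:2] <- 3L
  small <- new("LabeledIMSTable", table = tb,
               intensities = labeledIntensities(lab), mz = lab@mz,
               excluded = data.frame())
  expect_warning(res <- trainSegmentClassifier(small, fastSpec(folds = 3)),
                 "fewer pixels than folds")
  expect_equal(res@classes, c("1", "2"))
})

test_that("a planted 4x depth effect is detected with high balanced accuracy", {
  withr::local_seed(55)
  n <- 320; nRois <- 8
  roi <- rep(seq_len(nRois), each = n / nRois)
  depth <- ifelse(roi <= nRois / 2, "deep", "superficial")
  X <- matrix(rlnorm(n * 8, log(100), 0.15), n)
  X[depth == "deep", 2] <- X[depth == "deep", 2] * 4
  X[depth == "deep", 5] <- X[depth == "deep", 5] * 4
  lab <- toyLabeled(X, segment = rep(1L, n), roi = roi, depth = depth)
  res <- trainDepthClassifier(lab, 1L, fastSpec(folds = 4))
  ba <- classMetrics(res)
  expect_gte(min(ba$mean[ba$metric == "balanced_accuracy"]), 0.9)
})

test_that("zero depth effect gives chance-level balanced accuracy", {
  withr::local_seed(56)
  n <- 320; nRois <- 8
  roi <- rep(seq_len(nRois), each = n / nRois)
  depth <- ifelse(roi %% 2 == 0, "deep", "superficial")
  X <- matrix(rlnorm(n * 8, log(100), 0.15), n)
  lab <- toyLabeled(X, segment = rep(1L, n), roi = roi, depth = depth)
  res <- trainDepthClassifier(lab, 1L, fastSpec(folds = 4))
  ba <- classMetrics(res)
  ba <- ba[ba$metric == "balanced_accuracy", ]
  expect_true(all(abs(ba$mean - 0.5) <= pmax(3 * ba$sd, 0.15)))
})

test_that("a missing depth class is a hard error", {
  lab <- toyLabeled(matrix(rexp(80), 10), segment = rep(1L, 10),
                    roi = rep(1:2, 5), depth = rep("deep", 10))
  expect_error(trainDepthClassifier(lab, 1L, fastSpec()),
               "lacks one depth class")
  expect_error(trainDepthClassifier(lab, 9L, fastSpec()),
               "no pixels")
})

test_that("balanced accuracy degrades monotonically with IMS noise", {
  mins <- vapply(c(1, 30, 300), function(s) {
    sim <- smallSim(list(ims_noise = list(type = "poisson", scale = s)),
                    seed = 13)
    assoc <- associatePixels(sim$mxif, sim$ims, sim$truth@trueTransform)
    seg <- segmentMxIF(sim$mxif, sim$roi, seed = 3)
    lab <- labelIMSPixels(assoc, seg, sim$ims, sim$roi)
    m <- classMetrics(trainSegmentClassifier(lab, fastSpec(folds = 4)))
    mean(m$mean[m$metric == "balanced_accuracy"])
  }, numeric(1))
  expect_true(all(diff(mins) <= 0))
})
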