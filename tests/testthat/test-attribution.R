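## simple deterministic models for attribution checks
linModel <- function(w) function(X) cbind(as.matrix(X) %*% w)

test_that("linear models get the closed-form attribution", {
  m <- linModel(c(2, -1))
  bg <- rbind(c(0, 0), c(2, 2))           # background mean (1, 1)
  x <- rbind(c(3, 4))
  for (meth in c("exact", "permutation")) {
    res <- shapleyAttributions(m, x, bg, method = meth, nSamples = 20,
                               seed = 2)
    expect_equal(unname(res$shap[[1]][1, ]), c(4, -3), tolerance = 1e-9)
    expect_equal(unname(res$baseline[1]), 1, tolerance = 1e-9)
  }
})

test_that("a constant model gets zero attributions and its value as baseline", {
  m <- function(X) matrix(7, nrow(as.matrix(X)), 1)
  res <- shapleyAttributions(m, matrix(rnorm(10), 2), matrix(rnorm(25), 5),
                             method = "exact")
  expect_true(all(res$shap[[1]] == 0))
  expect_equal(unname(res$baseline), 7)
})

test_that("local accuracy holds on every evaluated pixel for both estimators", {
  withr::local_seed(9)
  m <- function(X) {
    X <- as.matrix(X)
    p <- 1 / (1 + exp(-(X[, 1] * X[, 2] - 0.5 * X[, 3])))
    cbind(p, 1 - p)
  }
  px <- matrix(rnorm(15), 5)
  bg <- matrix(rnorm(30), 10)
  for (meth in c("exact", "permutation")) {
    res <- shapleyAttributions(m, px, bg, method = meth, nSamples = 15,
                               seed = 3)
    for (k in 1:2) {
      recon <- rowSums(res$shap[[k]]) + res$baseline[k]
      expect_equal(unname(recon), unname(res$prediction[, k]),
                   tolerance = 1e-8)
    }
  }
})

test_that("sampling agrees with exact enumeration within Monte-Carlo error", {
  withr::local_seed(4)
  m <- function(X) {
    X <- as.matrix(X)
    cbind(X[, 1] * X[, 2] + sin(X[, 3]) + 0.3 * X[, 4] * X[, 3])
  }
  px <- matrix(rnorm(8), 2)
  bg <- matrix(rnorm(32), 8)
  exact <- shapleyAttributions(m, px, bg, method = "exact")$shap[[1]]
  reps <- vapply(1:12, function(s)
    shapleyAttributions(m, px, bg, method = "permutation", nSamples = 40,
                        seed = s)$shap[[1]],
    matrix(0, 2, 4))
  mc <- apply(reps, 1:2, mean)
  mcSd <- apply(reps, 1:2, sd) / sqrt(dim(reps)[3])
  expect_true(all(abs(mc - exact) <= 3 * mcSd + 1e-6))
})

test_that("symmetry: duplicated features split their attribution equally", {
  m <- function(X) cbind(as.matrix(X)[, 1] + as.matrix(X)[, 2])
  px <- rbind(c(2, 2, 5))
  bg <- rbind(c(0, 0, 1), c(1, 1, -1))
  res <- shapleyAttributions(m, px, bg, method = "exact")
  expect_equal(res$shap[[1]][1, 1], res$shap[[1]][1, 2], tolerance = 1e-12)
})

test_that("dummy features get zero attribution", {
  m <- function(X) cbind(as.matrix(X)[, 1]^2)
  px <- matrix(rnorm(9), 3)
  bg <- matrix(rnorm(15), 5)
  res <- shapleyAttributions(m, px, bg, method = "exact")
  expect_true(all(res$shap[[1]][, 2:3] == 0))
})

test_that("exact enumeration refuses more than 12 features", {
  m <- function(X) cbind(rowSums(as.matrix(X)))
  expect_error(shapleyAttributions(m, matrix(0, 1, 13), matrix(1, 2, 13),
                                   method = "exact"),
               "d <= 12.*permutation")
})

test_that("global scores are mean absolute attributions, order-invariant", {
  shap <- list(a = cbind(c(1, -1, 3, -3), c(0, 0, 0, 0)))
  sc <- globalShapScore(shap)
  expect_equal(unname(sc["a", ]), c(2, 0))
  perm <- list(a = shap$a[c(3, 1, 4, 2), ])
  expect_equal(globalShapScore(perm), sc)
})

test_that("correlation directions follow monotone relationships with a dead zone", {
  x <- cbind(seq_len(20), seq_len(20), rep(1, 20))
  shap <- list(s = cbind(2 * seq_len(20) + 1, -seq_len(20), rnorm(20)))
  d <- correlationDirection(shap, x)
  expect_equal(unname(d[1, 1:2]), c(1, -1))
  expect_equal(unname(d[1, 3]), 0)  # zero-variance feature column
  expect_error(correlationDirection(shap, x[1:2, ]), "at least 3")
})

test_that("bubble tables count, tie-break and round-trip as documented", {
  att <- new("AttributionResult",
             shapValues = list(), baseline = c(a = 0, b = 0),
             globalScore = rbind(a = c(3, 1, 0), b = c(0, 1, 3)),
             direction = rbind(a = c(1, 0, -1), b = c(-1, 0, 1)),
             ranking = list(a = c(1L, 2L, 3L), b = c(3L, 2L, 1L)),
             mz = c(650.4, 703.575, 810.6), classes = c("a", "b"),
             evaluated = 1:5,
             meta = list(method = "exact"))
  tb <- exportBubbleTable(att, topN = 1)
  expect_equal(nrow(tb), 4L)  # 2 disjoint top features x 2 segments
  expect_s3_class(plotBubble(tb), "ggplot")
  expect_equal(sort(unique(tb$mz)), c(650.4, 810.6))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tb, f, row.names = FALSE)
  expect_equal(read.csv(f), tb, tolerance = 1e-12)
  ## equal scores rank by ascending m/z
  att@globalScore <- rbind(a = c(1, 1, 1), b = c(1, 1, 1))
  att@ranking <- list(a = order(-att@globalScore["a", ], att@mz),
                      b = order(-att@globalScore["b", ], att@mz))
  tb2 <- exportBubbleTable(att, topN = 2)
  expect_equal(tb2$mz[tb2$segment == "a"], c(650.4, 703.575))
})

test_that("attributing a fitted classifier yields coherent rankings", {
  lab <- local({
    withr::local_seed(18)
    n <- 240
    X <- matrix(rlnorm(n * 6, log(50), 0.2), n)
    seg <- rep(1:2, each = n / 2)
    X[seg == 2, 4] <- X[seg == 2, 4] * 4
    toyLabeled(X, segment = seg, roi = rep(1:6, n / 6))
  })
  cls <- trainSegmentClassifier(lab, classifierSpec(folds = 3, nrounds = 60))
  att <- attributeSegments(cls, lab, backgroundN = 50, nEval = 60,
                           nSamples = 15, seed = 5)
  expect_equal(att@classes, c("1", "2"))
  expect_equal(att@meta$scale, "margin")
  expect_equal(rankings(att)[["2"]][1], 4L)   # the planted feature leads
  expect_equal(unname(directions(att)["2", 4]), 1)
  expect_equal(unname(directions(att)["1", 4]), -1)
  ## local accuracy on every evaluated pixel, on the recorded scale
  p <- predictMargin(cls@model, labeledIntensities(lab)[att@evaluated, ])
  for (k in 1:2)
    expect_equal(rowSums(att@shapValues[[k]]) + att@baseline[k],
                 unname(p[, k]), tolerance = 1e-6)
  ## the probability scale remains available and is recorded
  attP <- attributeSegments(cls, lab, backgroundN = 30, nEval = 30,
                            nSamples = 10, seed = 5, scale = "probability")
  expect_equal(attP@meta$scale, "probability")
  pp <- predictProba(cls@model, labeledIntensities(lab)[attP@evaluated, ])
  for (k in 1:2)
    expect_equal(rowSums(attP@shapValues[[k]]) + attP@baseline[k],
                 unname(pp[, k]), tolerance = 1e-6)
})
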