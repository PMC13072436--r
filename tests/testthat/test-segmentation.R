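test_that("standardization matches the closed form and is idempotent", {
  Z <- standardizeChannels(cbind(a = c(1, 2, 3)))
  expect_equal(as.vector(Z), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  Z2 <- standardizeChannels(Z)
  expect_equal(as.vector(Z2), as.vector(Z), tolerance = 1e-12)
})

test_that("zero-variance channels are dropped with a warning, all-constant is an error", {
  X <- cbind(a = c(1, 2, 3, 4), b = rep(7, 4))
  expect_warning(Z <- standardizeChannels(X), "zero-variance channel")
  expect_equal(colnames(Z), "a")
  expect_equal(attr(Z, "dropped"), "b")
  expect_error(standardizeChannels(cbind(a = rep(1, 3), b = rep(2, 3))),
               "all channels have zero variance")
})

test_that("k-means separates well-separated blobs exactly and canonically", {
  withr::local_seed(1)
  X <- rbind(matrix(rnorm(300, 0, 0.2), ncol = 2),
             matrix(rnorm(100, 8, 0.2), ncol = 2))
  truth <- rep(1:2, c(150, 50))
  fit <- clusterPixels(X, 2, seed = 4)
  expect_equal(fit$labels, truth)  # bigger blob gets label 1
  ## duplicating every point leaves the centroids unchanged
  fit2 <- clusterPixels(rbind(X, X), 2, seed = 4)
  expect_equal(fit2$centers, fit$centers, tolerance = 1e-9)
})

test_that("k-means attains the exhaustive-search optimum on a 12-point toy", {
  withr::local_seed(7)
  X <- rbind(matrix(rnorm(8, 0, 0.8), ncol = 2),
             matrix(rnorm(8, 5, 0.8), ncol = 2),
             matrix(rnorm(8, c(0, 9), 0.8), ncol = 2))
  fit <- clusterPixels(X, 3, seed = 2, nInit = 20)
  ## brute force over all 3^12 label assignments with nonempty clusters
  n <- nrow(X)
  A <- as.matrix(expand.grid(rep(list(1:3), n)))
  sq <- rowSums(X^2)
  wss <- rep(0, nrow(A))
  ok <- rep(TRUE, nrow(A))
  for (l in 1:3) {
    M <- A == l
    cnt <- rowSums(M)
    ok <- ok & cnt > 0
    Sx <- M %*% X[, 1]; Sy <- M %*% X[, 2]
    tot <- M %*% sq
    wss <- wss + ifelse(cnt > 0, tot - (Sx^2 + Sy^2) / cnt, 0)
  }
  expect_equal(fit$wss, min(wss[ok]), tolerance = 1e-9)
})

test_that("the Lloyd objective is non-increasing across iterations", {
  withr::local_seed(3)
  for (s in 1:4) {
    X <- matrix(rnorm(600), ncol = 3)
    fit <- clusterPixels(X, 4, seed = s, nInit = 1)
    expect_true(all(diff(fit$wssTrace) <= 1e-9))
  }
})

test_that("labels are invariant to pixel ordering up to the permutation", {
  withr::local_seed(5)
  X <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 5, 0.1), ncol = 2),
             matrix(rnorm(60, c(5, -5), 0.1), ncol = 2))
  perm <- sample.int(nrow(X))
  f1 <- clusterPixels(X, 3, seed = 8)
  f2 <- clusterPixels(X[perm, ], 3, seed = 8)
  expect_equal(f2$labels, f1$labels[perm])
})

test_that("cluster profiles map to cell types by marker pattern", {
  ch <- defaultSegmentationChannels()
  prof <- rbind(
    c(-0.5, 2, -0.5, -0.5, 1.8, 1.5),   # high pod markers
    c(-0.5, -0.5, -0.4, 2.5, -0.5, -0.5), # high CD31
    rep(0, 6))
  colnames(prof) <- ch
  got <- assignCellTypes(prof, glomerularPanel())
  expect_equal(got, c("podocyte", "endothelial", "substructure (unassigned)"))
  ## uniformly dim profiles stay unassigned rather than matching the
  ## least-positive expectation vector
  dim_ <- matrix(-0.6, 1, 6, dimnames = list(NULL, ch))
  expect_equal(assignCellTypes(dim_, glomerularPanel()),
               "substructure (unassigned)")
})

test_that("majority-vote label transfer follows the documented tie and count rules", {
  ims3 <- IMSDataset(matrix(1, 3, 1), mz = 700,
                     coords = data.frame(row = c(0, 0, 0), col = 0:2))
  ## IMS pixel 1: labels {1,1,2}; pixel 2: {1,2} tie; pixel 3: 25 x label 4
  memberOf <- c(1L, 1L, 1L, 2L, 2L, rep(3L, 25L))
  labels <- c(1L, 1L, 2L, 1L, 2L, rep(4L, 25L))
  assoc <- toyAssociation(memberOf, 3L)
  lab <- labelIMSPixels(assoc, labels, ims3, minCount = 1)
  expect_equal(labeledTable(lab)$segment, c(1L, 1L, 4L))
  expect_equal(labeledTable(lab)$n_members, c(3L, 2L, 25L))
  ## minCount excludes sparse footprints with a reason code
  lab5 <- labelIMSPixels(assoc, labels, ims3, minCount = 5)
  expect_equal(labeledTable(lab5)$segment, 4L)
  expect_equal(lab5@excluded$reason, rep("sparse_footprint", 2))
})

test_that("majority-vote labeling agrees with a counting oracle on random toys", {
  withr::local_seed(21)
  for (rep_ in 1:5) {
    nIms <- 12L; nMx <- 180L
    memberOf <- sample(0:nIms, nMx, replace = TRUE)
    labels <- sample(1:4, nMx, replace = TRUE)
    labels[sample.int(nMx, 30)] <- NA
    co <- expand.grid(row = 0:3, col = 0:2)
    ims <- IMSDataset(matrix(1, nIms, 1), mz = 700, coords = co)
    lab <- labelIMSPixels(toyAssociation(memberOf, nIms), labels, ims,
                          minCount = 1)
    for (r in seq_len(nrow(labeledTable(lab)))) {
      j <- labeledTable(lab)$pixel[r]
      votes <- table(factor(labels[memberOf == j & !is.na(labels)], 1:4))
      expect_equal(labeledTable(lab)$segment[r],
                   as.integer(which.max(votes)))
    }
  }
})

test_that("zero-noise segmentation recovers the planted cell map (Jaccard >= 0.95)", {
  sim <- smallSim(list(n_glomeruli = 2, radius_um = 45, noise_cv = 0,
                       ims_noise = list(type = "none")), seed = 4)
  seg <- segmentMxIF(sim$mxif, sim$roi, seed = 2)
  lv <- cellTypeLevels()
  inseg <- !is.na(seg@labels)
  truthTypes <- lv[as.vector(sim$truth@cellMap)][inseg]
  labs <- seg@labels[inseg]
  for (t in unique(truthTypes)) {
    best <- 0
    for (l in unique(labs)) {
      jac <- sum(labs == l & truthTypes == t) /
        sum(labs == l | truthTypes == t)
      best <- max(best, jac)
    }
    expect_gte(best, 0.95)
  }
})
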