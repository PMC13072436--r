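test_that("identity landmarks give the identity transform with zero residual", {
  pts <- cbind(c(0, 10, 0, 7), c(0, 0, 10, 3))
  tr <- estimateAffine(pts, pts)
  expect_equal(tr@matrix, diag(2), tolerance = 1e-12)
  expect_equal(tr@offset, c(0, 0), tolerance = 1e-12)
  expect_lt(attr(tr, "rms"), 1e-12)
})

test_that("a known scale/rotation/offset transform is recovered to 1e-9", {
  th <- pi / 2
  A <- 2 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(10, -5)
  pts <- cbind(c(0, 12, 3, 8, 1), c(0, 1, 9, 4, 7))
  q <- t(A %*% t(pts)) + rep(b, each = nrow(pts))
  tr <- estimateAffine(pts, q)
  expect_equal(tr@matrix, A, tolerance = 1e-9)
  expect_equal(tr@offset, b, tolerance = 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  pts2 <- cbind(c(0, 1), c(0, 1))
  expect_error(estimateAffine(pts2, pts2), "at least 3 landmark pairs")
  col <- cbind(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_error(estimateAffine(col, col), "degenerate landmark configuration")
})

test_that("inversion and composition undo an affine transform", {
  tr <- RegistrationTransform(matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2), c(4, -2))
  id <- composeTransforms(invertTransform(tr), tr)
  expect_equal(id@matrix, diag(2), tolerance = 1e-12)
  expect_equal(id@offset, c(0, 0), tolerance = 1e-12)
  pts <- cbind(runif(5), runif(5))
  expect_equal(transformPoints(invertTransform(tr), transformPoints(tr, pts)),
               transformPoints(RegistrationTransform(), pts),
               tolerance = 1e-12)
})

test_that("aligned frames at a 5:1 pitch ratio give 25 members per interior IMS pixel", {
  img <- MxIFImage(array(1, c(20, 20, 1)),
                   new("AntibodyPanel", entries = data.frame(
                     target = "CD31", cell_structures = "", cycle = 1L,
                     fluorophore = "Cy5", conjugation = "direct",
                     expected_segments = I(list("endothelial")))),
                   pitchUm = 1)
  ims <- IMSDataset(matrix(1, 16, 1), mz = 700,
                    coords = expand.grid(row = 0:3, col = 0:3),
                    pitchUm = 5)
  assoc <- associatePixels(img, ims)
  expect_true(all(assoc@counts == 25L))
  expect_true(all(assoc@channelMeans == 1))
  expect_false(any(assoc@emptyFootprint))
})

test_that("membership matches a brute-force containment oracle under a random affine", {
  withr::local_seed(42)
  panel1 <- new("AntibodyPanel", entries = data.frame(
    target = "CD31", cell_structures = "", cycle = 1L,
    fluorophore = "Cy5", conjugation = "direct",
    expected_segments = I(list("endothelial"))))
  img <- MxIFImage(array(runif(400), c(20, 20, 1)), panel1, pitchUm = 1)
  ims <- IMSDataset(matrix(1, 36, 1), mz = 700,
                    coords = expand.grid(row = 0:5, col = 0:5),
                    pitchUm = 4, originUm = c(-2, 1))
  th <- 0.1
  tr <- RegistrationTransform(
    1.05 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2), c(1.3, -0.7))
  assoc <- associatePixels(img, ims, tr)
  ## oracle: exhaustively test each transformed MxIF center against each
  ## half-open IMS footprint
  px <- expand.grid(row = 0:19, col = 0:19)
  ctr <- cbind(px$col + 0.5, px$row + 0.5)
  mapped <- transformPoints(tr, ctr)
  co <- pixelCoords(ims)
  oracle <- integer(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    for (j in seq_len(nrow(co))) {
      x0 <- -2 + co$col[j] * 4; y0 <- 1 + co$row[j] * 4
      if (mapped[i, 1] >= x0 && mapped[i, 1] < x0 + 4 &&
          mapped[i, 2] >= y0 && mapped[i, 2] < y0 + 4) {
        oracle[i] <- j; break
      }
    }
  }
  expect_identical(assoc@memberOf, oracle)
  ## aggregated means agree with direct per-footprint averaging
  vals <- as.vector(channelArray(img)[, , 1])
  for (j in which(assoc@counts > 0))
    expect_equal(unname(assoc@channelMeans[j, 1]), mean(vals[oracle == j]),
                 tolerance = 1e-12)
})

test_that("landmarks exported by the simulator recover the true transform", {
  sim <- smallSim(list(n_glomeruli = 2, radius_um = 45))
  tr <- estimateAffine(sim$landmarks$mxif, sim$landmarks$ims)
  expect_lt(attr(tr, "rms"), 0.1)
  expect_equal(tr@matrix, sim$truth@trueTransform@matrix, tolerance = 1e-9)
  expect_equal(tr@offset, sim$truth@trueTransform@offset, tolerance = 1e-9)
})

test_that("transforms serialize to JSON and back", {
  tr <- RegistrationTransform(matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2), c(4, -2))
  f <- withr::local_tempfile(fileext = ".json")
  writeTransform(tr, f)
  back <- readTransform(f)
  expect_equal(back@matrix, tr@matrix, tolerance = 1e-12)
  expect_equal(back@offset, tr@offset, tolerance = 1e-12)
  expect_equal(back@direction, tr@direction)
})
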