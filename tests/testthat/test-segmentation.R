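test_that("Otsu separates perfectly bimodal intensities", {
  x <- c(rep(10, 400), rep(200, 100))
  t <- otsuThreshold(x)
  expect_gt(t, 10); expect_lte(t, 200)
  expect_equal(sum(x > t), 100)
  expect_error(otsuThreshold(rep(5, 100)), "constant")
})

test_that("Otsu equals the brute-force between-class-variance maximizer", {
  # the worked toy histogram
  cnt <- c(5, 5, 5, 0, 0, 9, 9, 9)
  expect_equal(pkgOtsuCut(cnt), bruteOtsuCut(cnt))
  # random 8-bit-style histograms, including skewed and sparse ones
  set.seed(404)
  for (i in 1:200) {
    n <- sample(c(8, 32, 256), 1)
    cnt <- rpois(n, lambda = sample(c(0.5, 3, 20), 1))
    if (sum(cnt > 0) < 2) cnt[c(1, n)] <- cnt[c(1, n)] + 1
    expect_true(otsuMatchesOracle(cnt))
  }
})

test_that("a single synthetic nucleus is segmented with high overlap", {
  shape <- c(24, 96, 96)
  truth <- ellipsoidMask(shape, c(12, 48, 48), c(7, 38, 38))
  dapi <- truth * 60 + 2
  nuc <- segmentNucleus(dapi)
  expect_equal(nObjects(nuc), 1)
  m <- labelArray(nuc) > 0
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)
})

test_that("touching nuclei are split and the centred one retained", {
  shape <- c(24, 96, 96)
  centred <- ellipsoidMask(shape, c(12, 48, 48), c(7, 34, 34))
  neighbour <- ellipsoidMask(shape, c(12, 48, 112), c(7, 34, 34))
  dapi <- (centred | neighbour) * 60 + 2
  nuc <- segmentNucleus(dapi)
  expect_equal(nObjects(nuc), 1)
  idx <- which(labelArray(nuc) > 0, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 3]) - 48), 8)        # retained one is centred
  # a clipped nucleus alone is removed entirely
  dapiClipped <- neighbour * 60 + 2
  expect_error(segmentNucleus(dapiClipped), "no nucleus")
})

test_that("FISH segmentation keeps at most the two largest in-nucleus objects", {
  shape <- c(24, 96, 96)
  nucleus <- ellipsoidMask(shape, c(12, 48, 48), c(9, 42, 42))
  ch <- array(2, shape)
  ch <- addBlob(ch, c(12, 30, 30), sigma = c(1.5, 4, 4))    # largest
  ch <- addBlob(ch, c(12, 65, 60), sigma = c(1.2, 3, 3))    # middle
  ch <- addBlob(ch, c(12, 45, 75), sigma = c(1.0, 2, 2))    # smallest
  lab <- segmentFish(ch, nucleus)
  expect_equal(nObjects(lab), 2)
  la <- labelArray(lab)
  expect_true(all(la[!nucleus] == 0))           # objects inside the nucleus
  c1 <- colMeans(which(la == 1L, arr.ind = TRUE))
  c2 <- colMeans(which(la == 2L, arr.ind = TRUE))
  expect_lt(max(abs(c1 - c(12, 30, 30))), 1)
  expect_lt(max(abs(c2 - c(12, 65, 60))), 1)
  expect_gt(objectTable(lab)$voxels[1], objectTable(lab)$voxels[2])
})

test_that("signals outside the nucleus mask are not returned", {
  shape <- c(24, 96, 96)
  nucleus <- ellipsoidMask(shape, c(12, 48, 38), c(8, 30, 30))
  ch <- array(2, shape)
  ch <- addBlob(ch, c(12, 48, 38), sigma = c(1.2, 3, 3))    # inside
  ch <- addBlob(ch, c(12, 48, 88), sigma = c(1.2, 3, 3))    # outside
  lab <- segmentFish(ch, nucleus)
  expect_equal(nObjects(lab), 1)
  cen <- colMeans(which(labelArray(lab) == 1L, arr.ind = TRUE))
  expect_lt(abs(cen[3] - 38), 2)
})

test_that("an empty channel yields zero objects with a flag", {
  shape <- c(24, 96, 96)
  nucleus <- ellipsoidMask(shape, c(12, 48, 48), c(8, 30, 30))
  lab <- segmentFish(array(3, shape), nucleus)
  expect_equal(nObjects(lab), 0)
  expect_true("empty_channel" %in% qcFlags(lab))
})

test_that("segmentation masks are invariant to constant intensity offsets", {
  gm <- scanGene()
  pr <- list(probeForIntron(gm, 3, channel = 1), bacProbe(gm, channel = 2))
  sim <- simulateLoopStack(gm, DelayModel(10), pr, nNuclei = 1, seed = 13,
                           nNeighbors = 0)
  st <- sim$stacks[[1]]
  nuc1 <- segmentNucleus(st)
  fish1 <- segmentFish(getChannel(st, 1), nuc1, voxelSize(st))
  dapi2 <- getChannel(st, "DAPI") + 37
  nuc2 <- segmentNucleus(dapi2, voxelSize(st))
  expect_identical(labelArray(nuc1), labelArray(nuc2))
  fish2 <- segmentFish(getChannel(st, 1) + 123, nuc2, voxelSize(st))
  expect_identical(labelArray(fish1), labelArray(fish2))
})
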