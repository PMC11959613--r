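test_that("bead centroids are recovered with subvoxel accuracy", {
  a <- array(2, c(20, 80, 80))
  a <- addBlob(a, c(10, 50, 50))
  cents <- detectBeads(a)
  expect_equal(nrow(cents), 1)
  expect_lt(max(abs(cents[1, ] - c(10, 50, 50))), 0.1)
})

test_that("empty stacks and border-clipped beads yield no detections", {
  expect_warning(cents <- detectBeads(array(2, c(16, 64, 64))), "no beads")
  expect_equal(nrow(cents), 0)
  a <- array(2, c(20, 80, 80))
  a <- addBlob(a, c(10, 40, 2))                  # clipped at the x border
  a <- addBlob(a, c(10, 40, 40))                 # interior reference
  cents <- detectBeads(a)
  expect_equal(nrow(cents), 1)
  expect_lt(abs(cents[1, "x"] - 40), 0.5)
})

test_that("simulated integer and fractional shifts are recovered within tolerance", {
  sh <- rbind(c(0, 0, 0), c(1, 2, -1), c(0.4, -0.6, 0.2))
  bs <- simulateBeadStack(6, OpticsConfig(shifts = sh), seed = 42)
  est <- estimateShift(bs$stack)
  expect_equal(unname(unlist(est[1, c("dz", "dy", "dx")])), c(0, 0, 0))
  err <- abs(as.matrix(est[, c("dz", "dy", "dx")]) - sh)
  expect_lt(max(err), 0.25)
  expect_true(all(est$nBeads >= 3))
})

test_that("identical channels estimate a zero shift", {
  bq <- simulateBeadStack(4, quietOptics(nChannels = 2), seed = 6)
  est <- estimateShift(bq$stack)
  expect_equal(max(abs(as.matrix(est[, c("dz", "dy", "dx")]))), 0)
})

test_that("disjoint bead fields across channels raise an estimation error", {
  b1 <- simulateBeadStack(3, quietOptics(nChannels = 1), seed = 1)
  b2 <- simulateBeadStack(3, quietOptics(nChannels = 1), seed = 99)
  arr <- array(0, c(dim(b1$stack)[1:3], 2))
  arr[, , , 1] <- imgData(b1$stack)[, , , 1]
  arr[, , , 2] <- imgData(b2$stack)[, , , 1]
  st <- ImageStack(arr)
  expect_error(estimateShift(st), "matched beads between channels 1 and 2")
})

test_that("shift application is exact for zero and integer shifts", {
  bs <- simulateBeadStack(4, OpticsConfig(nChannels = 2), seed = 12)
  unchanged <- applyShift(bs$stack, matrix(0, 2, 3))
  expect_identical(imgData(unchanged), imgData(bs$stack))
  # integer shift equals pure index translation on an interior crop
  sh <- rbind(c(0, 0, 0), c(1, 2, -1))
  out <- applyShift(bs$stack, sh)                # translates by -shift
  a <- imgData(bs$stack)[, , , 2]
  b <- imgData(out)[, , , 2]
  expect_equal(b[3:20, 10:80, 10:80], a[4:21, 12:82, 9:79])
  expect_error(applyShift(bs$stack, rbind(c(0, 0, 0), c(5, 0, 0))),
               "5 voxels")
})

test_that("estimate-apply-estimate round trip leaves <= 0.1 voxel residual", {
  sh <- rbind(c(0, 0, 0), c(1.4, -2.2, 0.7), c(-0.8, 1.1, 2.4))
  bs <- simulateBeadStack(6, OpticsConfig(shifts = sh), seed = 77)
  est <- estimateShift(bs$stack)
  corrected <- applyShift(bs$stack, est)
  resid <- estimateShift(corrected)
  expect_lt(max(abs(as.matrix(resid[, c("dz", "dy", "dx")]))), 0.1)
  expect_match(tail(provenance(corrected), 1), "chromatic shift corrected")
})

test_that("shift estimates are translation-equivariant", {
  bs <- simulateBeadStack(5, OpticsConfig(nChannels = 2,
                                          shifts = rbind(c(0, 0, 0),
                                                         c(0.5, 1, -0.5))),
                          seed = 31)
  base <- estimateShift(bs$stack)
  arr <- imgData(bs$stack)
  t <- c(1, -2, 1.5)
  arr[, , , 2] <- loopSplice:::translate3d(arr[, , , 2], t, fill = 2)
  moved <- estimateShift(ImageStack(arr))
  delta <- unlist(moved[2, c("dz", "dy", "dx")]) -
    unlist(base[2, c("dz", "dy", "dx")])
  expect_lt(max(abs(delta - t)), 0.1)
})
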