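test_that("overlap ratio follows its closed-form cases", {
  a <- array(FALSE, c(16, 64, 64)); a[4:8, 10:20, 10:20] <- TRUE
  idn <- overlapRatio(a, a)
  expect_equal(idn@ratio, 0.5)
  expect_equal(idn@containment, 1)
  expect_true(qcPass(idn))

  b <- array(FALSE, c(16, 64, 64)); b[10:14, 40:50, 40:50] <- TRUE
  dis <- overlapRatio(a, b)
  expect_equal(dis@ratio, 0)
  expect_equal(dis@containment, 0)
  expect_false(qcPass(dis))

  # 100 voxels fully inside 900
  inner <- array(FALSE, c(16, 64, 64)); inner[5:8, 10:14, 10:14] <- TRUE
  outer <- array(FALSE, c(16, 64, 64)); outer[4:12, 8:17, 8:17] <- TRUE
  expect_equal(sum(inner), 100); expect_equal(sum(outer), 900)
  nested <- overlapRatio(inner, outer)
  expect_equal(nested@ratio, 0.1)
  expect_equal(nested@containment, 1)

  empty <- overlapRatio(array(FALSE, c(16, 64, 64)), a)
  expect_true(is.na(empty@ratio))
  expect_false(qcPass(empty))
})

test_that("overlap ratio is bounded by 0.5 with equality only for identical masks", {
  set.seed(7)
  for (i in 1:25) {
    a <- array(runif(16 * 32 * 32) < 0.2, c(16, 32, 32))
    b <- array(runif(16 * 32 * 32) < 0.2, c(16, 32, 32))
    r <- overlapRatio(a, b)@ratio
    expect_lte(r, 0.5)
    if (identical(a, b)) expect_equal(r, 0.5) else expect_lt(r, 0.5)
  }
})

test_that("expected overlap is the genomic length ratio", {
  expect_equal(round(100 * expectedOverlap(53.8, 153)), 35)
  expect_equal(expectedOverlap(53.8, 153), 53.8 / 153, tolerance = 1e-12)
  expect_equal(round(100 * expectedOverlap(7, 153)), 5)   # prints as ~4-5%
  expect_equal(round(expectedOverlap(7, 153), 4), 0.0458)
  expect_equal(expectedOverlap(153, 153), 1)
  expect_error(expectedOverlap(0, 10), "positive")
  expect_error(expectedOverlap(10, 5), "exceed")
})

test_that("PCC hits its analytic limits and ignores affine rescaling", {
  set.seed(11)
  a <- array(runif(16 * 64 * 64, 0, 50), c(16, 64, 64))
  mask <- array(TRUE, dim(a))
  expect_equal(pccValue(pcc(a, a, mask, sigma = 0)), 1)
  expect_equal(pccValue(pcc(a, max(a) - a, mask, sigma = 0)), -1)
  b <- array(runif(length(a), 0, 50), dim(a))
  r1 <- pccValue(pcc(a, b, mask, sigma = 1))
  r2 <- pccValue(pcc(2.5 * a + 7, 0.3 * b + 100, mask, sigma = 1))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("independent channels give near-zero PCC at large n", {
  set.seed(23)
  a <- array(rnorm(1e5, 100, 10), c(25, 80, 50))
  b <- array(rnorm(1e5, 100, 10), c(25, 80, 50))
  expect_lt(abs(pccValue(pcc(a, b, array(TRUE, dim(a)), sigma = 0))), 0.02)
})

test_that("undefined PCC is reported as QC failure, never zero", {
  a <- array(5, c(16, 64, 64))
  b <- array(runif(16 * 64 * 64), c(16, 64, 64))
  r <- pcc(a, b, array(TRUE, dim(a)), sigma = 0)
  expect_true(is.na(pccValue(r)))
  expect_false(qcPass(r))
  expect_true("zero_variance" %in% qcFlags(r))
  expect_error(pcc(a, b, array(FALSE, dim(a))), "empty")
})

test_that("the PCC analysis mask keeps interior signal and drops border objects", {
  shape <- c(24, 96, 96)
  nucleus <- ellipsoidMask(shape, c(12, 48, 48), c(8, 35, 35))
  a <- array(2, shape); b <- array(2, shape)
  a <- addBlob(a, c(12, 40, 40), sigma = c(1.5, 3, 3))
  b <- addBlob(b, c(12, 58, 55), sigma = c(1.5, 3, 3))
  # a blob straddling the nuclear border in channel a
  a <- addBlob(a, c(12, 48, 83), sigma = c(1.5, 3, 3))
  m <- pccMask(a, b, nucleus)
  expect_true(all(m[!nucleus] == FALSE))
  expect_true(m[12, 40, 40]); expect_true(m[12, 58, 55])
  expect_false(m[12, 48, 82])                    # border object removed
  expect_error(pccMask(array(2, shape), array(2, shape), nucleus), "signal")
})
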