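# Shared fixtures, built in code. Heavy simulations are cached per session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

tgModel <- function() cached("tg", tgGeneModel())

# uniform-intron gene for probe-separation scans: 20 introns of 4 kb
scanGene <- function() cached("scan",
  makeGeneModel(nExons = 21, exonLenRange = c(150, 150),
                intronLenRange = c(4000, 4000), longIntron = NULL,
                geneId = "scan", seed = 1))

# tiny two-exon gene for cheap rendering tests
tinyGene <- function() GeneModel("tiny", rbind(c(0, 200), c(500, 700)),
                                 length = 700)

quietOptics <- function(...) OpticsConfig(photonScale = 0, readNoiseSd = 0, ...)

# analytic Gaussian blob added to a 3D array at 1-based voxel centre
addBlob <- function(a, centre, sigma = c(1, 2.5, 2.5), peak = 100) {
  d <- dim(a)
  gz <- exp(-((seq_len(d[1]) - centre[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-((seq_len(d[2]) - centre[2])^2) / (2 * sigma[2]^2))
  gx <- exp(-((seq_len(d[3]) - centre[3])^2) / (2 * sigma[3]^2))
  a + peak * outer(outer(gz, gy), gx)
}

ellipsoidMask <- function(shape, centre, semi) {
  z <- (seq_len(shape[1]) - centre[1]) / semi[1]
  y <- (seq_len(shape[2]) - centre[2]) / semi[2]
  x <- (seq_len(shape[3]) - centre[3]) / semi[3]
  outer(outer(z^2, y^2, "+"), x^2, "+") <= 1
}

# brute-force Otsu oracle: exhaustive between-class-variance maximizer,
# returns the cut index k (background = bins 1..k), first maximum on ties
bruteOtsuCut <- function(cnt, mids = seq_along(cnt) - 1) {
  best <- -Inf; bk <- NA_integer_
  for (k in seq_len(length(cnt) - 1L)) {
    w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(cnt[1:k] * mids[1:k]) / w0
    m1 <- sum(cnt[(k + 1):length(cnt)] * mids[(k + 1):length(cnt)]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best * (1 + 1e-12) + 1e-12) { best <- v; bk <- k }
  }
  bk
}

# cut index chosen by otsuThreshold on pre-binned counts
pkgOtsuCut <- function(cnt, mids = seq_along(cnt) - 1) {
  t <- otsuThreshold(cnt, counts = TRUE, mids = mids)
  sum(mids < t)
}

# between-class variance (unnormalized) of cutting counts after bin k
betweenClassVar <- function(cnt, k, mids = seq_along(cnt) - 1) {
  w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
  if (w0 == 0 || w1 == 0) return(-Inf)
  m0 <- sum(cnt[1:k] * mids[1:k]) / w0
  m1 <- sum(cnt[(k + 1):length(cnt)] * mids[(k + 1):length(cnt)]) / w1
  w0 * w1 * (m0 - m1)^2
}

# TRUE when the package's cut attains the brute-force maximum (ties allowed)
otsuMatchesOracle <- function(cnt, mids = seq_along(cnt) - 1) {
  vmax <- max(vapply(seq_len(length(cnt) - 1L), betweenClassVar,
                     0, cnt = cnt, mids = mids))
  v <- betweenClassVar(cnt, pkgOtsuCut(cnt, mids), mids)
  isTRUE(all.equal(v, vmax, tolerance = 1e-9))
}

# run the segmentation + overlap chain on one simulated nucleus
measureOverlap <- function(sim, i) {
  st <- sim$stacks[[i]]
  nuc <- segmentNucleus(st)
  li <- segmentFish(getChannel(st, 1), nuc, voxelSize(st))
  lb <- segmentFish(getChannel(st, 2), nuc, voxelSize(st))
  overlapRatio(li, lb)
}

# run the segmentation + masked-PCC chain on one simulated nucleus
measurePcc <- function(sim, i) {
  st <- sim$stacks[[i]]
  nuc <- segmentNucleus(st)
  a <- getChannel(st, 1); b <- getChannel(st, 2)
  pcc(a, b, pccMask(a, b, nuc))
}
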