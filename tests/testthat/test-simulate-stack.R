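test_that("identical config and seed reproduce stacks bit-exactly", {
  gm <- scanGene()
  pr <- list(probeForIntron(gm, 1, channel = 1), bacProbe(gm, channel = 2))
  s1 <- simulateLoopStack(gm, DelayModel(10), pr, nNuclei = 2, seed = 9)
  s2 <- simulateLoopStack(gm, DelayModel(10), pr, nNuclei = 2, seed = 9)
  expect_identical(imgData(s1$stacks[[1]]), imgData(s2$stacks[[1]]))
  expect_identical(imgData(s1$stacks[[2]]), imgData(s2$stacks[[2]]))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateLoopStack(gm, DelayModel(10), pr, nNuclei = 2, seed = 10)
  expect_false(identical(imgData(s1$stacks[[1]]), imgData(s3$stacks[[1]])))
})

test_that("identical probes in two channels render identical images without noise or shift", {
  gm <- scanGene()
  p1 <- probeForIntron(gm, 3, channel = 1)
  pr <- list(p1, ProbeSet("same", p1@targets, 2L))
  sim <- simulateLoopStack(gm, DelayModel(0), pr, quietOptics(nChannels = 3),
                           seed = 3, nNeighbors = 0)
  st <- sim$stacks[[1]]
  expect_identical(getChannel(st, 1), getChannel(st, 2))
  expect_equal(sim$truth[[1]]$trueOverlap[1, 2], 0.5)
})

test_that("truth masks of well-separated probes on a stiff axis are disjoint", {
  gm <- scanGene()                               # 83 kb
  pr <- list(probeForIntron(gm, 1, channel = 1),
             probeForIntron(gm, 14, channel = 2))  # ~54 kb apart
  sim <- simulateLoopStack(gm, DelayModel(0), pr, quietOptics(nChannels = 3),
                           seed = 5, nNeighbors = 0,
                           persistenceNm = 5000, territoryRadiusNm = 2500)
  tr <- sim$truth[[1]]
  expect_true(any(tr$alleleAmps > 0))            # seed chosen with signal
  expect_lt(tr$trueRatio, 0.02)
})

test_that("burst categories are drawn near their configured probabilities", {
  gm <- tinyGene()
  pr <- list(ProbeSet("p", c(0, 200), 1L))
  sim <- simulateLoopStack(gm, DelayModel(0, burstProbs = c(1, 1, 1) / 3), pr,
                           quietOptics(nChannels = 2, shape = c(16, 64, 64)),
                           nNuclei = 120, seed = 4, nNeighbors = 0)
  states <- unlist(lapply(sim$truth, `[[`, "burstStates"))
  counts <- table(factor(states, c("on_full", "on_partial", "off")))
  # 240 draws at p = 1/3 each: expect 80 +- ~4 sd (sd = 7.3)
  expect_true(all(counts > 50 & counts < 110))
})

test_that("a probe with no nascent target warns and leaves the channel empty", {
  gm <- tinyGene()
  # exon targets persist to the gene end, so use an interval past the gene
  pr <- list(ProbeSet("beyond", c(6000, 7000), 1L))
  expect_warning(
    sim <- simulateLoopStack(gm, DelayModel(0), pr,
                             quietOptics(nChannels = 2, shape = c(16, 64, 64)),
                             seed = 1, nNeighbors = 0),
    "labels no nascent sequence")
  expect_equal(sum(sim$truth[[1]]$masks[[1]]), 0)
})

test_that("bead stacks honour configured shifts and spacing", {
  op <- OpticsConfig(shifts = rbind(c(0, 0, 0), c(1, 2, -1)))
  bs <- simulateBeadStack(5, op, seed = 21)
  tr <- bs$truth
  expect_equal(nrow(tr$centresVox), 5)
  d <- as.matrix(dist(sweep(tr$centresVox - 1, 2,
                            c(300, 60, 60), "*")))    # nm
  expect_gte(min(d[d > 0]), 2000)                 # >= 4 bead diameters
  # zero shift: channels identical without noise
  bq <- simulateBeadStack(4, quietOptics(nChannels = 2), seed = 3)
  expect_identical(getChannel(bq$stack, 1), getChannel(bq$stack, 2))
  expect_error(simulateBeadStack(2, op, seed = 1), "3 beads")
  expect_error(
    simulateBeadStack(200, OpticsConfig(nChannels = 2), seed = 1),
    "too many beads")
})

test_that("fractional bead shifts move centroids by the configured amount", {
  sh <- c(0.4, -0.6, 0.2)
  bs <- simulateBeadStack(4, quietOptics(shifts = rbind(c(0, 0, 0), sh)),
                          seed = 8)
  c1 <- detectBeads(bs$stack, 1)
  c2 <- detectBeads(bs$stack, 2)
  expect_equal(nrow(c1), 4)
  # match by order of nearest neighbour
  for (i in seq_len(nrow(c1))) {
    j <- which.min(rowSums(sweep(c2, 2, c1[i, ])^2))
    expect_lt(max(abs(c2[j, ] - c1[i, ] - sh)), 0.1)
  }
})

test_that("read-block union with spliced gaps is a contiguous genomic prefix", {
  gm <- scanGene()
  sim <- simulateReads(gm, DelayModel(8), 200, polyAFraction = 0, seed = 2)
  for (i in seq_along(sim$reads)) {
    b <- blockMatrix(sim$reads, i)
    expect_equal(unname(b[1, 1]), 0)             # starts at the 5' end
    tr <- sim$truth[sim$truth$readId == i, ]
    spl <- intronBounds(gm)[tr$intron[tr$state == "spliced"], , drop = FALSE]
    covered <- sum(b[, 2] - b[, 1]) + sum(spl[, 2] - spl[, 1])
    expect_equal(unname(covered), unname(max(b[, 2])))          # prefix length conserved
    if (nrow(b) > 1)
      expect_true(all(b[-1, 1] > b[-nrow(b), 2]))
  }
})
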