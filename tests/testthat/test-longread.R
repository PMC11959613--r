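test_that("intron calls follow the boundary rules", {
  gm <- GeneModel("g", rbind(c(0, 1000), c(3000, 4000), c(6000, 7000)),
                  length = 7000)                 # introns [1000,3000), [4000,6000)
  # gap exactly at intron 1 boundaries -> spliced
  cl <- classifyIntrons(rbind(c(0, 1000), c(3000, 3500)), gm)
  expect_equal(cl$state[cl$intron == 1], "spliced")
  # one contiguous block across exon-intron-exon -> unspliced
  cl <- classifyIntrons(rbind(c(0, 3500)), gm)
  expect_equal(cl$state[cl$intron == 1], "unspliced")
  # read ending mid-intron -> incomplete
  cl <- classifyIntrons(rbind(c(0, 1800)), gm)
  expect_equal(cl$state, "incomplete")
  # gap matching only one boundary -> ambiguous
  cl <- classifyIntrons(rbind(c(0, 1000), c(2500, 3500)), gm)
  expect_equal(cl$state[cl$intron == 1], "ambiguous")
  # boundary wobble within tolerance still counts as spliced
  cl <- classifyIntrons(rbind(c(0, 995), c(3008, 3500)), gm, boundaryTol = 10)
  expect_equal(cl$state[cl$intron == 1], "spliced")
  expect_error(classifyIntrons(rbind(c(100, 100)), gm), "malformed")
})

test_that("every overlapping intron receives exactly one call", {
  gm <- scanGene()
  sim <- simulateReads(gm, DelayModel(12), 300, seed = 6)
  calls <- classifyReads(sim$reads, gm)
  ib <- intronBounds(gm)
  for (i in sample(seq_along(sim$reads), 40)) {
    b <- blockMatrix(sim$reads, i)
    nOverlap <- sum(ib[, 2] > min(b[, 1]) & ib[, 1] < max(b[, 2]))
    expect_equal(sum(calls$readId == i), nOverlap)
  }
  expect_true(all(calls$state %in%
                    c("spliced", "unspliced", "incomplete", "ambiguous")))
})

test_that("noise-free classification matches simulator truth", {
  gm <- tgModel()
  sim <- simulateReads(gm, DelayModel(25), 1500, polyAFraction = 0.1,
                       seed = 17)
  calls <- classifyReads(sim$reads, gm)
  tr <- sim$truth
  m <- match(paste(calls$readId, calls$intron), paste(tr$readId, tr$intron))
  expect_true(all(!is.na(m)))
  expect_gte(mean(calls$state == tr$state[m]), 0.99)
})

test_that("intron-containing read selection matches the retention truth", {
  gm <- tgModel()
  sim <- simulateReads(gm, DelayModel(25), 800, polyAFraction = 0.3, seed = 19)
  icr <- intronContainingReads(sim$reads, gm)
  tr <- sim$truth
  truthSel <- sort(unique(tr$readId[tr$state %in% c("unspliced", "incomplete")]))
  got <- sort(match(S4Vectors::mcols(icr)$name, S4Vectors::mcols(sim$reads)$name))
  expect_gte(length(intersect(got, truthSel)) /
               length(union(got, truthSel)), 0.99)
  expect_equal(attr(icr, "nReadThrough"), 0)
  # a fully spliced mature read on its own is excluded
  mature <- makeSplicedReads(list(exonBounds(gm)), gm)
  expect_length(intronContainingReads(mature, gm), 0)
})

test_that("histograms bin half-open from zero and conserve totals", {
  gm <- GeneModel("g", rbind(c(0, 1000), c(2000, 3000)), length = 3000)
  reads <- makeSplicedReads(list(rbind(c(0, 100)),
                                 rbind(c(0, 299)),
                                 rbind(c(0, 300))), gm)
  h <- readLengthHist(reads, bin = 300)
  expect_equal(h$count[h$binStart == 0], 2)
  expect_equal(h$count[h$binStart == 300], 1)
  expect_equal(sum(h$count), 3)

  sim <- simulateReads(tgModel(), DelayModel(40), 400, seed = 21)
  icr <- intronContainingReads(sim$reads, tgModel())
  expect_equal(sum(readLengthHist(icr)$count), length(icr))
  calls <- classifyReads(icr, tgModel())
  ipr <- intronsPerReadHist(calls)
  expect_equal(sum(ipr$count), length(icr))      # every kept read has >= 1
})

test_that("per-intron coverage counts retained calls", {
  gm <- scanGene()
  sim <- simulateReads(gm, DelayModel(8), 400, seed = 23)
  calls <- classifyReads(sim$reads, gm)
  cov <- intronCoverage(sim$reads, gm)
  ret <- calls[calls$state %in% c("unspliced", "incomplete"), ]
  expect_equal(cov$reads, as.numeric(table(factor(ret$intron,
                                                  seq_len(nIntrons(gm))))))
})

test_that("delay extent is recovered from the unspliced read envelope", {
  gm <- tgModel()
  ib <- intronBounds(gm)
  dl <- ifelse(ib[, 2] - ib[, 1] < 10000, 40, 0)
  sim <- simulateReads(gm, DelayModel(dl), 3000, seed = 29)
  eligible <- which(ib[, 2] < geneLength(gm) - 50000 &
                      ib[, 2] - ib[, 1] < 10000)
  est <- estimateDelay(sim$reads, gm, whichIntrons = eligible)
  expect_equal(median(est$delayEstKb), 40, tolerance = 0.2)
})

test_that("model limits: zero delay retains only the transcribed intron", {
  gm <- scanGene()
  sim <- simulateReads(gm, DelayModel(0), 400, polyAFraction = 0, seed = 31)
  tr <- sim$truth
  retained <- tr[tr$state %in% c("unspliced", "incomplete"), ]
  expect_true(all(retained$state == "incomplete"))
  # infinite delay: reads are unspliced genomic prefixes
  simInf <- simulateReads(gm, DelayModel(1e6), 50, polyAFraction = 0, seed = 32)
  for (i in seq_len(10)) {
    b <- blockMatrix(simInf$reads, i)
    expect_equal(nrow(b), 1)
    expect_equal(unname(b[1, 1]), 0)
  }
})

test_that("transcription time is length over rate", {
  t40 <- transcriptionTime(53.8, 3.8)
  expect_gt(t40, 14)                             # the long intron: >14 min
  expect_equal(t40, 53.8 / 3.8, tolerance = 1e-12)
  expect_equal(transcriptionTime(0, 3.8), 0)
  expect_equal(transcriptionTime(8.4, 4.2), 2)
  expect_error(transcriptionTime(10, 0), "rate")
})

test_that("BED12 round trip preserves block structure", {
  gm <- scanGene()
  sim <- simulateReads(gm, DelayModel(8), 25, seed = 37)
  path <- file.path(tempdir(), "reads.bed")
  writeBed12(sim$reads, path)
  back <- readBed12(path)
  expect_equal(length(back), length(sim$reads))
  for (i in seq_len(10))
    expect_equal(blockMatrix(back, i), blockMatrix(sim$reads, i))
})
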