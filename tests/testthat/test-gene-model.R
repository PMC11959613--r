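test_that("explicit two-exon construction yields the forced structure", {
  gm <- GeneModel("g", rbind(c(0, 100), c(400, 500)), length = 500)
  expect_equal(geneLength(gm), 500)
  expect_equal(nIntrons(gm), 1)
  expect_equal(unname(intronBounds(gm)[1, ]), c(100, 400))
})

test_that("default gene model matches the thyroglobulin-like architecture", {
  for (seed in c(1, 7, 42)) {
    gm <- makeGeneModel(seed = seed)
    ib <- intronBounds(gm)
    expect_equal(nrow(exonBounds(gm)), 48)
    expect_equal(nrow(ib), 47)
    len <- ib[, 2] - ib[, 1]
    expect_equal(sum(len >= 50000), 1)          # exactly one large intron
    expect_equal(max(len), 53800)
    expect_gt(geneLength(gm), 150000)
    expect_lt(geneLength(gm), 215000)
  }
  expect_error(makeGeneModel(nExons = 1), "nExons")
  expect_error(makeGeneModel(exonLenRange = c(233, 66)), "ranges")
})

test_that("frozen default model pins the probed intron sizes", {
  tg <- tgModel()
  ib <- intronBounds(tg)
  len <- ib[, 2] - ib[, 1]
  expect_equal(len[c(20, 21, 22, 23, 24, 40, 41, 42)],
               c(2500, 7000, 1900, 2500, 5300, 53800, 1000, 9400))
  expect_identical(exonBounds(tgGeneModel()), exonBounds(tg)) # reproducible
})

test_that("labelled interval extends an intron by its delay and clips", {
  gm <- GeneModel("g", rbind(c(0, 10000), c(12000, 60000)), length = 60000)
  expect_equal(unname(labelledInterval(1, gm, DelayModel(0))),
               c(10000, 12000))
  expect_equal(unname(labelledInterval(1, gm, DelayModel(40))),
               c(10000, 52000))
  expect_equal(unname(labelledInterval(1, gm, DelayModel(60)))[2], 60000)
  expect_error(labelledInterval(2, gm, DelayModel(0)), "intron")
})

test_that("delay and probe constructors enforce their invariants", {
  expect_error(DelayModel(delayKb = -1))
  expect_error(DelayModel(burstProbs = c(0.5, 0.5, 0.5)))
  expect_error(ProbeSet("p", c(100, 100), 1))
  expect_silent(ProbeSet("p", c(100, 400), 1))
  pr <- probeForIntron(tgModel(), 40, width = 3000)
  ib <- intronBounds(tgModel())
  expect_equal(unname(pr@targets[1, ]), unname(c(ib[40, 1], ib[40, 1] + 3000)))
})

test_that("GFF3 and BED12 annotation import builds a strand-free model", {
  # plus-strand gene at chr offset 1000 with exons 1001-1100, 1301-1400 (1-based)
  gff <- file.path(tempdir(), "toy.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1001\t1400\t.\t+\t.\tID=gene1",
               "chr1\ttest\texon\t1001\t1100\t.\t+\t.\tParent=tx1",
               "chr1\ttest\texon\t1301\t1400\t.\t+\t.\tParent=tx1"), gff)
  gm <- readGeneModel(gff)
  expect_equal(geneLength(gm), 400)
  expect_equal(unname(exonBounds(gm)), rbind(c(0, 100), c(300, 400)))
  # minus strand: same exons must be reflected (5' end at 0)
  gffm <- file.path(tempdir(), "toym.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\texon\t1001\t1100\t.\t-\t.\tParent=tx1",
               "chr1\ttest\texon\t1301\t1400\t.\t-\t.\tParent=tx1"), gffm)
  gmm <- readGeneModel(gffm)
  expect_equal(unname(exonBounds(gmm)), rbind(c(0, 100), c(300, 400)))
  expect_equal(gmm@strand, "-")
  # BED12 round trip via the read container
  gm2 <- GeneModel("tx2", rbind(c(0, 150), c(800, 1000)), length = 1000)
  reads <- makeSplicedReads(list(exonBounds(gm2)), gm2, ids = "tx2")
  bed <- file.path(tempdir(), "toy.bed")
  writeBed12(reads, bed)
  gm3 <- readGeneModel(bed, gene = "tx2")
  expect_equal(unname(exonBounds(gm3)), unname(exonBounds(gm2)))
})
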