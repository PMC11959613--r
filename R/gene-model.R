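#' @include AllClasses.R
NULL

#' Build a random many-exon gene model
#'
#' Draws exon lengths uniformly and intron lengths log-uniformly within the
#' given ranges, then forces one intron to a fixed large size. The defaults
#' emulate a thyroglobulin-like gene: 48 exons of 66-233 nt, introns of
#' 197-9375 nt and a single ~54 kb intron, totalling roughly 180 kb.
#' Intron lengths are drawn log-uniformly because intron-size distributions
#' are strongly right-skewed; with the default ranges this makes the
#' expected total gene length land near 180 kb.
#'
#' @param nExons number of exons (>= 2).
#' @param exonLenRange length-2 range of exon lengths, nt.
#' @param intronLenRange length-2 range of (small) intron lengths, nt.
#' @param longIntron numeric (index, length_nt): intron index (1-based, intron
#'   i follows exon i) forced to length_nt, or NULL for none.
#' @param geneId gene identifier.
#' @param seed integer seed; the model is a deterministic function of the
#'   arguments and the seed.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' gm <- makeGeneModel(seed = 1)
#' nIntrons(gm)   # 47
#' @export
makeGeneModel <- function(nExons = 48, exonLenRange = c(66, 233),
                          intronLenRange = c(197, 9375),
                          longIntron = c(40, 53800),
                          geneId = "synthetic_gene", seed = 1) {
  if (nExons < 2) paramError("nExons must be >= 2 (no introns otherwise)")
  if (any(exonLenRange <= 0) || diff(exonLenRange) < 0 ||
      any(intronLenRange <= 0) || diff(intronLenRange) < 0)
    paramError("length ranges must be positive and increasing")
  if (!is.null(longIntron) && longIntron[1] > nExons - 1)
    paramError("longIntron index exceeds intron count")
  withSeed(seed, {
    exonLen <- round(runif(nExons, exonLenRange[1], exonLenRange[2]))
    intronLen <- round(exp(runif(nExons - 1, log(intronLenRange[1]),
                                 log(intronLenRange[2]))))
    if (!is.null(longIntron)) intronLen[longIntron[1]] <- longIntron[2]
    starts <- cumsum(c(0, head(exonLen, -1) + intronLen))
    GeneModel(geneId, cbind(starts, starts + exonLen),
              length = starts[nExons] + exonLen[nExons])
  })
}

#' Default thyroglobulin-like gene model
#'
#' A frozen 48-exon gene model used throughout examples and pipelines. The
#' introns probed in the bundled experiment presets are pinned to the sizes
#' used in the colocalization experiments (intron 20: 2.5 kb, 21: 7 kb,
#' 22: 1.9 kb, 23: 2.5 kb, 24: 5.3 kb, 40: 53.8 kb, 41: 1 kb, 42: 9.4 kb);
#' the remaining introns are drawn once from the default log-uniform model.
#' Where two printed sizes exist for intron 24 (5.5 vs 5.3 kb) the model
#' uses 5.3 kb.
#'
#' @return A \linkS4class{GeneModel} of ~180 kb with 47 introns.
#' @examples
#' tg <- tgGeneModel()
#' intronBounds(tg)[40, ]
#' @export
tgGeneModel <- function() {
  pin <- c("20" = 2500, "21" = 7000, "22" = 1900, "23" = 2500, "24" = 5300,
           "40" = 53800, "41" = 1000, "42" = 9400)
  withSeed(263872, {
    exonLen <- round(runif(48, 66, 233))
    intronLen <- round(exp(runif(47, log(197), log(9375))))
    intronLen[as.integer(names(pin))] <- pin
    starts <- cumsum(c(0, head(exonLen, -1) + intronLen))
    GeneModel("Tg", cbind(starts, starts + exonLen),
              length = starts[48] + exonLen[48])
  })
}

# Per-intron delay vector for a gene (recycles a scalar DelayModel).
delayVector <- function(delay, gene) {
  d <- delayKb(delay)
  n <- nIntrons(gene)
  if (length(d) == 1L) rep(d, n)
  else if (length(d) == n) d
  else paramError("delayKb must be scalar or one value per intron")
}

#' Gene-axis interval still carrying an intron probe target
#'
#' Nascent transcripts carry a (fully transcribed) intron until the
#' polymerase has moved \code{delay} kb past the intron 3' end, so on the
#' gene axis the intron's probe decorates the interval from the intron
#' start to that release point, clipped at the gene end.
#'
#' @param intron intron index (1-based).
#' @param gene a \linkS4class{GeneModel}.
#' @param delay a \linkS4class{DelayModel} or numeric delay in kb.
#' @return numeric (start, end), 0-based half-open gene coordinates.
#' @examples
#' gm <- GeneModel("g", rbind(c(0, 10000), c(12000, 20000)), length = 20000)
#' labelledInterval(1, gm, DelayModel(delayKb = 4))
#' @export
labelledInterval <- function(intron, gene, delay) {
  ib <- intronBounds(gene)
  if (intron < 1 || intron > nrow(ib)) paramError("no such intron")
  if (is.numeric(delay)) delay <- DelayModel(delayKb = delay)
  d <- delayVector(delay, gene)[intron]
  c(start = ib[intron, 1],
    end = min(ib[intron, 2] + d * 1000, geneLength(gene)))
}

#' Probe sets for common experiment designs
#'
#' \code{probeForIntron} targets the first part of an intron (oligoprobes
#' against the 1-3 kb downstream of the intron 5' end);
#' \code{bacProbe} emulates a large genomic clone spanning a contiguous
#' portion of the gene (all exons and introns within the span).
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param intron intron index.
#' @param width probe target width, nt (clipped to the intron).
#' @param channel imaging channel index.
#' @param span numeric (start, end) of the clone on the gene, nt; default
#'   spans the whole gene.
#' @param name probe name.
#' @return A \linkS4class{ProbeSet}.
#' @export
probeForIntron <- function(gene, intron, width = 3000, channel = 1,
                           name = paste0("intron", intron)) {
  ib <- intronBounds(gene)
  if (intron < 1 || intron > nrow(ib)) paramError("no such intron")
  ProbeSet(name,
           c(ib[intron, 1], min(ib[intron, 1] + width, ib[intron, 2])),
           channel)
}

#' @rdname probeForIntron
#' @export
bacProbe <- function(gene, span = c(0, geneLength(gene)), channel = 2,
                     name = "BAC") {
  span <- c(max(0, span[1]), min(geneLength(gene), span[2]))
  if (diff(span) <= 0) paramError("empty BAC span")
  ProbeSet(name, span, channel)
}

#' Read a gene model from GFF3 or BED12 annotation
#'
#' Imports exon features of one gene and converts them to the gene-local
#' 0-based half-open axis with the 5' end at 0. Minus-strand genes are
#' reflected so downstream code is strand-free. GFF3 1-based closed
#' coordinates are converted at this boundary.
#'
#' @param path annotation file (GFF3 with exon features, or BED12 with one
#'   record per transcript).
#' @param gene optional gene/transcript identifier to select when the file
#'   holds several.
#' @return A \linkS4class{GeneModel}.
#' @export
readGeneModel <- function(path, gene = NULL) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3") {
    gr <- gr[gr$type == "exon"]
    ids <- as.character(gr$Parent)
    if (!length(gr)) stop("no exon features in ", path)
    if (is.null(gene)) gene <- ids[1]
    gr <- gr[ids == gene]
    span <- range(gr)
    st <- as.character(GenomicRanges::strand(span))[1]
    s0 <- GenomicRanges::start(span) - 1
    e0 <- GenomicRanges::end(span)
    ex <- cbind(GenomicRanges::start(gr) - 1 - s0, GenomicRanges::end(gr) - s0)
  } else {
    if (is.null(gene)) gene <- gr$name[1]
    gr <- gr[gr$name == gene]
    if (!length(gr)) stop("record ", gene, " not found in ", path)
    st <- as.character(GenomicRanges::strand(gr))[1]
    bl <- gr$blocks[[1]]
    e0 <- GenomicRanges::width(gr)
    s0 <- 0
    ex <- cbind(GenomicRanges::start(bl) - 1, GenomicRanges::end(bl))
  }
  len <- e0 - s0
  if (st == "-") ex <- cbind(len - ex[, 2], len - ex[, 1])
  GeneModel(gene, ex[order(ex[, 1]), , drop = FALSE], length = len,
            strand = if (st == "-") "-" else "+")
}
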