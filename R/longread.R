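#' @include AllClasses.R gene-model.R utils.R
#' @importFrom GenomicRanges GRanges start end strand mcols
#' @importFrom IRanges IRanges IRangesList
#' @importFrom S4Vectors mcols<-
NULL

# ---- representation -------------------------------------------------------
# Spliced reads live in a GRanges on the gene-local axis (seqname = gene id,
# 1-based closed, as GRanges requires) with a `blocks` column holding the
# aligned blocks relative to the read start (1-based), exactly the BED12
# representation rtracklayer uses. Gene-local 0-based half-open block
# coordinates are recovered with blockMatrix().

#' Build a spliced-read set from absolute block coordinates
#'
#' @param blocks0 list of 2-column matrices, one per read: aligned blocks in
#'   gene-local 0-based half-open coordinates, sorted, with >= 1 nt gaps.
#' @param gene a \linkS4class{GeneModel} (provides the sequence name).
#' @param ids read identifiers.
#' @return GRanges with BED12-style \code{blocks} and \code{name} columns.
#' @export
makeSplicedReads <- function(blocks0, gene,
                             ids = sprintf("read%05d", seq_along(blocks0))) {
  spans <- vapply(blocks0, function(b) c(min(b[, 1]), max(b[, 2])),
                  numeric(2))
  gr <- GRanges(geneId(gene),
                IRanges(start = spans[1, ] + 1, end = spans[2, ]),
                strand = "+")
  mcols(gr)$name <- ids
  mcols(gr)$blocks <- IRangesList(lapply(seq_along(blocks0), function(i) {
    b <- blocks0[[i]]
    IRanges(start = b[, 1] - spans[1, i] + 1, end = b[, 2] - spans[1, i])
  }))
  gr
}

#' Absolute 0-based half-open blocks of one read
#'
#' @param reads GRanges with a \code{blocks} column.
#' @param i read index.
#' @return 2-column matrix (start, end).
#' @export
blockMatrix <- function(reads, i) {
  b <- mcols(reads)$blocks[[i]]
  off <- start(reads)[i] - 1
  m <- cbind(start = off + start(b) - 1, end = off + end(b))
  if (nrow(m) > 1L && (any(diff(m[, 1]) <= 0) ||
                       any(m[-1L, 1] < m[-nrow(m), 2] + 1)))
    stop("malformed read blocks: must be sorted with >= 1 nt gaps")
  m
}

#' Read or write spliced reads as BED12
#'
#' Thin wrappers around rtracklayer's BED import/export; block structure is
#' preserved.
#'
#' @param reads GRanges with \code{blocks}.
#' @param path BED12 file path.
#' @return \code{readBed12} returns the GRanges.
#' @export
writeBed12 <- function(reads, path) {
  rtracklayer::export(reads, path, format = "bed")
  invisible(path)
}

#' @rdname writeBed12
#' @export
readBed12 <- function(path) rtracklayer::import(path, format = "bed")

# ---- simulation -----------------------------------------------------------

#' Simulate nascent long reads under the splicing-delay model
#'
#' Each read is a nascent transcript truncated at a uniformly random
#' polymerase position. Every fully transcribed intron upstream is removed
#' from the read if and only if the polymerase has passed the intron 3' end
#' plus its delay distance; otherwise the intron is retained. A configurable
#' fraction of reads are contaminating mature mRNAs (all introns spliced,
#' full length).
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param delay a \linkS4class{DelayModel} or numeric delay (kb).
#' @param nReads number of reads (>= 1).
#' @param polyAFraction fraction of mature-mRNA reads.
#' @param seed integer seed.
#' @return list with \code{reads} (GRanges, BED12-style blocks) and
#'   \code{truth}: data.frame (readId, intron, state) of the true per-intron
#'   states (spliced / unspliced / incomplete) for every intron whose
#'   transcription the read's polymerase has started.
#' @examples
#' gm <- makeGeneModel(nExons = 5, seed = 2)
#' sim <- simulateReads(gm, DelayModel(10), nReads = 50, seed = 3)
#' head(sim$truth)
#' @export
simulateReads <- function(gene, delay, nReads, polyAFraction = 0.1,
                          seed = 1) {
  if (nReads < 1) paramError("nReads must be >= 1")
  if (is.numeric(delay)) delay <- DelayModel(delayKb = delay)
  dNt <- delayVector(delay, gene) * 1000
  ib <- intronBounds(gene)
  ex <- exonBounds(gene)
  L <- geneLength(gene)
  withSeed(seed, {
    mature <- runif(nReads) < polyAFraction
    pol <- runif(nReads, 0, L)
    pol[mature] <- L
    blocks <- vector("list", nReads)
    tId <- tIn <- tSt <- vector("list", nReads)
    for (r in seq_len(nReads)) {
      P <- pol[r]
      if (mature[r]) {
        blocks[[r]] <- ex
        st <- rep("spliced", nrow(ib))
        reached <- rep(TRUE, nrow(ib))
      } else {
        reached <- ib[, 1] < P
        st <- rep(NA_character_, nrow(ib))
        st[reached & ib[, 2] >= P] <- "incomplete"   # 3' end inside intron
        done <- reached & ib[, 2] < P
        st[done] <- ifelse(P >= ib[done, 2] + dNt[done],
                           "spliced", "unspliced")
        cuts <- ib[which(st == "spliced"), , drop = FALSE]
        bs <- 0; be <- numeric()
        if (nrow(cuts)) {
          bs <- c(0, cuts[, 2])
          be <- c(cuts[, 1])
        }
        be <- c(be, P)
        keep <- be > bs
        blocks[[r]] <- cbind(bs[keep], be[keep])
      }
      if (any(reached)) {
        w <- which(reached)
        tId[[r]] <- rep.int(r, length(w)); tIn[[r]] <- w; tSt[[r]] <- st[w]
      }
    }
    list(reads = makeSplicedReads(blocks, gene),
         truth = data.frame(readId = unlist(tId), intron = unlist(tIn),
                            state = unlist(tSt)))
  })
}

# ---- classification -------------------------------------------------------

#' Classify intron states within a spliced read
#'
#' For each annotated intron overlapping the read span: \code{spliced} when
#' a read gap matches both intron boundaries within \code{boundaryTol};
#' \code{unspliced} when a read block covers the entire intron contiguously
#' with flanking coverage on both sides; \code{incomplete} when the read's
#' 3' end falls inside the intron (transcription caught in the act);
#' \code{ambiguous} otherwise.
#'
#' @param read 2-column block matrix (0-based half-open) or GRanges row.
#' @param gene a \linkS4class{GeneModel}.
#' @param boundaryTol splice-site matching tolerance, nt.
#' @return data.frame with columns \code{intron}, \code{state}; one row per
#'   intron overlapping the read span.
#' @export
classifyIntrons <- function(read, gene, boundaryTol = 10) {
  b <- if (is.matrix(read)) read else blockMatrix(read, 1)
  cl <- .classifyBlocks(b, intronBounds(gene), boundaryTol)
  data.frame(intron = cl$intron, state = cl$state)
}

# classification core shared by classifyIntrons / classifyReads
.classifyBlocks <- function(b, ib, boundaryTol) {
  if (any(b[, 2] <= b[, 1])) stop("malformed read blocks: empty block")
  s0 <- min(b[, 1]); e0 <- max(b[, 2])
  idx <- which(ib[, 2] > s0 & ib[, 1] < e0)
  if (!length(idx)) return(list(intron = integer(), state = character()))
  nb <- nrow(b)
  gs <- if (nb > 1) b[-nb, 2] else numeric()
  ge <- if (nb > 1) b[-1, 1] else numeric()
  state <- vapply(idx, function(j) {
    is <- ib[j, 1]; ie <- ib[j, 2]
    if (any(abs(gs - is) <= boundaryTol & abs(ge - ie) <= boundaryTol))
      return("spliced")
    if (any(b[, 1] < is & b[, 2] > ie))
      return("unspliced")
    if (e0 > is && e0 <= ie)
      return("incomplete")
    "ambiguous"
  }, "")
  list(intron = idx, state = state)
}

#' Per-intron calls for a whole read set
#'
#' @param reads GRanges with \code{blocks}.
#' @inheritParams classifyIntrons
#' @return data.frame (readId, intron, state).
#' @export
classifyReads <- function(reads, gene, boundaryTol = 10) {
  ib <- intronBounds(gene)
  bl <- mcols(reads)$blocks
  offs <- start(reads) - 1
  bStart <- IRanges::start(bl); bEnd <- IRanges::end(bl)
  rId <- rIn <- rSt <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    b <- cbind(offs[i] + bStart[[i]] - 1, offs[i] + bEnd[[i]])
    cl <- .classifyBlocks(b, ib, boundaryTol)
    if (length(cl$intron)) {
      rId[[i]] <- rep.int(i, length(cl$intron))
      rIn[[i]] <- cl$intron; rSt[[i]] <- cl$state
    }
  }
  data.frame(readId = as.integer(unlist(rId)),
             intron = as.integer(unlist(rIn)),
             state = as.character(unlist(rSt)))
}

#' Select intron-containing reads
#'
#' Keeps reads with at least one retained (unspliced or incomplete) intron
#' call. Reads aligning past the annotated gene 3' end are flagged and, by
#' default, excluded; their count is returned as the
#' \code{"nReadThrough"} attribute.
#'
#' @param reads GRanges with \code{blocks}.
#' @inheritParams classifyIntrons
#' @param excludeReadThrough drop reads extending beyond the gene end.
#' @return the selected GRanges subset.
#' @export
intronContainingReads <- function(reads, gene, boundaryTol = 10,
                                  excludeReadThrough = TRUE) {
  throughs <- end(reads) > geneLength(gene)
  kept <- reads
  if (excludeReadThrough && any(throughs)) kept <- reads[!throughs]
  calls <- classifyReads(kept, gene, boundaryTol)
  sel <- unique(calls$readId[calls$state %in% c("unspliced", "incomplete")])
  out <- kept[sort(sel)]
  attr(out, "nReadThrough") <- sum(throughs)
  out
}

# ---- summaries ------------------------------------------------------------

#' Read-length histogram
#'
#' Histogram of total aligned read lengths (sum of block widths) in fixed
#' bins with origin 0; bins are half-open \code{[k*bin, (k+1)*bin)}.
#'
#' @param reads GRanges with \code{blocks}.
#' @param bin bin width, nt.
#' @return data.frame (binStart, binEnd, count); counts sum to the number
#'   of reads.
#' @export
readLengthHist <- function(reads, bin = 300) {
  if (!length(reads)) paramError("no reads")
  len <- vapply(seq_along(reads), function(i) {
    b <- mcols(reads)$blocks[[i]]
    sum(end(b) - start(b) + 1)
  }, 0)
  k <- floor(len / bin)
  counts <- tabulate(k + 1, max(k) + 1)
  data.frame(binStart = (seq_along(counts) - 1) * bin,
             binEnd = seq_along(counts) * bin, count = counts)
}

#' Introns-per-read histogram
#'
#' Distribution of the number of retained (unspliced or incomplete) introns
#' per intron-containing read.
#'
#' @param calls data.frame from \code{\link{classifyReads}}.
#' @return data.frame (nIntrons, count) for n >= 1.
#' @export
intronsPerReadHist <- function(calls) {
  if (!nrow(calls)) paramError("no calls")
  ret <- calls[calls$state %in% c("unspliced", "incomplete"), ]
  if (!nrow(ret)) return(data.frame(nIntrons = integer(), count = integer()))
  per <- table(ret$readId)
  counts <- tabulate(as.integer(per), max(per))
  data.frame(nIntrons = seq_along(counts), count = counts)
}

#' Per-intron retained-read coverage
#'
#' For each intron, the number of reads carrying it in an unspliced or
#' incomplete state.
#'
#' @param reads GRanges with \code{blocks}.
#' @inheritParams classifyIntrons
#' @return data.frame (intron, start, end, reads).
#' @export
intronCoverage <- function(reads, gene, boundaryTol = 10) {
  if (!length(reads)) paramError("no reads")
  calls <- classifyReads(reads, gene, boundaryTol)
  ib <- intronBounds(gene)
  ret <- calls[calls$state %in% c("unspliced", "incomplete"), ]
  n <- vapply(seq_len(nrow(ib)), function(j) sum(ret$intron == j), 0)
  data.frame(intron = seq_len(nrow(ib)), start = ib[, 1], end = ib[, 2],
             reads = n)
}

#' Estimate per-intron splicing-delay distances from reads
#'
#' For each intron, among reads whose 3' end lies downstream of the intron
#' 3' end, the largest distance (read 3' end minus intron 3' end) at which
#' the intron is still unspliced estimates the delay distance. Introns whose
#' delay window would be clipped by the gene end underestimate the truth;
#' restrict \code{whichIntrons} accordingly.
#'
#' @param reads GRanges with \code{blocks}.
#' @inheritParams classifyIntrons
#' @param whichIntrons intron indices to report (default all).
#' @param calls optional precomputed result of \code{\link{classifyReads}}.
#' @return data.frame (intron, nInformative, delayEstKb).
#' @export
estimateDelay <- function(reads, gene, boundaryTol = 10,
                          whichIntrons = NULL, calls = NULL) {
  if (is.null(calls)) calls <- classifyReads(reads, gene, boundaryTol)
  ib <- intronBounds(gene)
  if (is.null(whichIntrons)) whichIntrons <- seq_len(nrow(ib))
  ends <- end(reads)                             # 1-based closed == 0-based HO end
  res <- lapply(whichIntrons, function(j) {
    cj <- calls[calls$intron == j & calls$state %in%
                  c("unspliced", "spliced"), ]
    d <- ends[cj$readId] - ib[j, 2]
    un <- cj$state == "unspliced" & d > 0
    data.frame(intron = j, nInformative = sum(d > 0),
               delayEstKb = if (any(un)) max(d[un]) / 1000 else 0)
  })
  do.call(rbind, res)
}

#' Transcription time from length and polymerase speed
#'
#' @param lengthKb transcribed length, kb.
#' @param rateKbPerMin polymerase elongation rate, kb/min (default the
#'   commonly assumed average of 3.8).
#' @return time in minutes.
#' @examples
#' transcriptionTime(53.8)   # > 14 min for the long intron
#' @export
transcriptionTime <- function(lengthKb, rateKbPerMin = 3.8) {
  if (rateKbPerMin <= 0) paramError("rate must be positive")
  if (lengthKb < 0) paramError("length must be non-negative")
  lengthKb / rateKbPerMin
}
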