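#' @import methods
#' @importFrom stats quantile median rnorm rpois runif aov sd cor setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' Multi-channel 3D image stack
#'
#' Container for a confocal image stack: a numeric intensity array with
#' dimensions (z, y, x, channel), voxel-size metadata in nanometres and a
#' provenance log. Channel order is arbitrary but named; by convention the
#' DAPI counterstain is the last channel.
#'
#' @slot data numeric 4D array, dim (z, y, x, channel), non-negative.
#' @slot voxelSize named numeric of length 3, voxel edge lengths in nm
#'   (z, y, x).
#' @slot channels character vector of channel names, one per channel.
#' @slot log character vector of processing steps applied so far.
#'
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    data = "array",
    voxelSize = "numeric",
    channels = "character",
    log = "character"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D (z, y, x, channel) array")
  if (any(d[1:3] < 2L) || sum(d[1:3] >= 16L) < 2L)
    return("at least two spatial dimensions must have size >= 16")
  if (length(object@channels) != d[4L])
    return("length(channels) must equal the number of channels")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive values (z, y, x) in nm")
  if (anyNA(object@data) || min(object@data) < 0)
    return("intensities must be non-negative and finite")
  TRUE
})

#' Construct an ImageStack
#'
#' @param data numeric array, dim (z, y, x, channel); a 3D array is treated
#'   as a single channel.
#' @param voxelSize numeric length-3 vector, voxel size in nm (z, y, x).
#' @param channels channel names; defaults to \code{"ch1"}, ...
#' @param log provenance log lines.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' st <- ImageStack(array(0, c(16, 64, 64, 2)), voxelSize = c(300, 60, 60))
#' dim(st)
#' @export
ImageStack <- function(data, voxelSize = c(300, 60, 60), channels = NULL,
                       log = character()) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4L]))
  new("ImageStack", data = data,
      voxelSize = setNames(as.numeric(voxelSize), c("z", "y", "x")),
      channels = as.character(channels), log = log)
}

#' Labelled 3D segmentation volume
#'
#' Integer-labelled volume (0 = background) aligned to one channel of an
#' \linkS4class{ImageStack}, with a per-object voxel-volume table. Objects
#' are 26-connected components.
#'
#' @slot labels integer 3D array (z, y, x); 0 is background.
#' @slot table data.frame with columns \code{label} and \code{voxels}.
#' @slot flags character vector of QC flags raised during segmentation.
#'
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", table = "data.frame", flags = "character")
)

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D (z, y, x) array")
  if (nrow(object@table) > 0 && any(object@table$voxels <= 0))
    return("object volumes must be positive")
  TRUE
})

LabelVolume <- function(labels, flags = character()) {
  labels <- array(as.integer(labels), dim(labels))
  ids <- sort(unique(labels[labels > 0L]))
  tab <- data.frame(label = ids,
                    voxels = if (length(ids)) tabulate(labels, max(ids))[ids]
                             else integer())
  new("LabelVolume", labels = labels, table = tab, flags = flags)
}

#' Gene model in gene-local coordinates
#'
#' Exon/intron structure of a single gene on its own coordinate axis,
#' 0-based half-open, 5' end at 0. Minus-strand annotation is reflected onto
#' this axis at load time, so downstream code never sees strand.
#'
#' @slot geneId character gene identifier.
#' @slot strand \code{"+"} or \code{"-"} (orientation of the source
#'   annotation; coordinates are already 5'->3').
#' @slot exons numeric matrix, columns \code{start}, \code{end}; 0-based
#'   half-open, sorted, non-overlapping.
#' @slot length numeric, gene length in nt.
#'
#' @exportClass GeneModel
setClass("GeneModel",
  representation(geneId = "character", strand = "character",
                 exons = "matrix", length = "numeric")
)

setValidity("GeneModel", function(object) {
  e <- object@exons
  if (ncol(e) != 2L || nrow(e) < 1L)
    return("exons must be a matrix with >= 1 row and columns start, end")
  if (any(e[, 2] <= e[, 1])) return("exons must have end > start")
  if (nrow(e) > 1L && any(e[-1L, 1] < e[-nrow(e), 2]))
    return("exons must be sorted and non-overlapping")
  if (min(e) < 0 || max(e) > object@length)
    return("exon coordinates must lie within [0, length)")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  TRUE
})

GeneModel <- function(geneId, exons, length = max(exons), strand = "+") {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  new("GeneModel", geneId = as.character(geneId), strand = strand,
      exons = exons[order(exons[, 1]), , drop = FALSE],
      length = as.numeric(length))
}

#' Per-intron splicing-delay model
#'
#' Assigns each intron the gene-axis distance (kb, downstream of the intron
#' 3' end) over which nascent transcripts still carry it, plus the
#' transcriptional-bursting category probabilities used when simulating two
#' alleles per nucleus.
#'
#' @slot delayKb numeric vector, one non-negative delay (kb) per intron.
#' @slot burstProbs numeric length-3 probabilities of the allele activity
#'   categories (on_full, on_partial, off); must sum to 1.
#'
#' @exportClass DelayModel
setClass("DelayModel",
  representation(delayKb = "numeric", burstProbs = "numeric")
)

setValidity("DelayModel", function(object) {
  if (any(object@delayKb < 0)) return("delayKb must be non-negative")
  if (length(object@burstProbs) != 3L ||
      abs(sum(object@burstProbs) - 1) > 1e-8 || any(object@burstProbs < 0))
    return("burstProbs must be three non-negative values summing to 1")
  TRUE
})

#' @param delayKb non-negative numeric: per-intron delay in kb. A scalar is
#'   recycled over all introns of the gene it is used with.
#' @param burstProbs probabilities of the (on_full, on_partial, off) allele
#'   burst categories.
#' @rdname DelayModel-class
#' @export
DelayModel <- function(delayKb = 0, burstProbs = c(1, 1, 1) / 3) {
  new("DelayModel", delayKb = as.numeric(delayKb),
      burstProbs = as.numeric(burstProbs))
}

#' Oligoprobe set
#'
#' A set of genomic target intervals on the gene axis detected in one
#' imaging channel.
#'
#' @slot name probe-set name.
#' @slot targets numeric matrix (start, end), 0-based half-open gene
#'   coordinates.
#' @slot channel integer channel index the probe is imaged in.
#'
#' @exportClass ProbeSet
setClass("ProbeSet",
  representation(name = "character", targets = "matrix", channel = "integer")
)

setValidity("ProbeSet", function(object) {
  t <- object@targets
  if (ncol(t) != 2L || nrow(t) < 1L) return("targets must be (start, end) rows")
  if (any(t[, 2] <= t[, 1]) || min(t) < 0)
    return("targets must be non-empty intervals with start >= 0")
  if (object@channel < 1L) return("channel must be >= 1")
  TRUE
})

#' @param name probe-set name.
#' @param targets numeric matrix or length-2 vector of (start, end) gene
#'   coordinates, 0-based half-open.
#' @param channel channel index.
#' @rdname ProbeSet-class
#' @export
ProbeSet <- function(name, targets, channel) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 2L)
  targets <- matrix(as.numeric(targets), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
  new("ProbeSet", name = as.character(name), targets = targets,
      channel = as.integer(channel))
}

#' Imaging-system configuration for the simulator
#'
#' Voxel geometry, point-spread function, noise and per-channel chromatic
#' shift used when rendering synthetic confocal stacks.
#'
#' @slot voxelSize numeric (z, y, x) voxel size, nm.
#' @slot psfSigma numeric (z, y, x) Gaussian PSF sigma, nm.
#' @slot background numeric mean background photon level.
#' @slot photonScale numeric photons per intensity unit for Poisson noise;
#'   0 disables shot noise.
#' @slot readNoiseSd numeric Gaussian read-noise SD; 0 disables.
#' @slot shifts numeric matrix (channel x 3) chromatic shift in voxels
#'   (z, y, x); fractional allowed, magnitudes < 5.
#' @slot shape integer (z, y, x) stack shape.
#'
#' @exportClass OpticsConfig
setClass("OpticsConfig",
  representation(voxelSize = "numeric", psfSigma = "numeric",
                 background = "numeric", photonScale = "numeric",
                 readNoiseSd = "numeric", shifts = "matrix",
                 shape = "integer")
)

setValidity("OpticsConfig", function(object) {
  if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
  if (any(object@shape < c(16L, 64L, 64L)))
    return("stack shape must be at least (16, 64, 64)")
  if (ncol(object@shifts) != 3L) return("shifts must have 3 columns (z, y, x)")
  if (any(abs(object@shifts) >= 5))
    return("chromatic-shift magnitudes must be < 5 voxels")
  TRUE
})

#' @param voxelSize,psfSigma numeric (z, y, x), nm.
#' @param background,photonScale,readNoiseSd noise parameters.
#' @param shifts matrix (channel x 3) of per-channel chromatic shifts in
#'   voxels, or NULL for no shift on \code{nChannels} channels.
#' @param shape integer (z, y, x) stack shape.
#' @param nChannels number of channels when \code{shifts} is NULL.
#' @rdname OpticsConfig-class
#' @export
OpticsConfig <- function(voxelSize = c(300, 60, 60),
                         psfSigma = c(280, 100, 100),
                         background = 2, photonScale = 1, readNoiseSd = 0.5,
                         shifts = NULL, shape = c(24, 96, 96),
                         nChannels = 3) {
  if (is.null(shifts)) shifts <- matrix(0, nChannels, 3)
  shifts <- matrix(as.numeric(shifts), ncol = 3L,
                   dimnames = list(NULL, c("z", "y", "x")))
  new("OpticsConfig",
      voxelSize = setNames(as.numeric(voxelSize), c("z", "y", "x")),
      psfSigma = setNames(as.numeric(psfSigma), c("z", "y", "x")),
      background = background, photonScale = photonScale,
      readNoiseSd = readNoiseSd, shifts = shifts,
      shape = setNames(as.integer(shape), c("z", "y", "x")))
}

#' Overlap-ratio colocalization result
#'
#' Voxel volumes of the segmented intron and BAC FISH objects (both alleles
#' pooled), their overlap, the ratio V_overlap / (V_intron + V_BAC) --
#' bounded above by 0.5 -- and the containment-based QC decision: an image
#' set passes only if at least \code{minContainment} of the intron object
#' lies inside the BAC object.
#'
#' @slot vIntron,vBac,vOverlap voxel counts.
#' @slot ratio overlap ratio (NA when either channel is empty).
#' @slot containment fraction of intron voxels inside the BAC object.
#' @slot qcPass logical QC decision.
#' @slot minContainment QC threshold used.
#'
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(vIntron = "numeric", vBac = "numeric", vOverlap = "numeric",
                 ratio = "numeric", containment = "numeric",
                 qcPass = "logical", minContainment = "numeric")
)

setValidity("OverlapResult", function(object) {
  if (!is.na(object@ratio) &&
      (object@ratio < 0 || object@ratio > 0.5 + 1e-12))
    return("ratio must lie in [0, 0.5]")
  if (object@vOverlap > min(object@vIntron, object@vBac) + 1e-9)
    return("overlap volume cannot exceed either object volume")
  TRUE
})

#' Masked 3D Pearson colocalization result
#'
#' Pixel-wise Pearson correlation coefficient between two smoothed FISH
#' channels inside a signal mask, with the mask size and QC flags. An
#' undefined coefficient (constant channel inside the mask) is NA, never 0.
#'
#' @slot pcc correlation in [-1, 1] or NA.
#' @slot nVoxels number of analysis-mask voxels.
#' @slot qcPass logical; FALSE when pcc is undefined or the mask is smaller
#'   than \code{minVoxels}.
#' @slot flags character QC annotations.
#' @slot minVoxels minimum mask size used for QC.
#'
#' @exportClass PCCResult
setClass("PCCResult",
  representation(pcc = "numeric", nVoxels = "numeric", qcPass = "logical",
                 flags = "character", minVoxels = "numeric")
)

setValidity("PCCResult", function(object) {
  if (!is.na(object@pcc) && abs(object@pcc) > 1 + 1e-12)
    return("pcc must lie in [-1, 1]")
  TRUE
})
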