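#' @include AllClasses.R segmentation.R
NULL

#' Overlap ratio of segmented FISH volumes
#'
#' Computes the overlap statistic V_overlap / (V_intron + V_BAC) over the
#' union of retained objects in each channel (both alleles pooled), plus
#' the containment QC: the image set passes only when at least
#' \code{minContainment} (default 80\%) of the segmented intron volume lies
#' inside the segmented BAC volume. An empty channel yields an undefined
#' ratio and a QC failure.
#'
#' @param intron \linkS4class{LabelVolume} (or logical array) of the intron
#'   channel objects.
#' @param bac \linkS4class{LabelVolume} (or logical array) of the BAC
#'   channel objects.
#' @param minContainment QC threshold on the intron-in-BAC fraction.
#' @return An \linkS4class{OverlapResult}.
#' @examples
#' a <- array(FALSE, c(16, 64, 64)); a[4:8, 10:20, 10:20] <- TRUE
#' overlapRatio(a, a)   # identical masks: ratio 0.5
#' @export
overlapRatio <- function(intron, bac, minContainment = 0.8) {
  mi <- if (is(intron, "LabelVolume")) labelArray(intron) > 0L else intron > 0
  mb <- if (is(bac, "LabelVolume")) labelArray(bac) > 0L else bac > 0
  vi <- sum(mi); vb <- sum(mb); vo <- sum(mi & mb)
  if (vi == 0 || vb == 0)
    return(new("OverlapResult", vIntron = vi, vBac = vb, vOverlap = vo,
               ratio = NA_real_, containment = NA_real_, qcPass = FALSE,
               minContainment = minContainment))
  cont <- vo / vi
  new("OverlapResult", vIntron = vi, vBac = vb, vOverlap = vo,
      ratio = vo / (vi + vb), containment = cont,
      qcPass = cont >= minContainment, minContainment = minContainment)
}

#' Expected overlap from genomic probe lengths
#'
#' The overlap expected in the absence of any splicing delay: the
#' intron-to-BAC genomic length ratio.
#'
#' @param intronKb intron probe target length, kb.
#' @param bacKb BAC probe genomic span, kb.
#' @return fraction \code{intronKb / bacKb}.
#' @examples
#' expectedOverlap(53.8, 153)   # ~0.35
#' expectedOverlap(7, 153)      # ~0.04
#' @export
expectedOverlap <- function(intronKb, bacKb) {
  if (intronKb <= 0 || bacKb <= 0) paramError("lengths must be positive")
  if (intronKb > bacKb) paramError("intron length cannot exceed BAC length")
  intronKb / bacKb
}

#' Analysis mask for pixel-wise colocalization
#'
#' Confines the volume around the FISH signals by summing both channels,
#' thresholding the sum with Otsu's method inside the nuclear mask,
#' removing small artefacts and removing objects that overlap the nuclear
#' border.
#'
#' @param chanA,chanB 3D numeric arrays of the two FISH channels.
#' @param nucleus \linkS4class{LabelVolume} or logical nucleus mask.
#' @param minSize artefact cut-off, voxels.
#' @return logical 3D analysis mask.
#' @export
pccMask <- function(chanA, chanB, nucleus, minSize = 20) {
  nucMask <- if (is(nucleus, "LabelVolume")) labelArray(nucleus) > 0L
             else nucleus > 0
  s <- chanA + chanB
  vals <- s[nucMask]
  t <- tryCatch(otsuThreshold(vals), error = function(e) NULL)
  if (is.null(t)) stop("no signal volume: FISH channels are empty")
  mask <- array(FALSE, dim(s))
  mask[nucMask] <- vals > t
  lab <- filterBySize(label3d(mask), minSize)
  border <- nucMask & !erode3d(nucMask)
  onBorder <- sort(unique(lab[border & lab > 0L]))
  lab[lab %in% onBorder] <- 0L
  if (max(lab) == 0L) stop("no signal volume after mask clean-up")
  lab > 0L
}

#' Masked 3D Pearson correlation of two FISH channels
#'
#' Smooths both channels (Gaussian filter, sigma in voxel units, isotropic
#' in index space), then computes the pixel-wise Pearson correlation
#' coefficient over the analysis-mask voxels. A constant channel inside the
#' mask makes the coefficient undefined: it is reported as NA with a QC
#' failure, never as 0.
#'
#' @param chanA,chanB 3D numeric arrays.
#' @param mask logical analysis mask (e.g. from \code{\link{pccMask}}).
#' @param sigma Gaussian smoothing sigma, voxels.
#' @param minVoxels minimum mask size for QC.
#' @return A \linkS4class{PCCResult}.
#' @export
pcc <- function(chanA, chanB, mask, sigma = 1, minVoxels = 100) {
  if (!any(mask)) paramError("empty analysis mask")
  if (sigma > 0) {
    chanA <- gaussBlur3d(chanA, rep(sigma, 3))
    chanB <- gaussBlur3d(chanB, rep(sigma, 3))
  }
  a <- chanA[mask]; b <- chanB[mask]
  n <- length(a)
  flags <- character()
  if (n < minVoxels) flags <- c(flags, "small_mask")
  if (sd(a) == 0 || sd(b) == 0) {
    return(new("PCCResult", pcc = NA_real_, nVoxels = n, qcPass = FALSE,
               flags = c(flags, "zero_variance"), minVoxels = minVoxels))
  }
  r <- cor(a, b)
  new("PCCResult", pcc = r, nVoxels = n, qcPass = length(flags) == 0L,
      flags = flags, minVoxels = minVoxels)
}
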