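#' @include AllClasses.R utils.R
NULL

#' Otsu threshold
#'
#' Global threshold maximizing the between-class intensity variance of a
#' 256-bin histogram (ties broken toward the lower threshold). Voxels with
#' intensity strictly above the returned value are foreground.
#'
#' @param x numeric array/vector of intensities, or pre-binned counts when
#'   \code{counts = TRUE} (then \code{mids} gives the bin centres).
#' @param nbins number of histogram bins.
#' @param counts interpret \code{x} as histogram counts.
#' @param mids bin centres for \code{counts = TRUE}; defaults to
#'   \code{seq_along(x) - 1}.
#' @return the threshold intensity (upper edge of the last background bin).
#' @examples
#' otsuThreshold(c(rnorm(500, 10, 1), rnorm(500, 200, 5)))
#' @export
otsuThreshold <- function(x, nbins = 256, counts = FALSE, mids = NULL) {
  if (counts) {
    cnt <- as.numeric(x)
    if (is.null(mids)) mids <- seq_along(cnt) - 1
    edges <- c(mids[1] - 0.5, (head(mids, -1) + tail(mids, -1)) / 2,
               mids[length(mids)] + 0.5)
  } else {
    x <- as.numeric(x)
    rng <- range(x)
    if (diff(rng) == 0)
      stop("constant image: no threshold exists")
    edges <- seq(rng[1], rng[2], length.out = nbins + 1)
    cnt <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                         nbins), nbins)
    mids <- (head(edges, -1) + tail(edges, -1)) / 2
  }
  if (sum(cnt > 0) < 2) stop("histogram needs >= 2 non-empty bins")
  w <- cnt / sum(cnt)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  muT <- mu[length(mu)]
  k <- seq_len(length(cnt) - 1L)                 # cut after bin k
  denom <- omega[k] * (1 - omega[k])
  sigmaB <- ifelse(denom > 0, (muT * omega[k] - mu[k])^2 / denom, -Inf)
  best <- which.max(sigmaB)                      # which.max takes first tie
  edges[best + 1L]
}

# Marker-controlled 3D watershed: seeds are plateau patches of near-regional
# maxima of the (smoothed) distance map, seeds closer than `mergeRadius`
# (xy-pixel units, z scaled by the anisotropy) are fused, then the relief is
# flooded downhill from the seeds (26-connected immersion).
.watershedSplit <- function(dist, mask, aniso, seedMinDist = 3,
                            mergeRadius = 25) {
  mx <- maxFilter3d(dist, c(2L, 7L, 7L))
  cand <- mask & dist > seedMinDist & dist >= mx - 0.2
  if (!any(cand)) cand <- mask & dist >= max(dist[mask]) - 1e-9
  seeds <- label3d(cand)
  ns <- max(seeds)
  if (ns > 1L) {
    cents <- t(vapply(seq_len(ns), function(id) {
      idx <- which(seeds == id, arr.ind = TRUE)
      colMeans(idx * rep(c(aniso, 1, 1), each = nrow(idx)))
    }, numeric(3)))
    grp <- seq_len(ns)
    for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
      if (sqrt(sum((cents[i, ] - cents[j, ])^2)) < mergeRadius)
        grp[grp == grp[j]] <- grp[i]
    }
    remap <- match(grp, unique(grp))
    sel <- seeds > 0L
    seeds[sel] <- remap[seeds[sel]]
  }
  array(cpp_watershed_flood(as.numeric(dist), as.integer(seeds),
                            as.logical(mask), dim(mask)), dim(mask))
}

#' Segment the central nucleus from a DAPI channel
#'
#' Binarizes the DAPI signal with Otsu's method, removes small artefacts,
#' separates touching nuclei by watershedding the Gaussian-smoothed 3D
#' Euclidean distance transform, drops objects touching the image borders
#' and retains the single object with the largest volume.
#'
#' @param dapi 3D numeric array, or an \linkS4class{ImageStack} (the
#'   \code{"DAPI"}/last channel is used).
#' @param voxelSize voxel size (z, y, x) in nm; taken from the stack when
#'   one is supplied.
#' @param minSize artefact size cut-off, voxels.
#' @param smoothSigma Gaussian sigma (xy pixels) for the distance map used
#'   to seed the watershed; the z sigma is scaled by voxel anisotropy.
#' @param seedMinDist minimum distance-map height (xy pixels) for a
#'   watershed seed.
#' @param seedMergeRadius seeds closer than this (xy pixels) are fused
#'   before flooding, preventing over-segmentation of one nucleus.
#' @return A \linkS4class{LabelVolume} with exactly one object (label 1).
#' @export
segmentNucleus <- function(dapi, voxelSize = c(300, 60, 60), minSize = 500,
                           smoothSigma = 2, seedMinDist = 3,
                           seedMergeRadius = 25) {
  if (is(dapi, "ImageStack")) {
    voxelSize <- voxelSize(dapi)
    ch <- if ("DAPI" %in% channelNames(dapi)) "DAPI" else dim(dapi)[4]
    dapi <- getChannel(dapi, ch)
  }
  t <- otsuThreshold(dapi)
  mask <- dapi > t
  lab <- filterBySize(label3d(mask), minSize)
  mask <- lab > 0L
  if (!any(mask))
    stop(errorCondition("no nucleus detected",
                        class = c("loopSplice_no_nucleus", "error")))
  # distance map in xy-pixel units: one z step spans `aniso` xy pixels
  aniso <- voxelSize[1] / voxelSize[2]
  dist <- cpp_edt3d(mask, dim(mask), c(aniso, 1, 1))
  dist <- gaussBlur3d(array(dist, dim(mask)),
                      smoothSigma * c(voxelSize[2] / voxelSize[1], 1, 1))
  w <- .watershedSplit(dist, mask, aniso, seedMinDist, seedMergeRadius)
  drop <- borderLabels(w)
  vols <- tabulate(w[w > 0L], max(w))
  keep <- setdiff(which(vols > 0), drop)
  if (!length(keep))
    stop(errorCondition("no nucleus detected (all objects touch the border)",
                        class = c("loopSplice_no_nucleus", "error")))
  winner <- keep[which.max(vols[keep])]
  LabelVolume(array(as.integer(w == winner), dim(mask)))
}

#' Segment FISH signals within the nucleus
#'
#' Restricts analysis to the nucleus mask, confines the volume around each
#' FISH signal by thresholding (Otsu) a local-entropy image of the channel,
#' applies that mask to the original intensities, thresholds again with
#' Otsu's method, removes small artefacts and retains at most the two
#' largest objects (the two alleles).
#'
#' @param channel 3D numeric array of one FISH channel.
#' @param nucleus \linkS4class{LabelVolume} or logical array (nucleus mask).
#' @param voxelSize voxel size (z, y, x), nm.
#' @param entropyRadius radius (xy pixels) of the spherical local-entropy
#'   neighbourhood; the z extent is scaled by voxel anisotropy.
#' @param minSize artefact cut-off, voxels.
#' @param entropyBins quantization levels for the entropy input (min-max
#'   scaled inside the nucleus).
#' @return A \linkS4class{LabelVolume} with 0, 1 or 2 objects ranked by
#'   volume; an empty result carries the flag \code{"empty_channel"}.
#' @export
segmentFish <- function(channel, nucleus, voxelSize = c(300, 60, 60),
                        entropyRadius = 5, minSize = 20, entropyBins = 64) {
  nucMask <- if (is(nucleus, "LabelVolume")) labelArray(nucleus) > 0L
             else nucleus > 0
  if (!any(nucMask)) paramError("empty nucleus mask")
  vals <- channel[nucMask]
  rng <- range(vals)
  if (diff(rng) == 0)
    return(LabelVolume(array(0L, dim(channel)), flags = "empty_channel"))
  # quantization for the entropy image: min-max scaled over the in-nucleus
  # range, but with the bin width floored at ~1.5x the noise level (MAD of
  # the background-dominated in-nucleus intensities) so that flat noisy
  # background keeps a low local entropy however bright the signal is;
  # the whole volume is quantized so border neighbourhoods see ordinary
  # background texture rather than an artificial constant
  noiseW <- stats::mad(vals)
  binW <- max(diff(rng) / entropyBins, 1.5 * noiseW, diff(rng) / 256)
  nb <- max(2L, min(256L, as.integer(ceiling(diff(rng) / binW))))
  q <- array(as.integer(pmin(pmax(floor((channel - rng[1]) /
                                        diff(rng) * nb), 0L), nb - 1L)),
             dim(channel))
  ent <- cpp_entropy3d(q, nucMask, dim(channel),
                       sphericalOffsets(entropyRadius, setNames(
                         as.numeric(voxelSize), c("z", "y", "x"))),
                       nb)
  entVals <- ent[nucMask]
  entMask <- array(FALSE, dim(channel))
  tEnt <- tryCatch(otsuThreshold(entVals), error = function(e) NULL)
  if (is.null(tEnt))
    return(LabelVolume(array(0L, dim(channel)), flags = "empty_channel"))
  entMask[nucMask] <- entVals > tEnt
  inEnt <- channel[entMask]
  tInt <- tryCatch(otsuThreshold(inEnt), error = function(e) NULL)
  if (is.null(tInt) || !any(inEnt > tInt))
    return(LabelVolume(array(0L, dim(channel)), flags = "empty_channel"))
  mask <- entMask & channel > tInt
  lab <- filterBySize(label3d(mask), minSize)
  lab[lab > 2L] <- 0L                           # keep the two biggest volumes
  if (max(lab) == 0L)
    return(LabelVolume(lab, flags = "empty_channel"))
  LabelVolume(lab)
}
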