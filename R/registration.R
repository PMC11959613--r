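#' @include AllClasses.R utils.R
NULL

#' Detect calibration beads in one channel
#'
#' Thresholds the channel (Otsu), labels 26-connected components, discards
#' components touching the stack border and returns intensity-weighted
#' subvoxel centroids of the rest (background level subtracted before
#' weighting).
#'
#' @param stack an \linkS4class{ImageStack} or a 3D array.
#' @param channel channel index or name (ignored for arrays).
#' @param minVoxels minimum component size, voxels.
#' @return numeric matrix (one row per bead) of 1-based fractional (z, y, x)
#'   voxel coordinates; zero rows (with a warning) when nothing is found.
#' @export
detectBeads <- function(stack, channel = 1, minVoxels = 8) {
  vol <- if (is(stack, "ImageStack")) getChannel(stack, channel) else stack
  t <- tryCatch(otsuThreshold(vol), error = function(e) NULL)
  empty <- matrix(numeric(), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
  if (is.null(t)) { warning("no beads found (constant channel)"); return(empty) }
  lab <- filterBySize(label3d(vol > t), minVoxels)
  drop <- borderLabels(lab)
  ids <- setdiff(seq_len(max(lab)), drop)
  if (!length(ids)) { warning("no beads found"); return(empty) }
  bg <- median(vol[lab == 0L])
  cents <- t(vapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    w <- pmax(vol[lab == id] - bg, 0)
    if (sum(w) == 0) w <- rep(1, nrow(idx))
    colSums(idx * w) / sum(w)
  }, numeric(3)))
  colnames(cents) <- c("z", "y", "x")
  cents
}

#' Estimate per-channel chromatic shift from a bead stack
#'
#' Detects bead centroids in every channel, matches each non-reference
#' channel's beads to the reference channel by nearest neighbour (within
#' \code{maxMatchDist} voxels) and reports the componentwise median
#' centroid displacement as the channel's shift, with the residual RMS over
#' matched beads. The reference channel's shift is (0, 0, 0) by definition.
#'
#' @param beadStack an \linkS4class{ImageStack} of a bead calibration field.
#' @param refChannel reference channel index (default 1, conventionally the
#'   FISH channel closest to DAPI in wavelength).
#' @param maxMatchDist nearest-neighbour matching radius, voxels.
#' @return data.frame with one row per channel: \code{channel}, \code{dz},
#'   \code{dy}, \code{dx} (voxels), \code{nBeads}, \code{rms}.
#' @export
estimateShift <- function(beadStack, refChannel = 1, maxMatchDist = 3) {
  nCh <- dim(beadStack)[4]
  ref <- detectBeads(beadStack, refChannel)
  out <- data.frame(channel = seq_len(nCh), dz = 0, dy = 0, dx = 0,
                    nBeads = NA_integer_, rms = NA_real_)
  out$nBeads[refChannel] <- nrow(ref)
  out$rms[refChannel] <- 0
  for (ch in setdiff(seq_len(nCh), refChannel)) {
    cc <- detectBeads(beadStack, ch)
    d2 <- outer(seq_len(nrow(cc)), seq_len(nrow(ref)), function(i, j)
      rowSums((cc[i, , drop = FALSE] - ref[j, , drop = FALSE])^2))
    matches <- which(d2 <= maxMatchDist^2, arr.ind = TRUE)
    # keep one (mutual nearest) partner per bead
    if (length(matches)) {
      ord <- order(d2[matches])
      matches <- matches[ord, , drop = FALSE]
      keep <- !duplicated(matches[, 1]) & !duplicated(matches[, 2])
      matches <- matches[keep, , drop = FALSE]
    }
    if (is.null(dim(matches)) || nrow(matches) < 3)
      stop(sprintf("chromatic-shift estimation failed: <3 matched beads between channels %d and %d",
                   refChannel, ch))
    disp <- cc[matches[, 1], , drop = FALSE] - ref[matches[, 2], , drop = FALSE]
    sh <- apply(disp, 2, median)
    out[ch, c("dz", "dy", "dx")] <- sh
    out$nBeads[ch] <- nrow(disp)
    out$rms[ch] <- sqrt(mean(rowSums(sweep(disp, 2, sh)^2)))
  }
  out
}

#' Apply chromatic-shift correction to a stack
#'
#' Translates every channel by minus its estimated shift using trilinear
#' interpolation; voxels sampled from outside the stack are filled with the
#' channel's background estimate (median intensity). Refuses shifts of 5
#' voxels or more, which indicate bead mismatching rather than chromatic
#' aberration. The applied correction is recorded in the stack log.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param shifts data.frame as returned by \code{\link{estimateShift}}, or
#'   a (channel x 3) matrix of (dz, dy, dx) voxel shifts.
#' @return the corrected \linkS4class{ImageStack}.
#' @export
applyShift <- function(stack, shifts) {
  if (is.data.frame(shifts))
    shifts <- as.matrix(shifts[, c("dz", "dy", "dx")])
  if (any(abs(shifts) >= 5))
    stop("refusing to apply a shift >= 5 voxels (likely bead mismatch)")
  arr <- stack@data
  for (ch in seq_len(dim(arr)[4])) {
    sh <- shifts[ch, ]
    if (all(sh == 0)) next
    bg <- median(arr[, , , ch])
    arr[, , , ch] <- translate3d(arr[, , , ch], -sh, fill = bg)
  }
  initialize(stack, data = arr,
             log = c(stack@log,
                     paste0("chromatic shift corrected: ",
                            paste(apply(round(shifts, 3), 1, paste,
                                        collapse = ","), collapse = " | "))))
}
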