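#' @include AllClasses.R gene-model.R utils.R
NULL

# ---- internal rendering helpers -------------------------------------------

# Cumulative probe-target coverage |targets  [0, x)| for a vector of x.
.covTo <- function(targets, x) {
  out <- numeric(length(x))
  for (i in seq_len(nrow(targets)))
    out <- out + pmax(0, pmin(x, targets[i, 2]) - targets[i, 1])
  out
}

# Visible probe-target content (kb) carried by nascent RNA at a polymerase
# positioned at x: everything transcribed so far minus introns already
# released (polymerase past intron 3' end + delay).
.visibleKb <- function(x, targets, gene, delayNt) {
  ib <- intronBounds(gene)
  vis <- .covTo(targets, x)
  if (nrow(ib)) {
    ovl <- vapply(seq_len(nrow(ib)), function(j)
      .covTo(targets, ib[j, 2])[1] - .covTo(targets, ib[j, 1])[1], 0)
    release <- ib[, 2] + delayNt
    spliced <- outer(x, release, ">=")            # n_x x n_introns
    vis <- vis - as.numeric(spliced %*% ovl)
  }
  vis / 1000
}

# Worm-like-chain polyline of n steps of `stepNm`, started at `origin` (nm),
# persistence length `lp` nm, softly confined to a sphere of radius `rad`
# around origin and to the nucleus ellipsoid (centre `nc`, semi-axes `ax`).
.wlcWalk <- function(n, origin, stepNm, lp, rad, nc, ax) {
  p <- matrix(0, n, 3)
  p[1, ] <- origin
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  eta <- sqrt(stepNm / lp)
  for (k in 2:n) {
    u <- u + eta * rnorm(3)
    u <- u / sqrt(sum(u^2))
    cand <- p[k - 1, ] + stepNm * u
    insideTerr <- sum((cand - origin)^2) <= rad^2
    insideNuc <- sum(((cand - nc) / (0.9 * ax))^2) <= 1
    if (!insideTerr || !insideNuc) {
      pull <- origin - p[k - 1, ]
      u <- pull / sqrt(sum(pull^2)) + 0.5 * rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- p[k - 1, ] + stepNm * u
    }
    p[k, ] <- cand
  }
  p
}

# Deposit point masses (nm coordinates, weights) into a (z, y, x) voxel grid.
.deposit <- function(points, weights, shape, voxelNm) {
  g <- array(0, shape)
  iz <- pmin(pmax(round(points[, 1] / voxelNm[1]) + 1L, 1L), shape[1])
  iy <- pmin(pmax(round(points[, 2] / voxelNm[2]) + 1L, 1L), shape[2])
  ix <- pmin(pmax(round(points[, 3] / voxelNm[3]) + 1L, 1L), shape[3])
  idx <- cbind(iz, iy, ix)
  for (r in seq_len(nrow(idx)))
    g[idx[r, 1], idx[r, 2], idx[r, 3]] <-
      g[idx[r, 1], idx[r, 2], idx[r, 3]] + weights[r]
  g
}

# Filled ellipsoid mask on the voxel grid; centre/semi-axes in nm.
.ellipsoid <- function(shape, voxelNm, centre, semi) {
  z <- ((seq_len(shape[1]) - 1) * voxelNm[1] - centre[1]) / semi[1]
  y <- ((seq_len(shape[2]) - 1) * voxelNm[2] - centre[2]) / semi[2]
  x <- ((seq_len(shape[3]) - 1) * voxelNm[3] - centre[3]) / semi[3]
  outer(outer(z^2, y^2, "+"), x^2, "+") <= 1
}

.addNoise <- function(img, optics) {
  if (optics@photonScale > 0) {
    lam <- pmax(img, 0) * optics@photonScale
    img <- array(rpois(length(lam), lam), dim(img)) / optics@photonScale
  }
  if (optics@readNoiseSd > 0)
    img <- img + array(rnorm(length(img), 0, optics@readNoiseSd), dim(img))
  pmax(img, 0)
}

# ---- public simulators ----------------------------------------------------

#' Simulate transcription-loop RNA-FISH image stacks
#'
#' Renders multi-channel 3D confocal stacks of a single centred nucleus
#' whose two alleles carry the gene extended as a transcription loop. The
#' gene axis is a worm-like-chain polyline; each probe channel receives, at
#' every polymerase position along the axis, intensity proportional to the
#' probe-target content still present in nascent RNA under the per-intron
#' splicing-delay model. Whole-allele amplitudes follow the
#' transcriptional-bursting categories (fully on / partially on / off).
#' DAPI is rendered as the nucleus ellipsoid (last channel); optional
#' neighbour nuclei clipped by the stack border exercise nucleus
#' separation. Per-channel chromatic shift is applied to the noiseless
#' render before Poisson photon noise and Gaussian read noise.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param delay a \linkS4class{DelayModel}.
#' @param probes list of \linkS4class{ProbeSet}; channels must be distinct
#'   and consecutive starting at 1.
#' @param optics an \linkS4class{OpticsConfig}; its shift matrix needs one
#'   row per channel (FISH channels + DAPI).
#' @param nNuclei number of stacks (one nucleus each) to simulate.
#' @param seed integer seed; per-nucleus streams are derived from it.
#' @param nNeighbors number of border-clipped neighbour nuclei per stack
#'   (\code{NULL}: 0-2 at random).
#' @param contourPerKb gene-axis contour length per kb, nm.
#' @param persistenceNm worm-like-chain persistence length, nm.
#' @param brightPerKb photons deposited per kb of visible target per
#'   polymerase vertex.
#' @param nucleusSemiNm nucleus ellipsoid semi-axes (z, y, x), nm.
#' @param dapiLevel DAPI mean intensity inside the nucleus.
#' @param satLevel half-saturation intensity (photons) of the soft
#'   detector/probe saturation applied to the blurred signal; 0 disables.
#' @param territoryRadiusNm confinement radius of each allele's loop
#'   territory, nm; NULL picks ~30\% of the smallest nucleus semi-axis,
#'   reproducing the compact, strongly convoluted loop shape.
#' @return list with \code{stacks} (list of \linkS4class{ImageStack}) and
#'   \code{truth} (list of per-nucleus truth records: noiseless channel
#'   masks \code{masks}, pairwise mask-overlap ratios \code{trueOverlap},
#'   \code{trueRatio} for channels 1 vs 2, burst states and amplitudes,
#'   labelled gene intervals and applied shifts).
#' @examples
#' gm <- makeGeneModel(nExons = 6, seed = 1)
#' pr <- list(probeForIntron(gm, 1, channel = 1), bacProbe(gm, channel = 2))
#' sim <- simulateLoopStack(gm, DelayModel(0), pr,
#'                          OpticsConfig(shape = c(16, 64, 64)), seed = 1)
#' sim$stacks[[1]]
#' @export
simulateLoopStack <- function(gene, delay, probes, optics = OpticsConfig(),
                              nNuclei = 1, seed = 1, nNeighbors = NULL,
                              contourPerKb = 25, persistenceNm = 150,
                              brightPerKb = 2000,
                              nucleusSemiNm = c(2000, 2400, 2400),
                              dapiLevel = 60, satLevel = 100,
                              territoryRadiusNm = NULL) {
  if (length(probes) < 1) paramError("need at least one probe set")
  chans <- vapply(probes, function(p) p@channel, 0L)
  if (anyDuplicated(chans)) paramError("probe channels must be distinct")
  nCh <- max(chans) + 1L                        # + DAPI
  if (nrow(optics@shifts) < nCh)
    optics@shifts <- rbind(optics@shifts,
                           matrix(0, nCh - nrow(optics@shifts), 3))
  shape <- optics@shape
  vox <- optics@voxelSize
  sizeNm <- (shape - 1) * vox
  dNt <- delayVector(delay, gene) * 1000
  L <- geneLength(gene)
  stepNm <- 10
  nVert <- max(16L, ceiling(L / 1000 * contourPerKb / stepNm))
  genePos <- seq(0, L, length.out = nVert)
  # per-channel visible-content profile along the gene (allele-independent)
  visProf <- lapply(probes, function(p)
    .visibleKb(genePos, p@targets, gene, dNt))
  for (i in seq_along(probes))
    if (all(visProf[[i]] <= 0))
      warning("probe '", probes[[i]]@name,
              "' labels no nascent sequence; channel will be empty")
  stacks <- vector("list", nNuclei)
  truths <- vector("list", nNuclei)
  psfVox <- optics@psfSigma / vox
  for (nuc in seq_len(nNuclei)) {
    withSeed(subSeed(seed, nuc), {
      semi <- nucleusSemiNm * runif(3, 0.92, 1.08)
      centre <- sizeNm / 2
      burst <- sample(c("on_full", "on_partial", "off"), 2, replace = TRUE,
                      prob = delay@burstProbs)
      amps <- vapply(burst, function(b)
        switch(b, on_full = 1, on_partial = runif(1, 0.2, 0.6), off = 0), 0)
      # allele territory origins, kept off-centre and apart
      orig <- lapply(1:2, function(a) {
        o <- centre + runif(3, -0.45, 0.45) * semi
        o
      })
      sig <- lapply(seq_len(nCh - 1L), function(i) array(0, shape))
      for (a in 1:2) {
        rad <- if (is.null(territoryRadiusNm)) 0.30 * min(semi) + 150
               else territoryRadiusNm
        pts <- .wlcWalk(nVert, orig[[a]], stepNm, persistenceNm,
                        rad = rad, nc = centre, ax = semi)
        for (i in seq_along(probes)) {
          w <- amps[a] * visProf[[i]] * brightPerKb *
            (stepNm / contourPerKb)              # kb of gene per vertex
          keep <- w > 0
          if (!any(keep)) next
          ch <- probes[[i]]@channel
          sig[[ch]] <- sig[[ch]] +
            .deposit(pts[keep, , drop = FALSE], w[keep], shape, vox)
        }
      }
      for (ch in seq_len(nCh - 1L)) {
        sig[[ch]] <- gaussBlur3d(sig[[ch]], psfVox)
        if (satLevel > 0) {
          # soft detector/hybridization saturation on the blurred signal:
          # compresses the large intensity range that folding of the gene
          # axis produces, the way bright confocal FISH images saturate,
          # without changing the labelled extent that the volume
          # statistics measure
          sig[[ch]] <- sig[[ch]] / (1 + sig[[ch]] / satLevel)
        }
      }
      # truth masks from the noiseless, shift-free render
      masks <- lapply(sig, function(s) {
        m <- max(s)
        if (m <= 0) array(FALSE, shape) else s > 0.1 * m
      })
      ov <- matrix(NA_real_, nCh - 1L, nCh - 1L)
      for (i in seq_len(nCh - 1L)) for (j in seq_len(nCh - 1L)) {
        vi <- sum(masks[[i]]); vj <- sum(masks[[j]])
        ov[i, j] <- if (vi + vj > 0)
          sum(masks[[i]] & masks[[j]]) / (vi + vj) else NA_real_
      }
      # DAPI: nucleus ellipsoid (+ border neighbours), lightly smoothed
      dapi <- .ellipsoid(shape, vox, centre, semi) * dapiLevel
      nNb <- if (is.null(nNeighbors)) sample(0:2, 1) else nNeighbors
      if (nNb > 0) for (k in seq_len(nNb)) {
        side <- sample(2:3, 1)                   # clip at a y or x border
        cn <- centre
        cn[side] <- if (runif(1) < 0.5) -0.7 * semi[side]
                    else sizeNm[side] + 0.7 * semi[side]
        cn[-c(1, side)] <- cn[-c(1, side)] + runif(1, -0.2, 0.2) * sizeNm[2]
        dapi <- pmax(dapi, .ellipsoid(shape, vox, cn, semi * 0.95) * dapiLevel)
      }
      dapi <- gaussBlur3d(dapi, c(0.7, 1.2, 1.2))
      channels <- c(lapply(seq_len(nCh - 1L), function(ch) sig[[ch]]),
                    list(dapi))
      arr <- array(0, c(unname(shape), nCh))
      for (ch in seq_len(nCh)) {
        img <- channels[[ch]]
        sh <- optics@shifts[ch, ]
        if (any(sh != 0)) img <- translate3d(img, sh, fill = 0)
        arr[, , , ch] <- .addNoise(img + optics@background, optics)
      }
      chNames <- c(vapply(seq_len(nCh - 1L), function(ch) {
        i <- which(chans == ch)
        if (length(i)) probes[[i]]@name else paste0("ch", ch)
      }, ""), "DAPI")
      stacks[[nuc]] <- ImageStack(arr, voxelSize = vox, channels = chNames,
                                   log = sprintf("simulated nucleus %d (seed %s)",
                                                 nuc, format(seed)))
      truths[[nuc]] <- list(
        masks = masks, trueOverlap = ov, trueRatio = ov[1, min(2, nCh - 1L)],
        burstStates = burst, alleleAmps = amps,
        labelledIntervals = lapply(probes, function(p) p@targets),
        shifts = optics@shifts, seed = subSeed(seed, nuc))
    })
  }
  list(stacks = stacks, truth = truths)
}

#' Simulate a multicolour bead calibration stack
#'
#' Renders sub-resolution calibration beads (0.5 um spheres, Gaussian
#' approximation) at identical positions in every channel, then translates
#' each channel's noiseless render by its configured chromatic shift before
#' adding noise. Beads are kept at least four bead diameters apart and away
#' from the stack borders.
#'
#' @param nBeads number of beads (>= 3).
#' @param optics an \linkS4class{OpticsConfig}; \code{shifts} rows define
#'   the number of channels and their true shifts.
#' @param seed integer seed.
#' @param beadDiameterNm physical bead diameter, nm.
#' @param beadPhotons total photons per bead per channel.
#' @return list with \code{stack} (an \linkS4class{ImageStack}) and
#'   \code{truth} (bead centre voxel coordinates \code{centresVox}, 1-based
#'   (z, y, x), and the true \code{shifts} matrix).
#' @examples
#' bs <- simulateBeadStack(4, OpticsConfig(shifts = rbind(c(0, 0, 0),
#'                                                        c(1, 2, -1))),
#'                         seed = 1)
#' bs$truth$shifts
#' @export
simulateBeadStack <- function(nBeads = 6, optics = OpticsConfig(), seed = 1,
                              beadDiameterNm = 500, beadPhotons = 3e4) {
  if (nBeads < 3) paramError("need at least 3 beads")
  shape <- optics@shape
  vox <- optics@voxelSize
  sizeNm <- (shape - 1) * vox
  minSep <- 4 * beadDiameterNm
  marginNm <- c(3, 6, 6) * vox                  # keep blobs off the borders
  withSeed(seed, {
    pos <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pos) < nBeads) {
      tries <- tries + 1
      if (tries > 4000)
        stop("too many beads for this volume at the required spacing")
      cand <- runif(3, marginNm, sizeNm - marginNm)
      if (nrow(pos) == 0 ||
          min(sqrt(rowSums((pos - matrix(cand, nrow(pos), 3,
                                         byrow = TRUE))^2))) >= minSep)
        pos <- rbind(pos, cand)
    }
    sigNm <- sqrt(optics@psfSigma^2 + (beadDiameterNm / 2)^2 / 5)
    nCh <- nrow(optics@shifts)
    arr <- array(0, c(unname(shape), nCh))
    zc <- (seq_len(shape[1]) - 1) * vox[1]
    yc <- (seq_len(shape[2]) - 1) * vox[2]
    xc <- (seq_len(shape[3]) - 1) * vox[3]
    peak <- beadPhotons * prod(vox) / ((2 * pi)^1.5 * prod(sigNm))
    for (ch in seq_len(nCh)) {
      img <- array(0, shape)
      shNm <- optics@shifts[ch, ] * vox
      for (b in seq_len(nBeads)) {
        p <- pos[b, ] + shNm
        gz <- exp(-(zc - p[1])^2 / (2 * sigNm[1]^2))
        gy <- exp(-(yc - p[2])^2 / (2 * sigNm[2]^2))
        gx <- exp(-(xc - p[3])^2 / (2 * sigNm[3]^2))
        img <- img + peak * outer(outer(gz, gy), gx)
      }
      arr[, , , ch] <- .addNoise(img + optics@background, optics)
    }
    st <- ImageStack(arr, voxelSize = vox,
                     channels = paste0("beads_ch", seq_len(nCh)),
                     log = sprintf("simulated bead stack (seed %s)",
                                   format(seed)))
    list(stack = st,
         truth = list(centresVox = sweep(pos, 2, vox, "/") + 1,
                      shifts = optics@shifts))
  })
}
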