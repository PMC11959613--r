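#' @useDynLib loopSplice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
# All simulator entry points funnel their randomness through this so that
# (config, seed) -> bit-identical output, independent of surrounding code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic sub-seed derivation (keeps values well inside 32-bit range).
subSeed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629
}

# Separable Gaussian blur of a 3D array, sigma per axis in voxels.
# Edge handling: replicate (index clamping). sigma of 0 skips an axis.
gaussBlur3d <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, d)
    n <- d[ax]
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * switch(ax,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}

# 26-connected component labelling (wrapper around the C kernel).
label3d <- function(mask) {
  lab <- cpp_label3d(as.logical(mask), as.integer(dim(mask)))
  array(lab, dim(mask))
}

# Drop labelled components smaller than minSize voxels; relabel 1..n by
# decreasing volume.
filterBySize <- function(labels, minSize) {
  if (max(labels) == 0L) return(labels)
  vol <- tabulate(labels[labels > 0L], max(labels))
  keep <- which(vol >= minSize)
  keep <- keep[order(vol[keep], decreasing = TRUE)]
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  sel <- labels > 0L
  out[sel] <- remap[labels[sel]]
  out
}

# Labels of components having at least one voxel on the volume border.
borderLabels <- function(labels) {
  d <- dim(labels)
  b <- c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ], labels[, , c(1, d[3])])
  sort(unique(b[b > 0L]))
}

# Separable grey-level maximum filter, box radius r = (rz, ry, rx).
maxFilter3d <- function(a, r) {
  d <- dim(a)
  for (ax in 1:3) {
    if (r[ax] < 1L) next
    n <- d[ax]
    res <- a
    for (off in setdiff(-r[ax]:r[ax], 0L)) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      res <- pmax(res, switch(ax,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE]))
    }
    a <- res
  }
  a
}

# One-voxel 6-neighbour binary erosion (out-of-volume treated as background).
erode3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift1 <- function(m, ax, off) {
    r <- array(FALSE, d)
    n <- d[ax]
    src <- seq_len(n) - off
    ok <- src >= 1L & src <= n
    dst <- which(ok); src <- src[ok]
    switch(ax,
      { r[dst, , ] <- m[src, , ]; r },
      { r[, dst, ] <- m[, src, ]; r },
      { r[, , dst] <- m[, , src]; r })
  }
  for (ax in 1:3) for (off in c(-1L, 1L))
    out <- out & shift1(mask, ax, off)
  out
}

# Voxel offsets of an ellipsoidal neighbourhood with xy radius r (pixels);
# the z radius is r scaled by the voxel anisotropy.
sphericalOffsets <- function(r, voxelSize) {
  rz <- max(0L, floor(r * voxelSize["y"] / voxelSize["z"]))
  g <- expand.grid(dz = -rz:rz, dy = -r:r, dx = -r:r)
  keep <- (g$dz / max(rz, 0.5))^2 + (g$dy / r)^2 + (g$dx / r)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# Subvoxel translation of a 3D volume by `shift` = (dz, dy, dx) voxels
# (content moves by +shift), trilinear, out-of-range filled with `fill`.
translate3d <- function(vol, shift, fill = 0) {
  out <- cpp_shift3d(as.numeric(vol), as.integer(dim(vol)),
                     shift[1], shift[2], shift[3], fill)
  array(out, dim(vol))
}

paramError <- function(msg) {
  stop(errorCondition(msg, class = c("loopSplice_param_error", "error")))
}
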