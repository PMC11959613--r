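#' @include AllClasses.R
NULL

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are stored channel-fastest (page = (z - 1) * nChannels + channel,
#' the ImageJ hyperstack convention) as 32-bit float in [0, 1], with the
#' intensity scale, voxel size and channel names in a JSON sidecar
#' (\code{<path>.json}). \code{readImageStack} restores the stack; when the
#' sidecar is absent, voxel size, channel count and scale must be given.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path TIFF file path.
#' @param voxelSize,channels,scale metadata overrides used when no sidecar
#'   exists; \code{channels} may be a count or a name vector.
#' @return \code{readImageStack} returns an \linkS4class{ImageStack};
#'   \code{writeImageStack} returns \code{path} invisibly.
#' @export
writeImageStack <- function(stack, path) {
  d <- dim(stack@data)
  scale <- max(stack@data, 1e-12)
  pages <- vector("list", d[1] * d[4])
  for (z in seq_len(d[1]))
    for (ch in seq_len(d[4]))
      pages[[(z - 1) * d[4] + ch]] <- stack@data[z, , , ch] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(voxelSize = unname(stack@voxelSize), channels = stack@channels,
         scale = scale, shape = unname(d), log = stack@log),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path, voxelSize = NULL, channels = NULL,
                           scale = 1) {
  meta <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.null(meta)) {
    voxelSize <- meta$voxelSize
    channels <- meta$channels
    scale <- meta$scale
  }
  if (is.null(channels)) channels <- 1L
  nCh <- if (is.character(channels)) length(channels) else as.integer(channels)
  if (length(pages) %% nCh != 0)
    stop("page count is not a multiple of the channel count")
  nz <- length(pages) %/% nCh
  d2 <- dim(pages[[1]])
  arr <- array(0, c(nz, d2[1], d2[2], nCh))
  for (z in seq_len(nz))
    for (ch in seq_len(nCh))
      arr[z, , , ch] <- pages[[(z - 1) * nCh + ch]] * scale
  ImageStack(arr,
             voxelSize = if (is.null(voxelSize)) c(300, 60, 60) else voxelSize,
             channels = if (is.character(channels)) channels else NULL,
             log = if (!is.null(meta)) as.character(meta$log) else character())
}
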