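#' @include AllClasses.R
NULL

#' Accessors for loopSplice classes
#'
#' Small accessor generics: voxel geometry, channel names and data of an
#' \linkS4class{ImageStack}; exon/intron structure of a
#' \linkS4class{GeneModel}; object table of a \linkS4class{LabelVolume};
#' scalar fields of the result classes.
#'
#' @param object,x an object of the documented class.
#' @param channel channel index or name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(object, channel) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("imgData", function(object) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("objectTable", function(object) standardGeneric("objectTable"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("exonBounds", function(object) standardGeneric("exonBounds"))
#' @rdname accessors
#' @export
setGeneric("intronBounds", function(object) standardGeneric("intronBounds"))
#' @rdname accessors
#' @export
setGeneric("geneLength", function(object) standardGeneric("geneLength"))
#' @rdname accessors
#' @export
setGeneric("nIntrons", function(object) standardGeneric("nIntrons"))
#' @rdname accessors
#' @export
setGeneric("delayKb", function(object) standardGeneric("delayKb"))
#' @rdname accessors
#' @export
setGeneric("overlapStats", function(object) standardGeneric("overlapStats"))
#' @rdname accessors
#' @export
setGeneric("qcPass", function(object) standardGeneric("qcPass"))
#' @rdname accessors
#' @export
setGeneric("pccValue", function(object) standardGeneric("pccValue"))

#' @rdname accessors
setMethod("voxelSize", "ImageStack", function(object) object@voxelSize)
#' @rdname accessors
setMethod("channelNames", "ImageStack", function(object) object@channels)
#' @rdname accessors
setMethod("imgData", "ImageStack", function(object) object@data)
#' @rdname accessors
setMethod("provenance", "ImageStack", function(object) object@log)
#' @rdname accessors
setMethod("getChannel", "ImageStack", function(object, channel) {
  if (is.character(channel)) channel <- match(channel, object@channels)
  if (is.na(channel) || channel < 1L || channel > dim(object@data)[4L])
    stop("unknown channel")
  object@data[, , , channel, drop = TRUE]
})

#' @param value replacement value.
#' @rdname accessors
#' @export
setGeneric("setChannel<-", function(object, channel, value)
  standardGeneric("setChannel<-"))
#' @rdname accessors
setMethod("setChannel<-", "ImageStack", function(object, channel, value) {
  if (is.character(channel)) channel <- match(channel, object@channels)
  object@data[, , , channel] <- value
  object
})

#' @rdname accessors
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@data))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack:", d[1], "x", d[2], "x", d[3], "voxels (z, y, x),",
      d[4], "channel(s)\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat("  voxel size (nm):", paste(object@voxelSize, collapse = " x "), "\n")
  if (length(object@log))
    cat("  log:", paste(object@log, collapse = "; "), "\n")
})

#' @rdname accessors
setMethod("labelArray", "LabelVolume", function(object) object@labels)
#' @rdname accessors
setMethod("objectTable", "LabelVolume", function(object) object@table)
#' @rdname accessors
setMethod("nObjects", "LabelVolume", function(object) nrow(object@table))
#' @rdname accessors
setMethod("qcFlags", "LabelVolume", function(object) object@flags)

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume:", paste(dim(object@labels), collapse = " x "),
      "voxels,", nrow(object@table), "object(s)\n")
  if (nrow(object@table)) print(object@table, row.names = FALSE)
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("geneId", "GeneModel", function(object) object@geneId)
#' @rdname accessors
setMethod("exonBounds", "GeneModel", function(object) object@exons)
#' @rdname accessors
setMethod("geneLength", "GeneModel", function(object) object@length)
#' @rdname accessors
setMethod("intronBounds", "GeneModel", function(object) {
  e <- object@exons
  n <- nrow(e)
  if (n < 2L)
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  m <- cbind(start = e[-n, 2], end = e[-1L, 1])
  m[m[, 2] > m[, 1], , drop = FALSE]
})
#' @rdname accessors
setMethod("nIntrons", "GeneModel", function(object) nrow(intronBounds(object)))

setMethod("show", "GeneModel", function(object) {
  ib <- intronBounds(object)
  cat("GeneModel", object@geneId, "(", object@strand, "strand ):",
      object@length, "nt,", nrow(object@exons), "exons,", nrow(ib),
      "introns\n")
  if (nrow(ib))
    cat("  intron lengths (nt):",
        paste(head(ib[, 2] - ib[, 1], 8), collapse = ", "),
        if (nrow(ib) > 8) "...", "\n")
})

#' @rdname accessors
setMethod("delayKb", "DelayModel", function(object) object@delayKb)

setMethod("show", "DelayModel", function(object) {
  cat("DelayModel: delay",
      if (length(unique(object@delayKb)) == 1L)
        paste(object@delayKb[1], "kb (all introns)")
      else paste0("per-intron (", length(object@delayKb), " values)"),
      "| burst probs:", paste(round(object@burstProbs, 3), collapse = "/"),
      "\n")
})

setMethod("show", "ProbeSet", function(object) {
  cat("ProbeSet", object@name, ": channel", object@channel, ",",
      nrow(object@targets), "target interval(s),",
      sum(object@targets[, 2] - object@targets[, 1]) / 1000, "kb total\n")
})

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig: shape", paste(object@shape, collapse = " x "),
      "| voxel (nm)", paste(object@voxelSize, collapse = "/"),
      "| PSF sigma (nm)", paste(object@psfSigma, collapse = "/"), "\n")
  cat("  background", object@background, "| photonScale",
      object@photonScale, "| readNoiseSd", object@readNoiseSd,
      "| max |shift|", max(abs(object@shifts)), "voxels\n")
})

#' @rdname accessors
setMethod("overlapStats", "OverlapResult", function(object) {
  data.frame(vIntron = object@vIntron, vBac = object@vBac,
             vOverlap = object@vOverlap, ratio = object@ratio,
             containment = object@containment, qcPass = object@qcPass)
})
#' @rdname accessors
setMethod("qcPass", "OverlapResult", function(object) object@qcPass)
#' @rdname accessors
setMethod("qcPass", "PCCResult", function(object) object@qcPass)
#' @rdname accessors
setMethod("pccValue", "PCCResult", function(object) object@pcc)
#' @rdname accessors
setMethod("qcFlags", "PCCResult", function(object) object@flags)

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult: ratio",
      if (is.na(object@ratio)) "NA" else round(object@ratio, 4),
      "( V =", object@vOverlap, "/ (", object@vIntron, "+", object@vBac,
      ") ), containment",
      if (is.na(object@containment)) "NA" else round(object@containment, 3),
      "->", if (isTRUE(object@qcPass)) "QC pass" else "QC fail", "\n")
})

setMethod("show", "PCCResult", function(object) {
  cat("PCCResult: PCC",
      if (is.na(object@pcc)) "NA (undefined)" else round(object@pcc, 4),
      "over", object@nVoxels, "voxels ->",
      if (isTRUE(object@qcPass)) "QC pass" else "QC fail", "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
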