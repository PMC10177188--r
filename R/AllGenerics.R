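#' Accessors for cpoct objects
#'
#' Slot access for the package's S4 containers. \code{octData} returns the 4D
#' signal array; \code{deltaZ} and \code{pitchXY} the voxel geometry in mm;
#' \code{channelNames} the channel vocabulary; \code{meanNoise} the per-channel
#' noise floor; \code{muAtt}, \code{muEst} and \code{validMask} the corrected /
#' naive attenuation arrays and validity mask; \code{surfaceMap} the per-A-scan
#' surface index map; \code{mapValues} and \code{mapWindow} the en face values
#' and its depth window; \code{roiTable} the ROI data.frame.
#'
#' @param x a cpoct object.
#' @return The slot value.
#' @name cpoct-accessors
#' @rdname cpoct-accessors
#' @examples
#' a <- array(1, c(4, 3, 3))
#' v <- OCTVolume(list(a, a), deltaZ = 0.005, pitchXY = 0.009375)
#' deltaZ(v); pitchXY(v); channelNames(v)
NULL

#' @rdname cpoct-accessors
#' @export
setGeneric("octData", function(x) standardGeneric("octData"))
#' @rdname cpoct-accessors
#' @export
setGeneric("deltaZ", function(x) standardGeneric("deltaZ"))
#' @rdname cpoct-accessors
#' @export
setGeneric("pitchXY", function(x) standardGeneric("pitchXY"))
#' @rdname cpoct-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname cpoct-accessors
#' @export
setGeneric("meanNoise", function(x) standardGeneric("meanNoise"))
#' @rdname cpoct-accessors
#' @export
setGeneric("muAtt", function(x) standardGeneric("muAtt"))
#' @rdname cpoct-accessors
#' @export
setGeneric("muEst", function(x) standardGeneric("muEst"))
#' @rdname cpoct-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname cpoct-accessors
#' @export
setGeneric("surfaceMap", function(x) standardGeneric("surfaceMap"))
#' @rdname cpoct-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname cpoct-accessors
#' @export
setGeneric("mapWindow", function(x) standardGeneric("mapWindow"))
#' @rdname cpoct-accessors
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname cpoct-accessors
setMethod("octData", "OCTVolume", function(x) x@data)
#' @rdname cpoct-accessors
setMethod("deltaZ", "OCTVolume", function(x) x@deltaZ)
#' @rdname cpoct-accessors
setMethod("pitchXY", "OCTVolume", function(x) x@pitchXY)
#' @rdname cpoct-accessors
setMethod("channelNames", "OCTVolume", function(x) .CHANNELS)
#' @rdname cpoct-accessors
setMethod("meanNoise", "NoiseModel", function(x) x@meanNoise)
#' @rdname cpoct-accessors
setMethod("muAtt", "AttenuationVolume", function(x) x@muAtt)
#' @rdname cpoct-accessors
setMethod("muEst", "AttenuationVolume", function(x) x@muEst)
#' @rdname cpoct-accessors
setMethod("validMask", "AttenuationVolume", function(x) x@valid)
#' @rdname cpoct-accessors
setMethod("surfaceMap", "AttenuationVolume", function(x) x@surface)
#' @rdname cpoct-accessors
setMethod("deltaZ", "AttenuationVolume", function(x) x@deltaZ)
#' @rdname cpoct-accessors
setMethod("pitchXY", "AttenuationVolume", function(x) x@pitchXY)
#' @rdname cpoct-accessors
setMethod("channelNames", "AttenuationVolume", function(x) .CHANNELS)
#' @rdname cpoct-accessors
setMethod("mapValues", "EnFaceMap", function(x) x@values)
#' @rdname cpoct-accessors
setMethod("mapWindow", "EnFaceMap", function(x) x@window)
#' @rdname cpoct-accessors
setMethod("pitchXY", "EnFaceMap", function(x) x@pitchXY)
#' @rdname cpoct-accessors
setMethod("channelNames", "EnFaceMap", function(x) .CHANNELS)
#' @rdname cpoct-accessors
setMethod("roiTable", "ROISet", function(x) x@table)

setMethod("show", "OCTVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("OCTVolume: 2 channels (co, cross), %d x %d x %d (z, x, y)\n",
                d[2], d[3], d[4]))
    cat(sprintf("  deltaZ %.4g mm, pitchXY %.4g mm -> %.3g x %.3g x %.3g mm\n",
                object@deltaZ, object@pitchXY, d[3] * object@pitchXY,
                d[4] * object@pitchXY, d[2] * object@deltaZ))
    if (length(object@meta))
        cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "NoiseModel", function(object) {
    cat(sprintf("NoiseModel: <N> co = %.4g, cross = %.4g (%s, %d voxels)\n",
                object@meanNoise["co"], object@meanNoise["cross"],
                object@region, object@nVoxels))
})

setMethod("show", "AttenuationVolume", function(object) {
    d <- dim(object@muAtt)
    cat(sprintf("AttenuationVolume: %d x %d x %d (z, x, y), 2 channels\n",
                d[2], d[3], d[4]))
    cat(sprintf("  valid voxels: %.1f%%\n", 100 * mean(object@valid)))
})

setMethod("show", "EnFaceMap", function(object) {
    d <- dim(object@values)
    cat(sprintf(
        "EnFaceMap: %d x %d px, window %.3g-%.3g mm below surface\n",
        d[2], d[3], object@window[1], object@window[2]))
    cat(sprintf("  missing pixels: co %.1f%%, cross %.1f%%\n",
                100 * mean(is.na(object@values[1, , ])),
                100 * mean(is.na(object@values[2, , ]))))
})

setMethod("show", "ROISet", function(object) {
    cat(sprintf("ROISet: %d windows (%s)\n", nrow(object@table),
                object@provenance))
    print(table(factor(object@table$class, levels = .CLASS_LABELS)))
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf(
        "ROCResult %s [%s]: AUC %.3f (%.3f; %.3f)\n",
        object@comparison, object@channel, object@auc, object@aucCI[1],
        object@aucCI[2]))
    cat(sprintf(
        "  Pth %s%.3g /mm: Se %.0f%%, Sp %.0f%%, Ac %.0f%% (n=%d/%d)\n",
        if (object@direction == "lower") "<" else ">", object@pth,
        100 * object@se, 100 * object@sp, 100 * object@ac, object@nPos,
        object@nNeg))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: depth %.3g mm (dz %.4g), %d x %d px (pitch %.5g mm)\n",
        object@depthMm, object@deltaZMm, object@lateralPx[1],
        object@lateralPx[2], object@pitchXYMm))
    cat(sprintf("  surface %.3g mm, mu sampling '%s', speckle %s, noise %.3g\n",
                object@surfaceDepthMm, object@muSampling, object@speckle,
                object@noiseFloor))
    cat("  layout:", paste(object@layout$class, collapse = ", "), "\n")
})
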