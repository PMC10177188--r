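#' @import methods
NULL

## channel vocabulary is fixed by the acquisition geometry: the co-polarized
## and cross-polarized detection channels of a CP-OCT interferometer
.CHANNELS <- c("co", "cross")

## five-class breast tissue vocabulary: adipose tissue, non-tumorous fibrous
## connective tissue, hyalinized tumor stroma, low-density tumor cells in
## fibrotic tumor stroma, high-density tumor cell clusters
.CLASS_LABELS <- c("AT", "NCT", "HTS", "LDTC", "HDTC")

#' OCTVolume: a two-channel 3D CP-OCT signal volume
#'
#' Container for linear-scale (never dB) CP-OCT signal indexed
#' \code{[channel, z, x, y]} with channel 1 = "co", channel 2 = "cross".
#' Depth index \code{i} corresponds to depth \code{i * deltaZ(x)} mm, measured
#' downward from the probe; \code{z = 1} is the shallowest pixel.
#'
#' @slot data 4D numeric array \code{(2, nz, nx, ny)} of non-negative
#'   linear-scale signal values.
#' @slot deltaZ axial pixel size, mm.
#' @slot pitchXY lateral pixel size, mm (isotropic in x and y).
#' @slot meta free-form acquisition record (wavelength, date, specimen id...).
#'
#' @name OCTVolume-class
#' @aliases OCTVolume-class
#' @exportClass OCTVolume
setClass("OCTVolume",
    representation(data = "array", deltaZ = "numeric", pitchXY = "numeric",
                   meta = "list"),
    prototype(meta = list()))

setValidity("OCTVolume", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L)
        return("data must be a 4D array (channel, z, x, y)")
    if (d[1] != 2L)
        return("data must have exactly two channels (co, cross)")
    dn <- dimnames(object@data)
    if (is.null(dn) || !identical(dn[[1]], .CHANNELS))
        return("first dimension must be named c(\"co\", \"cross\")")
    if (anyNA(object@data) || min(object@data) < 0)
        return("signal values must be non-negative (linear scale)")
    if (length(object@deltaZ) != 1L || !is.finite(object@deltaZ) ||
        object@deltaZ <= 0)
        return("deltaZ must be a single positive number (mm)")
    if (length(object@pitchXY) != 1L || !is.finite(object@pitchXY) ||
        object@pitchXY <= 0)
        return("pitchXY must be a single positive number (mm)")
    TRUE
})

#' Construct an OCTVolume
#'
#' @param data 4D numeric array \code{(channel, z, x, y)} with 2 channels, or a
#'   list of two 3D arrays \code{(z, x, y)} named or ordered co, cross.
#' @param deltaZ axial pixel size in mm.
#' @param pitchXY lateral pixel size in mm.
#' @param meta optional list of acquisition metadata.
#' @return An \linkS4class{OCTVolume}.
#' @examples
#' a <- array(1, c(4, 3, 3))
#' v <- OCTVolume(list(co = a, cross = a), deltaZ = 0.005, pitchXY = 0.009375)
#' dim(octData(v))
#' @export
OCTVolume <- function(data, deltaZ, pitchXY, meta = list()) {
    if (is.list(data)) {
        stopifnot(length(data) == 2L)
        d3 <- dim(data[[1]])
        if (!identical(d3, dim(data[[2]])))
            stop("both channels must share identical dimensions")
        arr <- array(0, c(2L, d3))
        arr[1L, , , ] <- data[[1]]
        arr[2L, , , ] <- data[[2]]
        data <- arr
    }
    dimnames(data) <- c(list(.CHANNELS), vector("list", 3L))
    new("OCTVolume", data = data, deltaZ = deltaZ, pitchXY = pitchXY,
        meta = meta)
}

#' NoiseModel: per-channel additive noise floor
#'
#' Mean additive noise amplitude of the detection system, estimated from a
#' region declared signal-free (by default, above the tissue surface).
#'
#' @slot meanNoise named numeric of length 2 (co, cross), linear signal units.
#' @slot region description of the estimation region.
#' @slot nVoxels number of voxels the estimate used.
#' @exportClass NoiseModel
setClass("NoiseModel",
    representation(meanNoise = "numeric", region = "character",
                   nVoxels = "integer"),
    prototype(region = "unspecified", nVoxels = 0L))

setValidity("NoiseModel", function(object) {
    if (length(object@meanNoise) != 2L ||
        !identical(names(object@meanNoise), .CHANNELS))
        return("meanNoise must be a named numeric c(co=, cross=)")
    if (any(!is.finite(object@meanNoise)) || any(object@meanNoise < 0))
        return("meanNoise must be finite and >= 0")
    TRUE
})

#' Construct a NoiseModel
#' @param co,cross mean noise amplitude per channel (linear units).
#' @param region text describing where the noise was measured.
#' @param nVoxels voxel count of the estimation region.
#' @return A \linkS4class{NoiseModel}.
#' @export
NoiseModel <- function(co, cross = co, region = "user-supplied",
                       nVoxels = 0L) {
    new("NoiseModel", meanNoise = c(co = co, cross = cross), region = region,
        nVoxels = as.integer(nVoxels))
}

#' AttenuationVolume: per-voxel attenuation estimates
#'
#' Output of the depth-resolved estimator: the naive estimate, the
#' noise-compensation terms and the corrected attenuation coefficient, all
#' co-registered with the input volume. Voxels above the detected surface, at
#' the last axial pixel, or where noise dominates (bias factor H <= 0) are
#' masked invalid (NA in \code{muAtt}).
#'
#' @slot muAtt corrected attenuation per voxel per channel, 1/mm.
#' @slot muEst naive (noise-uncorrected) estimate, 1/mm; not masked.
#' @slot H multiplicative bias factor in (0, 1]; 0-length when diagnostics
#'   were dropped.
#' @slot nMu additive mu-domain noise term, 1/mm; 0-length when dropped.
#' @slot snrMu local signal-to-noise ratio; 0-length when dropped.
#' @slot valid logical mask of estimable voxels.
#' @slot surface per-A-scan surface index map (nx by ny).
#' @slot deltaZ,pitchXY voxel geometry, mm.
#' @exportClass AttenuationVolume
setClass("AttenuationVolume",
    representation(muAtt = "array", muEst = "array", H = "array",
                   nMu = "array", snrMu = "array", valid = "array",
                   surface = "matrix", deltaZ = "numeric",
                   pitchXY = "numeric"))

#' EnFaceMap: depth-averaged 2D attenuation map
#'
#' Per lateral pixel, the mean of valid corrected attenuation values over a
#' fixed depth window below the detected tissue surface. Pixels with no valid
#' contributing voxel are NA.
#'
#' @slot values numeric array \code{(2, nx, ny)}, 1/mm; NA = missing.
#' @slot window depth window (min, max) below the surface, mm.
#' @slot pitchXY lateral pixel size, mm.
#' @slot scaleRange fixed colour-scale bounds for rendering, 1/mm.
#' @exportClass EnFaceMap
setClass("EnFaceMap",
    representation(values = "array", window = "numeric", pitchXY = "numeric",
                   scaleRange = "numeric"),
    prototype(window = c(0.105, 0.630), scaleRange = c(0, 7)))

setValidity("EnFaceMap", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[1] != 2L)
        return("values must be a (2, nx, ny) array")
    if (length(object@window) != 2L || diff(object@window) <= 0)
        return("window must be (zmin, zmax) with zmax > zmin")
    TRUE
})

#' ROISet: labelled analysis windows on an en face map
#'
#' Rectangular regions of interest, one row per window, with 0-based lateral
#' pixel origins and half-open pixel ranges \code{[x0, x0 + width)}.
#'
#' @slot table data.frame with columns roi_id, class, x0, y0, width, height.
#' @slot provenance "manual" or "generated".
#' @exportClass ROISet
setClass("ROISet",
    representation(table = "data.frame", provenance = "character"),
    prototype(provenance = "generated"))

setValidity("ROISet", function(object) {
    tb <- object@table
    need <- c("roi_id", "class", "x0", "y0", "width", "height")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    bad <- setdiff(unique(tb$class), .CLASS_LABELS)
    if (length(bad))
        return(sprintf("unknown class label(s) %s; allowed: %s",
                       paste(bad, collapse = ", "),
                       paste(.CLASS_LABELS, collapse = ", ")))
    if (anyDuplicated(tb$roi_id))
        return("roi_id values must be unique")
    if (any(tb$width <= 0) || any(tb$height <= 0) || any(tb$x0 < 0) ||
        any(tb$y0 < 0))
        return("windows must have positive size and non-negative origin")
    TRUE
})

#' Construct an ROISet
#' @param table data.frame with columns roi_id, class, x0, y0, width, height
#'   (0-based origins, half-open ranges).
#' @param provenance "manual" or "generated".
#' @return An \linkS4class{ROISet}.
#' @export
ROISet <- function(table, provenance = "generated") {
    table$roi_id <- as.character(table$roi_id)
    new("ROISet", table = table, provenance = provenance)
}

#' PhantomSpec: synthetic CP-OCT phantom specification
#'
#' Describes a two-channel phantom with a flat tissue surface, lateral class
#' regions, exponential depth decay of the mean signal, optional fully
#' developed speckle (unit-mean exponential, multiplicative on intensity) and
#' an additive exponential noise floor. Per-region attenuation varies on a
#' lateral patch grid, sampled from the calibrated class distributions with a
#' deviate shared between channels (comonotone coupling).
#'
#' @slot depthMm total imaging depth, mm.
#' @slot deltaZMm axial pixel size, mm.
#' @slot lateralPx integer (nx, ny).
#' @slot pitchXYMm lateral pixel size, mm.
#' @slot surfaceDepthMm depth of the flat tissue surface, mm.
#' @slot layout data.frame (class, x0, y0, width, height), 0-based lateral
#'   rectangles; must not overlap.
#' @slot muSampling "patch" (attenuation sampled per lateral patch) or "none"
#'   (class medians everywhere).
#' @slot patchPx lateral patch size in pixels for "patch" sampling.
#' @slot speckle logical; add fully developed speckle.
#' @slot noiseFloor mean additive noise as a fraction of the brightest class's
#'   mean surface signal.
#' @slot classTable calibrated class table (see \code{\link{defaultClassTable}}).
#' @slot seed integer RNG seed; identical seed implies a bit-identical phantom.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(depthMm = "numeric", deltaZMm = "numeric",
                   lateralPx = "integer", pitchXYMm = "numeric",
                   surfaceDepthMm = "numeric", layout = "data.frame",
                   muSampling = "character", patchPx = "integer",
                   speckle = "logical", noiseFloor = "numeric",
                   classTable = "data.frame", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (object@depthMm <= object@surfaceDepthMm)
        return("depthMm must exceed surfaceDepthMm")
    if (object@deltaZMm <= 0 || object@pitchXYMm <= 0)
        return("pixel sizes must be positive")
    lay <- object@layout
    ct <- object@classTable
    if (!all(lay$class %in% ct$label))
        return("layout classes must appear in the class table")
    nx <- object@lateralPx[1]; ny <- object@lateralPx[2]
    if (any(lay$x0 < 0) || any(lay$y0 < 0) ||
        any(lay$x0 + lay$width > nx) || any(lay$y0 + lay$height > ny))
        return("layout rectangles must lie inside the lateral grid")
    if (nrow(lay) > 1L) {
        for (i in seq_len(nrow(lay) - 1L)) for (j in (i + 1L):nrow(lay)) {
            if (lay$x0[i] < lay$x0[j] + lay$width[j] &&
                lay$x0[j] < lay$x0[i] + lay$width[i] &&
                lay$y0[i] < lay$y0[j] + lay$height[j] &&
                lay$y0[j] < lay$y0[i] + lay$height[i])
                return(sprintf("layout rectangles %d and %d overlap", i, j))
        }
    }
    ## tail-truncation bias bound: the slowest-decaying class must have
    ## essentially no signal left at the bottom of the phantom
    idx <- match(unique(lay$class), ct$label)
    muMin <- min(ct$mu_co_median[idx], ct$mu_cross_median[idx])
    if (exp(-2 * muMin * (object@depthMm - object@surfaceDepthMm)) >= 0.02)
        return(sprintf(
            "phantom too shallow: exp(-2*%.2f*(depth-surface)) >= 0.02",
            muMin))
    TRUE
})

#' ROCResult: one class-pair discrimination result
#'
#' @slot comparison label "positive vs negative".
#' @slot channel "co" or "cross".
#' @slot direction "lower" or "higher": side on which the positive class lies.
#' @slot auc area under the ROC curve (ties counted 1/2).
#' @slot aucCI 95\% CI for the AUC (stratified bootstrap).
#' @slot pth optimal cutoff (Youden), 1/mm.
#' @slot se,sp,ac sensitivity, specificity, accuracy at pth.
#' @slot seCI,spCI,acCI Wilson 95\% CIs.
#' @slot nPos,nNeg class sizes.
#' @slot curve data.frame (threshold, fpr, tpr).
#' @exportClass ROCResult
setClass("ROCResult",
    representation(comparison = "character", channel = "character",
                   direction = "character", auc = "numeric",
                   aucCI = "numeric", pth = "numeric", se = "numeric",
                   sp = "numeric", ac = "numeric", seCI = "numeric",
                   spCI = "numeric", acCI = "numeric", nPos = "integer",
                   nNeg = "integer", curve = "data.frame"))
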