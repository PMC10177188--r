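#' Write a CP-OCT volume to disk
#'
#' Two container formats share one JSON sidecar holding the geometry:
#' \describe{
#'   \item{"raw"}{(default) one little-endian float64 stack per channel
#'     (\code{co.bin}, \code{cross.bin}, z fastest-varying plane order).
#'     Round-trips are the bit-exact identity for any data.}
#'   \item{"tiff"}{one multi-page 32-bit TIFF per channel (z-pages),
#'     normalised by a per-channel power of two recorded in the sidecar.
#'     Inspectable by any imaging tool, but TIFF samples are fixed-point
#'     integers, so small values carry about 2^-32 absolute (not relative)
#'     quantisation on the normalised scale.}
#' }
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param path directory to create/overwrite.
#' @param format "raw" or "tiff".
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readVolume}}
#' @export
writeVolume <- function(vol, path, format = c("raw", "tiff")) {
    stopifnot(is(vol, "OCTVolume"))
    format <- match.arg(format)
    validObject(vol)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path))
    scl <- list(co = 0L, cross = 0L)
    for (ch in 1:2) {
        a <- vol@data[ch, , , ]
        if (format == "raw") {
            con <- file(file.path(path, paste0(.CHANNELS[ch], ".bin")), "wb")
            writeBin(as.vector(a), con, size = 8L, endian = "little")
            close(con)
        } else {
            mx <- max(a)
            k <- if (mx <= 1) 0L else as.integer(ceiling(log2(mx)))
            scl[[ch]] <- k
            pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 2^k)
            tiff::writeTIFF(pages,
                            file.path(path, paste0(.CHANNELS[ch], ".tif")),
                            bits.per.sample = 32L, compression = "none")
        }
    }
    side <- list(delta_z_mm = vol@deltaZ, pitch_xy_mm = vol@pitchXY,
                 channels = as.list(.CHANNELS), format = format,
                 dim = dim(vol@data)[2:4], scale_log2 = scl,
                 meta = vol@meta)
    .jsonWrite(side, file.path(path, "volume.json"))
    invisible(path)
}

#' Read a CP-OCT volume from disk
#'
#' Reads either container written by \code{\link{writeVolume}} (raw-binary or
#' multi-page TIFF stacks, as declared in the sidecar). Geometry is taken
#' from the sidecar and is never guessed; a missing sidecar is a hard error,
#' as are a channel shape mismatch or negative signal values (reported with
#' the offending channel and z-plane).
#'
#' @param path directory containing the two channel stacks and
#'   \code{volume.json}.
#' @return An \linkS4class{OCTVolume}.
#' @export
readVolume <- function(path) {
    side <- file.path(path, "volume.json")
    .stopIfMissing(side, "JSON sidecar (geometry must not be guessed)")
    meta <- jsonlite::read_json(side)
    if (is.null(meta$delta_z_mm) || is.null(meta$pitch_xy_mm))
        stop("sidecar lacks delta_z_mm / pitch_xy_mm geometry")
    format <- if (is.null(meta$format)) "tiff" else meta$format
    chans <- vector("list", 2)
    for (ch in 1:2) {
        if (format == "raw") {
            f <- file.path(path, paste0(.CHANNELS[ch], ".bin"))
            .stopIfMissing(f, sprintf("%s-channel stack", .CHANNELS[ch]))
            d <- as.integer(unlist(meta$dim))
            n <- file.size(f) / 8
            con <- file(f, "rb")
            v <- readBin(con, "double", n = n, size = 8L, endian = "little")
            close(con)
            if (length(v) != prod(d))
                stop(sprintf(
                    "channel shape mismatch: '%s' holds %d voxels, sidecar dim %s",
                    .CHANNELS[ch], length(v), paste(d, collapse = "x")))
            a <- array(v, d)
        } else {
            f <- file.path(path, paste0(.CHANNELS[ch], ".tif"))
            .stopIfMissing(f, sprintf("%s-channel TIFF stack", .CHANNELS[ch]))
            pages <- tiff::readTIFF(f, all = TRUE, as.is = FALSE)
            if (!is.list(pages)) pages <- list(pages)
            k <- meta$scale_log2[[.CHANNELS[ch]]]
            if (is.null(k)) k <- 0
            a <- array(0, c(length(pages), dim(pages[[1]])))
            for (i in seq_along(pages)) a[i, , ] <- pages[[i]] * 2^k
        }
        bad <- which(apply(a < 0, 1, any))
        if (length(bad))
            stop(sprintf("negative signal values in channel '%s', z-plane %d",
                         .CHANNELS[ch], bad[1]))
        chans[[ch]] <- a
    }
    if (!identical(dim(chans[[1]]), dim(chans[[2]])))
        stop(sprintf(
            "channel shape mismatch: co %s vs cross %s",
            paste(dim(chans[[1]]), collapse = "x"),
            paste(dim(chans[[2]]), collapse = "x")))
    OCTVolume(chans, deltaZ = meta$delta_z_mm, pitchXY = meta$pitch_xy_mm,
              meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Write an ROI set as CSV
#'
#' Plain comma-separated text with header
#' \code{roi_id,class,x0,y0,width,height} and a leading \code{#} comment line
#' carrying the provenance note.
#'
#' @param rs an \linkS4class{ROISet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeROISet <- function(rs, path) {
    stopifnot(is(rs, "ROISet"))
    validObject(rs)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# provenance: %s", rs@provenance), con)
    utils::write.csv(rs@table[, c("roi_id", "class", "x0", "y0", "width",
                                  "height")],
                     con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an ROI set from CSV
#'
#' @param path CSV file with header \code{roi_id,class,x0,y0,width,height};
#'   lines starting with \code{#} are treated as comments (provenance).
#' @return An \linkS4class{ROISet}. Unknown class labels or duplicated
#'   \code{roi_id}s are hard errors; window-vs-map bounds are checked later,
#'   at use against a concrete map.
#' @export
readROISet <- function(path) {
    .stopIfMissing(path, "ROI table")
    first <- readLines(path, n = 1L)
    prov <- if (startsWith(first, "# provenance:"))
        trimws(sub("^# provenance:", "", first)) else "manual"
    tb <- utils::read.csv(path, comment.char = "#",
                          colClasses = c(roi_id = "character",
                                         class = "character"))
    ROISet(tb, provenance = prov)
}
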