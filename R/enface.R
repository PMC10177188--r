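#' Detect the tissue surface in each A-scan
#'
#' The surface is the first axial index at which the 3x3x3-smoothed co-channel
#' signal exceeds \code{k * <N>}, followed by 5x5 lateral median filtering.
#' A-scans that never exceed the threshold are marked missing (NA). A
#' contact-probe "flat" override is available via \code{flat}.
#'
#' @param vol an \linkS4class{OCTVolume}.
#' @param noise a \linkS4class{NoiseModel}; NULL bootstraps \code{<N>} from
#'   the top \code{bootstrapPx} z-planes (assumed to be probe standoff).
#' @param k threshold multiple of the noise floor.
#' @param medianPx lateral median-filter size (odd; 1 disables).
#' @param channel channel used for detection (co is brightest in all classes).
#' @param flat integer; return a constant surface at this index.
#' @param bootstrapPx planes used for the bootstrap noise estimate.
#' @return integer matrix (nx by ny) of surface indices, NA where missing.
#' @export
detectSurface <- function(vol, noise = NULL, k = 4, medianPx = 5L,
                          channel = "co", flat = NULL, bootstrapPx = 10L) {
    stopifnot(is(vol, "OCTVolume"))
    d <- dim(vol@data)
    if (!is.null(flat))
        return(matrix(as.integer(flat), d[3], d[4]))
    if (is.null(noise)) {
        zb <- seq_len(min(bootstrapPx, d[2]))
        noise <- NoiseModel(mean(vol@data[1, zb, , ]),
                            mean(vol@data[2, zb, , ]),
                            region = sprintf("top %d planes (bootstrap)",
                                             length(zb)))
    }
    ch <- match(match.arg(channel, .CHANNELS), .CHANNELS)
    thr <- k * noise@meanNoise[[ch]]
    sm <- .box27(vol@data[ch, , , ])
    L <- d[3] * d[4]
    M <- matrix(sm, d[2], L)
    hit <- M > thr
    any <- colSums(hit) > 0L
    first <- rep(NA_real_, L)
    first[any] <- apply(hit[, any, drop = FALSE], 2, which.max)
    surf <- matrix(first, d[3], d[4])
    if (medianPx > 1L) surf <- .medianFilter2D(surf, medianPx)
    matrix(as.integer(round(surf)), d[3], d[4])
}

#' Average corrected attenuation into an en face map
#'
#' Per lateral pixel, the mean of valid (unmasked) corrected attenuation
#' voxels over the depth window \code{[surface + zmin, surface + zmax)}
#' below the per-A-scan surface. The default window 0.105-0.630 mm spans
#' axial offsets 21..125 inclusive at 5 um pixels. Pixels with no valid voxel
#' (including missing surface) are NA.
#'
#' @param attvol an \linkS4class{AttenuationVolume}.
#' @param surface optional surface override (matrix or single index);
#'   defaults to the map stored in \code{attvol}.
#' @param window depth window (zmin, zmax) below the surface, mm.
#' @param scaleRange fixed colour-scale bounds carried for rendering, 1/mm.
#' @return An \linkS4class{EnFaceMap}.
#' @export
enfaceAverage <- function(attvol, surface = NULL, window = c(0.105, 0.630),
                          scaleRange = c(0, 7)) {
    stopifnot(is(attvol, "AttenuationVolume"))
    d <- dim(attvol@muAtt)
    nz <- d[2]; nx <- d[3]; ny <- d[4]; L <- nx * ny
    if (is.null(surface)) surface <- attvol@surface
    if (length(surface) == 1L) surface <- matrix(as.integer(surface), nx, ny)
    dz <- attvol@deltaZ
    offs <- round(window[1] / dz):(round(window[2] / dz) - 1L)
    sVec <- as.integer(as.vector(surface))
    if (all(is.na(sVec)))
        stop("surface map is entirely missing; cannot build an en face map")
    if (min(sVec, na.rm = TRUE) + offs[1] > nz)
        stop("depth window lies entirely below the volume bottom")
    vals <- array(NA_real_, c(2L, nx, ny))
    cols <- seq_len(L)
    for (ch in 1:2) {
        mu <- matrix(attvol@muAtt[ch, , , ], nz, L)
        acc <- numeric(L)
        cnt <- integer(L)
        for (o in offs) {
            zi <- sVec + o
            okc <- !is.na(zi) & zi >= 1L & zi <= nz
            v <- mu[cbind(zi[okc], cols[okc])]
            okv <- !is.na(v)
            w <- which(okc)[okv]
            acc[w] <- acc[w] + v[okv]
            cnt[w] <- cnt[w] + 1L
        }
        out <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
        vals[ch, , ] <- matrix(out, nx, ny)
    }
    new("EnFaceMap", values = vals, window = window, pitchXY = attvol@pitchXY,
        scaleRange = scaleRange)
}

## fixed absolute colour convention: <2 blue, 2-3 cyan, 4-5 yellow, >6 red
.ATTEN_ANCHORS <- c(0, 1, 2.5, 4.5, 6, 7)
.ATTEN_COLORS <- c("#00008B", "#0000FF", "#00FFFF", "#FFFF00", "#FF0000",
                   "#8B0000")

## map attenuation values to an n x 3 RGB matrix in [0,1] by piecewise-linear
## interpolation through the anchor colours; NA -> black
.attenRGB <- function(v, range = c(0, 7)) {
    x <- pmin(pmax(v, range[1]), range[2])
    cols <- t(grDevices::col2rgb(.ATTEN_COLORS)) / 255
    out <- matrix(0, length(v), 3)
    for (b in 1:3)
        out[, b] <- stats::approx(.ATTEN_ANCHORS, cols[, b], xout = x,
                                  rule = 2)$y
    out[is.na(v), ] <- 0
    out
}

#' Render an en face attenuation map as a PNG
#'
#' Deterministic rasterisation (no graphics device): values are mapped over a
#' fixed absolute scale (default 0-7 1/mm) through a blue-cyan-yellow-red
#' ramp, missing pixels are black, and a vertical colour bar is appended on
#' the right. Re-rendering identical input yields byte-identical files.
#'
#' @param map an \linkS4class{EnFaceMap}.
#' @param path output PNG file.
#' @param channel "co" or "cross".
#' @param barPx colour-bar width in pixels (0 disables).
#' @return Invisibly, \code{path}.
#' @export
renderMap <- function(map, path, channel = c("cross", "co"), barPx = 12L) {
    stopifnot(is(map, "EnFaceMap"))
    channel <- match.arg(channel)
    ch <- match(channel, .CHANNELS)
    nx <- dim(map@values)[2]; ny <- dim(map@values)[3]
    v <- matrix(map@values[ch, , ], nx, ny)
    rgb <- .attenRGB(as.vector(v), map@scaleRange)
    ## image rows = y (top = y max side kept simple: row 1 = y = 1)
    img <- array(0, c(ny, nx, 3))
    for (b in 1:3) img[, , b] <- t(matrix(rgb[, b], nx, ny))
    if (barPx > 0L) {
        barVals <- seq(map@scaleRange[2], map@scaleRange[1], length.out = ny)
        barRGB <- .attenRGB(barVals, map@scaleRange)
        bar <- array(0, c(ny, barPx, 3))
        for (b in 1:3) bar[, , b] <- matrix(barRGB[, b], ny, barPx)
        gap <- array(1, c(ny, 2L, 3))   # white separator
        out <- array(0, c(ny, nx + 2L + barPx, 3))
        out[, seq_len(nx), ] <- img
        out[, nx + 1:2, ] <- gap
        out[, nx + 2L + seq_len(barPx), ] <- bar
        img <- out
    }
    png::writePNG(img, path)
    invisible(path)
}

#' Stitch en face maps on an offset grid
#'
#' Places each tile at the given lateral pixel offset (no registration) and
#' averages overlapping pixels; the output bounding box covers all tiles.
#' Tiles must share pixel pitch and depth window.
#'
#' @param maps list of \linkS4class{EnFaceMap}.
#' @param offsets list (or 2-column matrix) of (dx, dy) pixel offsets, one
#'   per tile, 0-based.
#' @return An \linkS4class{EnFaceMap} covering the union of the tiles.
#' @export
stitchMaps <- function(maps, offsets) {
    stopifnot(length(maps) >= 1L)
    if (is.matrix(offsets))
        offsets <- lapply(seq_len(nrow(offsets)), function(i) offsets[i, ])
    stopifnot(length(offsets) == length(maps))
    p0 <- maps[[1]]@pitchXY; w0 <- maps[[1]]@window
    for (m in maps) {
        if (!isTRUE(all.equal(m@pitchXY, p0)) ||
            !isTRUE(all.equal(m@window, w0)))
            stop("tiles must share pixel pitch and depth window")
    }
    dxs <- vapply(offsets, `[`, numeric(1), 1L)
    dys <- vapply(offsets, `[`, numeric(1), 2L)
    nxs <- vapply(maps, function(m) dim(m@values)[2], integer(1))
    nys <- vapply(maps, function(m) dim(m@values)[3], integer(1))
    NX <- as.integer(max(dxs + nxs) - min(dxs))
    NY <- as.integer(max(dys + nys) - min(dys))
    ox <- as.integer(dxs - min(dxs)); oy <- as.integer(dys - min(dys))
    vals <- array(NA_real_, c(2L, NX, NY))
    for (ch in 1:2) {
        acc <- matrix(0, NX, NY); cnt <- matrix(0L, NX, NY)
        for (i in seq_along(maps)) {
            v <- maps[[i]]@values[ch, , ]
            xi <- ox[i] + seq_len(nxs[i]); yi <- oy[i] + seq_len(nys[i])
            ok <- !is.na(v)
            sub <- acc[xi, yi]; sub[ok] <- sub[ok] + v[ok]
            acc[xi, yi] <- sub
            subc <- cnt[xi, yi]; subc[ok] <- subc[ok] + 1L
            cnt[xi, yi] <- subc
        }
        out <- acc / cnt
        out[cnt == 0L] <- NA_real_
        vals[ch, , ] <- out
    }
    new("EnFaceMap", values = vals, window = w0, pitchXY = p0,
        scaleRange = maps[[1]]@scaleRange)
}
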