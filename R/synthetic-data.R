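#' Calibrated five-class breast-tissue attenuation table
#'
#' Median and quartile attenuation coefficients (1/mm) of the five breast
#' tissue classes in the co- and cross-polarization channels, together with
#' relative surface backscatter levels and default ROI counts. These values
#' calibrate the synthetic-data module: per-ROI attenuation is modelled as a
#' truncated normal with location = median and sd = IQR/1.349 (the
#' normal-theory conversion, since only medians and quartiles are available).
#'
#' Backscatter is proportional to the class attenuation within each channel
#' (single-scattering model with a constant backscatter-to-attenuation ratio),
#' normalised so the brightest class has mean surface signal 1.
#'
#' @return data.frame with one row per class (AT, NCT, HTS, LDTC, HDTC) and
#'   columns \code{label}, \code{mu_co_median}, \code{mu_co_q1},
#'   \code{mu_co_q3}, \code{mu_cross_median}, \code{mu_cross_q1},
#'   \code{mu_cross_q3}, \code{backscatter_co}, \code{backscatter_cross},
#'   \code{roi_count_default}.
#' @examples
#' ct <- defaultClassTable()
#' ct[ct$label == "HDTC", "mu_cross_median"]   # 1.0 /mm
#' sum(ct$roi_count_default)                   # 165
#' @export
defaultClassTable <- function() {
    tb <- data.frame(
        label           = c("AT", "NCT", "HTS", "LDTC", "HDTC"),
        mu_co_median    = c(3.9, 5.3, 5.1, 5.0, 4.3),
        mu_co_q1        = c(3.5, 4.9, 5.0, 4.7, 4.1),
        mu_co_q3        = c(4.2, 5.8, 5.4, 5.3, 4.4),
        mu_cross_median = c(0.9, 3.7, 4.7, 2.2, 1.0),
        mu_cross_q1     = c(0.7, 3.4, 4.6, 1.9, 0.7),
        mu_cross_q3     = c(1.2, 4.2, 5.1, 2.5, 1.2),
        roi_count_default = c(33L, 36L, 27L, 34L, 35L),
        stringsAsFactors = FALSE)
    tb$backscatter_co    <- tb$mu_co_median / max(tb$mu_co_median)
    tb$backscatter_cross <- tb$mu_cross_median / max(tb$mu_cross_median)
    tb
}

## sd implied by the printed interquartile range under normal theory
.classSd <- function(classRow, channel) {
    q1 <- classRow[[paste0("mu_", channel, "_q1")]]
    q3 <- classRow[[paste0("mu_", channel, "_q3")]]
    (q3 - q1) / 1.349
}

## smallest admissible attenuation for sampled values, 1/mm; keeps draws
## strictly positive where median - 3*sd would go negative
.MU_FLOOR <- 0.05

#' Sample per-ROI attenuation values from a calibrated class distribution
#'
#' Draws from a normal with location = class median and
#' sd = IQR/1.349, truncated at median +/- 3 sd (and floored at 0.05 1/mm so
#' attenuation stays positive). The deviate is generated by inverse-CDF, so
#' calling with the same seed for the two channels yields comonotone
#' (coupled) co/cross pairs.
#'
#' @param class a class label ("AT", "NCT", "HTS", "LDTC", "HDTC") or one row
#'   of \code{\link{defaultClassTable}}.
#' @param channel "co" or "cross".
#' @param n number of draws.
#' @param seed optional integer; NULL uses (and advances) the current RNG.
#' @param classTable calibration table; defaults to
#'   \code{\link{defaultClassTable}}.
#' @return numeric vector of n attenuation values, 1/mm.
#' @examples
#' median(sampleROIMu("NCT", "cross", 1e4, seed = 1))  # close to 3.7
#' @export
sampleROIMu <- function(class, channel = c("co", "cross"), n, seed = NULL,
                        classTable = defaultClassTable()) {
    channel <- match.arg(channel)
    if (is.character(class)) {
        if (!class %in% classTable$label)
            stop(sprintf("unknown class '%s'; allowed: %s", class,
                         paste(classTable$label, collapse = ", ")))
        class <- classTable[classTable$label == class, ]
    }
    stopifnot(n >= 1)
    med <- class[[paste0("mu_", channel, "_median")]]
    sdv <- .classSd(class, channel)
    z <- .withSeed(seed, .truncStdNorm(n))
    pmax(.MU_FLOOR, med + sdv * z)
}

#' Construct a phantom specification
#'
#' Defaults describe the package's reference phantom: 4 mm deep at 5 um axial
#' pixels (800 z-px), 128 x 128 lateral pixels at 9.375 um pitch (1.2 mm
#' field), flat surface at 0.25 mm, all five tissue classes laid out on a
#' 2 x 3 lateral grid (the sixth cell repeats adipose tissue), patch-sampled
#' attenuation, fully developed speckle and a 1\% additive noise floor. The
#' 4 mm depth keeps the estimator's finite-depth truncation bias below 2\% for
#' the slowest-decaying class.
#'
#' @param depthMm,deltaZMm,lateralPx,pitchXYMm,surfaceDepthMm geometry.
#' @param layout data.frame (class, x0, y0, width, height), 0-based lateral
#'   rectangles; NULL = default five-class grid.
#' @param muSampling "patch" or "none" (class medians everywhere).
#' @param patchPx lateral patch size for "patch" sampling.
#' @param speckle add multiplicative unit-mean exponential speckle.
#' @param noiseFloor additive mean noise relative to the brightest class's
#'   surface signal.
#' @param classTable calibration table.
#' @param seed integer seed; same seed, bit-identical phantom.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(depthMm = 4.0, deltaZMm = 0.005,
                        lateralPx = c(128L, 128L), pitchXYMm = 0.009375,
                        surfaceDepthMm = 0.25, layout = NULL,
                        muSampling = c("patch", "none"), patchPx = 16L,
                        speckle = TRUE, noiseFloor = 0.01,
                        classTable = defaultClassTable(), seed = 1L) {
    muSampling <- match.arg(muSampling)
    lateralPx <- as.integer(lateralPx)
    if (is.null(layout)) layout <- .defaultLayout(lateralPx)
    new("PhantomSpec", depthMm = depthMm, deltaZMm = deltaZMm,
        lateralPx = lateralPx, pitchXYMm = pitchXYMm,
        surfaceDepthMm = surfaceDepthMm, layout = layout,
        muSampling = muSampling, patchPx = as.integer(patchPx),
        speckle = speckle, noiseFloor = noiseFloor, classTable = classTable,
        seed = as.integer(seed))
}

## five classes on a 2 x 3 grid; the spare sixth cell repeats adipose tissue
## (adipose surrounds the tumor bed in resection specimens)
.defaultLayout <- function(lateralPx) {
    nx <- lateralPx[1]; ny <- lateralPx[2]
    xs <- c(0L, nx %/% 2L)
    w <- c(nx %/% 2L, nx - nx %/% 2L)
    y3 <- c(0L, round(ny / 3), round(2 * ny / 3))
    h3 <- c(diff(y3), ny - y3[3])
    data.frame(
        class = c("AT", "NCT", "HTS", "LDTC", "HDTC", "AT"),
        x0    = c(xs[1], xs[2], xs[1], xs[2], xs[1], xs[2]),
        y0    = c(y3[1], y3[1], y3[2], y3[2], y3[3], y3[3]),
        width = c(w[1], w[2], w[1], w[2], w[1], w[2]),
        height = c(h3[1], h3[1], h3[2], h3[2], h3[3], h3[3]),
        stringsAsFactors = FALSE)
}

#' Synthesize a two-channel CP-OCT phantom volume
#'
#' Mean signal follows the single-scattering model
#' \code{S(z) = b * exp(-2 mu (z - z_s))} below the flat surface at depth
#' \code{z_s} and 0 above it, with per-column backscatter \code{b}
#' proportional to the column's attenuation (constant
#' backscatter-to-attenuation ratio per channel). The observed signal is
#' \code{S * speckle + noiseFloor * deviate} where speckle and the additive
#' noise deviate are unit-mean exponential. With \code{muSampling = "patch"}
#' each lateral patch of a class region receives its own attenuation draw,
#' coupled between channels through a shared standard-normal deviate.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param muOverride optional named list \code{class -> c(co=, cross=)} fixing
#'   the attenuation of given classes (forces "none"-style sampling for them).
#' @return list with elements \code{volume} (\linkS4class{OCTVolume}),
#'   \code{truth} (list of co/cross nx-by-ny ground-truth attenuation maps,
#'   NA outside tissue regions), \code{noise} (\linkS4class{NoiseModel} with
#'   the generating noise floor) and \code{surfaceIndex} (the z index of the
#'   first tissue pixel).
#' @export
synthesizeVolume <- function(spec, muOverride = NULL) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    nz <- round(spec@depthMm / spec@deltaZMm)
    nx <- spec@lateralPx[1]; ny <- spec@lateralPx[2]
    sIdx <- round(spec@surfaceDepthMm / spec@deltaZMm)
    ct <- spec@classTable
    .withSeed(spec@seed, {
        muMap <- list(co = matrix(NA_real_, nx, ny),
                      cross = matrix(NA_real_, nx, ny))
        for (r in seq_len(nrow(spec@layout))) {
            row <- spec@layout[r, ]
            cls <- ct[ct$label == row$class, ]
            xi <- (row$x0 + 1):(row$x0 + row$width)
            yi <- (row$y0 + 1):(row$y0 + row$height)
            if (!is.null(muOverride) && row$class %in% names(muOverride)) {
                mu <- muOverride[[row$class]]
                muMap$co[xi, yi] <- mu["co"]
                muMap$cross[xi, yi] <- mu["cross"]
            } else if (spec@muSampling == "none") {
                muMap$co[xi, yi] <- cls$mu_co_median
                muMap$cross[xi, yi] <- cls$mu_cross_median
            } else {
                px <- spec@patchPx
                xb <- split(xi, (seq_along(xi) - 1L) %/% px)
                yb <- split(yi, (seq_along(yi) - 1L) %/% px)
                for (bx in xb) for (by in yb) {
                    zdev <- .truncStdNorm(1L)   # shared across channels
                    muMap$co[bx, by] <- pmax(.MU_FLOOR,
                        cls$mu_co_median + .classSd(cls, "co") * zdev)
                    muMap$cross[bx, by] <- pmax(.MU_FLOOR,
                        cls$mu_cross_median + .classSd(cls, "cross") * zdev)
                }
            }
        }
        depth <- pmax(0, (seq_len(nz) - sIdx)) * spec@deltaZMm
        tissue <- seq_len(nz) >= sIdx
        arr <- array(0, c(2L, nz, nx, ny))
        for (ch in 1:2) {
            chn <- .CHANNELS[ch]
            muRef <- max(ct[[paste0("mu_", chn, "_median")]])
            muv <- as.vector(muMap[[chn]])              # length nx*ny
            b <- muv / muRef                            # backscatter ~ mu
            S <- exp(outer(-2 * depth, muv))            # nz x L
            S <- S * rep(b, each = nz)
            S[!tissue, ] <- 0
            S[is.na(S)] <- 0                            # columns outside layout
            if (spec@speckle)
                S <- S * matrix(stats::rexp(length(S)), nrow(S))
            if (spec@noiseFloor > 0)
                S <- S + spec@noiseFloor *
                    matrix(stats::rexp(length(S)), nrow(S))
            arr[ch, , , ] <- S
        }
        vol <- OCTVolume(arr, deltaZ = spec@deltaZMm, pitchXY = spec@pitchXYMm,
                         meta = list(kind = "synthetic phantom",
                                     seed = spec@seed,
                                     surface_index = sIdx))
        list(volume = vol, truth = muMap,
             noise = NoiseModel(spec@noiseFloor, spec@noiseFloor,
                                region = "generator noise floor"),
             surfaceIndex = sIdx)
    })
}

#' Default ROI fixture matching the study's class composition
#'
#' Places 300 x 300 um windows (32 x 32 px at the default 9.375 um pitch)
#' inside each class rectangle of the phantom layout, with per-class counts
#' taken from the calibration table (33/36/27/34/35, total 165). Windows are
#' laid on a deterministic jittered lattice inside their rectangle and may
#' overlap or repeat when the rectangle cannot host the requested count
#' disjointly: at the phantom's small lateral scale this emulates the dense
#' manual ROI sampling of large stitched maps.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param roiSizeMm ROI window side, mm.
#' @return An \linkS4class{ROISet} (provenance "generated").
#' @export
defaultFixtureROIs <- function(spec, roiSizeMm = 0.3) {
    stopifnot(is(spec, "PhantomSpec"))
    wpx <- round(roiSizeMm / spec@pitchXYMm)
    ct <- spec@classTable
    lay <- spec@layout
    rows <- list()
    for (cls in ct$label) {
        cnt <- ct$roi_count_default[ct$label == cls]
        rects <- lay[lay$class == cls, , drop = FALSE]
        if (!nrow(rects)) next
        ## candidate origins per rectangle: lattice of up to 6 x 6 positions
        cand <- list()
        for (r in seq_len(nrow(rects))) {
            rc <- rects[r, ]
            if (rc$width < wpx || rc$height < wpx)
                stop(sprintf(
                    "class %s rectangle (%dx%d px) too small for a %d px ROI",
                    cls, rc$width, rc$height, wpx))
            xs <- unique(round(seq(0, rc$width - wpx, length.out = 6)))
            ys <- unique(round(seq(0, rc$height - wpx, length.out = 6)))
            g <- expand.grid(x = xs, y = ys)
            cand[[r]] <- data.frame(x0 = rc$x0 + g$x, y0 = rc$y0 + g$y)
        }
        cand <- do.call(rbind, cand)
        idx <- (seq_len(cnt) - 1L) %% nrow(cand) + 1L
        rows[[cls]] <- data.frame(
            class = cls, x0 = cand$x0[idx], y0 = cand$y0[idx],
            width = wpx, height = wpx, stringsAsFactors = FALSE)
    }
    tb <- do.call(rbind, rows)
    tb <- data.frame(roi_id = sprintf("roi_%03d", seq_len(nrow(tb))), tb,
                     stringsAsFactors = FALSE)
    rownames(tb) <- NULL
    ROISet(tb, provenance = "generated")
}
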