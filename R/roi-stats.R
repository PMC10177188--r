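#' Median attenuation over one ROI window
#'
#' Median of the valid (non-NA) map pixels inside the half-open window
#' \code{[x0, x0+width) x [y0, y0+height)} (0-based origins). An ROI with
#' fewer than \code{minValidFrac} valid pixels is excluded: the value is NA
#' and the reason is attached. A window straddling the map edge is a hard
#' error naming the roi_id.
#'
#' @param map an \linkS4class{EnFaceMap}.
#' @param roi one-row data.frame (roi_id, x0, y0, width, height).
#' @param channel "co" or "cross".
#' @param minValidFrac minimum fraction of valid pixels (default 0.5).
#' @return numeric scalar (NA when excluded) with attributes
#'   \code{fracValid} and, when excluded, \code{reason}.
#' @export
roiMedian <- function(map, roi, channel = c("co", "cross"),
                      minValidFrac = 0.5) {
    stopifnot(is(map, "EnFaceMap"))
    channel <- match.arg(channel)
    ch <- match(channel, .CHANNELS)
    d <- dim(map@values)
    if (roi$x0 < 0 || roi$y0 < 0 || roi$x0 + roi$width > d[2] ||
        roi$y0 + roi$height > d[3])
        stop(sprintf("ROI '%s' lies outside the %d x %d map",
                     roi$roi_id, d[2], d[3]))
    v <- map@values[ch, (roi$x0 + 1):(roi$x0 + roi$width),
                    (roi$y0 + 1):(roi$y0 + roi$height)]
    frac <- mean(!is.na(v))
    if (frac < minValidFrac) {
        out <- NA_real_
        attr(out, "fracValid") <- frac
        attr(out, "reason") <- sprintf(
            "only %.0f%% of pixels valid (< %.0f%%)", 100 * frac,
            100 * minValidFrac)
        return(out)
    }
    out <- stats::median(v, na.rm = TRUE)
    attr(out, "fracValid") <- frac
    out
}

#' ROI medians for a whole ROI set, both channels
#'
#' @param map an \linkS4class{EnFaceMap}.
#' @param rois an \linkS4class{ROISet}.
#' @param minValidFrac minimum valid-pixel fraction per ROI.
#' @return data.frame (roi_id, class, channel, value, frac_valid, excluded,
#'   reason), one row per ROI and channel.
#' @export
roiMedians <- function(map, rois, minValidFrac = 0.5) {
    stopifnot(is(rois, "ROISet"))
    tb <- rois@table
    out <- vector("list", 2L * nrow(tb))
    k <- 0L
    for (ch in .CHANNELS) for (i in seq_len(nrow(tb))) {
        k <- k + 1L
        v <- roiMedian(map, tb[i, ], channel = ch,
                       minValidFrac = minValidFrac)
        out[[k]] <- data.frame(
            roi_id = tb$roi_id[i], class = tb$class[i], channel = ch,
            value = as.numeric(v), frac_valid = attr(v, "fracValid"),
            excluded = is.na(v),
            reason = if (is.na(v)) attr(v, "reason") else "",
            stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Summary statistics for one class of ROI values
#'
#' Median and quartiles use the inclusive linear-interpolation convention
#' (\code{stats::quantile} type 7); this convention is fixed because the
#' interquartile range feeds the synthetic calibration. The mean is reported
#' alongside.
#'
#' @param values numeric vector of ROI medians, 1/mm.
#' @param label class label (recorded, not checked).
#' @param channel channel name (recorded).
#' @return one-row data.frame (class, channel, n, median, q1, q3, mean).
#' @examples
#' summarizeClass(1:5)   # Me 3, Q1 2, Q3 4
#' @export
summarizeClass <- function(values, label = NA_character_,
                           channel = NA_character_) {
    values <- values[!is.na(values)]
    if (!length(values)) stop("no values to summarize")
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(class = label, channel = channel, n = length(values),
               median = q[2], q1 = q[1], q3 = q[3], mean = mean(values),
               stringsAsFactors = FALSE)
}

#' Class statistics table from ROI medians
#'
#' @param medians data.frame from \code{\link{roiMedians}} (excluded ROIs are
#'   dropped).
#' @return data.frame with one row per (class, channel) present.
#' @export
classStats <- function(medians) {
    medians <- medians[!medians$excluded, ]
    parts <- split(medians, list(medians$channel, medians$class), drop = TRUE)
    out <- do.call(rbind, lapply(parts, function(p)
        summarizeClass(p$value, label = p$class[1], channel = p$channel[1])))
    out <- out[order(match(out$class, .CLASS_LABELS), out$channel), ]
    rownames(out) <- NULL
    out
}

## exact two-sided Mann-Whitney p by full enumeration of group assignments
## (handles ties through midranks); feasible for n1, n2 <= 8
.mwExactP <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sel <- utils::combn(n1 + n2, n1)
    uAll <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney U for every pair of groups: full enumeration of
#' assignments when both groups have n <= \code{exactMax} (ties handled by
#' midranks), otherwise the tie-corrected normal approximation
#' (\code{stats::wilcox.test} without continuity correction). Bonferroni:
#' \code{p_adj = min(1, p * m)} with m = number of pairs (10 for five
#' groups).
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param exactMax maximum per-group n for the enumeration path.
#' @return list with matrices \code{p} (raw) and \code{p_adj}, and \code{m}.
#' @export
compareGroups <- function(groups, exactMax = 8L) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    stopifnot(all(vapply(groups, length, 1L) >= 2L))
    k <- length(groups)
    m <- k * (k - 1) / 2
    p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        x <- groups[[i]]; y <- groups[[j]]
        if (length(unique(c(x, y))) == 1L) {
            warning(sprintf(
                "groups '%s' and '%s' are degenerate (all values tied); p = 1",
                names(groups)[i], names(groups)[j]))
            pij <- 1
        } else if (length(x) <= exactMax && length(y) <= exactMax) {
            pij <- .mwExactP(x, y)
        } else {
            pij <- suppressWarnings(
                stats::wilcox.test(x, y, exact = FALSE,
                                   correct = FALSE)$p.value)
        }
        p[i, j] <- p[j, i] <- pij
    }
    pAdj <- p * m
    pAdj[!is.na(pAdj) & pAdj > 1] <- 1
    list(p = p, p_adj = pAdj, m = m)
}
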