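## orient raw attenuation values so that larger score = more positive-like
.rocScore <- function(v, direction) if (direction == "lower") -v else v

#' ROC curve for one class pair
#'
#' Staircase of (false positive rate, true positive rate) points at
#' thresholds placed at every distinct observed value plus sentinels, running
#' monotonically from (0, 0) to (1, 1). \code{direction} states the side on
#' which the positive class lies: "lower" calls a sample positive when its
#' value falls below the cutoff.
#'
#' @param pos,neg numeric values for the positive / negative class.
#' @param direction "lower" or "higher".
#' @return data.frame (threshold, fpr, tpr); thresholds are on the original
#'   scale, NA for the sentinel endpoints.
#' @export
rocCurve <- function(pos, neg, direction = c("lower", "higher")) {
    direction <- match.arg(direction)
    stopifnot(length(pos) >= 1L, length(neg) >= 1L)
    sp <- .rocScore(pos, direction); sn <- .rocScore(neg, direction)
    cuts <- sort(unique(c(sp, sn)), decreasing = TRUE)
    tpr <- vapply(cuts, function(t) mean(sp >= t), 1)
    fpr <- vapply(cuts, function(t) mean(sn >= t), 1)
    thr <- if (direction == "lower") -cuts else cuts
    data.frame(threshold = c(NA_real_, thr), fpr = c(0, fpr),
               tpr = c(0, tpr))
}

## AUC as pairwise concordance via the rank-sum identity (ties counted 1/2)
.aucPoint <- function(sp, sn) {
    n1 <- length(sp); n2 <- length(sn)
    r <- rank(c(sp, sn))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Area under the ROC curve with bootstrap CI
#'
#' The AUC equals the pairwise concordance probability P(score_pos >
#' score_neg) with ties counted 1/2 (the Mann-Whitney U divided by
#' n_pos * n_neg), which is also the trapezoidal area under
#' \code{\link{rocCurve}}. The 95\% CI comes from a stratified bootstrap
#' (resampling within each class).
#'
#' @param pos,neg class values.
#' @param direction "lower" or "higher".
#' @param ci compute the bootstrap CI.
#' @param nBoot bootstrap resamples.
#' @param seed optional seed for the bootstrap; NULL uses the current RNG.
#' @return list(auc, ci, nBoot); \code{ci} is c(NA, NA) when \code{ci=FALSE}.
#' @export
rocAUC <- function(pos, neg, direction = c("lower", "higher"), ci = TRUE,
                   nBoot = 2000L, seed = NULL) {
    direction <- match.arg(direction)
    sp <- .rocScore(pos, direction); sn <- .rocScore(neg, direction)
    auc <- .aucPoint(sp, sn)
    bounds <- c(NA_real_, NA_real_)
    if (ci) {
        bounds <- .withSeed(seed, {
            reps <- vapply(seq_len(nBoot), function(b)
                .aucPoint(sample(sp, replace = TRUE),
                          sample(sn, replace = TRUE)), 1)
            stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
        })
    }
    list(auc = auc, ci = bounds, nBoot = if (ci) nBoot else 0L)
}

#' Optimal cutoff by the Youden index
#'
#' Scans cutoffs at midpoints between adjacent distinct observed values (plus
#' sentinels beyond the extremes) and picks the one maximising Se + Sp; ties
#' are broken toward higher accuracy, then toward the lowest cutoff. Se, Sp
#' and accuracy at the chosen cutoff are returned with Wilson 95\% CIs.
#'
#' @param pos,neg class values.
#' @param direction "lower" (positive call when value < cutoff) or "higher".
#' @return list(pth, se, sp, ac, seCI, spCI, acCI, youden).
#' @export
optimalCutoff <- function(pos, neg, direction = c("lower", "higher")) {
    direction <- match.arg(direction)
    v <- sort(unique(c(pos, neg)))
    cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
              v[length(v)] + 1)
    sesp <- vapply(cand, function(t) {
        se <- if (direction == "lower") mean(pos < t) else mean(pos > t)
        sp <- if (direction == "lower") mean(neg >= t) else mean(neg <= t)
        c(se, sp)
    }, numeric(2))
    se <- sesp[1, ]; sp <- sesp[2, ]
    n1 <- length(pos); n2 <- length(neg)
    ac <- (se * n1 + sp * n2) / (n1 + n2)
    j <- se + sp
    best <- which(j > max(j) - 1e-12)
    if (length(best) > 1L) best <- best[ac[best] > max(ac[best]) - 1e-12]
    best <- best[1L]
    list(pth = cand[best], se = se[best], sp = sp[best], ac = ac[best],
         seCI = .wilson(round(se[best] * n1), n1),
         spCI = .wilson(round(sp[best] * n2), n2),
         acCI = .wilson(round(ac[best] * (n1 + n2)), n1 + n2),
         youden = se[best] + sp[best] - 1)
}

## the three diagnostic contrasts, with the side the positive class takes in
## each channel (from the class-distribution ordering: tumor cells attenuate
## less than fibrous tissue in cross, more than adipose in co; hyalinized
## stroma sits above NCT in cross, just below it in co)
.COMPARISONS <- data.frame(
    comparison = rep(c("TC vs AT", "TC vs NCT", "HTS vs NCT"), each = 2),
    channel = rep(c("co", "cross"), 3),
    positive = rep(c("TC", "TC", "HTS"), each = 2),
    negative = rep(c("AT", "NCT", "NCT"), each = 2),
    direction = c("higher", "higher", "lower", "lower", "lower", "higher"),
    stringsAsFactors = FALSE)

#' Run the standard tumor-discrimination ROC panel
#'
#' Builds the six class-pair comparisons (three contrasts times two
#' channels): pooled tumor-cell areas (LDTC + HDTC) vs adipose tissue, pooled
#' tumor-cell areas vs non-tumorous fibrous connective tissue, and hyalinized
#' tumor stroma vs non-tumorous fibrous connective tissue. Directions are
#' fixed per contrast and channel from the class-distribution ordering.
#'
#' @param medians data.frame with columns class, channel, value (e.g. from
#'   \code{\link{roiMedians}}; excluded rows should be dropped first) or with
#'   an \code{excluded} column which is honoured.
#' @param nBoot bootstrap resamples for the AUC CIs.
#' @param seed optional seed for the bootstrap CIs.
#' @return named list of six \linkS4class{ROCResult} objects.
#' @export
tissueComparisons <- function(medians, nBoot = 2000L, seed = NULL) {
    if ("excluded" %in% names(medians))
        medians <- medians[!medians$excluded, ]
    missing <- setdiff(.CLASS_LABELS, unique(medians$class))
    if (length(missing))
        stop("missing class(es): ", paste(missing, collapse = ", "))
    getVals <- function(cls, chn) {
        if (identical(cls, "TC"))
            medians$value[medians$class %in% c("LDTC", "HDTC") &
                          medians$channel == chn]
        else medians$value[medians$class == cls & medians$channel == chn]
    }
    out <- list()
    for (i in seq_len(nrow(.COMPARISONS))) {
        cmp <- .COMPARISONS[i, ]
        pos <- getVals(cmp$positive, cmp$channel)
        neg <- getVals(cmp$negative, cmp$channel)
        a <- rocAUC(pos, neg, cmp$direction, nBoot = nBoot,
                    seed = if (is.null(seed)) NULL else seed + i)
        oc <- optimalCutoff(pos, neg, cmp$direction)
        res <- new("ROCResult", comparison = cmp$comparison,
                   channel = cmp$channel, direction = cmp$direction,
                   auc = a$auc, aucCI = a$ci, pth = oc$pth, se = oc$se,
                   sp = oc$sp, ac = oc$ac, seCI = oc$seCI, spCI = oc$spCI,
                   acCI = oc$acCI, nPos = length(pos), nNeg = length(neg),
                   curve = rocCurve(pos, neg, cmp$direction))
        out[[paste(cmp$comparison, cmp$channel, sep = " / ")]] <- res
    }
    out
}

#' Tabulate ROC results in diagnostic-performance form
#'
#' @param results list of \linkS4class{ROCResult} (from
#'   \code{\link{tissueComparisons}}).
#' @return data.frame with columns comparison, channel, auc, auc_lo, auc_hi,
#'   se, sp, ac (with CI columns) and pth (signed by direction).
#' @export
rocTable <- function(results) {
    do.call(rbind, lapply(results, function(r) data.frame(
        comparison = r@comparison, channel = r@channel,
        auc = r@auc, auc_lo = r@aucCI[1], auc_hi = r@aucCI[2],
        se = r@se, se_lo = r@seCI[1], se_hi = r@seCI[2],
        sp = r@sp, sp_lo = r@spCI[1], sp_hi = r@spCI[2],
        ac = r@ac, ac_lo = r@acCI[1], ac_hi = r@acCI[2],
        pth = r@pth,
        cutoff = sprintf("%s%.3g", if (r@direction == "lower") "<" else ">",
                         r@pth),
        row.names = NULL, stringsAsFactors = FALSE)))
}
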