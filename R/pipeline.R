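#' Default run configuration
#'
#' A run configuration is a plain named list (fully YAML-serializable): seed,
#' output directory, phantom overrides, estimator options, depth window and
#' ROI source. The configuration actually used is archived into the output
#' directory alongside the package version, so a run can be reproduced
#' exactly.
#'
#' @param out_dir output directory.
#' @param seed integer seed controlling phantom synthesis and bootstrap CIs.
#' @return named list.
#' @export
defaultRunConfig <- function(out_dir = "cpoct-run", seed = 1L) {
    list(
        seed = as.integer(seed),
        out_dir = out_dir,
        phantom = list(),             # overrides for phantomSpec()
        estimator = list(tail_mode = "truncate", discretization = TRUE),
        window = c(0.105, 0.630),
        roi_source = "fixture",       # or a path to an ROI CSV
        render_channels = c("co", "cross"),
        n_boot = 2000L)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; unknown keys are rejected. Malformed YAML errors
#'   carry the parser's line information.
#' @return named list as from \code{\link{defaultRunConfig}}.
#' @export
readRunConfig <- function(path) {
    .stopIfMissing(path, "run configuration")
    cfg <- yaml::read_yaml(path)
    base <- defaultRunConfig()
    unknown <- setdiff(names(cfg), names(base))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    base[names(cfg)] <- cfg
    base$seed <- as.integer(base$seed)
    base$window <- as.numeric(unlist(base$window))
    base
}

.cfgPhantom <- function(cfg) {
    args <- cfg$phantom
    ## YAML deserialises vectors/tables as plain lists; coerce them back
    if (!is.null(args$layout) && !is.data.frame(args$layout))
        args$layout <- as.data.frame(args$layout,
                                     stringsAsFactors = FALSE)
    if (!is.null(args$lateralPx))
        args$lateralPx <- as.integer(unlist(args$lateralPx))
    args$seed <- cfg$seed
    do.call(phantomSpec, args)
}

.archiveConfig <- function(cfg, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    writeLines(as.character(utils::packageVersion("cpoct")),
               file.path(dir, "VERSION"))
}

## write a lateral float map as scaled float32 TIFF (sidecar holds the scale)
.writeMapTIFF <- function(m, path) {
    m2 <- m
    m2[is.na(m2)] <- 0
    mx <- max(m2, 1e-12)
    k <- if (mx <= 1) 0L else as.integer(ceiling(log2(mx)))
    tiff::writeTIFF(m2 / 2^k, path, bits.per.sample = 32L,
                    compression = "none")
    .jsonWrite(list(scale_log2 = k, missing_value = 0), paste0(path, ".json"))
    invisible(path)
}

#' Pipeline stage: synthesize the phantom experiment inputs
#'
#' Writes the phantom volume (TIFF + sidecar container), the ground-truth
#' attenuation maps (scaled float32 TIFF + CSV of per-ROI ground truth) and
#' the default ROI fixture CSV into \code{out_dir/}.
#'
#' @param cfg run configuration list.
#' @return Invisibly, the output directory.
#' @export
runSimulate <- function(cfg = defaultRunConfig()) {
    dir <- cfg$out_dir
    .archiveConfig(cfg, dir)
    spec <- .cfgPhantom(cfg)
    sim <- synthesizeVolume(spec)
    writeVolume(sim$volume, file.path(dir, "volume"))
    .writeMapTIFF(sim$truth$co, file.path(dir, "truth_co.tif"))
    .writeMapTIFF(sim$truth$cross, file.path(dir, "truth_cross.tif"))
    rois <- if (identical(cfg$roi_source, "fixture")) defaultFixtureROIs(spec)
            else readROISet(cfg$roi_source)
    writeROISet(rois, file.path(dir, "rois.csv"))
    tb <- rois@table
    gt <- data.frame(roi_id = tb$roi_id, class = tb$class,
                     mu_co = NA_real_, mu_cross = NA_real_)
    for (i in seq_len(nrow(tb))) {
        xi <- (tb$x0[i] + 1):(tb$x0[i] + tb$width[i])
        yi <- (tb$y0[i] + 1):(tb$y0[i] + tb$height[i])
        gt$mu_co[i] <- stats::median(sim$truth$co[xi, yi], na.rm = TRUE)
        gt$mu_cross[i] <- stats::median(sim$truth$cross[xi, yi], na.rm = TRUE)
    }
    utils::write.csv(gt, file.path(dir, "roi_truth.csv"), row.names = FALSE)
    message(sprintf("simulate: seed %d, volume %s, %d ROIs", cfg$seed,
                    paste(dim(octData(sim$volume)), collapse = "x"),
                    nrow(tb)))
    invisible(dir)
}

#' Pipeline stage: estimate the attenuation volume
#'
#' Reads \code{out_dir/volume}, detects the surface, estimates the noise
#' floor and writes per-channel corrected attenuation stacks (scaled float32
#' TIFF; invalid voxels stored as 0 and flagged via the mask page count in
#' the sidecar) plus \code{surface.csv} and \code{noise.json}.
#'
#' @param cfg run configuration list.
#' @return Invisibly, the \linkS4class{AttenuationVolume} (also on disk).
#' @export
runEstimate <- function(cfg = defaultRunConfig()) {
    dir <- cfg$out_dir
    .stopIfMissing(file.path(dir, "volume", "volume.json"),
                   "phantom volume (run the simulate stage first)")
    vol <- readVolume(file.path(dir, "volume"))
    surf <- detectSurface(vol)
    noise <- estimateNoiseFloor(vol, surface = surf)
    att <- attenuationVolume(vol, noise = noise, surface = surf,
                             tailMode = cfg$estimator$tail_mode,
                             discretization =
                                 isTRUE(cfg$estimator$discretization),
                             diagnostics = FALSE, verbose = TRUE)
    for (ch in 1:2) {
        a <- att@muAtt[ch, , , ]
        a[is.na(a)] <- 0
        k <- as.integer(max(0, ceiling(log2(max(a, 1e-12)))))
        pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 2^k)
        tiff::writeTIFF(pages,
                        file.path(dir, sprintf("att_%s.tif", .CHANNELS[ch])),
                        bits.per.sample = 32L, compression = "none")
    }
    .jsonWrite(list(mean_noise = as.list(noise@meanNoise),
                    region = noise@region,
                    valid_fraction = mean(att@valid)),
               file.path(dir, "noise.json"))
    utils::write.csv(att@surface, file.path(dir, "surface.csv"),
                     row.names = FALSE)
    invisible(att)
}

#' Pipeline stage: en face maps and renders
#'
#' @param cfg run configuration list.
#' @param att optional \linkS4class{AttenuationVolume} from
#'   \code{\link{runEstimate}}; NULL recomputes it from disk.
#' @return Invisibly, the \linkS4class{EnFaceMap}.
#' @export
runMap <- function(cfg = defaultRunConfig(), att = NULL) {
    dir <- cfg$out_dir
    if (is.null(att)) att <- runEstimate(cfg)
    map <- enfaceAverage(att, window = cfg$window)
    for (ch in cfg$render_channels) {
        i <- match(ch, .CHANNELS)
        utils::write.csv(map@values[i, , ],
                         file.path(dir, sprintf("enface_%s.csv", ch)),
                         row.names = FALSE)
        renderMap(map, file.path(dir, sprintf("enface_%s.png", ch)),
                  channel = ch)
    }
    invisible(map)
}

#' Pipeline stage: ROI medians, class statistics and group tests
#'
#' @param cfg run configuration list.
#' @param map optional \linkS4class{EnFaceMap}; NULL recomputes.
#' @return Invisibly, the ROI-median data.frame.
#' @export
runStats <- function(cfg = defaultRunConfig(), map = NULL) {
    dir <- cfg$out_dir
    if (is.null(map)) map <- runMap(cfg)
    rois <- readROISet(file.path(dir, "rois.csv"))
    med <- roiMedians(map, rois)
    utils::write.csv(med, file.path(dir, "roi_medians.csv"),
                     row.names = FALSE)
    cs <- classStats(med)
    csOut <- cs
    for (col in c("median", "q1", "q3", "mean"))
        csOut[[col]] <- formatC(cs[[col]], format = "f", digits = 3)
    utils::write.csv(csOut, file.path(dir, "class_stats.csv"),
                     row.names = FALSE)
    pv <- list()
    for (ch in .CHANNELS) {
        sub <- med[!med$excluded & med$channel == ch, ]
        groups <- split(sub$value, factor(sub$class, levels = .CLASS_LABELS))
        groups <- groups[lengths(groups) >= 2L]
        if (length(groups) < 2L) next   # too few populated classes to test
        cg <- compareGroups(groups)
        utils::write.csv(cg$p_adj,
                         file.path(dir, sprintf("pvalues_%s.csv", ch)))
        pv[[ch]] <- list(p = cg$p, p_adj = cg$p_adj, m = cg$m)
    }
    .jsonWrite(pv, file.path(dir, "pvalues.json"))
    invisible(med)
}

#' Pipeline stage: ROC panel
#'
#' @param cfg run configuration list.
#' @param medians optional ROI-median data.frame; NULL reads
#'   \code{roi_medians.csv} from the output directory.
#' @return Invisibly, the list of \linkS4class{ROCResult}.
#' @export
runROC <- function(cfg = defaultRunConfig(), medians = NULL) {
    dir <- cfg$out_dir
    if (is.null(medians)) {
        f <- file.path(dir, "roi_medians.csv")
        .stopIfMissing(f, "ROI medians (run the stats stage first)")
        medians <- utils::read.csv(f)
    }
    res <- tissueComparisons(medians, nBoot = cfg$n_boot,
                             seed = cfg$seed + 1000L)
    utils::write.csv(rocTable(res), file.path(dir, "roc_results.csv"),
                     row.names = FALSE)
    .jsonWrite(lapply(res, function(r) list(
        comparison = r@comparison, channel = r@channel, auc = r@auc,
        auc_ci = r@aucCI, pth = r@pth, se = r@se, sp = r@sp, ac = r@ac)),
        file.path(dir, "roc_results.json"))
    curves <- do.call(rbind, lapply(names(res), function(nm)
        cbind(comparison = nm, res[[nm]]@curve)))
    utils::write.csv(curves, file.path(dir, "roc_curves.csv"),
                     row.names = FALSE)
    for (ch in .CHANNELS) {
        sub <- res[vapply(res, function(r) r@channel == ch, TRUE)]
        grDevices::png(file.path(dir, sprintf("roc_%s.png", ch)),
                       width = 600, height = 600)
        graphics::plot(NA, xlim = 0:1, ylim = 0:1,
                       xlab = "false positive rate",
                       ylab = "true positive rate",
                       main = sprintf("ROC, %s channel", ch))
        graphics::abline(0, 1, lty = 3, col = "grey")
        cols <- c("blue", "red", "darkgreen")
        for (i in seq_along(sub))
            graphics::lines(sub[[i]]@curve$fpr, sub[[i]]@curve$tpr,
                            col = cols[i], lwd = 2, type = "s")
        graphics::legend("bottomright", bty = "n", col = cols, lwd = 2,
                         legend = vapply(sub, function(r)
                             sprintf("%s (AUC %.2f)", r@comparison, r@auc),
                             ""))
        grDevices::dev.off()
    }
    invisible(res)
}

#' Run the whole synthetic experiment end to end
#'
#' Chains simulate, estimate, map, stats and roc, then writes
#' \code{summary.json} with the six AUCs and the ten class medians. The run
#' is deterministic under a fixed seed.
#'
#' @param cfg run configuration list.
#' @return Invisibly, a list(medians, stats, roc).
#' @export
runAll <- function(cfg = defaultRunConfig()) {
    runSimulate(cfg)
    att <- runEstimate(cfg)
    map <- runMap(cfg, att = att)
    med <- runStats(cfg, map = map)
    res <- runROC(cfg, medians = med)
    cs <- classStats(med)
    summary <- list(
        seed = cfg$seed,
        auc = lapply(res, function(r) r@auc),
        class_medians = stats::setNames(
            as.list(cs$median), paste(cs$class, cs$channel, sep = "_")))
    .jsonWrite(summary, file.path(cfg$out_dir, "summary.json"))
    invisible(list(medians = med, stats = cs, roc = res))
}
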