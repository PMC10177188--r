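# shared in-code fixtures: all phantoms are generated at test time

# single-class phantom spec over a small lateral grid
singleClassSpec <- function(nxy = 8L, class = "NCT", speckle = FALSE,
                            noiseFloor = 0, seed = 7L) {
    phantomSpec(lateralPx = c(nxy, nxy),
                layout = data.frame(class = class, x0 = 0, y0 = 0,
                                    width = nxy, height = nxy),
                muSampling = "none", speckle = speckle,
                noiseFloor = noiseFloor, seed = seed)
}

# phantom with a fixed attenuation in both channels; for noisy phantoms the
# scan depth is matched to the decay rate (surface + analysis window + the
# depth at which <1% of the signal remains), as the generator's own depth
# bound prescribes -- a needlessly deep scan only accumulates pure noise in
# the estimator's depth sums
singleMuPhantom <- function(mu, nxy = 8L, speckle = FALSE, noiseFloor = 0,
                            seed = 7L, depthMm = NULL) {
    if (is.null(depthMm))
        depthMm <- if (noiseFloor > 0)
            0.005 * ceiling((0.25 + 0.63 + log(100) / (2 * mu)) / 0.005)
        else 4.0
    spec <- phantomSpec(depthMm = depthMm, lateralPx = c(nxy, nxy),
                        layout = data.frame(class = "NCT", x0 = 0, y0 = 0,
                                            width = nxy, height = nxy),
                        muSampling = "none", speckle = speckle,
                        noiseFloor = noiseFloor, seed = seed)
    synthesizeVolume(spec, muOverride = list(NCT = c(co = mu, cross = mu)))
}

# compact two-class spec (high-attenuation classes, shallower volume) used
# where a full five-class phantom would be needlessly slow
twoClassSpec <- function(seed = 3L, nxy = 64L, speckle = TRUE,
                         noiseFloor = 0.01, muSampling = "none") {
    phantomSpec(depthMm = 2.0, lateralPx = c(nxy, nxy),
                layout = data.frame(class = c("NCT", "HTS"),
                                    x0 = c(0, nxy %/% 2), y0 = 0,
                                    width = nxy %/% 2, height = nxy),
                muSampling = muSampling, speckle = speckle,
                noiseFloor = noiseFloor, seed = seed)
}

# analytic depth profile of the estimator on an exact exponential of rate mu
# truncated at depth L: mu / (1 - exp(-2 mu (L - z)))
closedFormMu <- function(mu, z, L) mu / (1 - exp(-2 * mu * (L - z)))

# brute-force pairwise concordance AUC (ties counted 1/2), independent of the
# rank-based implementation
concordanceAUC <- function(scorePos, scoreNeg) {
    s <- 0
    for (p in scorePos) for (q in scoreNeg)
        s <- s + (p > q) + 0.5 * (p == q)
    s / (length(scorePos) * length(scoreNeg))
}

# trapezoidal area under an (fpr, tpr) staircase
trapezoidArea <- function(curve) {
    sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}
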