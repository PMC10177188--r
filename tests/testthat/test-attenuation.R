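test_that("noise floor estimation recovers constant and stochastic floors", {
    a <- array(7, c(2, 30, 6, 6))
    v <- OCTVolume(a, deltaZ = 0.005, pitchXY = 0.01)
    nm <- estimateNoiseFloor(v, zRegion = 1:10)
    expect_equal(unname(meanNoise(nm)), c(7, 7))
    ## phantom with known 1% floor: estimate within 1% on >= 10^4 voxels
    spec <- singleClassSpec(nxy = 32L, noiseFloor = 0.01, seed = 31)
    sim <- synthesizeVolume(spec)
    nm2 <- estimateNoiseFloor(sim$volume, surface = sim$surfaceIndex)
    expect_gt(nm2@nVoxels, 1e4)
    expect_lt(max(abs(meanNoise(nm2) - 0.01)) / 0.01, 0.01)
    ## a region overlapping tissue is a warning, not an error
    expect_warning(
        estimateNoiseFloor(sim$volume, zRegion = 1:60,
                           surface = sim$surfaceIndex),
        "overlaps tissue")
    expect_error(estimateNoiseFloor(v, zRegion = integer(0)), "empty")
})

test_that("3x3x3 smoothing is exact on analytic cases and a brute force", {
    cst <- OCTVolume(array(4.2, c(2, 5, 5, 5)), deltaZ = 1, pitchXY = 1)
    expect_equal(octData(smoothLocal(cst)), octData(cst))
    ## unit impulse in the interior spreads to 27 voxels of 1/27
    a <- array(0, c(2, 7, 7, 7))
    a[1, 4, 4, 4] <- 1
    sm <- octData(smoothLocal(OCTVolume(a, deltaZ = 1, pitchXY = 1)))
    expect_equal(unname(sm[1, 4, 4, 4]), 1 / 27)
    expect_equal(sum(sm[1, , , ] > 0), 27)
    expect_equal(sum(sm[1, , , ]), 1)
    ## brute-force triple-loop oracle on a random block, clamped edges
    set.seed(42)
    b <- array(runif(5^3), c(5, 5, 5))
    oracle <- array(0, c(5, 5, 5))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
        acc <- 0
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
            acc <- acc + b[min(max(i + di, 1), 5),
                           min(max(j + dj, 1), 5),
                           min(max(k + dk, 1), 5)]
        oracle[i, j, k] <- acc / 27
    }
    v <- OCTVolume(list(b, b), deltaZ = 1, pitchXY = 1)
    expect_equal(octData(smoothLocal(v))[1, , , ], oracle, tolerance = 1e-12)
    thin <- OCTVolume(array(1, c(2, 2, 5, 5)), deltaZ = 1, pitchXY = 1)
    expect_error(smoothLocal(thin), "at least 3 px")
})

test_that("naive estimator matches hand computation and geometric closed form", {
    expect_equal(estimateMuNaive(c(4, 2), deltaZ = 1), c(1, NA))
    ## scale invariance: the ratio cancels any common factor
    set.seed(3)
    p <- rexp(50)
    expect_equal(estimateMuNaive(p, 0.005), estimateMuNaive(10 * p, 0.005))
    ## exact exponential: the raw geometric-sum estimate has the closed form
    ## (e^{2 mu dz} - 1) / (2 dz (1 - e^{-2 mu (L - z)}))
    dz <- 0.005; n <- 800L; mu <- 3
    z <- seq_len(n) * dz
    prof <- exp(-2 * mu * z)
    est <- estimateMuNaive(prof, dz)
    i <- 21L   # 0.105 mm
    raw <- (exp(2 * mu * dz) - 1) /
        (2 * dz * (1 - exp(-2 * mu * (n - i) * dz)))
    expect_equal(est[i], raw, tolerance = 1e-10)
    ## after the discrete-to-continuous map the estimate is mu to < 1%
    corrected <- log1p(2 * dz * est[i]) / (2 * dz)
    expect_lt(abs(corrected - mu) / mu, 0.01)
    ## an all-zero tail makes deeper estimates invalid, not zero
    p2 <- c(1, 1, 0, 0)
    expect_true(all(is.na(estimateMuNaive(p2, 1)[2:4])))
})

test_that("H and N_mu attain their analytic limits", {
    prof <- exp(-2 * 3 * seq_len(400) * 0.005)
    hn0 <- computeHNmu(prof, 0, 0.005)
    expect_true(all(hn0$H[-400] == 1))
    expect_true(all(hn0$nMu[-400] == 0))
    ## constant pure-noise profile: H collapses to 0 (noise dominates)
    hnN <- computeHNmu(rep(0.01, 400), 0.01, 0.005)
    expect_true(all(hnN$H == 0))
    ## deterministic noisy exponential: (mu_est - N_mu)/H inverts exactly
    N <- 0.01
    noisy <- prof + N
    hn <- computeHNmu(noisy, N, 0.005)
    muEst <- estimateMuNaive(noisy, 0.005)
    inv <- (muEst - hn$nMu) / hn$H
    iWin <- 21:126
    cf <- closedFormMu(3, iWin * 0.005, 400 * 0.005)
    ## geometric-sum scale, so compare after the discrete correction
    invCont <- log1p(2 * 0.005 * inv[iWin]) / (2 * 0.005)
    expect_lt(max(abs(invCont - cf) / cf), 0.05)
})

test_that("SNR-weighted correction attains both limits and shrinks monotonely", {
    expect_equal(correctMu(5, H = 1, snrMu = Inf), 5)
    expect_equal(correctMu(5, H = 0.8, snrMu = 0), 0)
    expect_true(is.na(correctMu(5, H = 0, snrMu = 3)))
    set.seed(8)
    muEst <- runif(100, 0, 10)
    H <- runif(100, 0.05, 1)
    snr <- rexp(100, 1 / 20)
    out <- correctMu(muEst, H, snr)
    expect_true(all(out <= muEst / H + 1e-12))
    expect_true(all(out >= 0))
    ## negative SNR is clipped to zero, shrinking the voxel fully
    expect_equal(correctMu(4, 0.9, -2), 0)
})

test_that("full estimator recovers constant and layered phantoms", {
    ## noise-free single-mu phantom: constant mu_att over the valid window
    sim <- singleMuPhantom(4.0)
    att <- attenuationVolume(sim$volume, noise = NoiseModel(0, 0),
                             surface = sim$surfaceIndex)
    s <- sim$surfaceIndex
    win <- muAtt(att)[1, (s + 21):(s + 125), , ]
    expect_lt(max(abs(win - 4.0)) / 4.0, 0.01)
    ## shape and mask contract
    expect_identical(dim(muAtt(att)), dim(octData(sim$volume)))
    vm <- validMask(att)
    expect_false(any(vm[, seq_len(s - 1), , ]))
    expect_false(any(vm[, dim(vm)[2], , ]))
    expect_true(all(vm[, s:(dim(vm)[2] - 1L), , ]))
    ## two-layer phantom (2 then 6 /mm, backscatter ~ mu): layer medians
    dz <- 0.005; n <- 800L
    z <- seq_len(n) * dz
    zs <- 0.25; zb <- 1.0   # boundary 0.75 mm below the surface
    I <- ifelse(z < zs, 0,
         ifelse(z < zb, 2 * exp(-2 * 2 * (z - zs)),
                6 * exp(-2 * 2 * (zb - zs)) * exp(-2 * 6 * (z - zb))))
    a <- array(rep(I, 9), c(n, 3, 3)) / 6
    v <- OCTVolume(list(a, a), deltaZ = dz, pitchXY = 0.01)
    att2 <- attenuationVolume(v, noise = NoiseModel(0, 0), surface = 50L)
    prof <- muAtt(att2)[1, , 2, 2]
    lay1 <- median(prof[60:140])            # inside layer 1
    lay2 <- median(prof[220:400])           # inside layer 2
    expect_lt(abs(lay1 - 2) / 2, 0.10)
    expect_lt(abs(lay2 - 6) / 6, 0.10)
})

test_that("estimates are invariant to a joint rescaling of signal and noise", {
    spec <- singleClassSpec(nxy = 8L, speckle = TRUE, noiseFloor = 0.01,
                            seed = 17)
    sim <- synthesizeVolume(spec)
    c0 <- 37.5
    scaled <- OCTVolume(octData(sim$volume) * c0, deltaZ = 0.005,
                        pitchXY = 0.009375)
    a1 <- attenuationVolume(sim$volume, noise = NoiseModel(0.01, 0.01),
                            surface = 50L)
    a2 <- attenuationVolume(scaled, noise = NoiseModel(0.01 * c0, 0.01 * c0),
                            surface = 50L)
    expect_equal(muAtt(a1), muAtt(a2), tolerance = 1e-10)
    expect_identical(validMask(a1), validMask(a2))
})

test_that("speckled noisy phantoms are recovered within 5%", {
    for (mu in c(2.2, 5.0)) {
        sim <- singleMuPhantom(mu, nxy = 24L, speckle = TRUE,
                               noiseFloor = 0.01, seed = 19)
        surf <- detectSurface(sim$volume)
        noise <- estimateNoiseFloor(sim$volume, surface = surf)
        att <- attenuationVolume(sim$volume, noise = noise, surface = surf,
                                 diagnostics = FALSE)
        s <- min(surf)
        for (ch in 1:2) {
            med <- median(muAtt(att)[ch, (s + 21):(s + 125), , ],
                          na.rm = TRUE)
            expect_lt(abs(med - mu) / mu, 0.05)
        }
    }
})
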