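# build a synthetic AttenuationVolume directly (constant or patterned)
makeAttVol <- function(values, nz = 200L, nx = 12L, ny = 12L, dz = 0.005,
                       surface = 50L) {
    arr <- array(NA_real_, c(2, nz, nx, ny))
    for (ch in 1:2) arr[ch, , , ] <- values
    valid <- !is.na(arr)
    valid[, nz, , ] <- FALSE
    valid[, seq_len(surface - 1L), , ] <- FALSE
    arr[!valid] <- NA_real_
    new("AttenuationVolume", muAtt = arr, muEst = arr,
        H = array(0, c(0, 0, 0, 0)), nMu = array(0, c(0, 0, 0, 0)),
        snrMu = array(0, c(0, 0, 0, 0)), valid = valid,
        surface = matrix(surface, nx, ny), deltaZ = dz, pitchXY = 0.009375)
}

test_that("surface detection finds a flat phantom surface within 1 px", {
    spec <- singleClassSpec(nxy = 32L, speckle = TRUE, noiseFloor = 0.01,
                            seed = 41)
    sim <- synthesizeVolume(spec)
    surf <- detectSurface(sim$volume)
    expect_gte(mean(abs(surf - sim$surfaceIndex) <= 1), 0.99)
    ## flat override
    flat <- detectSurface(sim$volume, flat = 50L)
    expect_true(all(flat == 50L))
    expect_identical(dim(flat), c(32L, 32L))
})

test_that("an all-noise volume yields an all-missing surface and a clear error", {
    set.seed(5)
    a <- array(0.01 * rexp(2 * 100 * 8 * 8), c(2, 100, 8, 8))
    v <- OCTVolume(a, deltaZ = 0.005, pitchXY = 0.009375)
    surf <- detectSurface(v, noise = NoiseModel(0.01, 0.01))
    expect_true(all(is.na(surf)))
    att <- makeAttVol(5, nz = 100L, nx = 8L, ny = 8L)
    att@surface <- surf
    expect_error(enfaceAverage(att), "entirely missing")
})

test_that("en face averaging reproduces constants and the window arithmetic", {
    att <- makeAttVol(5)
    map <- enfaceAverage(att)
    expect_true(all(mapValues(map) == 5))
    ## default window at 5 um pixels spans (0.630 - 0.105)/0.005 = 105 px
    attz <- makeAttVol(0)
    for (ch in 1:2)
        attz@muAtt[ch, , , ] <- array(rep(seq_len(200L), 12 * 12),
                                      c(200, 12, 12))
    attz@muAtt[, c(1:49, 200), , ] <- NA
    mz <- enfaceAverage(attz)
    expect_equal(mapValues(mz)[1, 1, 1], mean((50 + 21):(50 + 125)))
    ## window entirely below the volume bottom errors
    expect_error(enfaceAverage(att, window = c(1.2, 1.5)), "below the volume")
})

test_that("map values stay within the contributing voxel range", {
    set.seed(9)
    att <- makeAttVol(0)
    att@muAtt[1, , , ] <- array(runif(200 * 144, 1, 6), c(200, 12, 12))
    att@muAtt[1, c(1:49, 200), , ] <- NA
    map <- enfaceAverage(att)
    win <- att@muAtt[1, (50 + 21):(50 + 125), , ]
    expect_gte(min(mapValues(map)[1, , ]), min(win, na.rm = TRUE))
    expect_lte(max(mapValues(map)[1, , ]), max(win, na.rm = TRUE))
})

test_that("en face averaging commutes with lateral cropping", {
    spec <- twoClassSpec(seed = 6, nxy = 16L)
    sim <- synthesizeVolume(spec)
    att <- attenuationVolume(sim$volume, noise = sim$noise, surface = 50L)
    full <- enfaceAverage(att)
    xi <- 3:10; yi <- 2:15
    cropped <- new("AttenuationVolume",
                   muAtt = att@muAtt[, , xi, yi, drop = FALSE],
                   muEst = att@muEst[, , xi, yi, drop = FALSE],
                   H = array(0, c(0, 0, 0, 0)), nMu = array(0, c(0, 0, 0, 0)),
                   snrMu = array(0, c(0, 0, 0, 0)),
                   valid = att@valid[, , xi, yi, drop = FALSE],
                   surface = att@surface[xi, yi], deltaZ = att@deltaZ,
                   pitchXY = att@pitchXY)
    sub <- enfaceAverage(cropped)
    expect_equal(mapValues(sub), mapValues(full)[, xi, yi])
})

test_that("surface-relative windowing is invariant to a surface shift", {
    base <- phantomSpec(depthMm = 2.4, lateralPx = c(16L, 16L),
                        layout = data.frame(class = "NCT", x0 = 0, y0 = 0,
                                            width = 16, height = 16),
                        muSampling = "none", speckle = TRUE,
                        noiseFloor = 0.01, seed = 8)
    shifted <- phantomSpec(depthMm = 2.4, lateralPx = c(16L, 16L),
                           layout = base@layout, surfaceDepthMm = 0.35,
                           muSampling = "none", speckle = TRUE,
                           noiseFloor = 0.01, seed = 8)
    m1 <- enfaceAverage(attenuationVolume(synthesizeVolume(base)$volume,
                                          noise = NoiseModel(0.01, 0.01),
                                          surface = 50L))
    m2 <- enfaceAverage(attenuationVolume(synthesizeVolume(shifted)$volume,
                                          noise = NoiseModel(0.01, 0.01),
                                          surface = 70L))
    ## same tissue statistics in the shifted frame (speckle redraw differs)
    expect_lt(abs(median(mapValues(m1)[1, , ]) -
                  median(mapValues(m2)[1, , ])), 0.15)
})

test_that("rendering uses the fixed colour scale and is byte-deterministic", {
    vals <- array(NA_real_, c(2, 4, 1))
    vals[1, , 1] <- c(0, 7, 6.5, 1.0)
    vals[2, , 1] <- c(NA, 3, 2.5, 4.5)
    map <- new("EnFaceMap", values = vals, window = c(0.105, 0.63),
               pitchXY = 0.009375, scaleRange = c(0, 7))
    f1 <- file.path(tempdir(), "m1.png")
    renderMap(map, f1, channel = "co", barPx = 0L)
    img <- png::readPNG(f1)
    px <- function(i) img[1, i, ]                      # row 1 = y index 1
    expect_equal(px(1), c(0, 0, 139 / 255))            # 0 -> scale bottom
    expect_equal(px(2), c(139 / 255, 0, 0))            # 7 -> scale top
    expect_gt(px(3)[1], 0.5); expect_lt(px(3)[3], 0.1) # 6.5 in the red band
    expect_gt(px(4)[3], 0.9); expect_lt(px(4)[1], 0.1) # 1.0 in the blue band
    f2 <- file.path(tempdir(), "m2.png")
    renderMap(map, f2, channel = "cross")
    img2 <- png::readPNG(f2)
    expect_equal(img2[1, 1, ], c(0, 0, 0))             # missing -> black
    f3 <- file.path(tempdir(), "m3.png")
    renderMap(map, f3, channel = "cross")
    expect_identical(readBin(f2, "raw", file.size(f2)),
                     readBin(f3, "raw", file.size(f3)))
})

test_that("offset-grid stitching handles identity, disjoint and overlap", {
    mk <- function(v) new("EnFaceMap",
                          values = array(v, c(2, 4, 4)),
                          window = c(0.105, 0.63), pitchXY = 0.009375,
                          scaleRange = c(0, 7))
    a <- mk(2); b <- mk(6)
    one <- stitchMaps(list(a), list(c(0, 0)))
    expect_equal(mapValues(one), mapValues(a))
    disj <- stitchMaps(list(a, b), list(c(0, 0), c(4, 0)))
    expect_identical(dim(mapValues(disj)), c(2L, 8L, 4L))
    expect_true(all(mapValues(disj)[, 1:4, ] == 2))
    expect_true(all(mapValues(disj)[, 5:8, ] == 6))
    ## identical overlapping tiles keep the common values exactly
    ovl <- stitchMaps(list(a, a), list(c(0, 0), c(2, 0)))
    expect_true(all(mapValues(ovl)[, 3:4, ] == 2))
    expect_identical(dim(mapValues(ovl)), c(2L, 6L, 4L))
    ## inconsistent pitch is rejected
    bad <- mk(1); bad@pitchXY <- 0.02
    expect_error(stitchMaps(list(a, bad), list(c(0, 0), c(0, 0))),
                 "share pixel pitch")
})
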