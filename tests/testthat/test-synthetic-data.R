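test_that("calibrated class table holds the published distribution summary", {
    ct <- defaultClassTable()
    expect_identical(ct$label, c("AT", "NCT", "HTS", "LDTC", "HDTC"))
    expect_equal(ct$mu_cross_median[ct$label == "HDTC"], 1.0)
    expect_equal(ct$mu_co_median[ct$label == "NCT"], 5.3)
    expect_equal(ct$mu_co_median, c(3.9, 5.3, 5.1, 5.0, 4.3))
    expect_equal(ct$mu_cross_q1, c(0.7, 3.4, 4.6, 1.9, 0.7))
    expect_equal(ct$mu_cross_q3, c(1.2, 4.2, 5.1, 2.5, 1.2))
    expect_identical(sum(ct$roi_count_default), 165L)
    ## quartiles bracket the median in every class and channel
    expect_true(all(ct$mu_co_q1 < ct$mu_co_median),
                all(ct$mu_co_median < ct$mu_co_q3))
    expect_true(all(ct$mu_cross_q1 < ct$mu_cross_median),
                all(ct$mu_cross_median < ct$mu_cross_q3))
})

test_that("sampleROIMu converges to the class median and is reproducible", {
    x <- sampleROIMu("NCT", "cross", 1e5, seed = 1)
    expect_lt(abs(median(x) - 3.7), 0.02)
    expect_true(all(x > 0))
    expect_length(sampleROIMu("AT", "co", 1), 1L)
    expect_gt(sampleROIMu("AT", "co", 1, seed = 5), 0)
    expect_identical(sampleROIMu("HTS", "co", 50, seed = 9),
                     sampleROIMu("HTS", "co", 50, seed = 9))
    ## same seed across channels gives comonotone (coupled) pairs
    co <- sampleROIMu("LDTC", "co", 100, seed = 4)
    cr <- sampleROIMu("LDTC", "cross", 100, seed = 4)
    expect_identical(order(co), order(cr))
    expect_error(sampleROIMu("NCT", "vertical", 5), "arg")
    expect_error(sampleROIMu("stroma", "co", 5), "unknown class")
})

test_that("noise-free speckle-free phantom signal is exactly exponential", {
    sim <- singleMuPhantom(3.0)
    a <- octData(sim$volume)
    s <- sim$surfaceIndex
    dz <- deltaZ(sim$volume)
    z <- seq_len(dim(a)[2]) * dz
    ct <- defaultClassTable()
    for (ch in 1:2) {
        b <- 3.0 / max(ct[[paste0("mu_", c("co", "cross")[ch], "_median")]])
        expected <- ifelse(z >= s * dz, b * exp(-2 * 3.0 * (z - s * dz)), 0)
        expect_equal(a[ch, , 4, 4], expected, tolerance = 1e-12)
        expect_true(all(a[ch, seq_len(s - 1), , ] == 0))
    }
})

test_that("additive noise floor has the declared mean above the surface", {
    spec <- singleClassSpec(nxy = 32L, noiseFloor = 0.01, seed = 21)
    sim <- synthesizeVolume(spec)
    top <- octData(sim$volume)[, 1:45, , ]   # >= 10^4 voxels, all noise
    expect_gt(length(top) / 2, 1e4)
    for (ch in 1:2)
        expect_lt(abs(mean(top[ch, , , ]) - 0.01) / 0.01, 0.01)
    expect_equal(unname(meanNoise(sim$noise)), c(0.01, 0.01))
})

test_that("fully developed speckle has unit coefficient of variation", {
    spec <- singleClassSpec(nxy = 64L, speckle = TRUE, noiseFloor = 0,
                            seed = 22)
    sim <- synthesizeVolume(spec, muOverride = list(NCT = c(co = 2, cross = 2)))
    plane <- octData(sim$volume)[1, 60, , ]   # homogeneous slab, one z
    cv <- sd(plane) / mean(plane)
    expect_lt(abs(cv - 1), 0.05)
})

test_that("identical seeds give bit-identical phantoms", {
    spec <- twoClassSpec(seed = 12, nxy = 16L)
    s1 <- synthesizeVolume(spec)
    s2 <- synthesizeVolume(spec)
    expect_identical(octData(s1$volume), octData(s2$volume))
    expect_identical(s1$truth, s2$truth)
})

test_that("ground-truth maps agree with the layout voxel-wise", {
    spec <- phantomSpec(depthMm = 2, lateralPx = c(16L, 16L),
                        layout = data.frame(class = "HTS", x0 = 2, y0 = 3,
                                            width = 8, height = 9),
                        muSampling = "none", speckle = FALSE,
                        noiseFloor = 0, seed = 1)
    sim <- synthesizeVolume(spec)
    expect_true(all(sim$truth$co[3:10, 4:12] == 5.1))
    expect_true(all(is.na(sim$truth$co[1:2, ])))
    expect_true(all(is.na(sim$truth$cross[11:16, ])))
    ## columns outside the layout carry no tissue signal
    expect_true(all(octData(sim$volume)[, , 1:2, ] == 0))
})

test_that("patch-sampled truth stays inside the truncation bounds", {
    spec <- twoClassSpec(seed = 5, nxy = 32L, muSampling = "patch",
                         speckle = FALSE, noiseFloor = 0)
    sim <- synthesizeVolume(spec)
    ct <- defaultClassTable()
    for (cls in c("NCT", "HTS")) {
        rect <- spec@layout[spec@layout$class == cls, ]
        xi <- (rect$x0 + 1):(rect$x0 + rect$width)
        vals <- sim$truth$cross[xi, ]
        med <- ct$mu_cross_median[ct$label == cls]
        sdv <- (ct$mu_cross_q3[ct$label == cls] -
                ct$mu_cross_q1[ct$label == cls]) / 1.349
        expect_true(all(vals >= pmax(0.05, med - 3 * sdv) - 1e-9))
        expect_true(all(vals <= med + 3 * sdv + 1e-9))
    }
})

test_that("phantom validity enforces layout and depth constraints", {
    expect_error(phantomSpec(layout = data.frame(
        class = c("AT", "NCT"), x0 = c(0, 10), y0 = 0,
        width = 64, height = 64)), "overlap")
    expect_error(phantomSpec(layout = data.frame(
        class = "AT", x0 = 0, y0 = 0, width = 256, height = 64)),
        "inside the lateral grid")
    ## adipose cross-channel decay (0.9 /mm) needs ~2.2 mm of depth
    expect_error(phantomSpec(depthMm = 1.5), "too shallow")
})

test_that("the default ROI fixture reproduces the study composition", {
    spec <- phantomSpec()
    rois <- defaultFixtureROIs(spec)
    tb <- roiTable(rois)
    expect_identical(nrow(tb), 165L)
    cnt <- table(tb$class)
    expect_identical(as.integer(cnt[c("AT", "NCT", "HTS", "LDTC", "HDTC")]),
                     c(33L, 36L, 27L, 34L, 35L))
    ## 300 um windows are 32 px at the default 9.375 um pitch
    expect_true(all(tb$width == 32L), all(tb$height == 32L))
    ## every window sits inside a rectangle of its own class
    lay <- spec@layout
    for (i in seq_len(nrow(tb))) {
        own <- lay[lay$class == tb$class[i], , drop = FALSE]
        inside <- any(tb$x0[i] >= own$x0 &
                      tb$x0[i] + tb$width[i] <= own$x0 + own$width &
                      tb$y0[i] >= own$y0 &
                      tb$y0[i] + tb$height[i] <= own$y0 + own$height)
        expect_true(inside)
    }
    ## a rectangle smaller than one window is rejected
    small <- phantomSpec(depthMm = 2, lateralPx = c(32L, 32L),
                         layout = data.frame(class = "NCT", x0 = 0, y0 = 0,
                                             width = 16, height = 32),
                         muSampling = "none")
    expect_error(defaultFixtureROIs(small), "too small")
})
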