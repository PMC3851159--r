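zeroTrace <- function(n) {
    data.frame(tx = numeric(n), ty = numeric(n), tz = numeric(n),
               rx = numeric(n), ry = numeric(n), rz = numeric(n))
}

test_that("motion QC applies the strict 1 mm / 1 degree rule", {
    cfg <- preprocConfig(nDiscard = 0)
    r <- motionQC(zeroTrace(20), cfg)
    expect_true(r$pass)
    expect_equal(r$worstTranslation, 0)
    expect_equal(r$worstRotation, 0)

    tr <- zeroTrace(20); tr$tx[10] <- 1.2
    expect_false(motionQC(tr, cfg)$pass)

    ## exactly at the limit passes: the rule is "more than"
    tr <- zeroTrace(20); tr$tx[5] <- 1.0; tr$ry[7] <- 1.0
    r <- motionQC(tr, cfg)
    expect_true(r$pass)
    expect_equal(r$worstTranslation, 1.0)
    expect_equal(r$worstRotation, 1.0)

    expect_error(motionQC(zeroTrace(1), cfg), ">= 2")
})

test_that("motion QC references the first retained volume", {
    ## constant 5 mm offset during the discarded frames only: harmless
    tr <- zeroTrace(20)
    tr$tx[1:4] <- 5
    expect_false(motionQC(tr, preprocConfig(nDiscard = 0))$pass)
    expect_true(motionQC(tr, preprocConfig(nDiscard = 4))$pass)
    expect_error(motionQC(zeroTrace(5), preprocConfig(nDiscard = 10)),
                 "shorter")
})

test_that("initial volume discarding drops exactly the first frames", {
    set.seed(11)
    arr <- array(rnorm(4^3 * 128), c(4, 4, 4, 128))
    vol <- Volume4D(arr)
    out <- discardInitial(vol, 10)
    expect_equal(dim(imgData(out))[4], 118)
    expect_identical(imgData(out), arr[, , , 11:128])
    expect_identical(imgData(discardInitial(vol, 0)), arr)
    small <- Volume4D(array(rnorm(4^3 * 5), c(4, 4, 4, 5)))
    expect_error(discardInitial(small, 10), "too few volumes")
})

test_that("Gaussian smoothing matches a direct convolution oracle", {
    set.seed(12)
    arr <- array(rnorm(9 * 9 * 9 * 2), c(9, 9, 9, 2))
    vol <- Volume4D(arr)
    sm <- smoothGaussian(vol, fwhm = 8)
    sig <- (8 / (2 * sqrt(2 * log(2)))) / 3
    k <- rehopipe:::.gaussKernel1D(sig)
    for (f in 1:2)
        expect_equal(imgData(sm)[, , , f], naiveSmooth3D(arr[, , , f], k),
                     tolerance = 1e-12)
})

test_that("smoothing preserves impulses, constants and totals", {
    ## unit impulse: peak = central kernel weight cubed, frame sum 1
    n <- 21
    arr <- array(0, c(n, n, n, 2)); arr[11, 11, 11, 1] <- 1
    sm <- smoothGaussian(Volume4D(arr), fwhm = 8)
    sig <- (8 / (2 * sqrt(2 * log(2)))) / 3
    k <- rehopipe:::.gaussKernel1D(sig)
    kc <- k[(length(k) + 1) / 2]
    expect_equal(sm@data[11, 11, 11, 1], kc^3, tolerance = 1e-12)
    expect_equal(sum(sm@data[, , , 1]), 1, tolerance = 1e-12)
    expect_equal(sum(abs(sm@data[, , , 2])), 0)   # frames are independent

    ## fwhm 0 is the identity
    expect_identical(imgData(smoothGaussian(Volume4D(arr), fwhm = 0)), arr)

    ## constant frames stay constant away from the boundary
    carr <- array(2.5, c(15, 15, 15, 2))
    smc <- smoothGaussian(Volume4D(carr), fwhm = 8)
    expect_equal(smc@data[6:10, 6:10, 6:10, ],
                 carr[6:10, 6:10, 6:10, ], tolerance = 1e-10)

    ## sheared affines are unsupported
    aff <- defaultAffine(); aff[1, 2] <- 0.5
    expect_error(smoothGaussian(Volume4D(arr, affine = aff), fwhm = 8),
                 "shear")
})

test_that("in-mask renormalization undoes edge attenuation", {
    mask <- ballMask(12, radius = 4)
    carr <- array(1, c(12, 12, 12, 2))
    carr[array(!imgData(mask), c(12, 12, 12, 2))] <- 0
    sm <- smoothGaussian(Volume4D(carr), fwhm = 8, mask = mask,
                         renormalize = TRUE)
    inVals <- sm@data[, , , 1][imgData(mask)]
    expect_equal(max(abs(inVals - 1)), 0, tolerance = 1e-10)
})

test_that("linear detrending removes lines exactly and is idempotent", {
    n <- 40
    t <- seq_len(n)
    arr <- array(0, c(3, 3, 3, n))
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
        arr[i, j, k, ] <- 2 + 3 * t
    out <- detrendLinear(Volume4D(arr))
    expect_lt(max(abs(imgData(out))), 1e-9)

    ## a full-period oscillation symmetric about the scan midpoint has
    ## exactly zero discrete projection on the line: untouched beyond its
    ## mean (a generic off-grid sinusoid is not, in discrete time)
    s <- cos(2 * pi * 4 * (t - (n + 1) / 2) / n)
    arr2 <- array(rep(s, each = 27), c(3, 3, 3, n))
    out2 <- detrendLinear(Volume4D(arr2))
    expect_equal(out2@data[1, 1, 1, ], s - mean(s), tolerance = 1e-10)

    ## refit check on random series: residual slope is numerically zero
    set.seed(13)
    arr3 <- array(rnorm(27 * n), c(3, 3, 3, n))
    out3 <- detrendLinear(Volume4D(arr3))
    slopes <- apply(matrix(out3@data, 27, n), 1,
                    function(y) coef(lm(y ~ t))[2])
    expect_lt(max(abs(slopes)), 1e-10)

    ## idempotence
    expect_equal(imgData(detrendLinear(out3)), imgData(out3),
                 tolerance = 1e-12)
})

test_that("the ideal band-pass keeps the band and kills the rest", {
    n <- 118; tr <- 3
    t <- seq_len(n)
    mkvol <- function(f) {
        s <- sin(2 * pi * f * t * tr)
        Volume4D(array(rep(s, each = 27), c(3, 3, 3, n)), tr = tr)
    }
    amp <- function(v) max(abs(imgData(v)[1, 1, 1, ]))
    ## DFT-grid frequencies near 0.04 Hz (in band) and 0.12 Hz (out)
    fIn <- 14 / (n * tr)     # 0.0395 Hz
    fOut <- 42 / (n * tr)    # 0.1186 Hz
    inb <- bandpassFilter(mkvol(fIn), c(0.01, 0.08))
    expect_gte(amp(inb) / 1, 0.95)
    outb <- bandpassFilter(mkvol(fOut), c(0.01, 0.08))
    expect_lte(amp(outb) / 1, 0.05)

    cst <- Volume4D(array(5, c(3, 3, 3, n)), tr = tr)
    expect_lt(max(abs(imgData(bandpassFilter(cst, c(0.01, 0.08))))), 1e-10)

    ## idempotence of the rectangular filter
    set.seed(14)
    noisy <- Volume4D(array(rnorm(27 * n), c(3, 3, 3, n)), tr = tr)
    once <- bandpassFilter(noisy, c(0.01, 0.08))
    twice <- bandpassFilter(once, c(0.01, 0.08))
    expect_equal(imgData(twice), imgData(once), tolerance = 1e-10)

    expect_error(bandpassFilter(noisy, c(0.01, 0.2)), "Nyquist")
})

test_that("the default chain runs in the documented order and shape", {
    mask <- ballMask(10, radius = 4)
    spec <- cohortSpec(c(A = 2, B = 2), mask, nVolumes = 48, seed = 6)
    vol <- generateSubject(spec, "A", 1)
    out <- preprocessSubject(vol, mask, preprocConfig(nDiscard = 8))
    expect_equal(dim(imgData(out))[4], 40)
    ## band-passed output has (numerically) zero mean per in-mask voxel
    arr <- imgData(out)
    v <- arr[5, 5, 5, ]
    expect_lt(abs(mean(v)), 1e-10)
})
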