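test_that("Kendall's W hits its closed-form anchor cases", {
    set.seed(20)
    x <- rnorm(30)
    expect_equal(kendallsW(cbind(x, x, x)), 1)
    expect_equal(kendallsW(cbind(1:10, 10:1)), 0)
    ## K = 3, n = 3, ranks (1,2,3),(1,2,3),(3,2,1): W = 1/9
    expect_equal(kendallsW(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))),
                 1 / 9)
    expect_error(kendallsW(matrix(rnorm(10), ncol = 1)), "K >= 2")
    expect_error(kendallsW(matrix(rnorm(4), 2, 2)), "n >= 3")
    expect_warning(w0 <- kendallsW(cbind(rep(1, 5), rep(2, 5))),
                   "degenerate")
    expect_equal(w0, 0)
})

test_that("W equals the mean-pairwise-Spearman closed form", {
    set.seed(21)
    for (rep in 1:50) {
        K <- sample(2:8, 1)
        n <- sample(4:30, 1)
        X <- matrix(rnorm(n * K), n, K)
        expect_equal(kendallsW(X), spearmanW(X), tolerance = 1e-12)
    }
})

test_that("W is a rank statistic: monotone-transform and permutation invariant", {
    set.seed(22)
    for (rep in 1:20) {
        X <- matrix(rnorm(15 * 5), 15, 5)
        w <- kendallsW(X)
        expect_equal(kendallsW(exp(2 * X) + 1), w, tolerance = 1e-12)
        expect_equal(kendallsW(X[, sample(5)]), w, tolerance = 1e-12)
    }
})

test_that("tie correction only raises W and matches hand-computed ties", {
    set.seed(23)
    X <- matrix(sample(1:4, 12 * 5, replace = TRUE), 12, 5)  # heavy ties
    w0 <- kendallsW(X, tieCorrection = FALSE)
    w1 <- kendallsW(X, tieCorrection = TRUE)
    expect_gte(w1, w0)
    ## independent denominator computation
    R <- apply(X, 2, rank)
    S <- sum((rowSums(R) - mean(rowSums(R)))^2)
    TT <- sum(apply(X, 2, function(col) {
        tt <- table(col); sum(tt^3 - tt)
    }))
    K <- ncol(X); n <- nrow(X)
    expect_equal(w1, 12 * S / (K^2 * (n^3 - n) - K * TT),
                 tolerance = 1e-12)
})

test_that("the vectorized map equals the naive per-voxel reference", {
    set.seed(24)
    mask <- BrainMask(array(TRUE, c(8, 8, 8)))
    arr <- array(rnorm(8^3 * 20), c(8, 8, 8, 20))
    vol <- Volume4D(arr)
    for (params in list(rehoParams(),
                        rehoParams(K = 7),
                        rehoParams(minNeighbors = 14))) {
        got <- computeReHo(vol, mask, params)
        ref <- naiveRehoMap(vol, mask, params)
        expect_equal(imgData(got), ref$W, tolerance = 1e-12)
        expect_identical(validVoxels(got), ref$valid)
    }
    ## tie-corrected path on integer-valued (tied) data
    arrT <- array(sample(1:5, 8^3 * 12, replace = TRUE), c(8, 8, 8, 12))
    volT <- Volume4D(arrT)
    pT <- rehoParams(tieCorrection = TRUE)
    expect_equal(imgData(computeReHo(volT, mask, pT)),
                 naiveRehoMap(volT, mask, pT)$W, tolerance = 1e-12)
})

test_that("an irregular mask restricts neighborhoods correctly", {
    set.seed(25)
    mk <- array(runif(9^3) > 0.3, c(9, 9, 9))
    mk[5, 5, 5] <- TRUE
    mask <- BrainMask(mk)
    vol <- Volume4D(array(rnorm(9^3 * 15), c(9, 9, 9, 15)))
    params <- rehoParams(minNeighbors = 10)
    got <- computeReHo(vol, mask, params)
    ref <- naiveRehoMap(vol, mask, params)
    expect_equal(imgData(got), ref$W, tolerance = 1e-12)
})

test_that("identical series give W = 1 in the map interior", {
    n <- 20
    s <- rnorm(n)
    arr <- array(rep(s, each = 6^3), c(6, 6, 6, n))
    mask <- BrainMask(array(TRUE, c(6, 6, 6)))
    m <- computeReHo(Volume4D(arr), mask)
    expect_equal(imgData(m)[3, 3, 3], 1, tolerance = 1e-12)
    expect_true(all(imgData(m)[2:5, 2:5, 2:5] == 1))
    ## boundary voxels have incomplete cubes: flagged, value 0
    expect_false(validVoxels(m)[1, 1, 1])
    expect_equal(imgData(m)[1, 1, 1], 0)
})

test_that("noise maps match the sampling distribution of W", {
    set.seed(26)
    n <- 118
    mask <- ballMask(12, radius = 5)
    spec <- cohortSpec(c(A = 2, B = 2), mask, nVolumes = n, seed = 27,
                       driftAmplitude = 0)
    vol <- generateSubject(spec, "A", 1)
    m <- computeReHo(vol, mask)
    mapMean <- mean(imgData(m)[validVoxels(m)])
    ## direct Monte-Carlo of W on independent 27 x n Gaussian sets
    draws <- replicate(200, kendallsW(matrix(rnorm(n * 27), n, 27)))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mapMean - mean(draws)), 3 * se + 0.002)
    expect_lt(mapMean, 0.1)   # near-null concordance for i.i.d. noise
})

test_that("a synchronized block raises W above the background", {
    mask <- ballMask(14, radius = 6)
    reg <- cuboidRegion("blk", c(6, 6, 6), c(10, 10, 10),
                        c(A = 0.9, B = 0))
    inside <- outside <- numeric(3)
    for (s in 1:3) {
        spec <- cohortSpec(c(A = 2, B = 2), mask, list(reg),
                           nVolumes = 64, seed = 30 + s,
                           driftAmplitude = 0)
        vol <- generateSubject(spec, "A", 1)
        vol <- bandpassFilter(detrendLinear(vol, mask), mask = mask)
        m <- computeReHo(vol, mask)
        inBlk <- array(FALSE, dim(imgData(mask)))
        inBlk[reg$voxels] <- TRUE
        inside[s] <- mean(imgData(m)[inBlk & validVoxels(m)])
        outside[s] <- mean(imgData(m)[!inBlk & validVoxels(m)])
    }
    expect_true(all(inside > outside))
    expect_gt(mean(inside - outside), 0.1)
})

test_that("map standardization has the definitional moments", {
    set.seed(28)
    mask <- ballMask(10, radius = 4)
    vol <- Volume4D(array(rnorm(10^3 * 20), c(10, 10, 10, 20)))
    raw <- computeReHo(vol, mask)

    div <- standardizeMap(raw, "divided_by_mean")
    expect_equal(mean(imgData(div)[validVoxels(div)]), 1,
                 tolerance = 1e-12)
    z <- standardizeMap(raw, "zscore")
    expect_lt(abs(mean(imgData(z)[validVoxels(z)])), 1e-12)
    expect_lt(abs(sd(imgData(z)[validVoxels(z)]) - 1), 1e-12)
    ## out-of-mask voxels remain zero
    expect_true(all(imgData(z)[!imgData(mask)] == 0))

    ## constant raw map: divide gives all-1, zscore is degenerate
    flat <- new("ReHoMap", data = array(0.4, c(10, 10, 10)) *
                    array(imgData(mask), c(10, 10, 10)),
                affine = imgAffine(mask), standardization = "raw",
                params = unclass(rehoParams()), valid = imgData(mask))
    d <- standardizeMap(flat, "divided_by_mean")
    expect_true(all(imgData(d)[imgData(mask)] == 1))
    expect_error(standardizeMap(flat, "zscore"), "constant")
    expect_error(standardizeMap(d, "zscore"), "already standardized")
})

test_that("constant in-mask series are reported and zeroed", {
    mask <- BrainMask(array(TRUE, c(5, 5, 5)))
    flat <- Volume4D(array(7, c(5, 5, 5, 10)))
    expect_warning(m <- computeReHo(flat, mask), "degenerate")
    expect_true(all(imgData(m) == 0))

    ## one flat series inside noise stays well-defined via midranks
    arr <- array(rnorm(5^3 * 10), c(5, 5, 5, 10))
    arr[3, 3, 3, ] <- 7
    m2 <- computeReHo(Volume4D(arr), mask)
    expect_true(all(imgData(m2) >= 0 & imgData(m2) <= 1))
})
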