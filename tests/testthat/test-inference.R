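mkDesign <- function(values1, values2, covs = NULL) {
    n <- length(values1) + length(values2)
    d <- data.frame(id = sprintf("s%02d", seq_len(n)),
                    group = rep(c("A", "B"),
                                c(length(values1), length(values2))),
                    stringsAsFactors = FALSE)
    if (!is.null(covs)) d <- cbind(d, covs)
    d
}

mapsFromValues <- function(values, mask) {
    maps <- lapply(values, constantMap, mask = mask)
    names(maps) <- sprintf("s%02d", seq_along(values))
    maps
}

test_that("identical group map sets give a zero t map", {
    mask <- cubeMask(4)
    vals <- c(1.1, 0.9, 1.0, 1.1, 0.9, 1.0)
    maps <- mapsFromValues(vals, mask)
    d <- mkDesign(vals[1:3], vals[4:6])
    sm <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "none")
    expect_true(all(imgData(sm) == 0))
    expect_equal(sm@df, 4)
})

test_that("the voxel t equals the closed-form pooled t", {
    mask <- cubeMask(4)
    a <- c(1.1, 1.2, 1.3); b <- c(0.9, 1.0, 1.1)
    maps <- mapsFromValues(c(a, b), mask)
    d <- mkDesign(a, b)
    sm <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "none")
    ## independent oracle: direct evaluation of the pooled-t formula
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    expect_equal(imgData(sm)[2, 2, 2], tref, tolerance = 1e-12)
    expect_equal(sm@df, 4)
    ## cross-check against stats::t.test on the same values
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(imgData(sm)[2, 2, 2], unname(tt$statistic),
                 tolerance = 1e-10)
    ## sign convention: first-listed group higher => positive t
    expect_gt(imgData(sm)[2, 2, 2], 0)
    smRev <- voxelwiseTTest(maps, d, c("B", "A"), mask, adjust = "none")
    expect_equal(imgData(smRev)[2, 2, 2], -tref, tolerance = 1e-12)
})

test_that("fully orthogonalized covariates leave the inference unchanged", {
    mask <- cubeMask(4)
    set.seed(41)
    vals <- rnorm(8, mean = 1, sd = 0.1)
    g <- c(rep(1, 4), rep(0, 4))
    ## covariate orthogonalized against intercept, group and data: carries
    ## no information, so adjustment must be an exact no-op on the t values
    covRaw <- rnorm(8)
    cov <- residuals(lm(covRaw ~ g + vals))
    covs <- data.frame(age = cov)
    maps <- mapsFromValues(vals, mask)
    d <- mkDesign(vals[1:4], vals[5:8], covs)
    t0 <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "none")
    tr <- voxelwiseTTest(maps, d, c("A", "B"), mask,
                         adjust = "residualize", covariates = "age")
    ta <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "ancova",
                         covariates = "age")
    expect_equal(imgData(tr), imgData(t0), tolerance = 1e-10)
    expect_equal(tr@df, 6)
    expect_equal(ta@df, 5)
    ## with an uninformative covariate the ancova differs from the plain t
    ## only through the df of the variance estimate
    expect_equal(imgData(ta)[2, 2, 2],
                 imgData(t0)[2, 2, 2] * sqrt(5 / 6), tolerance = 1e-10)
})

test_that("the ancova t matches lm() per voxel", {
    mask <- cubeMask(4)
    set.seed(42)
    vals <- rnorm(10, 1, 0.2)
    covs <- data.frame(age = rnorm(10, 35, 8), gender =
                           sample(c("M", "F"), 10, replace = TRUE))
    maps <- mapsFromValues(vals, mask)
    d <- mkDesign(vals[1:5], vals[6:10], covs)
    sm <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "ancova",
                         covariates = c("age", "gender"))
    g <- c(rep(1, 5), rep(0, 5))
    gen01 <- as.numeric(factor(covs$gender)) - 1
    fit <- summary(lm(vals ~ g + covs$age + gen01))
    expect_equal(imgData(sm)[1, 1, 1], fit$coefficients["g", "t value"],
                 tolerance = 1e-10)
    expect_equal(sm@df, 10 - 4)
})

test_that("zero-variance voxels are flagged with t = 0", {
    mask <- cubeMask(4)
    maps <- mapsFromValues(rep(1, 6), mask)
    d <- mkDesign(rep(1, 3), rep(1, 3))
    sm <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "none")
    expect_true(all(imgData(sm) == 0))
    expect_true(all(sm@zeroVariance[imgData(mask)]))
    expect_error(voxelwiseTTest(maps, mkDesign(1, rep(1, 5)),
                                c("A", "B"), mask, adjust = "none"),
                 ">= 2 subjects")
})

test_that("permutation of null labels keeps voxel-level type-I error at alpha", {
    set.seed(43)
    mask <- cubeMask(5)
    nv <- 5^3
    nsub <- 16
    maps <- lapply(seq_len(nsub), function(i) {
        new("ReHoMap", data = array(rnorm(nv, 1, 0.1), c(5, 5, 5)),
            affine = defaultAffine(), standardization = "divided_by_mean",
            params = unclass(rehoParams()), valid = imgData(mask))
    })
    names(maps) <- sprintf("s%02d", seq_len(nsub))
    tc <- criticalT(0.05, nsub - 2)
    rates <- replicate(100, {
        perm <- sample(rep(c("A", "B"), each = nsub / 2))
        d <- data.frame(id = names(maps), group = perm)
        sm <- voxelwiseTTest(maps, d, c("A", "B"), mask, adjust = "none")
        mean(abs(imgData(sm)) > tc)
    })
    p <- mean(rates)
    se <- sqrt(0.05 * 0.95 / (100 * nv))
    expect_lt(abs(p - 0.05), 4 * se)
})

test_that("critical t values match independent quantile inversion", {
    expect_equal(round(criticalT(0.05, 30), 3), 2.042)
    expect_equal(round(criticalT(0.05, 1e6), 3), 1.960)
    ## independent oracle: invert the distribution function numerically
    inv <- uniroot(function(c) 2 * pt(c, 31, lower.tail = FALSE) - 0.05,
                   c(0.1, 10), tol = 1e-12)$root
    expect_equal(criticalT(0.05, 31), inv, tolerance = 1e-9)
    expect_error(criticalT(0, 30), "alpha")
    expect_error(criticalT(0.05, 0), "df")
})

test_that("summary-statistic ANOVA agrees with aov on reconstructed data", {
    means <- c(36.06, 34.47, 35.13)
    sds <- c(9.43, 9.77, 7.88)
    ns <- c(16, 18, 16)   # even sizes for the two-point construction
    res <- anovaFromSummary(means, sds, ns)
    y <- unlist(mapply(exactSample, means, sds, ns, SIMPLIFY = FALSE))
    g <- factor(rep(seq_along(ns), ns))
    ref <- summary(aov(y ~ g))[[1]]
    expect_equal(res$F, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
    expect_equal(res$dfBetween, 2)
    expect_equal(res$dfWithin, sum(ns) - 3)

    ## invariances: group order and common rescaling leave F unchanged
    res2 <- anovaFromSummary(rev(means), rev(sds), rev(ns))
    expect_equal(res2$F, res$F, tolerance = 1e-12)
    res3 <- anovaFromSummary(10 * means, 10 * sds, ns)
    expect_equal(res3$F, res$F, tolerance = 1e-12)

    expect_equal(anovaFromSummary(c(5, 5, 5), c(1, 2, 1),
                                  c(10, 10, 10))$F, 0)
    expect_error(anovaFromSummary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("summary-statistic t-test agrees with t.test on reconstructed data", {
    res <- ttestFromSummary(4.38, 1.63, 16, 26.19, 4.98, 16)
    y1 <- exactSample(4.38, 1.63, 16)
    y2 <- exactSample(26.19, 4.98, 16)
    ref <- t.test(y1, y2, var.equal = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
    expect_equal(res$df, 30)
    expect_equal(ttestFromSummary(1, 1, 10, 1, 1, 10)$t, 0)
})

test_that("chi-square independence matches the Pearson formula", {
    tab <- rbind(c(8, 8), c(9, 8), c(8, 8))
    res <- chisqIndependence(tab)
    ## hand-computed Pearson statistic
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chisq, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(res$df, 2)
    expect_equal(chisqIndependence(rbind(c(10, 10), c(10, 10)))$chisq, 0)
    expect_error(chisqIndependence(rbind(c(0, 0), c(1, 2))),
                 "degenerate")
})
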