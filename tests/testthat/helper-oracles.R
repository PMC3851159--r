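# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# Kendall's W via its Spearman equivalence: W = ((K - 1) rhobar + 1) / K,
# rhobar = mean pairwise Spearman correlation. Valid for tie-free series.
spearmanW <- function(X) {
    K <- ncol(X)
    rho <- stats::cor(X, method = "spearman")
    rhobar <- mean(rho[lower.tri(rho)])
    ((K - 1) * rhobar + 1) / K
}

# Naive per-voxel ReHo map: triple loop, gather the cubic neighborhood,
# call kendallsW on the member series.
naiveRehoMap <- function(vol, mask, params = rehoParams()) {
    arr <- imgData(vol)
    mk <- imgData(mask)
    sp <- dim(arr)[1:3]
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- switch(as.character(params$K),
                   "7" = offs[rowSums(abs(offs)) <= 1, , drop = FALSE],
                   "19" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                   offs)
    W <- array(0, sp)
    valid <- array(FALSE, sp)
    for (i in seq_len(sp[1])) for (j in seq_len(sp[2]))
        for (k in seq_len(sp[3])) {
            if (!mk[i, j, k]) next
            members <- NULL
            for (o in seq_len(nrow(offs))) {
                ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
                kk <- k + offs[o, 3]
                if (ii < 1 || ii > sp[1] || jj < 1 || jj > sp[2] ||
                    kk < 1 || kk > sp[3]) next
                if (!mk[ii, jj, kk]) next
                members <- cbind(members, arr[ii, jj, kk, ])
            }
            if (is.null(members) || ncol(members) < params$minNeighbors)
                next
            valid[i, j, k] <- TRUE
            W[i, j, k] <- kendallsW(members, params$tieCorrection)
        }
    list(W = W, valid = valid)
}

# Breadth-first flood-fill connected-component labeling of a logical 3D
# array; reference for the igraph-based labeling.
floodFillLabels <- function(supra, connectivity = 26) {
    sp <- dim(supra)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    offs <- switch(as.character(connectivity),
                   "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                   "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                   offs)
    lab <- array(0L, sp)
    nextLab <- 0L
    for (start in which(supra)) {
        if (lab[start] != 0L) next
        nextLab <- nextLab + 1L
        queue <- start
        lab[start] <- nextLab
        while (length(queue)) {
            cur <- queue[1]; queue <- queue[-1]
            ijk <- arrayInd(cur, sp)
            for (o in seq_len(nrow(offs))) {
                ii <- ijk[1] + offs[o, 1]; jj <- ijk[2] + offs[o, 2]
                kk <- ijk[3] + offs[o, 3]
                if (ii < 1 || ii > sp[1] || jj < 1 || jj > sp[2] ||
                    kk < 1 || kk > sp[3]) next
                lin <- ii + sp[1] * ((jj - 1) + sp[2] * (kk - 1))
                if (supra[lin] && lab[lin] == 0L) {
                    lab[lin] <- nextLab
                    queue <- c(queue, lin)
                }
            }
        }
    }
    lab
}

# Direct triple-loop 3D convolution with a separable Gaussian kernel and
# zero padding; reference for the compiled separable smoother.
naiveSmooth3D <- function(arr, k) {
    r <- (length(k) - 1) / 2
    sp <- dim(arr)
    out <- array(0, sp)
    for (i in seq_len(sp[1])) for (j in seq_len(sp[2]))
        for (l in seq_len(sp[3])) {
            acc <- 0
            for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
                ii <- i + dx; jj <- j + dy; ll <- l + dz
                if (ii < 1 || ii > sp[1] || jj < 1 || jj > sp[2] ||
                    ll < 1 || ll > sp[3]) next
                acc <- acc + k[dx + r + 1] * k[dy + r + 1] *
                    k[dz + r + 1] * arr[ii, jj, ll]
            }
            out[i, j, l] <- acc
        }
    out
}

# Datasets with exactly prescribed mean and SD (half m + d, half m - d),
# for reconstructing summary statistics with stats::aov / stats::t.test.
exactSample <- function(m, s, n) {
    stopifnot(n %% 2 == 0)
    d <- s * sqrt((n - 1) / n)
    rep(c(m + d, m - d), each = n / 2)
}

# Small all-true cubic mask on an n^3 grid.
cubeMask <- function(n, affine = defaultAffine()) {
    BrainMask(array(TRUE, c(n, n, n)), affine = affine)
}

# Constant-valued standardized ReHoMap for closed-form t-test checks.
constantMap <- function(value, mask) {
    sp <- dim(imgData(mask))
    new("ReHoMap", data = array(value, sp), affine = imgAffine(mask),
        standardization = "divided_by_mean", params = unclass(rehoParams()),
        valid = imgData(mask))
}
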