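#' Construct a Volume4D
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix; defaults to 3 mm isotropic with
#'   the origin translation used by common MNI-space grids.
#' @param tr repetition time in seconds (default 3).
#' @return A \code{\linkS4class{Volume4D}}.
#' @export
#' @examples
#' vol <- Volume4D(array(rnorm(5^3 * 10), c(5, 5, 5, 10)), tr = 3)
#' repetitionTime(vol)
Volume4D <- function(data, affine = defaultAffine(), tr = 3) {
    new("Volume4D", data = data, affine = affine, tr = as.numeric(tr))
}

#' Construct a BrainMask
#'
#' @param data 3D array; coerced to logical (non-zero = in mask).
#' @param affine 4x4 voxel-to-world matrix.
#' @return A \code{\linkS4class{BrainMask}}.
#' @export
BrainMask <- function(data, affine = defaultAffine()) {
    d <- dim(data)
    data <- array(as.logical(data != 0), d)
    new("BrainMask", data = data, affine = affine)
}

#' Default 3 mm isotropic MNI-style affine
#'
#' Diagonal 3 mm voxel scaling with translation (-90, -126, -72) mm, the
#' origin offset of the common 61 x 73 x 61 MNI-space 3 mm grid.
#'
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param origin numeric(3) world coordinate of voxel index c(1, 1, 1).
#' @return 4x4 matrix.
#' @export
defaultAffine <- function(voxelSize = c(3, 3, 3),
                          origin = c(-90, -126, -72)) {
    a <- diag(c(voxelSize, 1))
    a[1:3, 4L] <- origin
    a
}

## Euclidean column norms of the spatial 3x3 block = voxel edge lengths (mm)
.voxelSizes <- function(affine) {
    sqrt(colSums(affine[1:3, 1:3]^2))
}

## Affines with shear/oblique spatial blocks are rejected where voxelwise
## separable operations (smoothing) assume axis-aligned grids.
.checkAxisAligned <- function(affine) {
    A <- affine[1:3, 1:3]
    off <- abs(A) - diag(abs(diag(A)))
    if (max(abs(off)) > 1e-6 * max(abs(A)))
        stop("affine has shear or oblique axes; ",
             "separable smoothing supports axis-aligned grids only")
    invisible(TRUE)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one global seed into independent per-stage / per-subject seeds by
#' a fixed multiplicative-congruential step, so that stages may process
#' subjects in any order without changing results.
#'
#' @param master integer master seed.
#' @param ... further integer indices (stage number, subject number, ...).
#' @return An integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' deriveSeed(42, 1, 3)
deriveSeed <- function(master, ...) {
    m <- 2147483647              # 2^31 - 1, Mersenne prime modulus
    s <- as.numeric(master) %% m
    for (idx in c(...)) {
        s <- (s * 69069 + as.numeric(idx) + 1) %% m
    }
    as.integer(s + 1)
}

## 1D normalized Gaussian kernel for a given sigma in voxels.
.gaussKernel1D <- function(sigmaVox) {
    if (sigmaVox <= 0) return(1)
    r <- max(1L, ceiling(3.5 * sigmaVox))
    w <- stats::dnorm(seq(-r, r), sd = sigmaVox)
    w / sum(w)
}

## Banded convolution matrix: out[i] = sum_d w[d] * in[i + d], zero padding.
.convMatrix <- function(n, w) {
    r <- (length(w) - 1L) %/% 2L
    M <- matrix(0, n, n)
    for (d in seq(-r, r)) {
        i <- seq_len(n)
        j <- i + d
        ok <- j >= 1L & j <= n
        M[cbind(i[ok], j[ok])] <- w[d + r + 1L]
    }
    M
}

## Separable Gaussian smoothing of a 3D or 4D array (sigma per spatial axis,
## in voxels); zero padding outside the grid. Convolution kernels run in C++.
.smoothArray <- function(arr, sigmaVox) {
    d <- dim(arr)
    stopifnot(length(d) %in% c(3L, 4L))
    if (all(sigmaVox <= 0)) return(arr)
    out <- arr
    for (ax in 1:3) {
        if (sigmaVox[ax] <= 0) next
        k <- .gaussKernel1D(sigmaVox[ax])
        out <- .cppConvAxis(out, as.integer(d), ax, k)
    }
    array(out, d)
}

## FWHM (mm) -> sigma (voxels), given voxel sizes in mm.
.fwhmToSigmaVox <- function(fwhm, voxelSizes) {
    (fwhm / (2 * sqrt(2 * log(2)))) / voxelSizes
}

#' Maximal cluster sizes of a Monte-Carlo null distribution
#'
#' @param x a \code{\linkS4class{NullClusterDistribution}}.
#' @return Integer vector of per-iteration maximal cluster sizes.
#' @export
maxClusterSizes <- function(x) {
    stopifnot(is(x, "NullClusterDistribution"))
    x@maxSizes
}

#' Per-iteration suprathreshold voxel fractions of a Monte-Carlo null
#'
#' Diagnostic for voxel-level calibration: under correct thresholding the
#' mean fraction equals the configured per-voxel alpha.
#'
#' @param x a \code{\linkS4class{NullClusterDistribution}}.
#' @return Numeric vector of fractions in [0, 1].
#' @export
supraFractions <- function(x) {
    stopifnot(is(x, "NullClusterDistribution"))
    x@supraFractions
}
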