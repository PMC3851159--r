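## Positive half of the neighbor offset set for a connectivity scheme.
.connOffsets <- function(connectivity) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[!(g[, 1L] == 0 & g[, 2L] == 0 & g[, 3L] == 0), , drop = FALSE]
    keep <- switch(as.character(connectivity),
                   "6"  = rowSums(abs(g)) == 1L,
                   "18" = rowSums(abs(g)) <= 2L,
                   "26" = rep(TRUE, nrow(g)),
                   stop("'connectivity' must be 6, 18 or 26"))
    g <- g[keep, , drop = FALSE]
    ## lexicographically positive half: each unordered pair counted once
    pos <- g[, 3L] > 0 | (g[, 3L] == 0 & g[, 2L] > 0) |
        (g[, 3L] == 0 & g[, 2L] == 0 & g[, 1L] > 0)
    g[pos, , drop = FALSE]
}

## Connected components of a logical 3D array. Returns integer labels
## (0 = background) via igraph components over the voxel adjacency graph.
.labelComponents <- function(supra, connectivity = 26L) {
    sp <- dim(supra)
    lin <- which(supra)
    lab <- array(0L, sp)
    if (!length(lin)) return(lab)
    rk <- integer(prod(sp))
    rk[lin] <- seq_along(lin)
    offs <- .connOffsets(connectivity)
    from <- integer(0)
    to <- integer(0)
    for (o in seq_len(nrow(offs))) {
        d <- offs[o, ]
        shift <- d[1L] + sp[1L] * (d[2L] + sp[2L] * d[3L])
        coords <- arrayInd(lin, sp)
        nb <- coords + matrix(d, nrow(coords), 3L, byrow = TRUE)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= sp[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= sp[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= sp[3L]
        if (!any(ok)) next
        nbLin <- lin[ok] + shift
        hit <- supra[nbLin]
        if (!any(hit)) next
        from <- c(from, rk[lin[ok]][hit])
        to <- c(to, rk[nbLin[hit]])
    }
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(lin) -
                                         igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    lab[lin] <- as.integer(comp)
    lab
}

#' Label supra-threshold clusters of a t map
#'
#' Voxels with \code{t > tThreshold} (increases) and \code{t < -tThreshold}
#' (decreases) are labeled separately into connected components under the
#' chosen connectivity. Each cluster record carries its size in voxels and
#' mm^3, the peak-|t| voxel (1-based grid index) and its world (MNI mm)
#' coordinates, and the sign. Records are ordered increases first, then by
#' descending size, ties broken by lexicographic peak index.
#'
#' @param statmap a \code{\linkS4class{StatMap}}.
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @param tThreshold positive voxel-level threshold (e.g.
#'   \code{criticalT(0.05, df)}).
#' @param connectivity 6, 18 or 26 (default 26, the 3x3x3 cube).
#' @param minSize drop clusters smaller than this many voxels (default 1,
#'   i.e. keep all; pass the \code{\link{extentThreshold}} for corrected
#'   inference).
#' @return data.frame with columns \code{sign}, \code{size},
#'   \code{size_mm3}, \code{peak_t}, \code{peak_i/j/k},
#'   \code{mni_x/y/z}; zero rows if nothing survives.
#' @export
labelClusters <- function(statmap, mask, tThreshold, connectivity = 26L,
                          minSize = 1L) {
    stopifnot(is(statmap, "StatMap"), is(mask, "BrainMask"))
    if (tThreshold <= 0) stop("'tThreshold' must be positive")
    sp <- dim(statmap@t)
    voxVol <- abs(det(statmap@affine[1:3, 1:3]))
    rows <- list()
    for (sgn in c("increase", "decrease")) {
        supra <- if (sgn == "increase")
            statmap@t > tThreshold & mask@data
        else
            statmap@t < -tThreshold & mask@data
        lab <- .labelComponents(supra, connectivity)
        nlab <- max(lab)
        if (nlab == 0L) next
        recs <- vector("list", nlab)
        for (cl in seq_len(nlab)) {
            lin <- which(lab == cl)
            tv <- statmap@t[lin]
            ## deterministic: smallest linear index among tied peaks
            pk <- min(lin[abs(tv) == max(abs(tv))])
            ijk <- arrayInd(pk, sp)
            world <- voxelToWorld(as.integer(ijk), statmap@affine)
            recs[[cl]] <- data.frame(
                sign = sgn, size = length(lin),
                size_mm3 = length(lin) * voxVol,
                peak_t = statmap@t[pk],
                peak_i = ijk[1L], peak_j = ijk[2L], peak_k = ijk[3L],
                mni_x = world[1L], mni_y = world[2L], mni_z = world[3L])
        }
        recs <- do.call(rbind, recs)
        ord <- order(-recs$size, recs$peak_i, recs$peak_j, recs$peak_k)
        rows[[sgn]] <- recs[ord, , drop = FALSE]
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(sign = character(), size = integer(),
                   size_mm3 = numeric(), peak_t = numeric(),
                   peak_i = integer(), peak_j = integer(),
                   peak_k = integer(), mni_x = numeric(),
                   mni_y = numeric(), mni_z = numeric())
    out <- out[out$size >= minSize, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Configuration of the Monte-Carlo cluster-size null
#'
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @param fwhm assumed noise smoothness, FWHM mm (length 1 or 3).
#' @param voxelP per-voxel two-tailed level (default 0.05).
#' @param alpha corrected cluster-level alpha (default 0.05).
#' @param nIter Monte-Carlo iterations (default 1000, >= 100).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param seed integer RNG seed.
#' @return A list of class \code{"ClusterSimConfig"}.
#' @export
clusterSimConfig <- function(mask, fwhm = c(8, 8, 8), voxelP = 0.05,
                             alpha = 0.05, nIter = 1000L,
                             connectivity = 26L, seed = 1L) {
    if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
    stopifnot(is(mask, "BrainMask"), voxelP > 0, voxelP < 1,
              alpha > 0, alpha < 1, nIter >= 100L,
              connectivity %in% c(6L, 18L, 26L))
    structure(list(mask = mask, fwhm = fwhm, voxelP = voxelP,
                   alpha = alpha, nIter = as.integer(nIter),
                   connectivity = as.integer(connectivity),
                   seed = as.integer(seed)),
              class = "ClusterSimConfig")
}

#' Monte-Carlo null distribution of maximal cluster sizes
#'
#' AlphaSim-style simulation: per iteration the mask's bounding grid is
#' filled with i.i.d. standard Gaussian noise, smoothed to the configured
#' FWHM, re-standardized to zero mean / unit variance within the mask,
#' thresholded two-tailed at the \code{voxelP} normal quantile, and the
#' maximal supra-threshold connected-component size is recorded. The
#' resulting distribution of maxima calibrates a family-wise
#' cluster-extent threshold (slightly conservative relative to AlphaSim's
#' per-cluster frequency table).
#'
#' @param config a \code{\link{clusterSimConfig}}.
#' @return A \code{\linkS4class{NullClusterDistribution}}.
#' @export
simulateNullDistribution <- function(config) {
    stopifnot(inherits(config, "ClusterSimConfig"))
    mask <- config$mask
    sp <- dim(mask@data)
    vs <- .voxelSizes(mask@affine)
    sig <- .fwhmToSigmaVox(config$fwhm, vs)
    if (any(config$fwhm > 0) && any(2 * config$fwhm / vs > sp))
        warning("mask grid is small relative to the requested FWHM; ",
                "smoothed-noise clusters may be grid-limited")
    zc <- stats::qnorm(1 - config$voxelP / 2)
    inIdx <- which(mask@data)
    set.seed(config$seed)
    maxSizes <- integer(config$nIter)
    supraFractions <- numeric(config$nIter)
    doSmooth <- any(sig > 0)
    for (it in seq_len(config$nIter)) {
        arr <- array(stats::rnorm(prod(sp)), sp)
        if (doSmooth) arr <- .smoothArray(arr, sig)
        v <- arr[inIdx]
        v <- (v - mean(v)) / stats::sd(v)
        supra <- array(FALSE, sp)
        hit <- abs(v) > zc
        supraFractions[it] <- mean(hit)
        supra[inIdx] <- hit
        if (!any(hit)) {
            maxSizes[it] <- 0L
            next
        }
        lab <- .labelComponents(supra, config$connectivity)
        maxSizes[it] <- max(tabulate(lab[lab > 0L]))
    }
    new("NullClusterDistribution", maxSizes = maxSizes,
        supraFractions = supraFractions,
        config = config[setdiff(names(config), "mask")])
}

#' Corrected cluster-extent threshold from a Monte-Carlo null
#'
#' The smallest integer s such that the fraction of null iterations whose
#' maximal cluster reaches s is at most alpha; clusters of at least s
#' voxels then have family-wise corrected p <= alpha.
#'
#' @param dist a \code{\linkS4class{NullClusterDistribution}}.
#' @param alpha corrected level (default the config's alpha, else 0.05).
#' @return Minimum significant cluster size in voxels (>= 1).
#' @export
extentThreshold <- function(dist, alpha = NULL) {
    stopifnot(is(dist, "NullClusterDistribution"))
    if (is.null(alpha))
        alpha <- if (!is.null(dist@config$alpha)) dist@config$alpha else 0.05
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
    n <- length(dist@maxSizes)
    if (n < 1 / alpha)
        stop("need at least 1/alpha = ", ceiling(1 / alpha),
             " iterations for alpha = ", alpha)
    s <- 1L
    sizes <- dist@maxSizes
    while (mean(sizes >= s) > alpha) s <- s + 1L
    s
}

#' Cluster size in mm^3
#'
#' @param nVoxels cluster size in voxels (>= 0).
#' @param affine 4x4 voxel-to-world matrix; the voxel volume is the
#'   absolute determinant of its spatial 3x3 block.
#' @return Volume in mm^3.
#' @export
#' @examples
#' voxelsToMm3(389, defaultAffine())   # 10503 at 3 mm isotropic
voxelsToMm3 <- function(nVoxels, affine = defaultAffine()) {
    if (any(nVoxels < 0)) stop("'nVoxels' must be >= 0")
    nVoxels * abs(det(affine[1:3, 1:3]))
}

#' Estimate noise smoothness (FWHM) from a residual map
#'
#' Variance-of-gradients estimator: per axis,
#' \eqn{FWHM = \sqrt{8 \ln 2} \; / \sqrt{-4 \ln r}} voxel units, with r the
#' lag-1 spatial autocorrelation of the in-mask values along that axis
#' (converted to mm via the affine). For real-data use when the noise
#' smoothness entering \code{\link{simulateNullDistribution}} should be
#' estimated rather than assumed.
#'
#' @param arr 3D numeric array (e.g. residuals or a z map).
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @return FWHM per axis in mm (NA where autocorrelation is non-positive).
#' @export
estimateSmoothness <- function(arr, mask) {
    stopifnot(length(dim(arr)) == 3L, is(mask, "BrainMask"))
    sp <- dim(arr)
    vs <- .voxelSizes(mask@affine)
    out <- numeric(3L)
    v <- arr
    v[!mask@data] <- NA
    for (ax in 1:3) {
        idxA <- lapply(sp, seq_len)
        idxB <- idxA
        idxA[[ax]] <- seq_len(sp[ax] - 1L)
        idxB[[ax]] <- 1L + seq_len(sp[ax] - 1L)
        a <- do.call(`[`, c(list(v), idxA))
        b <- do.call(`[`, c(list(v), idxB))
        ok <- !is.na(a) & !is.na(b)
        r <- stats::cor(a[ok], b[ok])
        out[ax] <- if (is.finite(r) && r > 0)
            sqrt(8 * log(2)) / sqrt(-4 * log(r)) * vs[ax] else NA_real_
    }
    out
}
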