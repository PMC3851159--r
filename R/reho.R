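#' ReHo computation parameters
#'
#' @param K cubic neighborhood size in voxels: 27 (center + 26 face, edge
#'   and corner neighbors; the conventional choice), 19 (center + face +
#'   edge) or 7 (center + face).
#' @param tieCorrection logical: apply the tie correction to the Kendall's-W
#'   denominator (default FALSE, matching the classical uncorrected
#'   formula; ties always get midranks either way).
#' @param minNeighbors minimum number of in-mask neighborhood members
#'   (center included) required to emit a value (default \code{K}: full
#'   cubes only, so mask-edge voxels are flagged instead of computed with a
#'   truncated, edge-biased neighborhood). A permissive analysis may lower
#'   this, e.g. to 14.
#' @return A list of class \code{"ReHoParams"}.
#' @export
#' @examples
#' rehoParams()            # K = 27, strict full-cube neighborhoods
#' rehoParams(minNeighbors = 14)
rehoParams <- function(K = 27L, tieCorrection = FALSE, minNeighbors = K) {
    K <- as.integer(K)
    if (!K %in% c(7L, 19L, 27L))
        stop("'K' must be 7, 19 or 27")
    minNeighbors <- as.integer(minNeighbors)
    if (minNeighbors < 2L || minNeighbors > K)
        stop("'minNeighbors' must be in [2, K]")
    structure(list(K = K, tieCorrection = isTRUE(tieCorrection),
                   minNeighbors = minNeighbors),
              class = "ReHoParams")
}

## Neighborhood offset table for K in {7, 19, 27}: center + neighbors.
.neighborhoodOffsets <- function(K) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    ord <- rowSums(abs(g))
    switch(as.character(K),
           "7"  = g[ord <= 1L, , drop = FALSE],
           "19" = g[ord <= 2L, , drop = FALSE],
           "27" = g,
           stop("'K' must be 7, 19 or 27"))
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among K "judges" (time series) ranking n items (time points):
#' \deqn{W = \frac{12 \sum_i (R_i - \bar R)^2}{K^2 (n^3 - n)}}
#' where \eqn{R_i} is the sum across series of the rank of time point i and
#' \eqn{\bar R} their mean. W ranges from 0 (no agreement) to 1 (perfect
#' agreement). Ties receive midranks; with \code{tieCorrection} the
#' denominator is reduced by \eqn{K \sum_j T_j}, \eqn{T_j = \sum (t^3 - t)}
#' over the tie groups of series j. A set of all-constant series has
#' degenerate ranks: W is defined as 0 and a warning is issued.
#'
#' @param seriesSet numeric n x K matrix, one column per series.
#' @param tieCorrection logical (default FALSE).
#' @return W in [0, 1].
#' @export
#' @examples
#' x <- rnorm(20)
#' kendallsW(cbind(x, x, x))            # identical series: W = 1
#' kendallsW(cbind(1:10, 10:1))         # exactly reversed ranks: W = 0
kendallsW <- function(seriesSet, tieCorrection = FALSE) {
    X <- as.matrix(seriesSet)
    n <- nrow(X)
    K <- ncol(X)
    if (K < 2L) stop("need K >= 2 series")
    if (n < 3L) stop("need n >= 3 time points")
    nConst <- sum(apply(X, 2L, function(col) max(col) == min(col)))
    if (nConst > 0L)
        warning(nConst, " constant series: degenerate ranks",
                if (nConst == K) "; W defined as 0")
    if (nConst == K) return(0)
    R <- apply(X, 2L, rank)              # midranks on ties
    Ri <- rowSums(R)
    S <- sum((Ri - mean(Ri))^2)
    TT <- 0
    if (tieCorrection) {
        TT <- sum(apply(X, 2L, function(col) {
            t <- table(col)
            sum(t^3 - t)
        }))
    }
    denom <- K^2 * (n^3 - n) - K * TT
    if (denom <= 0) {
        warning("degenerate ranks (constant series); W defined as 0")
        return(0)
    }
    W <- 12 * S / denom
    min(max(W, 0), 1)
}

#' Voxel-wise regional-homogeneity (KCC) map
#'
#' For every in-mask voxel whose cubic neighborhood intersected with the
#' mask has at least \code{minNeighbors} members, the value is Kendall's W
#' over the member time series (the voxel itself plus its K - 1 nearest
#' neighbors). Voxels failing the neighborhood requirement are set to 0 and
#' flagged invalid; \code{\link{standardizeMap}} excludes them from the
#' whole-brain mean and SD.
#'
#' The effective K of a (permissive-mode) truncated neighborhood is its
#' in-mask member count; in the default strict mode only full-K cubes are
#' evaluated.
#'
#' @param vol a preprocessed \code{\linkS4class{Volume4D}} with >= 3 frames.
#' @param mask a \code{\linkS4class{BrainMask}} on the same grid.
#' @param params a \code{\link{rehoParams}}.
#' @return A raw \code{\linkS4class{ReHoMap}}.
#' @export
computeReHo <- function(vol, mask, params = rehoParams()) {
    stopifnot(is(vol, "Volume4D"), is(mask, "BrainMask"))
    sp <- dim(vol@data)[1:3]
    n <- dim(vol@data)[4L]
    if (!identical(sp, dim(mask@data)))
        stop("mask grid does not match the volume")
    if (n < 3L) stop("need >= 3 time points")
    if (!any(mask@data)) stop("empty mask")
    nv <- prod(sp)
    inIdx <- which(mask@data)
    Vin <- length(inIdx)

    ## membership table: for every in-mask voxel, the row (in the in-mask
    ## series matrix) of each cubic-neighborhood member, 0 if out of
    ## grid/mask
    rowOf <- integer(nv)
    rowOf[inIdx] <- seq_len(Vin)
    coords <- arrayInd(inIdx, sp)
    offs <- .neighborhoodOffsets(params$K)
    nbr <- matrix(0L, Vin, nrow(offs))
    for (o in seq_len(nrow(offs))) {
        nc1 <- coords[, 1L] + offs[o, 1L]
        nc2 <- coords[, 2L] + offs[o, 2L]
        nc3 <- coords[, 3L] + offs[o, 3L]
        ok <- nc1 >= 1L & nc1 <= sp[1L] & nc2 >= 1L & nc2 <= sp[2L] &
            nc3 >= 1L & nc3 <= sp[3L]
        lin <- nc1[ok] + sp[1L] * ((nc2[ok] - 1L) + sp[2L] * (nc3[ok] - 1L))
        nbr[ok, o] <- rowOf[lin]
    }

    Y <- matrix(vol@data, nv, n)[inIdx, , drop = FALSE]
    res <- .cppRehoMap(Y, nbr, params$minNeighbors, params$tieCorrection)

    cnt <- array(0, sp)
    cnt[inIdx] <- res$Keff
    valid <- mask@data & cnt >= params$minNeighbors
    W <- array(0, sp)
    W[inIdx] <- res$W
    W[!valid] <- 0
    if (res$nDegenerate > 0L)
        warning(res$nDegenerate,
                " voxel(s) with degenerate (constant) series; W set to 0")
    new("ReHoMap", data = W, affine = vol@affine, standardization = "raw",
        params = unclass(params), valid = valid)
}

#' Standardize a ReHo map across the brain
#'
#' \code{"divided_by_mean"} divides each voxel's KCC by the mean KCC over
#' the valid in-mask voxels, giving an in-mask mean of exactly 1 (the
#' classical normalization). \code{"zscore"} subtracts the valid-voxel mean
#' and divides by the SD, giving mean 0 / SD 1 (the transformation argued
#' to improve normality). Flagged (invalid) and out-of-mask voxels stay 0.
#'
#' @param map a raw \code{\linkS4class{ReHoMap}}.
#' @param mode \code{"divided_by_mean"} (default) or \code{"zscore"}.
#' @return A standardized \code{\linkS4class{ReHoMap}}.
#' @export
standardizeMap <- function(map, mode = c("divided_by_mean", "zscore")) {
    stopifnot(is(map, "ReHoMap"))
    mode <- match.arg(mode)
    if (map@standardization != "raw")
        stop("map is already standardized ('", map@standardization, "')")
    v <- map@data[map@valid]
    if (!length(v)) stop("no valid voxels to standardize over")
    out <- array(0, dim(map@data))
    if (mode == "divided_by_mean") {
        m <- mean(v)
        if (m <= .Machine$double.eps)
            stop("in-mask mean KCC is zero; cannot divide")
        out[map@valid] <- v / m
    } else {
        m <- mean(v)
        s <- stats::sd(v)
        if (!is.finite(s) || s <= .Machine$double.eps)
            stop("in-mask KCC is constant; cannot z-score")
        out[map@valid] <- (v - m) / s
    }
    new("ReHoMap", data = out, affine = map@affine,
        standardization = mode, params = map@params, valid = map@valid)
}
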