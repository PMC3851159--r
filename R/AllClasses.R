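#' @import methods
NULL

.checkAffine <- function(affine) {
    if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
        return("'affine' must be a 4x4 matrix")
    if (!all(is.finite(affine)))
        return("'affine' contains non-finite values")
    d <- det(affine)
    if (!is.finite(d) || abs(d) < .Machine$double.eps * 64)
        return("'affine' is not invertible")
    NULL
}

#' Volume4D: a subject's 4D BOLD time series
#'
#' Container for one subject's 4D functional image: the voxel grid
#' (x, y, z, t), the 4x4 voxel-to-world affine (world coordinates in mm,
#' MNI space for normalized data) and the repetition time in seconds.
#'
#' @slot data 4D numeric array, dimensions (x, y, z, t).
#' @slot affine 4x4 voxel-index-to-world-mm matrix (1-based voxel indices;
#'   index \code{c(1,1,1)} maps to \code{affine \%*\% c(0,0,0,1)}).
#' @slot tr repetition time, seconds per volume.
#' @aliases Volume4D
#' @exportClass Volume4D
setClass("Volume4D",
    representation(data = "array", affine = "matrix", tr = "numeric"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@data)
        if (length(d) != 4L)
            msg <- c(msg, "'data' must be a 4D array (x, y, z, t)")
        else {
            if (any(d[1:3] < 3L))
                msg <- c(msg, "all spatial dimensions must be >= 3")
            if (d[4L] < 2L)
                msg <- c(msg, "time dimension must be >= 2")
        }
        msg <- c(msg, .checkAffine(object@affine))
        if (length(object@tr) != 1L || !is.finite(object@tr) ||
            object@tr <= 0)
            msg <- c(msg, "'tr' must be a single positive number")
        if (length(msg)) msg else TRUE
    })

#' BrainMask: 3D binary analysis mask
#'
#' A binary mask gating which voxels enter analysis, on the same grid and
#' affine as the functional volumes it is applied to.
#'
#' @slot data 3D logical array.
#' @slot affine 4x4 voxel-to-world matrix.
#' @aliases BrainMask
#' @exportClass BrainMask
setClass("BrainMask",
    representation(data = "array", affine = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "'data' must be a 3D array")
        if (!is.logical(object@data))
            msg <- c(msg, "'data' must be logical")
        if (!any(object@data))
            msg <- c(msg, "mask has no in-mask voxels")
        msg <- c(msg, .checkAffine(object@affine))
        if (length(msg)) msg else TRUE
    })

#' ReHoMap: voxel-wise regional-homogeneity map
#'
#' 3D map of Kendall's coefficient of concordance (KCC) values, raw
#' (in [0, 1]) or standardized. Voxels whose in-mask cubic neighborhood was
#' smaller than \code{minNeighbors} hold 0 and are marked invalid in
#' \code{valid}; they are excluded from the whole-brain statistics used by
#' \code{\link{standardizeMap}}.
#'
#' @slot data 3D numeric array of KCC values.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot standardization one of \code{"raw"}, \code{"divided_by_mean"},
#'   \code{"zscore"}.
#' @slot params the \code{\link{rehoParams}} list used.
#' @slot valid 3D logical array: in-mask voxels with a complete enough
#'   neighborhood to carry a KCC value.
#' @aliases ReHoMap
#' @exportClass ReHoMap
setClass("ReHoMap",
    representation(data = "array", affine = "matrix",
                   standardization = "character", params = "list",
                   valid = "array"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "'data' must be a 3D array")
        if (!object@standardization %in%
                c("raw", "divided_by_mean", "zscore"))
            msg <- c(msg, "unknown standardization mode")
        if (!identical(dim(object@data), dim(object@valid)))
            msg <- c(msg, "'valid' must match the shape of 'data'")
        if (object@standardization == "raw" && any(object@valid) &&
            (min(object@data[object@valid]) < -1e-9 ||
             max(object@data[object@valid]) > 1 + 1e-9))
            msg <- c(msg, "raw KCC values must lie in [0, 1]")
        msg <- c(msg, .checkAffine(object@affine))
        if (length(msg)) msg else TRUE
    })

#' StatMap: voxel-wise t-statistic map
#'
#' Result of a voxel-wise two-sample comparison: the t map, its degrees of
#' freedom and the ordered contrast (positive t means the first-listed group
#' has the higher mean).
#'
#' @slot t 3D numeric array of t statistics (0 outside the mask).
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot df residual degrees of freedom.
#' @slot contrast character(2), the ordered group pair.
#' @slot zeroVariance 3D logical array flagging in-mask voxels where the
#'   pooled variance was zero (t forced to 0).
#' @aliases StatMap
#' @exportClass StatMap
setClass("StatMap",
    representation(t = "array", affine = "matrix", df = "numeric",
                   contrast = "character", zeroVariance = "array"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@t)) != 3L)
            msg <- c(msg, "'t' must be a 3D array")
        if (length(object@df) != 1L || object@df < 1)
            msg <- c(msg, "'df' must be a single value >= 1")
        if (length(object@contrast) != 2L)
            msg <- c(msg, "'contrast' must name two groups")
        msg <- c(msg, .checkAffine(object@affine))
        if (length(msg)) msg else TRUE
    })

#' NullClusterDistribution: Monte-Carlo null of maximal cluster sizes
#'
#' One maximal supra-threshold cluster size per Monte-Carlo iteration of
#' smoothed Gaussian noise in the analysis mask, used by
#' \code{\link{extentThreshold}} to calibrate the corrected cluster-extent
#' threshold.
#'
#' @slot maxSizes integer vector, length = number of iterations.
#' @slot supraFractions numeric vector: per-iteration fraction of in-mask
#'   voxels exceeding the voxel-level threshold (calibration diagnostic).
#' @slot config echo of the \code{\link{clusterSimConfig}} used.
#' @aliases NullClusterDistribution
#' @exportClass NullClusterDistribution
setClass("NullClusterDistribution",
    representation(maxSizes = "integer", supraFractions = "numeric",
                   config = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@maxSizes) < 1L)
            msg <- c(msg, "empty distribution")
        if (any(object@maxSizes < 0L))
            msg <- c(msg, "cluster sizes must be >= 0")
        if (length(object@supraFractions) != length(object@maxSizes))
            msg <- c(msg, "'supraFractions' must match 'maxSizes' length")
        if (length(msg)) msg else TRUE
    })

#' CohortSpec: specification of a synthetic BOLD cohort
#'
#' Describes a cohort of simulated resting-state scans: group sizes,
#' acquisition length and TR, the analysis mask, synchronized regions with
#' per-group synchrony weights, drift and noise amplitudes and the signal
#' passband. Constructed with \code{\link{cohortSpec}}.
#'
#' @slot groups named integer vector: subjects per group.
#' @slot nVolumes number of volumes acquired per subject.
#' @slot tr repetition time (s).
#' @slot mask a \code{BrainMask}.
#' @slot regions list of region specifications (see \code{\link{regionSpec}}).
#' @slot driftAmplitude linear drift over the whole scan, arbitrary units.
#' @slot noiseSd SD of the per-voxel white noise.
#' @slot passband numeric(2), shared-signal band (Hz).
#' @slot seed master integer seed.
#' @aliases CohortSpec
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(groups = "integer", nVolumes = "integer", tr = "numeric",
                   mask = "BrainMask", regions = "list",
                   driftAmplitude = "numeric", noiseSd = "numeric",
                   passband = "numeric", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (is.null(names(object@groups)) || any(!nzchar(names(object@groups))))
            msg <- c(msg, "'groups' must be a named vector")
        if (any(object@groups < 2L))
            msg <- c(msg, "each group needs >= 2 subjects")
        if (object@nVolumes < 32L)
            msg <- c(msg, "'nVolumes' must be >= 32")
        if (object@tr <= 0)
            msg <- c(msg, "'tr' must be positive")
        nyq <- 1 / (2 * object@tr)
        if (length(object@passband) != 2L ||
            object@passband[1L] < 0 ||
            object@passband[1L] >= object@passband[2L] ||
            object@passband[2L] >= nyq)
            msg <- c(msg, sprintf(
                "passband must satisfy 0 <= low < high < Nyquist (%.4f Hz)",
                nyq))
        sp <- dim(object@mask@data)
        for (r in object@regions) {
            vox <- r$voxels
            if (any(vox < 1L) || any(vox > matrix(sp, nrow(vox), 3L,
                                                  byrow = TRUE)))
                msg <- c(msg, sprintf("region '%s' has out-of-grid voxels",
                                      r$label))
            else if (!all(object@mask@data[vox]))
                msg <- c(msg, sprintf("region '%s' has voxels outside the mask",
                                      r$label))
            w <- r$syncWeights
            if (any(w < 0 | w > 1))
                msg <- c(msg, sprintf("region '%s' weights must be in [0, 1]",
                                      r$label))
        }
        if (length(msg)) msg else TRUE
    })
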