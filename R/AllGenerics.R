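#' Accessors for rehopipe image classes
#'
#' \code{imgData} returns the voxel array; \code{imgAffine} the 4x4
#' voxel-to-world matrix; \code{repetitionTime} the TR in seconds;
#' \code{standardization} the standardization mode of a \code{ReHoMap};
#' \code{validVoxels} the logical array of voxels carrying a computed value.
#'
#' @param x a \code{Volume4D}, \code{BrainMask}, \code{ReHoMap} or
#'   \code{StatMap}.
#' @return \code{imgData}: an array; \code{imgAffine}: a 4x4 matrix;
#'   \code{repetitionTime}: a number (seconds); \code{standardization}: a
#'   string; \code{validVoxels}: a logical array.
#' @name accessors
#' @examples
#' vol <- Volume4D(array(rnorm(4^3 * 8), c(4, 4, 4, 8)))
#' dim(imgData(vol))
#' repetitionTime(vol)
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("standardization",
           function(x) standardGeneric("standardization"))
#' @rdname accessors
#' @export
setGeneric("validVoxels", function(x) standardGeneric("validVoxels"))

#' @rdname accessors
#' @export
setMethod("imgData", "Volume4D", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("imgData", "BrainMask", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("imgData", "ReHoMap", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("imgData", "StatMap", function(x) x@t)

#' @rdname accessors
#' @export
setMethod("imgAffine", "Volume4D", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("imgAffine", "BrainMask", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("imgAffine", "ReHoMap", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("imgAffine", "StatMap", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("repetitionTime", "Volume4D", function(x) x@tr)

#' @rdname accessors
#' @export
setMethod("standardization", "ReHoMap", function(x) x@standardization)

#' @rdname accessors
#' @export
setMethod("validVoxels", "ReHoMap", function(x) x@valid)

setMethod("show", "Volume4D", function(object) {
    d <- dim(object@data)
    vs <- .voxelSizes(object@affine)
    cat(sprintf("Volume4D: %d x %d x %d grid, %d volumes\n",
                d[1L], d[2L], d[3L], d[4L]))
    cat(sprintf("  voxel size: %.2f x %.2f x %.2f mm, TR = %g s\n",
                vs[1L], vs[2L], vs[3L], object@tr))
})

setMethod("show", "BrainMask", function(object) {
    d <- dim(object@data)
    cat(sprintf("BrainMask: %d x %d x %d grid, %d in-mask voxels\n",
                d[1L], d[2L], d[3L], sum(object@data)))
})

setMethod("show", "ReHoMap", function(object) {
    d <- dim(object@data)
    v <- object@data[object@valid]
    cat(sprintf("ReHoMap (%s): %d x %d x %d grid\n",
                object@standardization, d[1L], d[2L], d[3L]))
    if (length(v))
        cat(sprintf("  %d valid voxels, mean %.4f, sd %.4f\n",
                    length(v), mean(v), stats::sd(v)))
})

setMethod("show", "StatMap", function(object) {
    d <- dim(object@t)
    cat(sprintf("StatMap [%s - %s]: %d x %d x %d grid, df = %g\n",
                object@contrast[1L], object@contrast[2L],
                d[1L], d[2L], d[3L], object@df))
    cat(sprintf("  t range: [%.3f, %.3f], %d zero-variance voxels\n",
                min(object@t), max(object@t), sum(object@zeroVariance)))
})

setMethod("show", "NullClusterDistribution", function(object) {
    cat(sprintf(
        "NullClusterDistribution: %d iterations, max-cluster median %g (IQR %g-%g)\n",
        length(object@maxSizes), stats::median(object@maxSizes),
        stats::quantile(object@maxSizes, 0.25),
        stats::quantile(object@maxSizes, 0.75)))
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf("CohortSpec: %s; %d volumes, TR %g s, band %g-%g Hz\n",
                paste(sprintf("%s=%d", names(object@groups), object@groups),
                      collapse = ", "),
                object@nVolumes, object@tr,
                object@passband[1L], object@passband[2L]))
    cat(sprintf("  %d region(s), drift %g, noise sd %g, seed %d\n",
                length(object@regions), object@driftAmplitude,
                object@noiseSd, object@seed))
})
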