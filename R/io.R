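#' Read a 4D NIfTI time series
#'
#' Reads a NIfTI-1 volume, requiring 4 dimensions, and populates the grid,
#' the voxel-to-world affine (sform/qform as stored) and the repetition
#' time. Orientation is preserved exactly as stored; no resampling or
#' reorientation is performed.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param tr repetition time in seconds, used only when the header's time
#'   pixdim is absent or zero; an error is raised if neither source
#'   provides it.
#' @return A \code{\linkS4class{Volume4D}}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume4D(Volume4D(array(rnorm(4^3 * 6), c(4, 4, 4, 6))), f)
#' vol <- readVolume4D(f)
#' dim(imgData(vol))
readVolume4D <- function(path, tr = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L)
        stop("not a 4D time series: '", path, "' has ", length(d),
             " dimensions")
    hdr <- RNifti::niftiHeader(img)
    trHdr <- hdr$pixdim[5L]
    ## temporal unit bits of xyzt_units: 8 = s, 16 = ms, 24 = us, 0 = unknown
    tUnit <- bitwAnd(as.integer(hdr$xyzt_units), 56L)
    trHdr <- switch(as.character(tUnit),
                    "8" = trHdr, "16" = trHdr / 1e3, "24" = trHdr / 1e6,
                    NA_real_)
    if (is.na(trHdr) || trHdr <= 0) {
        if (is.null(tr))
            stop("no repetition time (or no time unit) in the header of '",
                 path, "'; supply 'tr' explicitly")
        trHdr <- tr
    }
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = dim(aff))
    Volume4D(array(as.numeric(img), d), affine = aff, tr = trHdr)
}

#' Write a Volume4D as NIfTI-1
#'
#' @param vol a \code{\linkS4class{Volume4D}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume4D <- function(vol, path) {
    stopifnot(is(vol, "Volume4D"))
    img <- RNifti::asNifti(vol@data)
    img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
    img$pixdim <- c(1, .voxelSizes(vol@affine), vol@tr, 0, 0, 0)
    img$xyzt_units <- 10L   # mm + s
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read / write a 3D binary brain mask
#'
#' Any non-zero voxel is in-mask. The mask must share grid and affine with
#' the functional volumes it gates; no resampling is performed.
#'
#' @param path path to a 3D NIfTI file.
#' @return \code{readBrainMask}: a \code{\linkS4class{BrainMask}}.
#' @export
readBrainMask <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("mask must be 3D: '", path, "' has ", length(d), " dimensions")
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = dim(aff))
    BrainMask(array(as.numeric(img), d), affine = aff)
}

## 3D scalar map writer (ReHo / t maps) sharing the volume conventions.
.writeMap3D <- function(data, affine, path) {
    img <- RNifti::asNifti(array(as.numeric(data), dim(data)))
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    img$pixdim <- c(1, .voxelSizes(affine), 0, 0, 0, 0)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname readBrainMask
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @export
writeBrainMask <- function(mask, path) {
    stopifnot(is(mask, "BrainMask"))
    img <- RNifti::asNifti(array(as.integer(mask@data), dim(mask@data)))
    img <- RNifti::`sform<-`(img, structure(mask@affine, code = 2L))
    img$pixdim <- c(1, .voxelSizes(mask@affine), 0, 0, 0, 0)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Convert between voxel indices and world (mm) coordinates
#'
#' Voxel indices are 1-based (R convention); index \code{c(1, 1, 1)} maps to
#' the affine's translation column. World coordinates are whatever the
#' affine encodes -- MNI mm for spatially normalized data.
#'
#' @param index integer triple (or n x 3 matrix) of 1-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dim optional grid dimensions; when given, out-of-bounds indices
#'   raise an error.
#' @return \code{voxelToWorld}: world coordinates (triple or n x 3 matrix).
#' @export
#' @examples
#' voxelToWorld(c(1, 1, 1), defaultAffine())   # the origin translation
#' voxelToWorld(c(2, 1, 1), defaultAffine())   # one 3 mm step in x
voxelToWorld <- function(index, affine, dim = NULL) {
    ix <- if (is.matrix(index)) index else matrix(index, 1L)
    if (ncol(ix) != 3L)
        stop("'index' must be a triple or an n x 3 matrix")
    if (any(ix < 1L))
        stop("voxel indices are 1-based; got index < 1")
    if (!is.null(dim) &&
        any(ix > matrix(dim[1:3], nrow(ix), 3L, byrow = TRUE)))
        stop("voxel index out of grid bounds")
    w <- cbind(ix - 1, 1) %*% t(affine)
    w <- w[, 1:3, drop = FALSE]
    if (is.matrix(index)) w else drop(w)
}

#' @rdname voxelToWorld
#' @param world numeric triple (or n x 3 matrix) of world mm coordinates.
#' @return \code{worldToVoxel}: continuous 1-based voxel indices (round to
#'   get grid indices).
#' @export
worldToVoxel <- function(world, affine) {
    w <- if (is.matrix(world)) world else matrix(world, 1L)
    v <- cbind(w, 1) %*% t(solve(affine))
    v <- v[, 1:3, drop = FALSE] + 1
    if (is.matrix(world)) v else drop(v)
}

#' Read a cohort design table
#'
#' CSV with header \code{id,group,age,gender,education,hama}: subject id,
#' group label, age (years), gender, education (years) and Hamilton anxiety
#' score.
#'
#' @param path CSV path.
#' @return data.frame with one row per subject, ids as character, group and
#'   gender as factors.
#' @export
readDesignTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "group", "age", "gender", "education", "hama")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop("design table lacks column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(d) == 0L)
        stop("no subjects in design table '", path, "'")
    if (anyDuplicated(d$id))
        stop("duplicate subject id(s): ",
             paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
    for (col in c("age", "education", "hama")) {
        bad <- which(is.na(suppressWarnings(as.numeric(d[[col]]))))
        if (length(bad))
            stop("non-numeric '", col, "' at data line(s) ",
                 paste(bad, collapse = ", "))
        d[[col]] <- as.numeric(d[[col]])
    }
    d$id <- as.character(d$id)
    d$group <- factor(d$group)
    d$gender <- factor(d$gender)
    d
}

#' Read a rigid-body motion trace
#'
#' Whitespace-delimited 6-column realignment-parameter text (SPM
#' \code{rp_*.txt} dialect): 3 translations in mm followed by 3 rotations in
#' radians. Rotations are converted to degrees on read (a message notes the
#' conversion), matching the degree-based motion exclusion rule.
#'
#' @param path text file path.
#' @param rotationUnit unit of the rotation columns in the file:
#'   \code{"radians"} (SPM convention, default) or \code{"degrees"}.
#' @return data.frame with columns \code{tx, ty, tz} (mm) and
#'   \code{rx, ry, rz} (degrees), one row per volume.
#' @export
readMotionTrace <- function(path, rotationUnit = c("radians", "degrees")) {
    rotationUnit <- match.arg(rotationUnit)
    if (!file.exists(path))
        stop("file not found: ", path)
    m <- tryCatch(as.matrix(utils::read.table(path)),
                  error = function(e) stop("cannot parse motion file '",
                                           path, "': ", conditionMessage(e)))
    if (ncol(m) != 6L)
        stop("motion file must have 6 columns (3 translations mm, ",
             "3 rotations); '", path, "' has ", ncol(m))
    if (nrow(m) < 2L)
        stop("motion trace needs >= 2 volumes")
    if (!is.numeric(m))
        stop("non-numeric values in motion file '", path, "'")
    rot <- m[, 4:6, drop = FALSE]
    if (rotationUnit == "radians") {
        rot <- rot * 180 / pi
        message("motion trace '", basename(path),
                "': rotations converted from radians to degrees")
    }
    out <- data.frame(tx = m[, 1L], ty = m[, 2L], tz = m[, 3L],
                      rx = rot[, 1L], ry = rot[, 2L], rz = rot[, 3L])
    out
}

#' Write a motion trace in SPM rp_*.txt form
#'
#' @param trace data.frame as returned by \code{\link{readMotionTrace}}
#'   (rotations in degrees); written with rotations in radians.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMotionTrace <- function(trace, path) {
    m <- cbind(trace$tx, trace$ty, trace$tz,
               trace$rx * pi / 180, trace$ry * pi / 180,
               trace$rz * pi / 180)
    utils::write.table(format(m, digits = 10, scientific = FALSE),
                       path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
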