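#' Preprocessing configuration
#'
#' Defaults follow the standard post-alignment resting-state chain:
#' discard the first 10 volumes, reject subjects exceeding 1 mm maximum
#' displacement or 1 degree of rotation, smooth with an 8 mm isotropic
#' FWHM Gaussian, remove the linear trend, and band-pass to 0.01-0.08 Hz.
#'
#' @param nDiscard initial volumes to discard (default 10).
#' @param maxTranslation motion-QC translation limit, mm (default 1);
#'   exceeding it strictly (\code{> 1}) fails QC.
#' @param maxRotation motion-QC rotation limit, degrees (default 1).
#' @param fwhm Gaussian smoothing FWHM, mm, length 1 or 3 (default 8).
#' @param passband band-pass limits in Hz (default \code{c(0.01, 0.08)}).
#' @param smoothStage when to smooth: \code{"before_reho"} (smooth the time
#'   series, the conventional order), \code{"after_reho"} (smooth the KCC
#'   map instead, avoiding inflation of local concordance) or \code{"off"}.
#' @param renormalizeAtMask logical: divide smoothed frames by the smoothed
#'   mask to undo zero-padding attenuation at the mask edge (default FALSE).
#' @return A list of class \code{"PreprocConfig"}.
#' @export
#' @examples
#' preprocConfig(fwhm = 6)
preprocConfig <- function(nDiscard = 10L, maxTranslation = 1,
                          maxRotation = 1, fwhm = c(8, 8, 8),
                          passband = c(0.01, 0.08),
                          smoothStage = c("before_reho", "after_reho",
                                          "off"),
                          renormalizeAtMask = FALSE) {
    smoothStage <- match.arg(smoothStage)
    if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
    stopifnot(nDiscard >= 0, maxTranslation > 0, maxRotation > 0,
              all(fwhm >= 0), length(passband) == 2L,
              passband[1L] >= 0, passband[1L] < passband[2L])
    structure(list(nDiscard = as.integer(nDiscard),
                   maxTranslation = maxTranslation,
                   maxRotation = maxRotation, fwhm = fwhm,
                   passband = passband, smoothStage = smoothStage,
                   renormalizeAtMask = renormalizeAtMask),
              class = "PreprocConfig")
}

#' Head-motion quality control
#'
#' A subject fails QC iff the maximum displacement from the first retained
#' volume exceeds \code{maxTranslation} mm on any translation axis, or the
#' analogous rotation excess exceeds \code{maxRotation} degrees. The
#' comparison is strict: a worst displacement of exactly 1 mm / 1 degree
#' passes. Displacement is cumulative from the reference volume, not
#' frame-to-frame.
#'
#' @param trace motion data.frame (see \code{\link{readMotionTrace}}),
#'   one row per acquired volume.
#' @param config a \code{\link{preprocConfig}}; its \code{nDiscard} rows are
#'   dropped from the head of the trace before QC so that the reference is
#'   the first retained volume.
#' @return list(pass = logical, worstTranslation = mm, worstRotation =
#'   degrees).
#' @export
#' @examples
#' tr0 <- data.frame(tx = c(0, 0.5), ty = 0, tz = 0,
#'                   rx = 0, ry = 0, rz = 0)
#' motionQC(tr0, preprocConfig(nDiscard = 0))
motionQC <- function(trace, config = preprocConfig()) {
    m <- as.matrix(trace[, c("tx", "ty", "tz", "rx", "ry", "rz")])
    if (config$nDiscard > 0L) {
        if (nrow(m) <= config$nDiscard)
            stop("motion trace shorter than the number of discarded volumes")
        m <- m[-seq_len(config$nDiscard), , drop = FALSE]
    }
    if (nrow(m) < 2L)
        stop("motion trace needs >= 2 retained volumes")
    disp <- abs(sweep(m, 2L, m[1L, ]))
    worstT <- max(disp[, 1:3])
    worstR <- max(disp[, 4:6])
    list(pass = !(worstT > config$maxTranslation ||
                  worstR > config$maxRotation),
         worstTranslation = worstT, worstRotation = worstR)
}

#' Discard initial volumes
#'
#' Drops the first \code{nDiscard} time points (signal-equilibration frames);
#' remaining frames are unchanged.
#'
#' @param vol a \code{\linkS4class{Volume4D}}.
#' @param nDiscard number of initial volumes to drop.
#' @return A \code{\linkS4class{Volume4D}} with \code{t - nDiscard} frames.
#' @export
discardInitial <- function(vol, nDiscard = 10L) {
    stopifnot(is(vol, "Volume4D"))
    nDiscard <- as.integer(nDiscard)
    if (nDiscard < 0L) stop("'nDiscard' must be >= 0")
    if (nDiscard == 0L) return(vol)
    nt <- dim(vol@data)[4L]
    if (nt <= nDiscard + 1L)
        stop("too few volumes: ", nt, " acquired, cannot discard ",
             nDiscard)
    Volume4D(vol@data[, , , -seq_len(nDiscard), drop = FALSE],
             affine = vol@affine, tr = vol@tr)
}

#' Spatial Gaussian smoothing
#'
#' Convolves every frame with a separable Gaussian of
#' \code{sigma = fwhm / (2 * sqrt(2 * log(2)))} per axis, FWHM given in mm
#' and converted to voxels through the affine scales. Zero padding outside
#' the grid; total in-frame intensity is conserved away from boundaries.
#' Requires an axis-aligned (shear-free) affine.
#'
#' @param vol a \code{\linkS4class{Volume4D}}.
#' @param fwhm FWHM in mm, length 1 or 3.
#' @param mask optional \code{\linkS4class{BrainMask}}; with
#'   \code{renormalize = TRUE} smoothed frames are divided by the smoothed
#'   mask inside the mask, undoing edge attenuation.
#' @param renormalize logical (default FALSE).
#' @return A smoothed \code{\linkS4class{Volume4D}}.
#' @export
smoothGaussian <- function(vol, fwhm = c(8, 8, 8), mask = NULL,
                           renormalize = FALSE) {
    stopifnot(is(vol, "Volume4D"))
    if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
    if (any(fwhm < 0)) stop("'fwhm' components must be >= 0")
    if (all(fwhm == 0)) return(vol)
    .checkAxisAligned(vol@affine)
    sig <- .fwhmToSigmaVox(fwhm, .voxelSizes(vol@affine))
    out <- .smoothArray(vol@data, sig)
    if (renormalize) {
        if (is.null(mask))
            stop("'renormalize = TRUE' requires a mask")
        sm <- .smoothArray(array(as.numeric(mask@data), dim(mask@data)),
                           sig)
        w <- which(mask@data & sm > 1e-6)
        nt <- dim(out)[4L]
        nv <- prod(dim(mask@data))
        for (t in seq_len(nt))
            out[w + (t - 1L) * nv] <- out[w + (t - 1L) * nv] / sm[w]
    }
    Volume4D(out, affine = vol@affine, tr = vol@tr)
}

## Least-squares removal of intercept + slope from each column of Y (n x V).
.detrendMatrix <- function(Y) {
    n <- nrow(Y)
    X <- cbind(1, seq_len(n))
    B <- solve(crossprod(X), crossprod(X, Y))
    Y - X %*% B
}

#' Remove linear trends per voxel
#'
#' Per voxel, the least-squares line (intercept + slope over time) is
#' subtracted, leaving series with zero mean and zero linear trend.
#'
#' @param vol a \code{\linkS4class{Volume4D}} with at least 3 frames.
#' @param mask optional \code{\linkS4class{BrainMask}}; only in-mask voxels
#'   are detrended (others zeroed) when given.
#' @return A detrended \code{\linkS4class{Volume4D}}.
#' @export
detrendLinear <- function(vol, mask = NULL) {
    stopifnot(is(vol, "Volume4D"))
    d <- dim(vol@data)
    if (d[4L] < 3L) stop("detrending needs >= 3 time points")
    n <- d[4L]
    nv <- prod(d[1:3])
    Y <- t(matrix(vol@data, nv, n))       # n x V
    if (is.null(mask)) {
        Y <- .detrendMatrix(Y)
    } else {
        idx <- which(mask@data)
        Yd <- .detrendMatrix(Y[, idx, drop = FALSE])
        Y[] <- 0
        Y[, idx] <- Yd
    }
    Volume4D(array(t(Y), d), affine = vol@affine, tr = vol@tr)
}

## Ideal rectangular band-pass of the columns of Y (n x V) via the DFT.
## A bin is kept iff low - eps <= f <= high + eps, eps = 1e-9 Hz, with
## f the folded frequency min(k, n - k) / (n * tr). Output is real.
.bandpassSeries <- function(Y, passband, tr) {
    n <- nrow(Y)
    eps <- 1e-9
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) / (n * tr)
    keep <- f >= passband[1L] - eps & f <= passband[2L] + eps
    F <- stats::mvfft(Y)
    F[!keep, ] <- 0
    Re(stats::mvfft(F, inverse = TRUE)) / n
}

#' Ideal band-pass filter per voxel
#'
#' Rectangular frequency-domain filter: discrete-Fourier bins with
#' (folded) frequency inside \code{[low, high]} are retained, all others --
#' including the 0 Hz mean -- are zeroed. This is the filter of the
#' REST/DPARSF lineage; it is exactly idempotent.
#'
#' @param vol a \code{\linkS4class{Volume4D}}.
#' @param passband numeric(2) in Hz, \code{0 <= low < high < 1/(2 tr)}.
#' @param tr repetition time override in seconds (default: the volume's).
#' @param mask optional \code{\linkS4class{BrainMask}}; only in-mask voxels
#'   are filtered (others zeroed) when given.
#' @return A filtered \code{\linkS4class{Volume4D}}.
#' @export
#' @examples
#' vol <- Volume4D(array(rnorm(3^3 * 40), c(3, 3, 3, 40)), tr = 3)
#' filt <- bandpassFilter(vol, c(0.01, 0.08))
bandpassFilter <- function(vol, passband = c(0.01, 0.08), tr = NULL,
                           mask = NULL) {
    stopifnot(is(vol, "Volume4D"))
    if (is.null(tr)) tr <- vol@tr
    nyq <- 1 / (2 * tr)
    if (passband[1L] < 0 || passband[1L] >= passband[2L] ||
        passband[2L] >= nyq)
        stop(sprintf(
            "passband must satisfy 0 <= low < high < Nyquist (%.4f Hz)",
            nyq))
    d <- dim(vol@data)
    n <- d[4L]
    Y <- t(matrix(vol@data, prod(d[1:3]), n))
    if (is.null(mask)) {
        Y <- .bandpassSeries(Y, passband, tr)
    } else {
        idx <- which(mask@data)
        Yf <- .bandpassSeries(Y[, idx, drop = FALSE], passband, tr)
        Y[] <- 0
        Y[, idx] <- Yf
    }
    Volume4D(array(t(Y), d), affine = vol@affine, tr = vol@tr)
}

#' Run the default preprocessing chain on one subject
#'
#' Order: discard initial volumes, then (if \code{smoothStage ==
#' "before_reho"}) spatial smoothing, then linear detrending, then ideal
#' band-pass. Motion QC is a separate gate (\code{\link{motionQC}}) applied
#' by the pipeline before this function.
#'
#' @param vol a \code{\linkS4class{Volume4D}}.
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @param config a \code{\link{preprocConfig}}.
#' @return A preprocessed \code{\linkS4class{Volume4D}}.
#' @export
preprocessSubject <- function(vol, mask, config = preprocConfig()) {
    vol <- discardInitial(vol, config$nDiscard)
    if (config$smoothStage == "before_reho" && any(config$fwhm > 0))
        vol <- smoothGaussian(vol, config$fwhm, mask,
                              renormalize = config$renormalizeAtMask)
    vol <- detrendLinear(vol, mask)
    bandpassFilter(vol, config$passband, mask = mask)
}
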