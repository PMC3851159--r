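#' Specify a synchronized region of a synthetic cohort
#'
#' A region is a set of in-mask voxels that share one band-limited BOLD-like
#' signal; the mixing weight of that shared signal can differ by group,
#' which is how between-group regional-homogeneity differences are injected.
#'
#' @param label region name.
#' @param voxels integer n x 3 matrix of 1-based voxel indices.
#' @param syncWeights named numeric vector, group -> weight in [0, 1]; a
#'   group absent from the vector gets weight 0.
#' @return A list of class \code{"RegionSpec"}.
#' @export
#' @examples
#' regionSpec("block", as.matrix(expand.grid(5:9, 5:9, 5:9)),
#'            c(patient = 0.6, control = 0))
regionSpec <- function(label, voxels, syncWeights) {
    voxels <- as.matrix(voxels)
    storage.mode(voxels) <- "integer"
    if (ncol(voxels) != 3L)
        stop("'voxels' must be an n x 3 matrix of voxel indices")
    if (is.null(names(syncWeights)))
        stop("'syncWeights' must be named by group")
    structure(list(label = as.character(label), voxels = voxels,
                   syncWeights = syncWeights),
              class = "RegionSpec")
}

#' Build a cuboid region
#'
#' Convenience wrapper over \code{\link{regionSpec}} for axis-aligned blocks.
#'
#' @param label region name.
#' @param from,to integer triples, inclusive corner indices.
#' @param syncWeights named numeric vector, group -> weight.
#' @return A \code{"RegionSpec"}.
#' @export
cuboidRegion <- function(label, from, to, syncWeights) {
    vox <- as.matrix(expand.grid(seq(from[1L], to[1L]),
                                 seq(from[2L], to[2L]),
                                 seq(from[3L], to[3L])))
    regionSpec(label, vox, syncWeights)
}

#' Specify a synthetic resting-state cohort
#'
#' Defaults follow a typical 1.5 T resting-state acquisition: TR 3 s and
#' 128 volumes (6 min 24 s), with spontaneous fluctuations confined to the
#' 0.01-0.08 Hz band.
#'
#' @param groups named integer vector of subjects per group (each >= 2).
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @param regions list of \code{\link{regionSpec}} objects.
#' @param nVolumes volumes acquired per subject (default 128).
#' @param tr repetition time in seconds (default 3).
#' @param driftAmplitude peak-to-peak linear scanner drift over the scan,
#'   in units of the noise SD (default 1).
#' @param noiseSd SD of the i.i.d. per-voxel noise (default 1).
#' @param passband numeric(2), Hz band of the shared signals
#'   (default 0.01-0.08).
#' @param seed master seed for the cohort.
#' @return A \code{\linkS4class{CohortSpec}}.
#' @export
#' @examples
#' mask <- ballMask(12, radius = 5)
#' spec <- cohortSpec(c(patient = 4, control = 4), mask,
#'                    nVolumes = 64, seed = 1)
#' spec
cohortSpec <- function(groups, mask, regions = list(), nVolumes = 128L,
                       tr = 3, driftAmplitude = 1, noiseSd = 1,
                       passband = c(0.01, 0.08), seed = 1L) {
    new("CohortSpec", groups = structure(as.integer(groups),
                                         names = names(groups)),
        nVolumes = as.integer(nVolumes), tr = as.numeric(tr), mask = mask,
        regions = regions, driftAmplitude = as.numeric(driftAmplitude),
        noiseSd = as.numeric(noiseSd), passband = as.numeric(passband),
        seed = as.integer(seed))
}

#' Spherical brain-like mask on a cubic grid
#'
#' @param n grid edge length (voxels).
#' @param radius ball radius in voxels (default centered, n/2 - 1).
#' @param affine voxel-to-world matrix (default 3 mm isotropic).
#' @return A \code{\linkS4class{BrainMask}}.
#' @export
ballMask <- function(n, radius = n / 2 - 1, affine = defaultAffine()) {
    ctr <- (n + 1) / 2
    g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
    inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= radius^2
    BrainMask(array(inside, c(n, n, n)), affine = affine)
}

## Band-limited standardized signal: white Gaussian noise filtered to the
## passband in the frequency domain, then scaled to mean 0 / SD 1.
.bandLimitedSignal <- function(n, tr, passband) {
    x <- stats::rnorm(n)
    y <- .bandpassSeries(matrix(x, ncol = 1L), passband, tr)
    y <- drop(y)
    s <- stats::sd(y)
    if (s < .Machine$double.eps)
        stop("degenerate band-limited signal; widen the passband")
    (y - mean(y)) / s
}

#' Generate one synthetic subject
#'
#' Each in-mask voxel's series is \code{w * s_r(t) + (1 - w) * eps_v(t) +
#' drift(t)}: \code{s_r} is a band-limited standardized signal shared by all
#' voxels of region r (w = the region's weight for this subject's group;
#' w = 0 outside all regions), \code{eps_v} is i.i.d. Gaussian noise per
#' voxel with SD \code{noiseSd}, and the drift is linear, spanning
#' \code{driftAmplitude} over the scan. Out-of-mask voxels are pure noise.
#' Fully reproducible from \code{(spec@seed, subjectSeed)}.
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @param group group label of the subject.
#' @param subjectSeed integer identifying the subject within the cohort.
#' @return A \code{\linkS4class{Volume4D}}.
#' @export
generateSubject <- function(spec, group, subjectSeed) {
    stopifnot(is(spec, "CohortSpec"))
    if (!group %in% names(spec@groups))
        stop("unknown group '", group, "'")
    sp <- dim(spec@mask@data)
    n <- spec@nVolumes
    set.seed(deriveSeed(spec@seed, 1L, subjectSeed))
    arr <- array(stats::rnorm(prod(sp) * n, sd = spec@noiseSd), c(sp, n))
    ## weight field: w per voxel (0 outside regions)
    wField <- array(0, sp)
    sigField <- array(0L, sp)   # which region's signal a voxel carries
    signals <- matrix(0, n, max(1L, length(spec@regions)))
    for (ri in seq_along(spec@regions)) {
        r <- spec@regions[[ri]]
        w <- r$syncWeights[group]
        if (is.na(w)) w <- 0
        wField[r$voxels] <- w
        sigField[r$voxels] <- ri
        signals[, ri] <- .bandLimitedSignal(n, spec@tr, spec@passband)
    }
    if (length(spec@regions)) {
        sel <- which(sigField > 0L & spec@mask@data)
        if (length(sel)) {
            ## out-of-mask region voxels were rejected by validity already
            w <- wField[sel]
            ri <- sigField[sel]
            ## series(sel, t) = w * s_ri(t) + (1 - w) * noise
            for (t in seq_len(n)) {
                idx <- sel + (t - 1L) * prod(sp)
                arr[idx] <- w * signals[t, ri] + (1 - w) * arr[idx]
            }
        }
    }
    if (spec@driftAmplitude != 0) {
        drift <- spec@driftAmplitude * (seq_len(n) - 1) / (n - 1)
        inIdx <- which(spec@mask@data)
        for (t in seq_len(n)) {
            idx <- inIdx + (t - 1L) * prod(sp)
            arr[idx] <- arr[idx] + drift[t]
        }
    }
    Volume4D(arr, affine = spec@mask@affine, tr = spec@tr)
}

## Small-amplitude random-walk motion trace (translations mm, rotations
## degrees); stepSd controls amplitude so QC pass and fail cases can both
## be generated.
.simulateMotion <- function(n, stepSd = 0.02, rotStepSd = 0.02) {
    data.frame(
        tx = cumsum(stats::rnorm(n, sd = stepSd)),
        ty = cumsum(stats::rnorm(n, sd = stepSd)),
        tz = cumsum(stats::rnorm(n, sd = stepSd)),
        rx = cumsum(stats::rnorm(n, sd = rotStepSd)),
        ry = cumsum(stats::rnorm(n, sd = rotStepSd)),
        rz = cumsum(stats::rnorm(n, sd = rotStepSd)))
}

#' Generate a full synthetic cohort
#'
#' Produces, per subject, the 4D volume (see \code{\link{generateSubject}}),
#' a synthetic head-motion trace (small-amplitude random walk) and a design
#' row with covariates drawn independently of group: age ~ U(20, 53),
#' education ~ U(9, 16) years, gender ~ Bernoulli(0.5), HAMA ~ U(0, 30)
#' (plus an optional per-group offset to create a confounded covariate).
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @param motionStepSd per-volume SD of the motion random walk (mm and
#'   degrees; default 0.02 keeps every subject well under the 1 mm / 1 deg
#'   exclusion rule).
#' @param highMotionSubjects character vector of subject ids to simulate
#'   with 50x the step SD, guaranteeing downstream motion-QC failure.
#' @param hamaGroupOffset optional named numeric: additive HAMA offset per
#'   group (a confounding knob; default none).
#' @return A list with elements \code{subjects} (named list of
#'   \code{volume}, \code{motion} per subject) and \code{design}
#'   (data.frame \code{id, group, age, gender, education, hama}).
#' @export
#' @examples
#' spec <- cohortSpec(c(A = 2, B = 2), ballMask(8, 3), nVolumes = 40,
#'                    seed = 7)
#' coh <- generateCohort(spec)
#' coh$design
generateCohort <- function(spec, motionStepSd = 0.02,
                           highMotionSubjects = character(),
                           hamaGroupOffset = NULL) {
    stopifnot(is(spec, "CohortSpec"))
    ids <- character()
    groupsOf <- character()
    k <- 0L
    for (g in names(spec@groups)) {
        for (i in seq_len(spec@groups[[g]])) {
            k <- k + 1L
            ids <- c(ids, sprintf("sub-%s-%02d", g, i))
            groupsOf <- c(groupsOf, g)
        }
    }
    unknown <- setdiff(highMotionSubjects, ids)
    if (length(unknown))
        stop("highMotionSubjects not in cohort: ",
             paste(unknown, collapse = ", "))
    subjects <- vector("list", length(ids))
    names(subjects) <- ids
    n <- spec@nVolumes
    for (k in seq_along(ids)) {
        vol <- generateSubject(spec, groupsOf[k], k)
        set.seed(deriveSeed(spec@seed, 2L, k))
        sd_k <- if (ids[k] %in% highMotionSubjects)
            motionStepSd * 50 else motionStepSd
        motion <- .simulateMotion(n, stepSd = sd_k, rotStepSd = sd_k)
        subjects[[k]] <- list(volume = vol, motion = motion)
    }
    set.seed(deriveSeed(spec@seed, 3L))
    m <- length(ids)
    hama <- round(stats::runif(m, 0, 30), 1)
    if (!is.null(hamaGroupOffset)) {
        off <- hamaGroupOffset[groupsOf]
        off[is.na(off)] <- 0
        hama <- hama + off
    }
    design <- data.frame(
        id = ids, group = groupsOf,
        age = round(stats::runif(m, 20, 53)),
        gender = sample(c("M", "F"), m, replace = TRUE),
        education = round(stats::runif(m, 9, 16)),
        hama = hama,
        stringsAsFactors = FALSE)
    list(subjects = subjects, design = design)
}

#' Write a synthetic cohort to disk in standard formats
#'
#' One NIfTI per subject (\code{<id>.nii.gz}), one SPM-style motion file
#' (\code{rp_<id>.txt}, rotations in radians), \code{mask.nii.gz} and
#' \code{design.csv} -- format-indistinguishable from a real preprocessed
#' cohort.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param mask the cohort's \code{\linkS4class{BrainMask}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, mask, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(cohort$subjects)) {
        s <- cohort$subjects[[id]]
        writeVolume4D(s$volume, file.path(dir, paste0(id, ".nii.gz")))
        writeMotionTrace(s$motion, file.path(dir, paste0("rp_", id, ".txt")))
    }
    writeBrainMask(mask, file.path(dir, "mask.nii.gz"))
    utils::write.csv(cohort$design, file.path(dir, "design.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory containing \code{design.csv},
#'   \code{mask.nii.gz}, \code{<id>.nii.gz} and \code{rp_<id>.txt}.
#' @return A list \code{subjects} / \code{design} / \code{mask}, matching
#'   the in-memory layout of \code{\link{generateCohort}}.
#' @export
readCohort <- function(dir) {
    design <- readDesignTable(file.path(dir, "design.csv"))
    mask <- readBrainMask(file.path(dir, "mask.nii.gz"))
    subjects <- vector("list", nrow(design))
    names(subjects) <- design$id
    for (id in design$id) {
        subjects[[id]] <- list(
            volume = readVolume4D(file.path(dir, paste0(id, ".nii.gz"))),
            motion = suppressMessages(
                readMotionTrace(file.path(dir, paste0("rp_", id, ".txt")))))
    }
    list(subjects = subjects, design = design, mask = mask)
}
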