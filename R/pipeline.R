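#' Assemble a full pipeline configuration
#'
#' Bundles every stage's parameters so a whole analysis is auditable in one
#' object; \code{\link{runPipeline}} echoes it into the run manifest.
#'
#' @param contrasts list of character(2) ordered group pairs to compare
#'   (e.g. \code{list(c("UD", "Control"), c("BD", "Control"),
#'   c("BD", "UD"))}).
#' @param preproc a \code{\link{preprocConfig}}.
#' @param reho a \code{\link{rehoParams}}.
#' @param standardization \code{"divided_by_mean"} (default) or
#'   \code{"zscore"}.
#' @param adjust covariate handling for \code{\link{voxelwiseTTest}}.
#' @param covariates covariate column names (used unless
#'   \code{adjust = "none"}).
#' @param voxelP per-voxel two-tailed level (default 0.05).
#' @param alpha corrected cluster-level alpha (default 0.05).
#' @param clusterFwhm assumed noise smoothness for the Monte-Carlo null
#'   (FWHM mm; default = the preprocessing smoothing kernel).
#' @param nIter Monte-Carlo iterations (default 1000).
#' @param connectivity cluster connectivity (default 26).
#' @param seed global seed; expanded into per-stage seeds with
#'   \code{\link{deriveSeed}}.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(contrasts,
                           preproc = preprocConfig(),
                           reho = rehoParams(),
                           standardization = c("divided_by_mean",
                                               "zscore"),
                           adjust = c("residualize", "ancova", "none"),
                           covariates = c("age", "gender", "education",
                                          "hama"),
                           voxelP = 0.05, alpha = 0.05,
                           clusterFwhm = NULL, nIter = 1000L,
                           connectivity = 26L, seed = 1L) {
    standardization <- match.arg(standardization)
    adjust <- match.arg(adjust)
    if (is.null(clusterFwhm)) clusterFwhm <- preproc$fwhm
    structure(list(contrasts = contrasts, preproc = preproc, reho = reho,
                   standardization = standardization, adjust = adjust,
                   covariates = covariates, voxelP = voxelP, alpha = alpha,
                   clusterFwhm = clusterFwhm, nIter = as.integer(nIter),
                   connectivity = as.integer(connectivity),
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the \code{\link{pipelineConfig}} and
#' \code{\link{preprocConfig}} / \code{\link{rehoParams}} arguments:
#' \code{contrasts} (list of 2-element lists), \code{preproc} (mapping),
#' \code{reho} (mapping), and the scalar options.
#'
#' @param path YAML file path.
#' @return A \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pre <- do.call(preprocConfig, as.list(y$preproc %||% list()))
    rh <- do.call(rehoParams, as.list(y$reho %||% list()))
    args <- y[setdiff(names(y), c("preproc", "reho", "contrasts"))]
    args$contrasts <- lapply(y$contrasts, unlist)
    args$preproc <- pre
    args$reho <- rh
    do.call(pipelineConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full regional-homogeneity group analysis
#'
#' End to end: head-motion QC (subjects exceeding the translation/rotation
#' limits are excluded and never consumed downstream), per-subject
#' preprocessing, KCC map computation and standardization, voxel-wise
#' covariate-adjusted two-sample t-tests for every configured contrast,
#' Monte-Carlo calibration of the cluster-extent threshold, and cluster
#' reporting. Deterministic given the config seed.
#'
#' @param cohort in-memory cohort (list with \code{subjects} and
#'   \code{design}, as from \code{\link{generateCohort}} or
#'   \code{\link{readCohort}}); give either this or \code{inputDir}.
#' @param mask a \code{\linkS4class{BrainMask}} (taken from the cohort if
#'   it carries one).
#' @param config a \code{\link{pipelineConfig}}.
#' @param inputDir cohort directory (see \code{\link{readCohort}}),
#'   alternative to \code{cohort}.
#' @param outDir optional output directory; when given, standardized maps
#'   and t maps are written as NIfTI, cluster tables as CSV and the
#'   manifest as JSON.
#' @param nullDistribution optional precomputed
#'   \code{\linkS4class{NullClusterDistribution}} for this mask/FWHM
#'   configuration; when NULL it is simulated here.
#' @return list with \code{rehoMaps} (standardized, per subject),
#'   \code{statMaps} and \code{clusterTables} (per contrast, named
#'   "A_vs_B"), \code{extentThresholdVoxels}, \code{qc} (per-subject QC
#'   table), \code{exclusions} (ids failing QC) and \code{manifest}.
#' @export
runPipeline <- function(cohort = NULL, mask = NULL, config,
                        inputDir = NULL, outDir = NULL,
                        nullDistribution = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (is.null(cohort)) {
        if (is.null(inputDir)) stop("give 'cohort' or 'inputDir'")
        cohort <- readCohort(inputDir)
    }
    if (is.null(mask)) mask <- cohort$mask
    if (is.null(mask)) stop("no mask given and none in the cohort")
    design <- cohort$design
    design$id <- as.character(design$id)
    design$group <- as.character(design$group)

    ## 1. motion QC gate
    qc <- do.call(rbind, lapply(design$id, function(id) {
        r <- motionQC(cohort$subjects[[id]]$motion, config$preproc)
        data.frame(id = id, pass = r$pass,
                   worst_translation_mm = r$worstTranslation,
                   worst_rotation_deg = r$worstRotation)
    }))
    excluded <- qc$id[!qc$pass]
    kept <- design[!design$id %in% excluded, , drop = FALSE]
    for (ct in config$contrasts) {
        for (g in ct) {
            if (sum(kept$group == g) < 2L)
                stop("group '", g, "' has < 2 subjects after motion QC (",
                     length(excluded), " excluded); aborting. Excluded: ",
                     paste(excluded, collapse = ", "))
        }
    }

    ## 2. preprocessing + ReHo per retained subject
    rehoMaps <- list()
    for (id in kept$id) {
        vol <- preprocessSubject(cohort$subjects[[id]]$volume, mask,
                                 config$preproc)
        raw <- computeReHo(vol, mask, config$reho)
        if (config$preproc$smoothStage == "after_reho" &&
            any(config$preproc$fwhm > 0)) {
            sm <- .smoothArray(raw@data,
                               .fwhmToSigmaVox(config$preproc$fwhm,
                                               .voxelSizes(raw@affine)))
            sm[!raw@valid] <- 0
            sm[sm < 0] <- 0
            sm[sm > 1] <- 1
            raw <- new("ReHoMap", data = sm, affine = raw@affine,
                       standardization = "raw", params = raw@params,
                       valid = raw@valid)
        }
        rehoMaps[[id]] <- standardizeMap(raw, config$standardization)
    }

    ## 3. cluster-extent calibration (depends only on mask/FWHM/seed)
    if (is.null(nullDistribution)) {
        simCfg <- clusterSimConfig(mask, fwhm = config$clusterFwhm,
                                   voxelP = config$voxelP,
                                   alpha = config$alpha,
                                   nIter = config$nIter,
                                   connectivity = config$connectivity,
                                   seed = deriveSeed(config$seed, 4L))
        nullDistribution <- simulateNullDistribution(simCfg)
    }
    extVox <- extentThreshold(nullDistribution, config$alpha)

    ## 4. contrasts
    statMaps <- list()
    clusterTables <- list()
    for (ct in config$contrasts) {
        key <- paste(ct, collapse = "_vs_")
        sm <- voxelwiseTTest(rehoMaps, kept, ct, mask,
                             adjust = config$adjust,
                             covariates = config$covariates)
        tc <- criticalT(config$voxelP, sm@df)
        tab <- labelClusters(sm, mask, tc,
                             connectivity = config$connectivity,
                             minSize = extVox)
        statMaps[[key]] <- sm
        clusterTables[[key]] <- tab
    }

    manifest <- list(
        package = as.character(utils::packageVersion("rehopipe")),
        seed = config$seed,
        n_subjects_input = nrow(design),
        n_subjects_analyzed = nrow(kept),
        excluded_by_motion_qc = as.list(excluded),
        preproc = unclass(config$preproc),
        reho = unclass(config$reho),
        standardization = config$standardization,
        adjust = config$adjust,
        covariates = config$covariates,
        voxel_p = config$voxelP,
        alpha = config$alpha,
        cluster_fwhm_mm = config$clusterFwhm,
        n_iter = config$nIter,
        connectivity = config$connectivity,
        extent_threshold_voxels = extVox,
        extent_threshold_mm3 = voxelsToMm3(extVox, mask@affine),
        contrasts = lapply(config$contrasts, as.list))

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        for (id in names(rehoMaps)) {
            m <- rehoMaps[[id]]
            .writeMap3D(m@data, m@affine,
                        file.path(outDir, paste0("reho_", id, ".nii.gz")))
        }
        for (key in names(statMaps)) {
            sm <- statMaps[[key]]
            .writeMap3D(sm@t, sm@affine,
                        file.path(outDir, paste0("tmap_", key, ".nii.gz")))
            utils::write.csv(renderClusterTable(clusterTables[[key]]),
                             file.path(outDir,
                                       paste0("clusters_", key, ".csv")),
                             row.names = FALSE)
        }
        utils::write.csv(qc, file.path(outDir, "motion_qc.csv"),
                         row.names = FALSE)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
    }

    list(rehoMaps = rehoMaps, statMaps = statMaps,
         clusterTables = clusterTables,
         nullDistribution = nullDistribution,
         extentThresholdVoxels = extVox, qc = qc,
         exclusions = excluded, manifest = manifest)
}

#' Render a publication-style cluster table
#'
#' Columns: sign, cluster size (voxels), peak T (signed: positive =
#' increase of ReHo in the first-listed group) and MNI X/Y/Z of the peak.
#' Increases are listed before decreases, each block sorted by descending
#' size.
#'
#' @param records cluster data.frame from \code{\link{labelClusters}}.
#' @return data.frame with columns \code{sign},
#'   \code{cluster_size_voxels}, \code{peak_T}, \code{mni_x},
#'   \code{mni_y}, \code{mni_z} (header-only when \code{records} is empty).
#' @export
renderClusterTable <- function(records) {
    out <- data.frame(sign = records$sign,
                      cluster_size_voxels = records$size,
                      peak_T = records$peak_t,
                      mni_x = records$mni_x, mni_y = records$mni_y,
                      mni_z = records$mni_z)
    ord <- order(records$sign != "increase", -records$size)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}
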