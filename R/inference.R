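#' Voxel-wise two-sample t-test on standardized ReHo maps
#'
#' Pooled-variance two-sample t at every in-mask voxel; positive t means the
#' first-listed group has the higher mean. Nuisance covariates (age, gender,
#' education, anxiety score, ...) can be handled two ways:
#' \describe{
#'   \item{\code{"residualize"}}{covariate effects are estimated across all
#'     subjects in one linear fit (intercept retained, so only the
#'     covariate part is removed) and the residualized maps are t-tested
#'     with df = n1 + n2 - 2 (default; mirrors "regress out nuisance
#'     covariates then compare").}
#'   \item{\code{"ancova"}}{the group coefficient is tested in a joint
#'     linear model with the covariates, df = n1 + n2 - 2 - p.}
#'   \item{\code{"none"}}{plain two-sample t.}
#' }
#' In-mask voxels with zero pooled variance get t = 0 and are flagged.
#'
#' @param maps named list of standardized \code{\linkS4class{ReHoMap}}s
#'   (names = subject ids).
#' @param design data.frame with columns \code{id}, \code{group} and any
#'   covariate columns (see \code{\link{readDesignTable}}).
#' @param contrast character(2): the ordered group pair to compare.
#' @param mask a \code{\linkS4class{BrainMask}}.
#' @param adjust \code{"none"}, \code{"residualize"} (default) or
#'   \code{"ancova"}.
#' @param covariates character vector of design columns to adjust for
#'   (default \code{c("age", "gender", "education", "hama")}); factor
#'   columns with two levels are coded 0/1.
#' @return A \code{\linkS4class{StatMap}}.
#' @export
voxelwiseTTest <- function(maps, design, contrast, mask,
                           adjust = c("residualize", "ancova", "none"),
                           covariates = c("age", "gender", "education",
                                          "hama")) {
    adjust <- match.arg(adjust)
    stopifnot(is(mask, "BrainMask"), length(contrast) == 2L)
    design$id <- as.character(design$id)
    sel <- design$group %in% contrast
    subj <- design[sel, , drop = FALSE]
    if (any(!subj$id %in% names(maps)))
        stop("no map for subject(s): ",
             paste(setdiff(subj$id, names(maps)), collapse = ", "))
    g1 <- subj$id[subj$group == contrast[1L]]
    g2 <- subj$id[subj$group == contrast[2L]]
    n1 <- length(g1)
    n2 <- length(g2)
    if (n1 < 2L || n2 < 2L)
        stop("each contrast group needs >= 2 subjects (got ",
             n1, " and ", n2, ")")
    ids <- c(g1, g2)
    sp <- dim(mask@data)
    idxIn <- which(mask@data)
    Y <- matrix(0, length(ids), length(idxIn))   # subjects x voxels
    aff <- NULL
    for (i in seq_along(ids)) {
        m <- maps[[ids[i]]]
        stopifnot(is(m, "ReHoMap"))
        if (!identical(dim(m@data), sp))
            stop("map grid mismatch for subject ", ids[i])
        if (is.null(aff)) aff <- m@affine
        Y[i, ] <- m@data[idxIn]
    }
    grp <- c(rep(1, n1), rep(0, n2))

    C <- NULL
    if (adjust != "none") {
        if (length(covariates) == 0L)
            stop("adjustment requested but no covariates given")
        rows <- subj[match(ids, subj$id), , drop = FALSE]
        C <- sapply(covariates, function(cn) {
            if (!cn %in% names(rows))
                stop("covariate '", cn, "' not in design")
            v <- rows[[cn]]
            if (is.factor(v) || is.character(v)) {
                f <- factor(v)
                if (nlevels(f) > 2L)
                    stop("covariate '", cn,
                         "' has > 2 levels; recode it numerically")
                as.numeric(f) - 1
            } else as.numeric(v)
        })
        C <- as.matrix(C)
        if (anyNA(C))
            stop("incomplete covariates for the adjusted model")
    }

    if (adjust == "ancova") {
        X <- cbind(1, grp, C)
        p <- ncol(X)
        df <- length(ids) - p
        if (df < 1L) stop("not enough subjects for the ancova model")
        XtXinv <- solve(crossprod(X))
        B <- XtXinv %*% crossprod(X, Y)
        res <- Y - X %*% B
        sigma2 <- colSums(res^2) / df
        se <- sqrt(sigma2 * XtXinv[2L, 2L])
        tvals <- ifelse(se > 0, B[2L, ] / ifelse(se > 0, se, 1), 0)
        zeroVar <- se <= 0
    } else {
        if (adjust == "residualize") {
            X <- cbind(1, C)
            B <- solve(crossprod(X), crossprod(X, Y))
            ## remove covariate part only; intercept retained
            Y <- Y - C %*% B[-1L, , drop = FALSE]
        }
        df <- n1 + n2 - 2L
        m1 <- colMeans(Y[seq_len(n1), , drop = FALSE])
        m2 <- colMeans(Y[n1 + seq_len(n2), , drop = FALSE])
        ss1 <- colSums(Y[seq_len(n1), , drop = FALSE]^2) - n1 * m1^2
        ss2 <- colSums(Y[n1 + seq_len(n2), , drop = FALSE]^2) - n2 * m2^2
        vp <- (ss1 + ss2) / df
        se <- sqrt(vp * (1 / n1 + 1 / n2))
        zeroVar <- se <= .Machine$double.eps * 64
        tvals <- ifelse(zeroVar, 0, (m1 - m2) / ifelse(zeroVar, 1, se))
    }
    tArr <- array(0, sp)
    tArr[idxIn] <- tvals
    zArr <- array(FALSE, sp)
    zArr[idxIn] <- zeroVar
    new("StatMap", t = tArr, affine = if (is.null(aff)) mask@affine else aff,
        df = as.numeric(df), contrast = as.character(contrast),
        zeroVariance = zArr)
}

#' Two-tailed critical t value
#'
#' The value c with \eqn{P(|T_{df}| > c) = \alpha}; e.g. alpha = 0.05 at
#' df = 30 gives 2.042.
#'
#' @param alpha two-tailed level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return The critical value.
#' @export
#' @examples
#' criticalT(0.05, 30)   # 2.042
criticalT <- function(alpha, df) {
    if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must be in (0, 1)")
    if (!is.finite(df) || df < 1)
        stop("'df' must be >= 1")
    stats::qt(1 - alpha / 2, df)
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Recovers the exact F statistic from per-group means, SDs and sizes:
#' SSB = sum n_j (xbar_j - xbar)^2, SSW = sum (n_j - 1) s_j^2, with
#' F = (SSB / (k - 1)) / (SSW / (N - k)). Useful for auditing published
#' demographic tables printed as mean +/- SD.
#'
#' @param means,sds,ns numeric vectors of equal length (>= 2 groups, each
#'   n >= 2).
#' @return list(F, dfBetween, dfWithin, p).
#' @export
#' @examples
#' anovaFromSummary(c(36.06, 34.47, 35.13), c(9.43, 9.77, 7.88),
#'                  c(16, 17, 16))
anovaFromSummary <- function(means, sds, ns) {
    k <- length(means)
    if (k < 2L || length(sds) != k || length(ns) != k)
        stop("need >= 2 groups with matching means/sds/ns")
    if (any(ns < 2)) stop("each group needs n >= 2")
    N <- sum(ns)
    grand <- sum(ns * means) / N
    ssb <- sum(ns * (means - grand)^2)
    ssw <- sum((ns - 1) * sds^2)
    df1 <- k - 1
    df2 <- N - k
    Fval <- (ssb / df1) / (ssw / df2)
    list(F = Fval, dfBetween = df1, dfWithin = df2,
         p = stats::pf(Fval, df1, df2, lower.tail = FALSE))
}

#' Pooled two-sample t-test from group summaries
#'
#' @param mean1,sd1,n1 first group's summary.
#' @param mean2,sd2,n2 second group's summary.
#' @return list(t, df, p) with p two-tailed.
#' @export
#' @examples
#' ttestFromSummary(4.38, 1.63, 16, 26.19, 4.98, 16)   # HAMD-style audit
ttestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
    df <- n1 + n2 - 2
    vp <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    if (vp <= 0) stop("zero pooled variance")
    tval <- (mean1 - mean2) / sqrt(vp * (1 / n1 + 1 / n2))
    list(t = tval, df = df,
         p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on a two-way count table, without continuity
#' correction, df = (r - 1)(c - 1).
#'
#' @param table matrix of non-negative counts with positive row and column
#'   margins.
#' @return list(chisq, df, p).
#' @export
#' @examples
#' chisqIndependence(rbind(c(8, 8), c(9, 8), c(8, 8)))
chisqIndependence <- function(table) {
    tab <- as.matrix(table)
    if (any(tab < 0)) stop("counts must be >= 0")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate margins (empty row or column)")
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chisq = unname(res$statistic), df = unname(res$parameter),
         p = unname(res$p.value))
}
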