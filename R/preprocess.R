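#' Filter proteins by detection share within fractions
#'
#' A protein is retained iff in at least one fraction the share of samples
#' in which it was detected is at least `threshold` (70% by default —
#' the usual "70% presence in at least one fraction" rule for label-free
#' data). Row order is preserved; the operation is idempotent.
#'
#' @param x a [ProteomeExperiment-class].
#' @param threshold detection share in (0, 1].
#' @return the filtered [ProteomeExperiment-class].
#' @export
filterByPresence <- function(x, threshold = 0.70) {
    stopifnot(threshold > 0, threshold <= 1)
    detected <- !missingMask(x)
    fr <- fractionLabels(x)
    share <- sapply(FRACTION_LEVELS, function(f) {
        idx <- which(fr == f)
        if (!length(idx)) return(rep(0, nrow(x)))
        rowMeans(detected[, idx, drop = FALSE])
    })
    # tolerance absorbs float division noise at exact-threshold shares
    keep <- apply(share >= threshold - 1e-12, 1L, any)
    if (!any(keep))
        stop("no protein passes the presence filter; lower the threshold")
    x[keep, ]
}

#' Impute left-censored missing values from a downshifted normal
#'
#' Replaces missing entries per sample column with draws from
#' Normal(mean_obs - downshift * sd_obs, (width * sd_obs)^2), where
#' mean_obs and sd_obs are that column's observed mean and sd. This is the
#' de-facto standard left-censored imputation for label-free proteomics:
#' non-detected proteins are assumed to sit below the sample's detection
#' limit, so imputed values are pulled into the low tail. Observed cells
#' are never altered; the missing mask is cleared.
#'
#' @param x a [ProteomeExperiment-class].
#' @param width imputation sd as a fraction of the column sd. Default 0.3.
#' @param downshift centre shift in column-sd multiples. Default 1.8.
#' @param seed integer seed (same seed reproduces the imputation).
#' @return an imputed [ProteomeExperiment-class] with an all-`FALSE` mask.
#' @export
imputeDownshiftedNormal <- function(x, width = 0.3, downshift = 1.8,
                                    seed = 1L) {
    vals <- intensityValues(x)
    mask <- missingMask(x)
    if (!any(mask)) return(x)
    n_obs <- colSums(!mask)
    if (any(n_obs < 2L))
        stop("column(s) with fewer than 2 observed values: ",
             paste(colnames(x)[n_obs < 2L], collapse = ", "))
    withr::with_seed(seed, {
        for (j in seq_len(ncol(vals))) {
            mj <- mask[, j]
            if (!any(mj)) next
            obs <- vals[!mj, j]
            vals[mj, j] <- stats::rnorm(sum(mj),
                                        mean = mean(obs) - downshift * stats::sd(obs),
                                        sd = width * stats::sd(obs))
        }
    })
    ProteomeExperiment(vals, fraction = fractionLabels(x),
                       subject = subjectIds(x),
                       missing = matrix(FALSE, nrow(vals), ncol(vals)))
}

#' Quantile-normalise sample columns
#'
#' Forces every sample column onto the common reference distribution (the
#' mean of the column-sorted values); ties within a column receive the
#' mean of the reference values at their tied ranks. Requires a fully
#' observed (imputed) matrix. Idempotent and rank-preserving within
#' columns.
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @return the normalised [ProteomeExperiment-class].
#' @export
quantileNormalizeIntensities <- function(x) {
    if (any(missingMask(x)))
        stop("quantile normalisation requires an imputed matrix (no missing values)")
    vals <- limma::normalizeQuantiles(intensityValues(x), ties = TRUE)
    dimnames(vals) <- dimnames(intensityValues(x))
    ProteomeExperiment(vals, fraction = fractionLabels(x),
                       subject = subjectIds(x),
                       missing = missingMask(x))
}

#' Sample QC: Spearman correlation, classical MDS and k-means
#'
#' Computes the sample-by-sample Spearman correlation matrix, embeds the
#' samples by classical multidimensional scaling (2 components on the
#' distance 1 - rho), partitions the embedding by k-means (seeded, 25
#' restarts), and flags outliers as samples whose median within-fraction
#' Spearman correlation falls below the lower Tukey fence (Q1 - 1.5 IQR)
#' of all such medians and sits at least 0.05 below their median. The
#' absolute margin keeps the fence from flagging healthy samples when the
#' medians are tightly clustered (a homogeneous run spreads them by about
#' 0.005, while a truly aberrant sample loses far more than 0.05 of rank
#' correlation). Cluster/fraction agreement is summarised by the adjusted
#' Rand index.
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @param k number of clusters; defaults to the number of fraction levels.
#' @param seed integer seed for k-means.
#' @return a `QcReport`: list with `spearman` (sample x sample matrix),
#'   `mds` (sample x 2 coordinates), `cluster` (named integer),
#'   `outliers` (character), `ari_vs_fraction` (numeric in [-1, 1]).
#' @export
qcCluster <- function(x, k = 3L, seed = 1L) {
    if (any(missingMask(x)))
        stop("qcCluster requires an imputed matrix")
    stopifnot(k <= ncol(x))
    vals <- intensityValues(x)
    if (any(apply(vals, 2L, stats::sd) == 0))
        stop("constant sample column: Spearman correlation undefined")
    rho <- stats::cor(vals, method = "spearman")
    d <- stats::as.dist(1 - rho)
    mds <- stats::cmdscale(d, k = 2L)
    colnames(mds) <- c("MDS1", "MDS2")
    km <- withr::with_seed(seed,
        stats::kmeans(mds, centers = k, nstart = 25L))
    cl <- setNames(km$cluster, colnames(x))

    fr <- fractionLabels(x)
    med_rho <- vapply(seq_len(ncol(x)), function(j) {
        same <- which(fr == fr[j] & seq_len(ncol(x)) != j)
        if (!length(same)) return(NA_real_)
        stats::median(rho[j, same])
    }, numeric(1))
    q <- stats::quantile(med_rho, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    fence <- q[1] - 1.5 * (q[2] - q[1])
    floor_rho <- stats::median(med_rho, na.rm = TRUE) - 0.05
    outliers <- colnames(x)[!is.na(med_rho) & med_rho < fence &
                            med_rho < floor_rho]

    structure(list(spearman = rho, mds = mds, cluster = cl,
                   outliers = outliers,
                   ari_vs_fraction = mclust::adjustedRandIndex(cl, fr)),
              class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
    cat(sprintf("QcReport: %d samples, %d clusters, ARI vs fraction = %.3f\n",
                nrow(x$spearman), length(unique(x$cluster)),
                x$ari_vs_fraction))
    cat(if (length(x$outliers))
            paste("outliers:", paste(x$outliers, collapse = ", "), "\n")
        else "no outliers flagged\n")
    invisible(x)
}
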