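#' Reduce an ELISA plate to relative units per subject
#'
#' Converts raw 450 nm absorbances to relative units (RU/mL) by
#' background subtraction and normalisation to the plate reference
#' standard: `RU = (A_sample - mean A_background) / (mean A_reference -
#' mean A_background)`. The lower detection limit (LOD) is the smallest
#' signal distinguishable from blank, operationalised as
#' `mean(blank RU) + 3 sd(blank RU)`; subjects below it are flagged
#' undetected.
#'
#' @param wells ELISA well data.frame (see [readElisaTable()]).
#' @return list with `samples` (data.frame: subject, group, fraction, ru,
#'   detected) and `lod`.
#' @export
reducePlate <- function(wells) {
    need <- c("uncoated_background", "blank", "reference_standard")
    for (r in need)
        if (!any(wells$role == r)) stop("plate has no ", r, " wells")
    bg <- mean(wells$absorbance[wells$role == "uncoated_background"])
    ref <- mean(wells$absorbance[wells$role == "reference_standard"])
    if (ref <= bg)
        stop("assay failure: reference standard does not exceed background")
    toRU <- function(a) (a - bg) / (ref - bg)
    blank_ru <- toRU(wells$absorbance[wells$role == "blank"])
    lod <- mean(blank_ru) + 3 * stats::sd(blank_ru)
    s <- wells[wells$role == "sample", ]
    out <- data.frame(subject = s$subject, group = s$group,
                      fraction = s$fraction, ru = toRU(s$absorbance),
                      stringsAsFactors = FALSE)
    out$detected <- out$ru >= lod
    list(samples = out, lod = lod)
}

# tie-corrected Kruskal-Wallis H from ranks (matches stats::kruskal.test)
.kwStatistic <- function(values, groups) {
    n <- length(values)
    r <- rank(values)
    rs <- tapply(r, groups, sum)
    ns <- tapply(r, groups, length)
    H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
    ties <- table(values)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr == 0) return(0)
    H / corr
}

#' Kruskal-Wallis test across labelled groups
#'
#' Tie-corrected H with a chi-squared p-value (via
#' [stats::kruskal.test()]); for small cohorts (total n <= 8, or on
#' request) an exact permutation p-value is additionally computed by
#' enumerating every assignment of the observations to the group sizes.
#'
#' @param values numeric vector.
#' @param groups parallel group labels (>= 2 groups, each non-empty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact enumeration;
#'   default `NULL` enumerates when total n <= 8.
#' @return list with `statistic` (H), `df`, `p` (chi-squared), and
#'   `p_exact` when enumerated.
#' @export
kruskalWallisGroups <- function(values, groups, exact = NULL) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
    if (any(table(groups) == 0L)) stop("empty group")
    n <- length(values)
    if (length(unique(values)) == 1L) {
        res <- list(statistic = 0, df = nlevels(groups) - 1L, p = 1)
    } else {
        kt <- stats::kruskal.test(values, groups)
        res <- list(statistic = unname(kt$statistic),
                    df = unname(kt$parameter), p = kt$p.value)
    }
    do_exact <- if (is.null(exact)) n <= 8L else isTRUE(exact)
    if (do_exact) {
        perms <- .groupAssignments(n, table(groups))
        h_obs <- .kwStatistic(values, groups)
        h_null <- vapply(perms, function(idx) {
            g <- factor(rep(levels(groups), table(groups))[order(idx)],
                        levels = levels(groups))
            .kwStatistic(values, g)
        }, numeric(1))
        res$p_exact <- mean(h_null >= h_obs - 1e-12)
    }
    res
}

# all assignments of 1..n to ordered group sizes; returns permutations of
# positions (each a vector placing observation i into slot idx[i])
.groupAssignments <- function(n, sizes) {
    recurse <- function(avail, sizes) {
        if (length(sizes) == 1L) return(list(avail))
        first <- utils::combn(avail, sizes[1L], simplify = FALSE)
        out <- list()
        for (f in first) {
            rest <- recurse(setdiff(avail, f), sizes[-1L])
            out <- c(out, lapply(rest, function(r) c(f, r)))
        }
        out
    }
    recurse(seq_len(n), as.integer(sizes))
}

#' AUC quality bin
#'
#' Classifies an AUC on the conventional scale: exactly 0.5 "not
#' discriminant"; (0.5, 0.6) "fail"; [0.6, 0.7) "poor"; [0.7, 0.8)
#' "fair"; [0.8, 0.9) "good"; [0.9, 1] "excellent". AUCs below 0.5 are
#' binned on the mirrored scale (1 - auc) with a "(reversed)" note.
#'
#' @param auc numeric in [0, 1].
#' @return the bin label.
#' @examples
#' aucQualityBin(0.86)  # "good"
#' @export
aucQualityBin <- function(auc) {
    stopifnot(auc >= 0, auc <= 1)
    if (auc == 0.5) return("not discriminant")
    rev <- auc < 0.5
    a <- if (rev) 1 - auc else auc
    bin <- if (a < 0.6) "fail" else if (a < 0.7) "poor" else
           if (a < 0.8) "fair" else if (a < 0.9) "good" else "excellent"
    if (rev) paste(bin, "(reversed)") else bin
}

#' Positive likelihood ratio
#'
#' `LR+ = sensitivity / (1 - specificity)`; `Inf` at perfect specificity.
#'
#' @param sensitivity,specificity values in [0, 1].
#' @return the positive likelihood ratio.
#' @examples
#' likelihoodRatioPositive(0.90, 0.70)  # 3
#' @export
likelihoodRatioPositive <- function(sensitivity, specificity) {
    stopifnot(sensitivity >= 0, sensitivity <= 1,
              specificity >= 0, specificity <= 1)
    if (specificity == 1) return(Inf)
    sensitivity / (1 - specificity)
}

# DeLong variance of the AUC (oriented so cases tend high)
.delongVariance <- function(cases, controls) {
    psi <- function(x, y) (x > y) + 0.5 * (x == y)
    V10 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
    V01 <- vapply(controls, function(y) mean(psi(cases, y)), numeric(1))
    stats::var(V10) / length(cases) + stats::var(V01) / length(controls)
}

#' ROC analysis with DeLong interval, Youden cutoff and likelihood ratios
#'
#' AUC from the Mann-Whitney identity (half credit for ties), oriented so
#' the reported AUC is at least 0.5: when cases run low the cutoff
#' direction is `<` (a value below the cutoff is called a case), otherwise
#' `>`. The confidence interval and the two-sided p-value against
#' AUC = 0.5 use the DeLong variance. The cutoff maximises Youden's
#' J = sensitivity + specificity - 1 over midpoints of adjacent observed
#' values, ties broken toward higher specificity.
#'
#' @param values numeric measurements (e.g. RU/mL).
#' @param is_case logical vector, `TRUE` for cases.
#' @param conf_level confidence level for the DeLong interval.
#'   Default 0.95.
#' @param n_boot if positive, adds a seeded percentile-bootstrap interval.
#' @param seed integer seed for the bootstrap.
#' @return a `RocResult`: list with `auc`, `ci_low`, `ci_high`, `p`,
#'   `cutoff`, `direction` (`"<"` or `">"`), `sensitivity`, `specificity`,
#'   `youden_j`, `lr_positive`, `lr_negative`, `quality_bin`, `degenerate`
#'   and (optionally) `boot_ci`.
#' @export
rocAnalysis <- function(values, is_case, conf_level = 0.95, n_boot = 0L,
                        seed = 1L) {
    stopifnot(length(values) == length(is_case))
    cases <- values[is_case]; controls <- values[!is_case]
    if (!length(cases) || !length(controls))
        stop("both classes must be non-empty")
    degenerate <- length(unique(values)) == 1L
    raw <- aucMannWhitney(controls, cases)   # P(case > control) + ties/2
    direction <- if (raw >= 0.5) ">" else "<"
    v <- if (direction == "<") -values else values
    cs <- v[is_case]; ct <- v[!is_case]
    auc <- aucMannWhitney(ct, cs)

    se <- sqrt(max(.delongVariance(cs, ct), 0))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    if (se > 0) {
        ci <- c(max(0, auc - z * se), min(1, auc + z * se))
        p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
    } else {
        ci <- c(auc, auc)
        p <- if (auc == 0.5) 1 else .Machine$double.xmin
    }

    sv <- sort(unique(v))
    cuts <- if (length(sv) > 1L) (sv[-1] + sv[-length(sv)]) / 2 else sv
    best <- list(j = -Inf, sens = NA, spec = NA, cut = NA)
    for (cu in cuts) {
        sens <- mean(cs > cu); spec <- mean(ct <= cu)
        j <- sens + spec - 1
        if (j > best$j + 1e-12 ||
            (abs(j - best$j) <= 1e-12 && !is.na(best$spec) && spec > best$spec)) {
            best <- list(j = j, sens = sens, spec = spec, cut = cu)
        }
    }
    cutoff <- if (direction == "<") -best$cut else best$cut

    res <- list(auc = auc, ci_low = ci[1], ci_high = ci[2], p = min(p, 1),
                cutoff = cutoff, direction = direction,
                sensitivity = best$sens, specificity = best$spec,
                youden_j = best$j,
                lr_positive = likelihoodRatioPositive(best$sens, best$spec),
                lr_negative = if (best$spec > 0)
                    (1 - best$sens) / best$spec else Inf,
                quality_bin = aucQualityBin(auc), degenerate = degenerate)
    if (n_boot > 0L) {
        res$boot_ci <- withr::with_seed(seed, {
            idx_c <- which(is_case); idx_n <- which(!is_case)
            bo <- vapply(seq_len(n_boot), function(i) {
                bc <- sample(idx_c, replace = TRUE)
                bn <- sample(idx_n, replace = TRUE)
                aucMannWhitney(v[bn], v[bc])
            }, numeric(1))
            stats::quantile(bo, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2), names = FALSE)
        })
    }
    structure(res, class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
    cat(sprintf("RocResult: AUC %.3f (%.2f-%.2f, p=%.3g) [%s]\n",
                x$auc, x$ci_low, x$ci_high, x$p, x$quality_bin))
    cat(sprintf("cutoff %s%.3g: sens %.2f, spec %.2f, J %.2f, LR+ %.3g\n",
                x$direction, x$cutoff, x$sensitivity, x$specificity,
                x$youden_j, x$lr_positive))
    invisible(x)
}

#' Group medians and interquartile ranges
#'
#' Per-group median with first and third quartiles via the
#' linear-interpolation quantile convention (R type 7).
#'
#' @param values numeric vector.
#' @param groups parallel group labels.
#' @return data.frame: `group`, `n`, `median`, `q1`, `q3`.
#' @export
groupSummary <- function(values, groups) {
    groups <- factor(groups)
    if (any(table(groups) == 0L)) stop("empty group")
    out <- do.call(rbind, lapply(levels(groups), function(g) {
        v <- values[groups == g]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(group = g, n = length(v), median = q[2], q1 = q[1],
                   q3 = q[3], stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
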