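PAIRWISE_COMPARISONS <- list(Tot_vs_Mv = c("Tot", "Mv"),
                             Tot_vs_Ex = c("Tot", "Ex"),
                             Ex_vs_Mv = c("Ex", "Mv"))

.rowVars <- function(m) {
    n <- ncol(m)
    (rowSums(m^2) - n * rowMeans(m)^2) / (n - 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' with input validation: p-values must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in the original order, clipped at 1.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

# post-hoc power of the one-way F test at the observed effect
.fPower <- function(F, df1, df2, alpha) {
    crit <- stats::qf(1 - alpha, df1, df2)
    lambda <- F * df1          # = SS_between / MS_within
    p <- stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
    p[is.infinite(F)] <- 1
    p[F == 0] <- alpha         # limit: central F, power = size
    p
}

# post-hoc power of the two-sided Welch t test at the observed effect
.tPower <- function(t, df, alpha) {
    crit <- stats::qt(1 - alpha / 2, df)
    p <- stats::pt(-crit, df, ncp = t) +
         stats::pt(crit, df, ncp = t, lower.tail = FALSE)
    p[is.infinite(t)] <- 1
    p[t == 0] <- alpha
    p
}

.finishTable <- function(tbl, alpha, power_threshold) {
    tbl$p_adj <- benjaminiHochberg(tbl$p)
    tbl$significant <- tbl$p_adj <= alpha & tbl$power >= power_threshold
    rownames(tbl) <- NULL
    class(tbl) <- c("DifferentialTable", "data.frame")
    tbl
}

#' Per-protein one-way ANOVA across the three fractions
#'
#' Fixed-effects one-way ANOVA on log2 intensities, samples treated as
#' unpaired. P-values are Benjamini-Hochberg adjusted across proteins, and
#' each protein gets a post-hoc power at the observed effect size from the
#' noncentral F distribution. A protein is called significant only when
#' both the adjusted p-value is at or below `alpha` and the power reaches
#' `power_threshold` (the adjusted-p <= 0.05 and power >= 80% conjunction).
#'
#' @param x an imputed [ProteomeExperiment-class] with >= 2 samples per
#'   fraction.
#' @param alpha significance level. Default 0.05.
#' @param power_threshold minimum post-hoc power. Default 0.80.
#' @return a `DifferentialTable` data.frame: `protein`, `comparison`
#'   (`"anova"`), `log2_fc` (largest absolute pairwise group-mean
#'   difference), `p`, `p_adj`, `power`, `significant`, `direction`.
#' @export
anovaPerProtein <- function(x, alpha = 0.05, power_threshold = 0.80) {
    if (any(missingMask(x))) stop("ANOVA requires an imputed matrix")
    vals <- intensityValues(x)
    fr <- droplevels(factor(fractionLabels(x)))
    lev <- levels(fr)
    if (length(lev) < 2L) stop("need at least 2 fractions")
    ns <- table(fr)
    if (any(ns < 2L)) stop("every fraction needs >= 2 samples")
    k <- length(ns); n <- ncol(vals)
    gm <- sapply(lev, function(f) rowMeans(vals[, fr == f, drop = FALSE]))
    grand <- rowMeans(vals)
    ssb <- as.vector(gm^2 %*% as.numeric(ns[lev])) - n * grand^2
    sst <- rowSums(vals^2) - n * grand^2
    ssw <- pmax(sst - ssb, 0)
    ssb <- pmax(ssb, 0)
    df1 <- k - 1L; df2 <- n - k
    F <- (ssb / df1) / (ssw / df2)
    F[ssb < 1e-12] <- 0
    F[ssw < 1e-12 & ssb >= 1e-12] <- Inf
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    p[F == 0] <- 1
    pairs <- utils::combn(seq_len(k), 2L)
    pair_diff <- gm[, pairs[2L, ], drop = FALSE] -
        gm[, pairs[1L, ], drop = FALSE]
    max_fc <- pair_diff[cbind(seq_len(nrow(vals)),
                              max.col(abs(pair_diff), "first"))]
    tbl <- data.frame(protein = rownames(vals), comparison = "anova",
                      log2_fc = max_fc, p = p,
                      power = .fPower(F, df1, df2, alpha),
                      direction = "none", stringsAsFactors = FALSE)
    .finishTable(tbl, alpha, power_threshold)
}

#' Pairwise Welch t-tests between two fractions
#'
#' Two-sided unpaired Welch (unequal-variance) t-test per protein between
#' the two requested fractions; the log2 fold change is second-minus-first
#' group mean. BH adjustment, noncentral-t post-hoc power, and the same
#' conjunction significance rule as [anovaPerProtein()]. Direction is
#' `up_in_B` when the second fraction is higher, `up_in_A` when the first
#' is, `none` for a zero difference.
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @param comparison character pair of fraction labels, e.g.
#'   `c("Tot", "Mv")`.
#' @inheritParams anovaPerProtein
#' @return a `DifferentialTable` data.frame (one row per protein).
#' @export
ttestPairwise <- function(x, comparison, alpha = 0.05,
                          power_threshold = 0.80) {
    if (any(missingMask(x))) stop("t-tests require an imputed matrix")
    stopifnot(length(comparison) == 2L,
              all(comparison %in% FRACTION_LEVELS))
    fr <- fractionLabels(x)
    a <- intensityValues(x)[, fr == comparison[1], drop = FALSE]
    b <- intensityValues(x)[, fr == comparison[2], drop = FALSE]
    if (ncol(a) < 2L || ncol(b) < 2L)
        stop("both fractions need >= 2 samples")
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- .rowVars(a); v2 <- .rowVars(b)
    fc <- m2 - m1
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, fc / sqrt(se2), ifelse(fc == 0, 0, Inf * sign(fc)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
    p <- 2 * stats::pt(-abs(tt), df)
    p[tt == 0] <- 1
    p[is.infinite(tt)] <- .Machine$double.xmin
    tbl <- data.frame(protein = rownames(x),
                      comparison = paste(comparison, collapse = "_vs_"),
                      log2_fc = fc, p = p,
                      power = .tPower(abs(tt), df, alpha),
                      direction = ifelse(fc > 0, "up_in_B",
                                         ifelse(fc < 0, "up_in_A", "none")),
                      stringsAsFactors = FALSE)
    .finishTable(tbl, alpha, power_threshold)
}

#' Hyperbolic volcano cutoff
#'
#' Flags proteins beyond the volcano cutoff curve `y = |c / (x - x0)|` on
#' the (|log2 fold change|, -log10 p) plane: a protein passes iff
#' `|log2_fc| > x0` and `-log10(p) > |c / (|log2_fc| - x0)|`. The pole at
#' `x0` acts as a minimal-fold-change gate — at `|log2_fc| = x0` the
#' threshold is infinite and nothing passes.
#'
#' @param table a `DifferentialTable` with `log2_fc` and `p`.
#' @param c positive curvature constant. Default 0.5.
#' @param x0 pole position (log2-FC units). Default 1.
#' @return the table with a logical `volcano_pass` column.
#' @export
volcanoFlag <- function(table, c = 0.5, x0 = 1) {
    stopifnot(c > 0, x0 >= 0)
    afc <- abs(table$log2_fc)
    thr <- ifelse(afc > x0, abs(c / (afc - x0)), Inf)
    table$volcano_pass <- afc > x0 & -log10(table$p) > thr
    table
}

#' Significant protein ids of a DifferentialTable
#'
#' @param table a `DifferentialTable`.
#' @param volcano also require the volcano flag, if present.
#' @return character vector of protein ids.
#' @export
significantProteins <- function(table, volcano = FALSE) {
    keep <- table$significant
    if (volcano && "volcano_pass" %in% colnames(table))
        keep <- keep & table$volcano_pass
    table$protein[keep]
}

#' Run the full differential stage
#'
#' Convenience wrapper: per-protein ANOVA plus the three pairwise Welch
#' tests (Tot vs Mv, Tot vs Ex, Ex vs Mv) with volcano flags, up/down
#' tallies and a Venn partition of the three pairwise significant sets.
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @param config a [pipelineConfig()].
#' @return list with `anova`, `pairwise` (named list of tables), `counts`
#'   (data.frame of significant/up/down per comparison) and `venn`.
#' @export
runDifferential <- function(x, config = pipelineConfig()) {
    anova <- anovaPerProtein(x, config$alpha, config$power_threshold)
    pairwise <- lapply(PAIRWISE_COMPARISONS, function(cmp)
        volcanoFlag(ttestPairwise(x, cmp, config$alpha,
                                  config$power_threshold),
                    c = config$volcano_c, x0 = config$volcano_x0))
    counts <- do.call(rbind, lapply(names(pairwise), function(nm) {
        tb <- pairwise[[nm]]
        data.frame(comparison = nm,
                   significant = sum(tb$significant),
                   up_in_second = sum(tb$significant & tb$direction == "up_in_B"),
                   up_in_first = sum(tb$significant & tb$direction == "up_in_A"))
    }))
    sig <- lapply(pairwise, significantProteins)
    list(anova = anova, pairwise = pairwise, counts = counts,
         venn = vennPartition(sig[[1]], sig[[2]], sig[[3]],
                              labels = names(pairwise)))
}
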