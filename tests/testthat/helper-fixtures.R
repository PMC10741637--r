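# shared fixtures and independent oracles

# small experiment with explicit values; fractions balanced over samples
makeExperiment <- function(values, n_per_fraction = NULL, fraction = NULL,
                           missing = is.na(values)) {
    if (is.null(fraction)) {
        stopifnot(!is.null(n_per_fraction))
        fraction <- rep(c("Tot", "Mv", "Ex"), each = n_per_fraction)
    }
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    ProteomeExperiment(values, fraction = fraction,
                       subject = colnames(values), missing = missing)
}

# plant an additive shift for one protein in one fraction
plantShift <- function(pe, protein, fraction, shift) {
    v <- intensityValues(pe)
    v[protein, fractionLabels(pe) == fraction] <-
        v[protein, fractionLabels(pe) == fraction] + shift
    makeExperiment(v, fraction = as.character(fractionLabels(pe)),
                   missing = missingMask(pe))
}

# brute-force BH: enumerate the step-up rule index by index
bruteForceBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
        # smallest min over j >= i of p_(j) * n / j
        cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
        adj[o[i]] <- min(1, min(cand))
    }
    adj
}

# empirical ROC area by the trapezoidal rule
trapezoidAuc <- function(controls, cases) {
    thr <- sort(unique(c(controls, cases, -Inf, Inf)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# mean-rank enrichment score, written from the definition
bruteMeanRankScore <- function(values, members) {
    r <- rank(values)
    idx <- which(names(values) %in% members)
    (2 / length(values)) * (mean(r[idx]) - (length(values) + 1) / 2)
}

# write a protein matrix TSV + metadata for reader tests
writeMatrixFixture <- function(tab, fractions, subjects = NULL) {
    mp <- tempfile(fileext = ".tsv"); md <- tempfile(fileext = ".tsv")
    utils::write.table(tab, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    samples <- colnames(tab)[-1]
    if (is.null(subjects)) subjects <- samples
    utils::write.table(
        data.frame(sample_id = samples, fraction = fractions,
                   subject = subjects),
        md, sep = "\t", quote = FALSE, row.names = FALSE)
    list(matrix = mp, metadata = md)
}
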