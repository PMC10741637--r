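#' Simulate a three-fraction CSF proteome with known ground truth
#'
#' Emulates the statistical structure of a label-free three-fraction
#' (Tot / Mv / Ex) protein-group matrix: log-normal abundances over a wide
#' dynamic range (baseline log2 means drawn from Normal(25, 4)),
#' fraction-specific differential shifts for a chosen share of proteins,
#' within-group technical noise, and missing-not-at-random left censoring
#' in which detection probability rises with abundance. Each fraction
#' contributes `n_per_fraction` samples; when `n_per_fraction >= 8` the
#' last two are pooled samples formed by averaging two fresh subject
#' draws, mirroring a 6-individuals-plus-2-pools design.
#'
#' @param n_proteins number of proteins. Default 1622.
#' @param n_per_fraction samples per fraction (>= 3). Default 8.
#' @param frac_differential share of proteins with a planted fraction
#'   effect, in [0, 1). Default 0.15.
#' @param effect_sd sd (log2 units) of planted shifts. Planted proteins
#'   receive a shift ~ Normal(0, `effect_sd`) in one or two fractions.
#'   Default 2.
#' @param noise_sd within-group sd (log2 units). Default 0.5.
#' @param missing_rate target overall share of censored cells, in [0, 1).
#'   Default 0.1.
#' @param seed integer seed; same seed and parameters give byte-identical
#'   output.
#' @return list with `experiment` (a [ProteomeExperiment-class]) and
#'   `truth`: `effects` (protein x fraction matrix of planted shifts),
#'   `differential` (per comparison — `anova`, `Tot_vs_Mv`, `Tot_vs_Ex`,
#'   `Ex_vs_Mv` — the protein ids with a true effect) and the generator
#'   parameters.
#' @examples
#' sim <- simulateFractionProteome(n_proteins = 100, seed = 1)
#' dim(sim$experiment)
#' @export
simulateFractionProteome <- function(n_proteins = 1622L,
                                     n_per_fraction = 8L,
                                     frac_differential = 0.15,
                                     effect_sd = 2,
                                     noise_sd = 0.5,
                                     missing_rate = 0.1,
                                     seed = 1L) {
    stopifnot(n_per_fraction >= 3L, frac_differential >= 0,
              frac_differential < 1)
    if (missing_rate >= 1) stop("missing_rate must be < 1")
    withr::with_seed(seed, {
        prot <- sprintf("P%04d", seq_len(n_proteins))
        mu <- stats::rnorm(n_proteins, mean = 25, sd = 4)

        effects <- matrix(0, n_proteins, 3,
                          dimnames = list(prot, FRACTION_LEVELS))
        n_diff <- round(frac_differential * n_proteins)
        if (n_diff > 0) {
            diff_idx <- sample.int(n_proteins, n_diff)
            for (i in diff_idx) {
                k <- sample(1:2, 1L)
                f <- sample(3L, k)
                effects[i, f] <- stats::rnorm(k, 0, effect_sd)
            }
        }

        n_pool <- if (n_per_fraction >= 8L) 2L else 0L
        n_ind <- n_per_fraction - n_pool
        cols <- list(); fr <- character(0); subj <- character(0)
        for (f in FRACTION_LEVELS) {
            base <- mu + effects[, f]
            for (s in seq_len(n_ind))
                cols[[length(cols) + 1L]] <-
                    base + stats::rnorm(n_proteins, 0, noise_sd)
            for (s in seq_len(n_pool))
                cols[[length(cols) + 1L]] <-
                    base + (stats::rnorm(n_proteins, 0, noise_sd) +
                            stats::rnorm(n_proteins, 0, noise_sd)) / 2
            fr <- c(fr, rep(f, n_per_fraction))
            subj <- c(subj, sprintf("%s_subj%02d", f, seq_len(n_ind)),
                      if (n_pool) sprintf("%s_pool%d", f, seq_len(n_pool)))
        }
        values <- do.call(cbind, cols)
        dimnames(values) <- list(prot, sprintf("%s_s%02d", fr,
                                               sequence(rep(n_per_fraction, 3))))

        miss <- matrix(FALSE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
        if (missing_rate > 0) {
            loc <- .censorLocation(values, missing_rate, scale = 2)
            pmiss <- stats::plogis(-(values - loc) / 2)
            miss <- matrix(stats::runif(length(values)) < pmiss,
                           nrow(values), ncol(values),
                           dimnames = dimnames(values))
        }

        pe <- ProteomeExperiment(values, fraction = fr, subject = subj,
                                 missing = miss)
        dd <- abs(effects[, c(2, 3, 3)] - effects[, c(1, 1, 2)]) > 0
        truth <- list(
            effects = effects,
            differential = list(
                anova = prot[rowSums(dd) > 0],
                Tot_vs_Mv = prot[dd[, 1]],
                Tot_vs_Ex = prot[dd[, 2]],
                Ex_vs_Mv = prot[dd[, 3]]),
            params = list(n_proteins = n_proteins,
                          n_per_fraction = n_per_fraction,
                          frac_differential = frac_differential,
                          effect_sd = effect_sd, noise_sd = noise_sd,
                          missing_rate = missing_rate, seed = seed))
        list(experiment = pe, truth = truth)
    })
}

# logistic censoring location giving the requested overall missing share
.censorLocation <- function(values, missing_rate, scale) {
    f <- function(loc) mean(stats::plogis(-(values - loc) / scale)) - missing_rate
    stats::uniroot(f, lower = min(values) - 50, upper = max(values) + 50)$root
}

#' Simulate annotation terms over a simulated proteome
#'
#' Builds `n_terms` gene sets over the simulated protein universe. The
#' first `n_enriched` are truly enriched: at least 80% of their members are
#' drawn from proteins with a planted positive shift in one comparison
#' (cycling over the three pairwise comparisons), so their signed
#' fold-change ranks are coherently high. The remaining terms sample the
#' universe uniformly. Term sizes are uniform over `term_size_range`.
#'
#' @param sim output of [simulateFractionProteome()].
#' @param n_terms total number of terms. Default 50.
#' @param term_size_range integer pair (min, max members). Default c(10, 40).
#' @param n_enriched number of truly enriched terms (<= `n_terms`).
#'   Default 5.
#' @param namespace namespace label for the emitted terms.
#' @param seed integer seed.
#' @return list with `db` (an [AnnotationDb-class]) and `enriched_terms`
#'   (data.frame: term, target comparison, direction).
#' @export
simulateAnnotations <- function(sim, n_terms = 50L,
                                term_size_range = c(10L, 40L),
                                n_enriched = 5L, namespace = "GO",
                                seed = 1L) {
    stopifnot(n_enriched <= n_terms)
    prot <- proteinIds(sim$experiment)
    if (max(term_size_range) > length(prot))
        stop("term_size_range exceeds the protein universe")
    eff <- sim$truth$effects
    comps <- list(Tot_vs_Mv = c("Tot", "Mv"), Tot_vs_Ex = c("Tot", "Ex"),
                  Ex_vs_Mv = c("Ex", "Mv"))
    withr::with_seed(seed, {
        terms <- list(); meta <- list()
        for (i in seq_len(n_terms)) {
            size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
            if (i <= n_enriched) {
                cn <- names(comps)[(i - 1L) %% 3L + 1L]
                fp <- comps[[cn]]
                delta <- eff[, fp[2]] - eff[, fp[1]]   # second-minus-first
                up <- prot[delta > 0]
                n_up <- min(length(up), ceiling(0.8 * size))
                members <- c(sample(up, n_up),
                             sample(setdiff(prot, up), size - n_up))
                meta[[length(meta) + 1L]] <-
                    data.frame(term = sprintf("ENRICHED_%02d", i),
                               comparison = cn, direction = "up")
                terms[[sprintf("ENRICHED_%02d", i)]] <- members
            } else {
                terms[[sprintf("TERM_%03d", i)]] <- sample(prot, size)
            }
        }
        list(db = AnnotationDb(terms, namespace = namespace),
             enriched_terms = if (length(meta)) do.call(rbind, meta)
                              else data.frame(term = character(0),
                                              comparison = character(0),
                                              direction = character(0)))
    })
}

#' Simulate an ELISA validation cohort
#'
#' Generates a plate of 450 nm absorbances for a three-group cohort
#' (congenital hydrocephalus controls CTR and two tumour groups PA, MB)
#' in one CSF fraction, such that background-subtracted relative units
#' (RU/mL, normalised to the plate reference standard) have approximately
#' the requested group medians and interquartile range. The plate carries
#' uncoated background wells, a reference standard in triplicate and blank
#' wells near the detection limit.
#'
#' @param n_per_group subjects per group (>= 3). Default 10.
#' @param group_medians named vector of true median RU/mL per group,
#'   names among `CTR`, `PA`, `MB`. Default `c(CTR = 1.35, PA = 1.27,
#'   MB = 1.30)`.
#' @param group_iqr target interquartile range of RU/mL. Default 0.1.
#' @param n_blank number of blank wells. Default 3.
#' @param fraction fraction label for the plate. Default "Mv".
#' @param seed integer seed.
#' @return list with `wells` (data.frame: well, absorbance, role, group,
#'   fraction, subject) and `truth` (`group_medians`, `group_iqr`).
#' @export
simulateElisaCohort <- function(n_per_group = 10L,
                                group_medians = c(CTR = 1.35, PA = 1.27,
                                                  MB = 1.30),
                                group_iqr = 0.1, n_blank = 3L,
                                fraction = "Mv", seed = 1L) {
    stopifnot(n_per_group >= 3L, all(names(group_medians) %in% ELISA_GROUPS))
    if (any(group_medians <= 0)) stop("group medians must be positive")
    bg_mean <- 0.08; ref_mean <- 0.78
    ru_sd <- group_iqr / (2 * stats::qnorm(0.75))  # IQR of a normal = 1.349 sd
    withr::with_seed(seed, {
        rows <- list()
        add <- function(absorb, role, group, subject)
            rows[[length(rows) + 1L]] <<- data.frame(
                absorbance = absorb, role = role, group = group,
                fraction = fraction, subject = subject)
        add(stats::rnorm(3, bg_mean, 0.005), "uncoated_background", NA, NA)
        add(stats::rnorm(3, ref_mean, 0.01), "reference_standard", NA, NA)
        add(bg_mean + abs(stats::rnorm(n_blank, 0, 0.003)), "blank", NA, NA)
        for (g in names(group_medians)) {
            ru <- stats::rnorm(n_per_group, group_medians[[g]], ru_sd)
            add(bg_mean + ru * (ref_mean - bg_mean) +
                    stats::rnorm(n_per_group, 0, 0.002),
                "sample", g, sprintf("%s_%02d", g, seq_len(n_per_group)))
        }
        wells <- do.call(rbind, rows)
        wells$absorbance <- pmax(wells$absorbance, 0)
        wells <- data.frame(well = sprintf("W%02d", seq_len(nrow(wells))),
                            wells)
        list(wells = wells,
             truth = list(group_medians = group_medians,
                          group_iqr = group_iqr))
    })
}
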