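#' One-dimensional rank-based enrichment score
#'
#' Ranks all proteins of the universe ascending by a per-protein statistic
#' (midranks for ties) and scores a member set by its centred mean rank,
#' rescaled to (-1, 1): `score = (2/n) * (mean rank of members - (n+1)/2)`.
#' A set concentrated at the top of the ranking approaches +1, at the
#' bottom -1, and the whole universe scores exactly 0. The two-sided
#' p-value comes from the Mann-Whitney U statistic: exact (via the U
#' distribution) for member counts up to 3 without ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param values named numeric vector (one statistic per protein of the
#'   universe; names = protein ids).
#' @param members character vector of member protein ids (case
#'   insensitive).
#' @return list with `score`, `p`, `n_members` (members found in the
#'   universe).
#' @examples
#' v <- setNames(1:5, paste0("P", 1:5))
#' enrichmentScore1d(v, "P5")$score  # 0.8
#' @export
enrichmentScore1d <- function(values, members) {
    n <- length(values)
    stopifnot(n >= 2L, !is.null(names(values)))
    idx <- which(toupper(names(values)) %in% toupper(members))
    m <- length(idx)
    if (m == 0L) stop("members are disjoint from the universe")
    r <- rank(values)
    score <- (2 / n) * (mean(r[idx]) - (n + 1) / 2)

    n2 <- n - m
    if (n2 == 0L) return(list(score = 0, p = 1, n_members = m))
    U <- sum(r[idx]) - m * (m + 1) / 2
    ties <- table(values)
    if (m <= 3L && all(ties == 1L)) {
        p <- 2 * min(stats::pwilcox(U, m, n2),
                     stats::pwilcox(U - 1, m, n2, lower.tail = FALSE))
    } else {
        mu <- m * n2 / 2
        sigma2 <- (m * n2 / 12) *
            ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sigma2 <= 0) return(list(score = score, p = 1, n_members = m))
        z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
        p <- 2 * stats::pnorm(-abs(z))
    }
    list(score = score, p = min(p, 1), n_members = m)
}

#' Two-dimensional annotation enrichment across two comparisons
#'
#' Scores every annotation term independently on the signed log2 fold
#' changes of two differential comparisons with [enrichmentScore1d()],
#' giving a point (score_x, score_y) in [-1, 1]^2 per term. Terms on the
#' x = y diagonal are equally enriched in both comparisons; the signed
#' diagonal distance `(score_y - score_x) / sqrt(2)` measures differential
#' enrichment. P-values are BH-adjusted per dimension across terms; a term
#' is significant when its FDR is at or below `alpha` in at least one
#' dimension and it has at least `min_members` members in the universe.
#' `beyond_ci` flags terms whose |diagonal distance| exceeds the 97.5th
#' percentile of the null obtained from random same-size member sets.
#'
#' @param diff_x,diff_y `DifferentialTable`s over the same protein
#'   universe (e.g. the Tot-vs-Mv and Tot-vs-Ex tables).
#' @param annotations an [AnnotationDb-class].
#' @param min_members minimum members present in the universe. Default 5.
#' @param alpha FDR level. Default 0.05.
#' @param n_permutations random memberships for the diagonal band.
#'   Default 1000 (a warning is issued below 100).
#' @param seed integer seed for the permutations.
#' @return data.frame: `term`, `namespace`, `n_members`, `score_x`,
#'   `score_y`, `p_x`, `p_y`, `fdr_x`, `fdr_y`, `diag_distance`,
#'   `beyond_ci`, `significant`.
#' @export
enrichment2d <- function(diff_x, diff_y, annotations, min_members = 5L,
                         alpha = 0.05, n_permutations = 1000L, seed = 1L) {
    if (!setequal(diff_x$protein, diff_y$protein))
        stop("the two differential tables must share a protein universe")
    if (n_permutations < 100L)
        warning("fewer than 100 permutations: the diagonal band is unstable")
    vx <- stats::setNames(diff_x$log2_fc, diff_x$protein)
    vy <- stats::setNames(diff_y$log2_fc, diff_y$protein)
    vy <- vy[names(vx)]
    terms <- annotationTerms(annotations)
    present <- lapply(terms, function(m)
        which(toupper(names(vx)) %in% toupper(m)))
    keep <- lengths(present) > 0L
    terms <- terms[keep]; present <- present[keep]
    if (!length(terms)) stop("no annotation term overlaps the universe")

    sx <- lapply(names(terms), function(tn) enrichmentScore1d(vx, terms[[tn]]))
    sy <- lapply(names(terms), function(tn) enrichmentScore1d(vy, terms[[tn]]))
    out <- data.frame(
        term = names(terms),
        namespace = as.character(termNamespace(annotations)[names(terms)]),
        n_members = vapply(sx, `[[`, 0, "n_members"),
        score_x = vapply(sx, `[[`, 0, "score"),
        score_y = vapply(sy, `[[`, 0, "score"),
        p_x = vapply(sx, `[[`, 0, "p"),
        p_y = vapply(sy, `[[`, 0, "p"),
        stringsAsFactors = FALSE)
    out$fdr_x <- benjaminiHochberg(out$p_x)
    out$fdr_y <- benjaminiHochberg(out$p_y)
    out$diag_distance <- (out$score_y - out$score_x) / sqrt(2)

    # null |diagonal distance| depends only on the member count
    rx <- rank(vx); ry <- rank(vy); n <- length(vx)
    out$beyond_ci <- withr::with_seed(seed, {
        band <- vapply(sort(unique(out$n_members)), function(m) {
            null_d <- vapply(seq_len(n_permutations), function(i) {
                idx <- sample.int(n, m)
                abs(mean(ry[idx]) - mean(rx[idx])) * 2 / (n * sqrt(2))
            }, numeric(1))
            stats::quantile(null_d, 0.975, names = FALSE)
        }, numeric(1))
        names(band) <- sort(unique(out$n_members))
        abs(out$diag_distance) > band[as.character(out$n_members)]
    })
    out$significant <- (out$fdr_x <= alpha | out$fdr_y <= alpha) &
        out$n_members >= min_members
    rownames(out) <- NULL
    out
}

#' Kinase enrichment analysis by hypergeometric over-representation
#'
#' Tests each kinase's substrate set for over-representation among the
#' significant proteins against the identified-protein universe (one-sided
#' hypergeometric), BH-adjusted across kinases. If per-protein log2 fold
#' changes are supplied, each kinase is labelled `up` or `down` when at
#' least 60% of its significant substrates share that sign, otherwise
#' `mixed`.
#'
#' @param significant character vector of significant protein ids (subset
#'   of `universe`).
#' @param universe character vector of all identified protein ids.
#' @param kinase_sets an [AnnotationDb-class] of kinase substrate sets.
#' @param alpha FDR level. Default 0.05.
#' @param fold_changes optional named numeric vector of log2 fold changes.
#' @return data.frame: `kinase`, `substrates_in_universe`,
#'   `substrates_significant`, `p`, `fdr`, `direction`, `significant`.
#' @export
kinaseEnrichment <- function(significant, universe, kinase_sets,
                             alpha = 0.05, fold_changes = NULL) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(toupper(universe))
    significant <- unique(toupper(significant))
    if (!all(significant %in% universe))
        stop("significant proteins must be a subset of the universe")
    N <- length(universe); n <- length(significant)
    rows <- lapply(names(annotationTerms(kinase_sets)), function(kn) {
        subs <- intersect(toupper(annotationTerms(kinase_sets)[[kn]]),
                          universe)
        K <- length(subs)
        hits <- intersect(subs, significant)
        k <- length(hits)
        p <- if (K == 0L) 1 else
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        dir <- "mixed"
        if (!is.null(fold_changes) && k > 0L) {
            fc <- fold_changes[match(hits, toupper(names(fold_changes)))]
            fc <- fc[!is.na(fc)]
            if (length(fc)) {
                up <- mean(fc > 0)
                dir <- if (up >= 0.6) "up" else if (up <= 0.4) "down"
                       else "mixed"
            }
        }
        data.frame(kinase = kn, substrates_in_universe = K,
                   substrates_significant = k, p = min(p, 1),
                   direction = dir, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- benjaminiHochberg(out$p)
    out$significant <- out$fdr <= alpha
    out[order(out$p), c("kinase", "substrates_in_universe",
                        "substrates_significant", "p", "fdr", "direction",
                        "significant")]
}
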