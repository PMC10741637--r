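# z-score each protein (feature) across samples; constant features -> 0
.standardizeFeatures <- function(x) {
    X <- t(intensityValues(x))          # samples x proteins
    mu <- colMeans(X)
    sd <- apply(X, 2L, stats::sd)
    X <- sweep(X, 2L, mu)
    nz <- sd > 0
    X[, nz] <- sweep(X[, nz, drop = FALSE], 2L, sd[nz], "/")
    X[, !nz] <- 0
    X
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a PLS2 discriminant model by NIPALS on z-scored proteins against a
#' one-hot fraction response and returns each protein's VIP score:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{w_a} are the component weight vectors and \eqn{SSY_a} the
#' response variance explained by component \eqn{a}. Higher VIP = more
#' discriminating; the squared scores average exactly 1 over the modelled
#' proteins.
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @param n_components number of latent components; defaults to
#'   `min(classes - 1, 5)`, capped by the sample and feature counts.
#' @return data.frame with `protein` and `vip`, in matrix row order.
#' @export
plsdaVip <- function(x, n_components = NULL) {
    fr <- droplevels(factor(fractionLabels(x)))
    if (nlevels(fr) < 2L) stop("PLS-DA needs at least 2 classes")
    X <- .standardizeFeatures(x)
    Y <- stats::model.matrix(~ fr - 1)
    Y <- scale(Y, center = TRUE, scale = FALSE)
    n <- nrow(X); p <- ncol(X)
    if (is.null(n_components)) n_components <- min(nlevels(fr) - 1L, 5L)
    A <- min(n_components, n - 1L, p)

    W <- matrix(0, p, A); ssy <- numeric(A)
    Xr <- X; Yr <- Y
    for (a in seq_len(A)) {
        u <- Yr[, which.max(apply(Yr, 2L, stats::var))]
        w <- rep(0, p)
        for (it in seq_len(500L)) {
            w_new <- crossprod(Xr, u)
            nw <- sqrt(sum(w_new^2))
            if (nw < 1e-12) break
            w_new <- w_new / nw
            tt <- Xr %*% w_new
            q <- crossprod(Yr, tt) / sum(tt^2)
            u_new <- Yr %*% q / sum(q^2)
            done <- sum((w_new - w)^2) < 1e-12
            w <- as.vector(w_new); u <- as.vector(u_new)
            if (done) break
        }
        if (sum(w^2) < 1e-12) { ssy <- ssy[seq_len(a - 1L)]; W <- W[, seq_len(a - 1L), drop = FALSE]; break }
        tt <- Xr %*% w
        tt2 <- sum(tt^2)
        pl <- crossprod(Xr, tt) / tt2
        cl <- crossprod(Yr, tt) / tt2
        Xr <- Xr - tt %*% t(pl)
        Yr <- Yr - tt %*% t(cl)
        W[, a] <- w
        ssy[a] <- sum(cl^2) * tt2
    }
    if (!length(ssy) || sum(ssy) == 0)
        vip <- rep(1, p)
    else
        vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
    data.frame(protein = proteinIds(x), vip = vip, stringsAsFactors = FALSE)
}

# linear one-vs-rest SVM decision values, oriented so higher = that class
.ovrDecision <- function(Xl, yl, Xt, cost) {
    classes <- levels(yl)
    dv <- sapply(classes, function(cl) {
        yb <- factor(yl == cl, levels = c(TRUE, FALSE))
        m <- e1071::svm(Xl, yb, kernel = "linear", cost = cost,
                        scale = FALSE)
        d <- attr(stats::predict(m, Xt, decision.values = TRUE),
                  "decision.values")
        if (colnames(d)[1L] == "TRUE/FALSE") d[, 1L] else -d[, 1L]
    })
    matrix(dv, nrow = nrow(Xt), dimnames = list(rownames(Xt), classes))
}

#' Linear-SVM cross-validated classification of fractions
#'
#' Repeated stratified Monte-Carlo splits: each repetition draws a
#' `learn_fraction` learn set per class (the 65%/35% learn/test scheme),
#' trains soft-margin linear SVMs one-vs-rest, and predicts the held-out
#' samples by the largest decision value. Repetitions continue past
#' `n_splits` until every sample has appeared in at least one learn and
#' one test set. Returns the per-split and mean accuracy and the test
#' confusion matrix aggregated over all splits.
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @param learn_fraction share of each class used for learning. Default
#'   0.65.
#' @param n_splits minimum number of splits. Default 4.
#' @param cost SVM soft-margin constant. Default 1.
#' @param seed integer seed for the splits.
#' @return a `CvResult`: list with `splits` (list of learn/test id sets),
#'   `accuracy_per_split`, `mean_accuracy`, `confusion` (true class in
#'   rows, predicted in columns).
#' @export
svmCv <- function(x, learn_fraction = 0.65, n_splits = 4L, cost = 1,
                  seed = 1L) {
    y <- droplevels(factor(fractionLabels(x)))
    if (nlevels(y) < 2L) stop("need at least 2 classes")
    X <- .standardizeFeatures(x)
    n <- nrow(X)
    n_learn <- pmin(pmax(round(learn_fraction * table(y)), 2L),
                    table(y) - 1L)
    if (any(table(y) < 3L))
        stop("every class needs >= 3 samples for a stratified learn/test split")
    classes <- levels(y)
    conf <- matrix(0L, nlevels(y), nlevels(y),
                   dimnames = list(true = classes, predicted = classes))
    withr::with_seed(seed, {
        splits <- list(); acc <- numeric(0)
        seen_learn <- seen_test <- rep(FALSE, n)
        rep_i <- 0L
        while (rep_i < n_splits || !all(seen_learn & seen_test)) {
            rep_i <- rep_i + 1L
            if (rep_i > 1000L) stop("split coverage not reached")
            learn <- unlist(lapply(classes, function(cl)
                sample(which(y == cl), n_learn[[cl]])))
            test <- setdiff(seq_len(n), learn)
            seen_learn[learn] <- TRUE; seen_test[test] <- TRUE
            dv <- .ovrDecision(X[learn, , drop = FALSE], droplevels(y[learn]),
                               X[test, , drop = FALSE], cost)
            pred <- colnames(dv)[max.col(dv, "first")]
            acc <- c(acc, mean(pred == y[test]))
            for (i in seq_along(test))
                conf[as.character(y[test[i]]), pred[i]] <-
                    conf[as.character(y[test[i]]), pred[i]] + 1L
            splits[[rep_i]] <- list(learn = rownames(X)[learn],
                                    test = rownames(X)[test])
        }
        structure(list(splits = splits, accuracy_per_split = acc,
                       mean_accuracy = mean(acc), confusion = conf),
                  class = "CvResult")
    })
}

#' @export
print.CvResult <- function(x, ...) {
    cat(sprintf("CvResult: %d splits, mean accuracy %.3f\n",
                length(x$splits), x$mean_accuracy))
    print(x$confusion)
    invisible(x)
}

# squared-weight feature scores summed over all class-pair hyperplanes
.svmPairScores <- function(X, y, cost) {
    classes <- levels(y)
    score <- rep(0, ncol(X))
    for (i in seq_len(length(classes) - 1L)) for (j in seq((i + 1L), length(classes))) {
        sel <- y %in% classes[c(i, j)]
        m <- e1071::svm(X[sel, , drop = FALSE], droplevels(y[sel]),
                        kernel = "linear", cost = cost, scale = FALSE)
        w <- crossprod(m$coefs, m$SV)
        score <- score + colSums(w^2)
    }
    score
}

#' SVM recursive feature elimination rank
#'
#' Ranks proteins by recursive feature elimination with linear SVMs:
#' repeatedly fit all class-pair hyperplanes, score each surviving protein
#' by the summed squared hyperplane weights, and eliminate the
#' lowest-scoring half. Rank 1 is the last survivor — the lowest rank
#' corresponds to the maximum discriminating power. Ties in the weight
#' score are broken by protein id so the ranking is deterministic.
#'
#' @param x an imputed [ProteomeExperiment-class] with >= 2 proteins.
#' @param cost SVM soft-margin constant. Default 1.
#' @return data.frame with `protein` and `svm_rank` (a permutation of
#'   `1..p`), in matrix row order.
#' @export
svmRankFeatures <- function(x, cost = 1) {
    p <- nrow(x)
    if (p < 2L) stop("need at least 2 proteins to rank")
    y <- droplevels(factor(fractionLabels(x)))
    if (nlevels(y) < 2L) stop("need at least 2 classes")
    X <- .standardizeFeatures(x)
    ids <- proteinIds(x)
    active <- seq_len(p)
    rank <- integer(p); next_worst <- p
    while (length(active) > 1L) {
        sc <- .svmPairScores(X[, active, drop = FALSE], y, cost)
        ord <- order(sc, ids[active])           # worst first, id tie-break
        n_drop <- max(1L, length(active) %/% 2L)
        # never split an exact tie group across the elimination boundary:
        # exactly tied features (e.g. duplicated proteins) drop together
        while (n_drop < length(active) - 1L &&
               sc[ord[n_drop + 1L]] == sc[ord[n_drop]])
            n_drop <- n_drop + 1L
        n_drop <- min(n_drop, length(active) - 1L)
        drop <- ord[seq_len(n_drop)]
        # worst score gets the worst remaining rank
        rank[active[drop]] <- next_worst - (seq_len(n_drop) - 1L)
        next_worst <- next_worst - n_drop
        active <- active[-drop]
    }
    rank[active] <- 1L
    data.frame(protein = ids, svm_rank = rank, stringsAsFactors = FALSE)
}

#' Per-protein ROC AUC between two fractions
#'
#' AUC from the Mann-Whitney U identity with half credit for ties,
#' oriented so values above 0.5 mean "higher in the second fraction".
#'
#' @param x a [ProteomeExperiment-class] (no missing values in the two
#'   fractions used).
#' @param comparison character pair of fraction labels.
#' @return data.frame with `protein` and `auc`.
#' @export
rocAucPerProtein <- function(x, comparison) {
    stopifnot(length(comparison) == 2L)
    fr <- fractionLabels(x)
    i1 <- which(fr == comparison[1]); i2 <- which(fr == comparison[2])
    if (!length(i1) || !length(i2)) stop("empty class in comparison")
    vals <- intensityValues(x)
    auc <- apply(vals, 1L, function(v) aucMannWhitney(v[i1], v[i2]))
    data.frame(protein = proteinIds(x), auc = auc, stringsAsFactors = FALSE)
}

#' AUC via the Mann-Whitney U identity
#'
#' `P(second > first) + 0.5 P(tie)` computed from midranks.
#'
#' @param first,second numeric vectors (the two classes).
#' @return the AUC in [0, 1].
#' @examples
#' aucMannWhitney(c(1, 3), c(2, 4))  # 0.75
#' @export
aucMannWhitney <- function(first, second) {
    n1 <- length(first); n2 <- length(second)
    r <- rank(c(first, second))
    (sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' Combined VIP / SVM-rank / AUC feature ranking
#'
#' @param x an imputed [ProteomeExperiment-class].
#' @param cost SVM soft-margin constant.
#' @return data.frame with `protein`, `vip`, `svm_rank` and one
#'   `auc_<comparison>` column per pairwise fraction comparison.
#' @export
featureRanking <- function(x, cost = 1) {
    out <- merge(plsdaVip(x), svmRankFeatures(x, cost), by = "protein",
                 sort = FALSE)
    for (nm in names(PAIRWISE_COMPARISONS)) {
        a <- rocAucPerProtein(x, PAIRWISE_COMPARISONS[[nm]])
        colnames(a)[2] <- paste0("auc_", nm)
        out <- merge(out, a, by = "protein", sort = FALSE)
    }
    out[match(proteinIds(x), out$protein), , drop = FALSE]
}

#' Minimal core biomarker panel by confusion-matrix search
#'
#' Orders candidate proteins by concordant priority — ascending SVM rank,
#' ties broken by descending VIP, then protein id — and grows the panel
#' k = 1, 2, 3, ... until the aggregated cross-validated confusion matrix
#' over the top-k proteins is diagonal (accuracy 1). The VIP score of the
#' k-th protein is reported as the empirical VIP limit. If no k up to
#' `max_k` achieves a diagonal confusion matrix, the best-performing k is
#' returned with a warning.
#'
#' @param x an imputed [ProteomeExperiment-class] (typically restricted to
#'   the ANOVA-significant proteins).
#' @param ranking data.frame from [featureRanking()] (columns `protein`,
#'   `vip`, `svm_rank`).
#' @param config a [pipelineConfig()] (learn fraction, split count, seed).
#' @param max_k largest panel size tried. Default `min(p, 30)`.
#' @param cost SVM soft-margin constant.
#' @return list with `panel` (protein ids), `k`, `vip_limit`, `achieved`
#'   (logical: diagonal confusion reached), `cv` (the winning `CvResult`)
#'   and `ranking` with an `in_core_panel` column.
#' @export
corePanel <- function(x, ranking, config = pipelineConfig(),
                      max_k = NULL, cost = 1) {
    stopifnot(all(c("protein", "vip", "svm_rank") %in% colnames(ranking)))
    ord <- ranking[order(ranking$svm_rank, -ranking$vip, ranking$protein), ]
    if (is.null(max_k)) max_k <- min(nrow(ord), 30L)
    best <- NULL; best_acc <- -1
    for (k in seq_len(max_k)) {
        sub <- x[ord$protein[seq_len(k)], ]
        cv <- svmCv(sub, learn_fraction = config$learn_fraction,
                    n_splits = config$n_splits, cost = cost,
                    seed = config$seed)
        off_diag <- sum(cv$confusion) - sum(diag(cv$confusion))
        if (cv$mean_accuracy > best_acc) {
            best_acc <- cv$mean_accuracy
            best <- list(k = k, cv = cv)
        }
        if (off_diag == 0L) { best <- list(k = k, cv = cv); break }
    }
    achieved <- sum(best$cv$confusion) - sum(diag(best$cv$confusion)) == 0L
    if (!achieved)
        warning(sprintf(
            "no panel up to k=%d gives a diagonal confusion matrix; best k=%d (accuracy %.3f)",
            max_k, best$k, best$cv$mean_accuracy))
    panel <- ord$protein[seq_len(best$k)]
    ranking$in_core_panel <- ranking$protein %in% panel
    list(panel = panel, k = best$k,
         vip_limit = ord$vip[best$k], achieved = achieved,
         cv = best$cv, ranking = ranking)
}
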