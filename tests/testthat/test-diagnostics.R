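makePlate <- function(bg = c(0.08, 0.08, 0.08), ref = c(0.78, 0.78, 0.78),
                      blanks = c(0.09, 0.095, 0.092), ru = NULL,
                      groups = NULL) {
    rows <- data.frame(
        absorbance = c(bg, ref, blanks),
        role = rep(c("uncoated_background", "reference_standard", "blank"),
                   c(length(bg), length(ref), length(blanks))),
        group = NA, fraction = "Mv", subject = NA,
        stringsAsFactors = FALSE)
    if (!is.null(ru)) {
        a <- mean(bg) + ru * (mean(ref) - mean(bg))
        rows <- rbind(rows, data.frame(
            absorbance = a, role = "sample", group = groups, fraction = "Mv",
            subject = sprintf("s%02d", seq_along(ru))))
    }
    data.frame(well = sprintf("W%02d", seq_len(nrow(rows))), rows)
}

test_that("reducePlate anchors RU at background and reference", {
    wells <- makePlate(ru = c(0, 1, 0.5), groups = c("CTR", "PA", "MB"))
    red <- reducePlate(wells)
    expect_equal(red$samples$ru, c(0, 1, 0.5), tolerance = 1e-12)
    expect_false(red$samples$detected[1])  # RU 0 sits below the LOD
    # LOD = mean(blank RU) + 3 sd(blank RU), by hand
    blank_ru <- (c(0.09, 0.095, 0.092) - 0.08) / (0.78 - 0.08)
    expect_equal(red$lod, mean(blank_ru) + 3 * sd(blank_ru),
                 tolerance = 1e-9)
    # assay failure when the reference does not exceed background
    bad <- makePlate(ref = c(0.05, 0.05, 0.05), ru = 0.5, groups = "CTR")
    expect_error(reducePlate(bad), "assay failure")
    expect_error(reducePlate(wells[wells$role != "blank", ]), "blank")
})

test_that("kruskalWallisGroups handles ties, degeneracy and group merging", {
    expect_equal(kruskalWallisGroups(rep(1, 9), rep(1:3, 3))$p, 1)
    expect_equal(kruskalWallisGroups(rep(1, 9), rep(1:3, 3))$statistic, 0)
    k3 <- kruskalWallisGroups(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2),
                              exact = FALSE)
    k2 <- kruskalWallisGroups(c(1, 2, 3, 4, 5, 6), c(1, 1, 2, 2, 2, 2),
                              exact = FALSE)
    expect_identical(k3$df, 2L)
    expect_identical(k2$df, 1L)
    expect_error(kruskalWallisGroups(1:5, rep(1, 5)), "2 groups")
    # agrees with stats::kruskal.test
    withr::with_seed(81, v <- rnorm(30))
    g <- rep(1:3, 10)
    ref <- stats::kruskal.test(v, g)
    mine <- kruskalWallisGroups(v, g, exact = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("exact Kruskal-Wallis p matches full permutation enumeration", {
    v <- c(1, 2, 3, 4, 5, 6)
    g <- factor(rep(1:3, each = 2))
    res <- kruskalWallisGroups(v, g)
    # independent oracle: enumerate every permutation of the values
    perms <- expand.grid(rep(list(1:6), 6))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
    h_obs <- unname(stats::kruskal.test(v, g)$statistic)
    h_all <- apply(perms, 1, function(idx)
        unname(stats::kruskal.test(v[idx], g)$statistic))
    expect_equal(res$p_exact, mean(h_all >= h_obs - 1e-12),
                 tolerance = 1e-12)
})

test_that("aucQualityBin implements the conventional scale", {
    expect_identical(aucQualityBin(0.86), "good")
    expect_identical(aucQualityBin(0.68), "poor")
    expect_identical(aucQualityBin(0.5), "not discriminant")
    expect_identical(aucQualityBin(0.55), "fail")
    expect_identical(aucQualityBin(0.6), "poor")
    expect_identical(aucQualityBin(0.7), "fair")
    expect_identical(aucQualityBin(0.9), "excellent")
    expect_identical(aucQualityBin(1), "excellent")
    expect_identical(aucQualityBin(0.25), "fair (reversed)")
    expect_error(aucQualityBin(1.2))
})

test_that("rocAnalysis handles separation, orientation and identities", {
    # cases low: direction "<", perfect separation
    r <- rocAnalysis(c(1, 2, 3, 4, 5, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(r$auc, 1)
    expect_identical(r$direction, "<")
    expect_equal(r$youden_j, 1)
    expect_equal(r$sensitivity, 1)
    expect_equal(r$specificity, 1)
    expect_true(r$cutoff > 3 && r$cutoff < 4)
    expect_identical(r$quality_bin, "excellent")

    # defining identities on random data
    withr::with_seed(83, {
        for (rep in 1:10) {
            v <- rnorm(24); cls <- rep(c(TRUE, FALSE), each = 12)
            r <- rocAnalysis(v, cls)
            expect_equal(r$youden_j, r$sensitivity + r$specificity - 1,
                         tolerance = 1e-12)
            if (r$specificity < 1)
                expect_equal(r$lr_positive,
                             r$sensitivity / (1 - r$specificity),
                             tolerance = 1e-12)
            expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
            # AUC equals the trapezoidal area under the oriented ROC
            vv <- if (r$direction == "<") -v else v
            expect_equal(r$auc, trapezoidAuc(vv[!cls], vv[cls]),
                         tolerance = 1e-12)
        }
    })
    # degenerate all-tied input
    rd <- rocAnalysis(rep(1, 8), rep(c(TRUE, FALSE), 4))
    expect_equal(rd$auc, 0.5)
    expect_true(rd$degenerate)
    expect_error(rocAnalysis(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("DeLong interval and p agree with pROC", {
    withr::with_seed(85, {
        v <- c(rnorm(15, 1), rnorm(15))
        cls <- rep(c(TRUE, FALSE), each = 15)
    })
    mine <- rocAnalysis(v, cls)
    ref <- pROC::roc(cls, v, direction = "<", quiet = TRUE)
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    expect_equal(mine$ci_low, ci[1], tolerance = 1e-6)
    expect_equal(mine$ci_high, ci[3], tolerance = 1e-6)
})

test_that("groupSummary uses linear-interpolation quantiles", {
    gs <- groupSummary(c(1, 2, 3, 4, 5), rep("a", 5))
    expect_equal(unlist(gs[, c("median", "q1", "q3")]),
                 c(median = 3, q1 = 2, q3 = 4))
    gs1 <- groupSummary(7, "a")
    expect_equal(unlist(gs1[, c("median", "q1", "q3")]),
                 c(median = 7, q1 = 7, q3 = 7))
    # appending a duplicate of the median leaves the median unchanged
    gs2 <- groupSummary(c(1, 2, 3, 4, 5, 3), rep("a", 6))
    expect_equal(gs2$median, 3)
})

test_that("paper-like Mv scenario separates groups more often than Ex", {
    pv <- function(medians, iqr, seed) {
        eli <- simulateElisaCohort(group_medians = medians, group_iqr = iqr,
                                   seed = seed)
        red <- reducePlate(eli$wells)
        kruskalWallisGroups(red$samples$ru, red$samples$group)$p
    }
    p_mv <- vapply(1:60, function(s)
        pv(c(CTR = 1.35, PA = 1.27, MB = 1.30), 0.1, s), numeric(1))
    p_ex <- vapply(1:60, function(s)
        pv(c(CTR = 1.28, PA = 1.24, MB = 1.22), 0.19, 1000 + s), numeric(1))
    expect_lt(median(p_mv), 0.05)
    expect_lt(median(p_mv), median(p_ex))
})

test_that("elisaValidation pools tumour groups against controls", {
    eli <- simulateElisaCohort(seed = 19)
    ev <- elisaValidation(eli$wells)
    expect_identical(nrow(ev$summary), 3L)
    expect_s3_class(ev$roc, "RocResult")
    # CTR higher than tumours -> a low value flags a case
    expect_identical(ev$roc$direction, "<")
    expect_gte(ev$roc$auc, 0.5)
})
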