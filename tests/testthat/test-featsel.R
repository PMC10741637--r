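test_that("VIP scores satisfy the mean-square identity and symmetry", {
    sim <- simulateFractionProteome(n_proteins = 40, frac_differential = 0,
                                    missing_rate = 0, seed = 51)
    v <- plsdaVip(sim$experiment)
    expect_equal(mean(v$vip^2), 1, tolerance = 1e-6)

    # duplicated protein rows receive equal VIP
    vals <- intensityValues(sim$experiment)
    vals[2, ] <- vals[1, ]
    pe <- makeExperiment(vals, fraction = as.character(fractionLabels(sim$experiment)))
    v2 <- plsdaVip(pe)
    expect_equal(v2$vip[1], v2$vip[2], tolerance = 1e-9)
    expect_error(plsdaVip(sim$experiment[, fractionLabels(sim$experiment) == "Tot"]),
                 "2 classes")
})

test_that("a perfectly separating protein attains the top VIP", {
    hits <- vapply(1:20, function(s) {
        sim <- simulateFractionProteome(n_proteins = 50,
                                        frac_differential = 0,
                                        missing_rate = 0, seed = 200 + s)
        pe <- plantShift(sim$experiment, 1L, "Mv", 8)
        v <- plsdaVip(pe)
        which.max(v$vip) == 1L
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("VIP agrees with the mixOmics reference implementation", {
    sim <- simulateFractionProteome(n_proteins = 30, frac_differential = 0.4,
                                    effect_sd = 2, missing_rate = 0,
                                    seed = 53)
    pe <- sim$experiment
    mine <- plsdaVip(pe, n_components = 2)
    X <- scale(t(intensityValues(pe)))
    fit <- mixOmics::plsda(X, factor(fractionLabels(pe)), ncomp = 2)
    ref <- mixOmics::vip(fit)[, 2]
    expect_gt(cor(mine$vip, ref), 0.95)
    expect_gt(cor(rank(mine$vip), rank(ref), method = "spearman"), 0.9)
})

test_that("svmRankFeatures yields a permutation with informative proteins first", {
    sim <- simulateFractionProteome(n_proteins = 40, frac_differential = 0,
                                    missing_rate = 0, seed = 55)
    r0 <- svmRankFeatures(sim$experiment)
    expect_identical(sort(r0$svm_rank), 1:40)

    hits <- vapply(1:20, function(s) {
        sim <- simulateFractionProteome(n_proteins = 40,
                                        frac_differential = 0,
                                        missing_rate = 0, seed = 300 + s)
        # one protein with three well-separated class levels
        pe <- plantShift(plantShift(sim$experiment, 1L, "Mv", 8),
                         1L, "Ex", -8)
        svmRankFeatures(pe)$svm_rank[1] == 1L
    }, logical(1))
    expect_gte(mean(hits), 0.95)

    # two identical informative proteins end on adjacent ranks
    sim2 <- simulateFractionProteome(n_proteins = 30, frac_differential = 0,
                                     missing_rate = 0, seed = 56)
    pe2 <- plantShift(sim2$experiment, 1L, "Mv", 8)
    vals <- intensityValues(pe2); vals[2, ] <- vals[1, ]
    pe2 <- makeExperiment(vals, fraction = as.character(fractionLabels(pe2)))
    r2 <- svmRankFeatures(pe2)
    expect_identical(abs(r2$svm_rank[1] - r2$svm_rank[2]), 1L)
    expect_error(svmRankFeatures(sim2$experiment[1, ]), "at least 2 proteins")
})

test_that("svmCv is deterministic, covers all samples and finds structure", {
    sim <- simulateFractionProteome(n_proteins = 60, frac_differential = 0.3,
                                    effect_sd = 4, missing_rate = 0,
                                    seed = 57)
    cv1 <- svmCv(sim$experiment, seed = 5)
    cv2 <- svmCv(sim$experiment, seed = 5)
    expect_identical(cv1$splits, cv2$splits)
    expect_identical(cv1$confusion, cv2$confusion)
    # planted separation -> perfect classification
    expect_equal(cv1$mean_accuracy, 1)
    expect_identical(sum(cv1$confusion) - sum(diag(cv1$confusion)), 0L)
    # coverage stopping rule: every sample in >= 1 learn and >= 1 test set
    learn <- unique(unlist(lapply(cv1$splits, `[[`, "learn")))
    test <- unique(unlist(lapply(cv1$splits, `[[`, "test")))
    expect_setequal(learn, colnames(sim$experiment))
    expect_setequal(test, colnames(sim$experiment))
    # learn/test disjoint and exhaustive per split
    for (sp in cv1$splits) {
        expect_length(intersect(sp$learn, sp$test), 0L)
        expect_setequal(c(sp$learn, sp$test), colnames(sim$experiment))
    }
})

test_that("label-permuted data classify at chance level", {
    sim <- simulateFractionProteome(n_proteins = 60, frac_differential = 0.3,
                                    effect_sd = 4, missing_rate = 0,
                                    seed = 58)
    perm <- withr::with_seed(1, sample(as.character(fractionLabels(sim$experiment))))
    pe <- makeExperiment(intensityValues(sim$experiment), fraction = perm)
    accs <- vapply(1:5, function(s) svmCv(pe, seed = s)$mean_accuracy,
                   numeric(1))
    expect_lt(abs(mean(accs) - 1 / 3), 0.15)
    # paired comparison: true labels always beat permuted ones
    accs_true <- vapply(1:5, function(s)
        svmCv(sim$experiment, seed = s)$mean_accuracy, numeric(1))
    expect_true(all(accs_true >= accs))
})

test_that("aucMannWhitney matches enumeration and the trapezoidal oracle", {
    expect_equal(aucMannWhitney(c(1, 2, 3), c(4, 5, 6)), 1)
    expect_equal(aucMannWhitney(c(1, 3), c(2, 4)), 0.75)
    expect_equal(aucMannWhitney(c(1, 1), c(1, 1)), 0.5)  # all ties
    withr::with_seed(61, {
        for (rep in 1:20) {
            a <- sample(1:8, sample(3:10, 1), replace = TRUE)
            b <- sample(1:8, sample(3:10, 1), replace = TRUE)
            expect_equal(aucMannWhitney(a, b), trapezoidAuc(a, b),
                         tolerance = 1e-12)
        }
    })
})

test_that("rocAucPerProtein is oriented toward the second fraction", {
    v <- rbind(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1))
    pe <- makeExperiment(v, fraction = rep(c("Tot", "Mv"), each = 3))
    a <- rocAucPerProtein(pe, c("Tot", "Mv"))
    expect_equal(a$auc, c(1, 0))
    expect_error(rocAucPerProtein(pe, c("Tot", "Ex")), "empty class")
})

test_that("corePanel finds a minimal panel and reports its VIP limit", {
    sim <- simulateFractionProteome(n_proteins = 50, frac_differential = 0,
                                    missing_rate = 0, seed = 63)
    pe <- plantShift(sim$experiment, 1L, "Mv", 8)
    pe <- plantShift(pe, 2L, "Ex", 8)
    pe <- plantShift(pe, 3L, "Tot", 8)
    rk <- featureRanking(pe)
    cp <- corePanel(pe, rk, pipelineConfig(seed = 2))
    expect_true(cp$achieved)
    expect_lte(cp$k, 5L)
    expect_identical(sum(cp$ranking$in_core_panel), cp$k)
    expect_true(all(cp$panel %in% cp$ranking$protein[cp$ranking$in_core_panel]))
    expect_equal(cp$vip_limit,
                 cp$ranking$vip[cp$ranking$protein == cp$panel[cp$k]])

    # monotone in information: a fourth perfect separator cannot hurt
    pe4 <- plantShift(pe, 4L, "Mv", 8)
    cp4 <- corePanel(pe4, featureRanking(pe4), pipelineConfig(seed = 2))
    expect_lte(cp4$k, cp$k + 0L)
})

test_that("corePanel warns when classes are inseparable", {
    sim <- simulateFractionProteome(n_proteins = 10, frac_differential = 0,
                                    missing_rate = 0, n_per_fraction = 4,
                                    seed = 64)
    rk <- featureRanking(sim$experiment)
    expect_warning(cp <- corePanel(sim$experiment, rk,
                                   pipelineConfig(seed = 3), max_k = 4),
                   "diagonal")
    expect_false(cp$achieved)
    expect_lt(cp$cv$mean_accuracy, 0.9)
})
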