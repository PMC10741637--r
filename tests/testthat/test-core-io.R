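test_that("readProteinMatrix maps zeros/blanks/NaN to missing and log2-transforms", {
    tab <- data.frame(protein = c("A", "B", "C"),
                      s1 = c("4", "0", "8"), s2 = c("16", "2", "NaN"),
                      stringsAsFactors = FALSE)
    fx <- writeMatrixFixture(tab, fractions = c("Tot", "Mv"))
    pe <- readProteinMatrix(fx$matrix, fx$metadata)
    expect_equal(dim(pe), c(3L, 2L))
    expect_equal(intensityValues(pe)["A", ], c(s1 = 2, s2 = 4))
    expect_identical(sum(missingMask(pe)), 2L)
    expect_true(missingMask(pe)["B", "s1"] && missingMask(pe)["C", "s2"])
})

test_that("readProteinMatrix rejects bad input with informative errors", {
    tab <- data.frame(protein = c("A", "A"), s1 = c("1", "2"), s2 = c("3", "4"))
    fx <- writeMatrixFixture(tab, fractions = c("Tot", "Mv"))
    expect_error(readProteinMatrix(fx$matrix, fx$metadata), "duplicate protein")

    tab2 <- data.frame(protein = c("A", "B"), s1 = c("1", "2"), s2 = c("3", "4"))
    fx2 <- writeMatrixFixture(tab2, fractions = c("Tot", "Mv"))
    meta_bad <- tempfile(fileext = ".tsv")
    utils::write.table(data.frame(sample_id = "s1", fraction = "Tot",
                                  subject = "x"),
                       meta_bad, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readProteinMatrix(fx2$matrix, meta_bad), "absent from metadata")

    tab3 <- data.frame(protein = c("A", "B"), s1 = c("1", "oops"),
                       s2 = c("3", "4"))
    fx3 <- writeMatrixFixture(tab3, fractions = c("Tot", "Mv"))
    err <- tryCatch(readProteinMatrix(fx3$matrix, fx3$metadata),
                    error = conditionMessage)
    expect_match(err, "oops")
    expect_match(err, "B")
    expect_match(err, "s1")
})

test_that("write/read round trip preserves values, mask and labels", {
    withr::with_seed(42, {
        v <- matrix(rnorm(60, 25, 3), 10, 6)
        miss <- matrix(runif(60) < 0.2, 10, 6)
    })
    pe <- makeExperiment(v, n_per_fraction = 2, missing = miss)
    mp <- tempfile(); md <- tempfile()
    writeProteinMatrix(pe, mp, md)
    back <- readProteinMatrix(mp, md)
    expect_identical(missingMask(back), missingMask(pe))
    expect_equal(intensityValues(back), intensityValues(pe), tolerance = 1e-9)
    expect_identical(as.character(fractionLabels(back)),
                     as.character(fractionLabels(pe)))
    expect_identical(subjectIds(back), subjectIds(pe))
})

test_that("readGmt parses, upper-cases and validates", {
    f <- tempfile(fileext = ".gmt")
    writeLines(c("SYNAPTOSOME\tdesc\tstxbp1\tGNB1\tSTXBP1",
                 "OTHER\tdesc\tA\tB\tC"), f)
    db <- readGmt(f, namespace = "GO")
    expect_identical(sort(annotationTerms(db)$SYNAPTOSOME),
                     c("GNB1", "STXBP1"))   # duplicates collapse, upper case
    expect_identical(unname(termNamespace(db)["OTHER"]), "GO")

    writeLines(c("T1\tdesc\tA", "short\tonly2fields"), f)
    expect_error(readGmt(f), "line 2")

    writeLines(c("T1\tdesc\tA", "T1\tdesc\tB"), f)
    expect_error(readGmt(f), "duplicate term")

    writeLines(c("EMPTY\tdesc\t\t", "T2\tdesc\tX"), f)
    expect_warning(db2 <- readGmt(f), "empty member list")
    expect_identical(names(annotationTerms(db2)), "T2")
})

test_that("GMT round trip preserves term content", {
    db <- AnnotationDb(list(K1 = c("A", "B"), K2 = letters[1:5]),
                       namespace = "kinase_substrate")
    f <- tempfile(fileext = ".gmt")
    writeGmt(db, f)
    back <- readGmt(f, namespace = "kinase_substrate")
    expect_identical(annotationTerms(back), annotationTerms(db))
})

test_that("vennPartition handles worked examples", {
    v <- vennPartition(c("a", "b"), c("b", "c"), "c")
    expect_identical(unname(v$region_counts[c("A_only", "B_only", "C_only")]),
                     c(1L, 0L, 0L))
    expect_identical(unname(v$region_counts["ABC"]), 0L)
    expect_identical(v$union_size, 3L)

    s <- letters[1:7]
    v2 <- vennPartition(s, s, s)
    expect_identical(unname(v2$region_counts["ABC"]), 7L)
    expect_identical(sum(v2$region_counts), 7L)
})

test_that("vennPartition satisfies inclusion-exclusion on random triples", {
    withr::with_seed(11, {
        for (rep in 1:20) {
            u <- sprintf("g%03d", 1:80)
            A <- sample(u, sample(5:60, 1)); B <- sample(u, sample(5:60, 1))
            C <- sample(u, sample(5:60, 1))
            v <- vennPartition(A, B, C)
            # element-by-element oracle
            rc <- v$region_counts
            expect_identical(sum(rc), length(union(union(A, B), C)))
            expect_identical(unname(rc["A_only"] + rc["AB"] + rc["AC"] + rc["ABC"]),
                             length(A))
            expect_identical(unname(rc["B_only"] + rc["AB"] + rc["BC"] + rc["ABC"]),
                             length(B))
            expect_identical(unname(rc["ABC"]),
                             length(intersect(intersect(A, B), C)))
        }
    })
})

test_that("pipelineConfig validates fields and reads YAML", {
    expect_error(pipelineConfig(presence_threshold = 0))
    expect_error(pipelineConfig(learn_fraction = 1))
    f <- tempfile(fileext = ".yaml")
    writeLines(c("alpha: 0.01", "vip_limit: 9.1"), f)
    cfg <- readPipelineConfig(f)
    expect_equal(cfg$alpha, 0.01)
    expect_equal(cfg$presence_threshold, 0.7)
    writeLines("nonsense_key: 1", f)
    expect_error(readPipelineConfig(f), "unknown configuration key")
})

test_that("ProteomeExperiment enforces its invariants", {
    v <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
    expect_error(ProteomeExperiment(v, fraction = c("Tot", "Weird"),
                                    subject = c("x", "y")),
                 "fraction")
    rownames(v) <- c("A", "A")
    expect_error(validObject(
        ProteomeExperiment(v, fraction = c("Tot", "Mv"),
                           subject = c("x", "y"))),
        "unique")
})
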