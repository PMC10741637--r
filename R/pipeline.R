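#' ELISA validation statistics for a three-group cohort
#'
#' The validation analysis applied to one reduced plate: per-group medians
#' with interquartile ranges, a Kruskal-Wallis test across the three
#' clinical groups, and a ROC analysis of controls against the pooled
#' tumour groups (PA and MB together), where a case is a tumour subject.
#'
#' @param wells ELISA well data.frame (see [readElisaTable()]).
#' @param control the control group label. Default `"CTR"`.
#' @return list with `lod`, `samples`, `summary` (medians/IQr), `kw`
#'   (Kruskal-Wallis) and `roc` (a `RocResult`, controls vs pooled
#'   tumours).
#' @export
elisaValidation <- function(wells, control = "CTR") {
    red <- reducePlate(wells)
    s <- red$samples
    list(lod = red$lod, samples = s,
         summary = groupSummary(s$ru, s$group),
         kw = kruskalWallisGroups(s$ru, s$group),
         roc = rocAnalysis(s$ru, s$group != control))
}

#' Simulate and write all pipeline inputs
#'
#' Emits a simulated protein matrix with metadata, a GMT annotation file,
#' an ELISA plate table and a ground-truth JSON into `outdir`.
#'
#' @param outdir output directory (created if absent).
#' @param seed integer master seed.
#' @param ... passed to [simulateFractionProteome()].
#' @return invisibly, the named list of file paths.
#' @export
simulateInputs <- function(outdir, seed = 1L, ...) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateFractionProteome(seed = seed, ...)
    ann <- simulateAnnotations(sim, seed = seed + 1L)
    eli <- simulateElisaCohort(seed = seed + 2L)
    paths <- list(matrix = file.path(outdir, "intensities.tsv"),
                  metadata = file.path(outdir, "samples.tsv"),
                  gmt = file.path(outdir, "annotations.gmt"),
                  elisa = file.path(outdir, "elisa.tsv"),
                  truth = file.path(outdir, "truth.json"))
    writeProteinMatrix(sim$experiment, paths$matrix, paths$metadata)
    writeGmt(ann$db, paths$gmt)
    writeElisaTable(eli$wells, paths$elisa)
    jsonlite::write_json(
        list(differential = sim$truth$differential,
             params = sim$truth$params,
             enriched_terms = ann$enriched_terms,
             elisa = eli$truth),
        paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(paths)
}

.writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline on input files
#'
#' Chains every stage: read, presence filter, downshifted-normal
#' imputation, quantile normalisation, QC clustering, ANOVA and pairwise
#' Welch tests with volcano flags, VIP / SVM-RFE feature ranking with the
#' minimal core panel on the ANOVA-significant subset, two-dimensional
#' annotation enrichment over the three comparison pairs, kinase
#' enrichment, and (when an ELISA table is given) the validation
#' statistics. All stage outputs are written as TSV plus a JSON run
#' manifest; outputs are byte-identical across runs with the same inputs
#' and configuration.
#'
#' @param matrix_path,metadata_path protein matrix and sample metadata TSV.
#' @param outdir output directory.
#' @param gmt_path optional GMT annotation file (enrichment is skipped
#'   without it). Terms in the `kinase_substrate` namespace are not
#'   expected here; pass them via `kinase_gmt_path`.
#' @param kinase_gmt_path optional GMT of kinase substrate sets.
#' @param elisa_path optional ELISA plate TSV.
#' @param config a [pipelineConfig()].
#' @param use_all_proteins rank all proteins instead of the
#'   ANOVA-significant subset.
#' @return invisibly, the list of stage results.
#' @export
runPipeline <- function(matrix_path, metadata_path, outdir,
                        gmt_path = NULL, kinase_gmt_path = NULL,
                        elisa_path = NULL, config = pipelineConfig(),
                        use_all_proteins = FALSE) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    pe <- readProteinMatrix(matrix_path, metadata_path)
    pe <- filterByPresence(pe, config$presence_threshold)
    pe <- imputeDownshiftedNormal(pe, config$impute_width,
                                  config$impute_downshift,
                                  seed = config$seed)
    pe <- quantileNormalizeIntensities(pe)
    writeProteinMatrix(pe, file.path(outdir, "normalized.tsv"),
                       file.path(outdir, "normalized_samples.tsv"))

    qc <- qcCluster(pe, seed = config$seed)
    .writeTsv(data.frame(sample = colnames(pe), qc$mds,
                         cluster = qc$cluster[colnames(pe)]),
              file.path(outdir, "qc_mds.tsv"))

    diff <- runDifferential(pe, config)
    for (nm in names(diff$pairwise))
        .writeTsv(diff$pairwise[[nm]],
                  file.path(outdir, paste0("diff_", nm, ".tsv")))
    .writeTsv(diff$anova, file.path(outdir, "diff_anova.tsv"))
    .writeTsv(diff$counts, file.path(outdir, "diff_counts.tsv"))

    sig <- significantProteins(diff$anova)
    sub <- if (use_all_proteins || length(sig) < 3L) pe else pe[sig, ]
    ranking <- featureRanking(sub)
    panel <- corePanel(sub, ranking, config)
    .writeTsv(panel$ranking, file.path(outdir, "feature_ranking.tsv"))

    enr <- NULL
    if (!is.null(gmt_path)) {
        db <- readGmt(gmt_path, namespace = "GO")
        pairs <- utils::combn(names(diff$pairwise), 2L, simplify = FALSE)
        enr <- lapply(pairs, function(pr)
            enrichment2d(diff$pairwise[[pr[1]]], diff$pairwise[[pr[2]]],
                         db, min_members = config$min_members,
                         alpha = config$alpha,
                         n_permutations = config$n_permutations,
                         seed = config$seed))
        names(enr) <- vapply(pairs, paste, "", collapse = "__")
        for (nm in names(enr))
            .writeTsv(enr[[nm]],
                      file.path(outdir, paste0("enrich2d_", nm, ".tsv")))
    }
    kea <- NULL
    if (!is.null(kinase_gmt_path)) {
        kdb <- readGmt(kinase_gmt_path, namespace = "kinase_substrate")
        tb <- diff$pairwise$Tot_vs_Mv
        kea <- kinaseEnrichment(significantProteins(tb), tb$protein, kdb,
                                alpha = config$alpha,
                                fold_changes = stats::setNames(tb$log2_fc,
                                                               tb$protein))
        .writeTsv(kea, file.path(outdir, "kinase_enrichment.tsv"))
    }
    elisa <- NULL
    if (!is.null(elisa_path)) {
        elisa <- elisaValidation(readElisaTable(elisa_path))
        .writeTsv(elisa$summary, file.path(outdir, "elisa_summary.tsv"))
        jsonlite::write_json(
            c(elisa$roc[c("auc", "ci_low", "ci_high", "p", "cutoff",
                          "direction", "sensitivity", "specificity",
                          "youden_j", "lr_positive", "quality_bin")],
              list(kw_p = elisa$kw$p, lod = elisa$lod)),
            file.path(outdir, "elisa_roc.json"), auto_unbox = TRUE,
            digits = NA)
    }

    manifest <- list(config = unclass(config),
                     n_proteins = nrow(pe), n_samples = ncol(pe),
                     qc = list(ari = qc$ari_vs_fraction,
                               outliers = qc$outliers),
                     panel = list(k = panel$k, vip_limit = panel$vip_limit,
                                  achieved = panel$achieved),
                     outputs = list.files(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(experiment = pe, qc = qc, differential = diff,
                   ranking = ranking, panel = panel, enrichment = enr,
                   kinase = kea, elisa = elisa))
}
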