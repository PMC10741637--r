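#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow common
#' practice in label-free proteomics: proteins must be detected in at least
#' 70% of the samples of one fraction to enter the analysis; differential
#' calls require a Benjamini-Hochberg adjusted p-value at or below `alpha`
#' and post-hoc power at or above `power_threshold`; the volcano cutoff
#' curve is `y = |c / (x - x0)|` on the (|log2 fold change|, -log10 p)
#' plane; classifier cross-validation uses repeated stratified splits with
#' a 65%/35% learn/test partition.
#'
#' @param presence_threshold detection share required in at least one
#'   fraction, in (0, 1]. Default 0.70.
#' @param alpha significance level for adjusted p-values. Default 0.05.
#' @param power_threshold minimum post-hoc power for a differential call.
#'   Default 0.80.
#' @param volcano_c positive curvature constant of the volcano cutoff.
#'   Default 0.5.
#' @param volcano_x0 minimal |log2 fold change| (curve pole). Default 1.
#' @param vip_limit VIP score reference threshold. Default 9.1.
#' @param learn_fraction share of samples used for learning per split,
#'   in (0, 1). Default 0.65.
#' @param n_splits minimum number of Monte-Carlo splits. Default 4.
#' @param impute_width imputation width as a fraction of the per-sample sd.
#'   Default 0.3.
#' @param impute_downshift imputation downshift in per-sample sd multiples.
#'   Default 1.8.
#' @param min_members minimum annotation-term size for 2D enrichment.
#'   Default 5.
#' @param n_permutations permutations for the enrichment diagonal band.
#'   Default 1000.
#' @param seed non-negative integer seed.
#' @return a validated `PipelineConfig` (a named list).
#' @examples
#' cfg <- pipelineConfig(alpha = 0.01)
#' cfg$alpha
#' @export
pipelineConfig <- function(presence_threshold = 0.70,
                           alpha = 0.05,
                           power_threshold = 0.80,
                           volcano_c = 0.5,
                           volcano_x0 = 1,
                           vip_limit = 9.1,
                           learn_fraction = 0.65,
                           n_splits = 4L,
                           impute_width = 0.3,
                           impute_downshift = 1.8,
                           min_members = 5L,
                           n_permutations = 1000L,
                           seed = 0L) {
    cfg <- list(presence_threshold = presence_threshold, alpha = alpha,
                power_threshold = power_threshold, volcano_c = volcano_c,
                volcano_x0 = volcano_x0, vip_limit = vip_limit,
                learn_fraction = learn_fraction, n_splits = as.integer(n_splits),
                impute_width = impute_width,
                impute_downshift = impute_downshift,
                min_members = as.integer(min_members),
                n_permutations = as.integer(n_permutations),
                seed = as.integer(seed))
    stopifnot(presence_threshold > 0, presence_threshold <= 1,
              alpha > 0, alpha < 1,
              power_threshold > 0, power_threshold < 1,
              volcano_c > 0, volcano_x0 >= 0, vip_limit > 0,
              learn_fraction > 0, learn_fraction < 1,
              cfg$n_splits >= 1L, impute_width > 0, impute_downshift >= 0,
              cfg$seed >= 0L)
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file with any subset of the [pipelineConfig()] fields.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(raw), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(pipelineConfig, raw)
}

#' @export
print.PipelineConfig <- function(x, ...) {
    cat("PipelineConfig:\n")
    for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
    invisible(x)
}
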