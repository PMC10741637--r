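#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

FRACTION_LEVELS <- c("Tot", "Mv", "Ex")
ELISA_GROUPS <- c("CTR", "PA", "MB")

#' ProteomeExperiment: a log2 protein-by-sample intensity container
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays: `intensity`
#' (log2 protein abundances, `NA` where the protein was not detected) and
#' `missing` (a logical mask, `TRUE` = not detected). Column data carry the
#' CSF fraction of each sample (`Tot`, `Mv` or `Ex`) and its subject id.
#' Missing entries are never used in downstream statistics unless imputed
#' first (see [imputeDownshiftedNormal()]).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [ProteomeExperiment()] for the constructor,
#'   [intensityValues()], [missingMask()], [fractionLabels()], [subjectIds()]
#'   for accessors.
#' @export
setClass("ProteomeExperiment", contains = "SummarizedExperiment")

.validProteomeExperiment <- function(object) {
    msg <- NULL
    an <- names(SummarizedExperiment::assays(object))
    if (!all(c("intensity", "missing") %in% an))
        msg <- c(msg, "assays must include 'intensity' and 'missing'")
    else {
        mm <- SummarizedExperiment::assay(object, "missing")
        if (!is.logical(mm))
            msg <- c(msg, "'missing' assay must be logical")
        else {
            iv <- SummarizedExperiment::assay(object, "intensity")
            if (any(is.na(iv) & !mm))
                msg <- c(msg, "NA intensity found outside the missing mask")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "protein ids (rownames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("fraction", "subject") %in% colnames(cd)))
        msg <- c(msg, "colData must have columns 'fraction' and 'subject'")
    else if (!all(as.character(cd$fraction) %in% FRACTION_LEVELS))
        msg <- c(msg, sprintf("fraction labels must be drawn from {%s}",
                              paste(FRACTION_LEVELS, collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("ProteomeExperiment", .validProteomeExperiment)

#' Construct a ProteomeExperiment
#'
#' @param intensity numeric matrix of log2 intensities, proteins in rows
#'   (unique rownames = gene names), samples in columns (unique colnames).
#'   `NA` entries are treated as not detected.
#' @param fraction character/factor of length `ncol(intensity)` with values
#'   in `Tot`, `Mv`, `Ex`.
#' @param subject character of subject ids, same length.
#' @param missing optional logical mask of the same shape; defaults to
#'   `is.na(intensity)`.
#' @return a [ProteomeExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 25), 3, 4,
#'             dimnames = list(c("STXBP1", "GNB1", "ANXA2"), paste0("s", 1:4)))
#' pe <- ProteomeExperiment(m, fraction = c("Tot", "Tot", "Mv", "Mv"),
#'                          subject = paste0("p", 1:4))
#' @export
ProteomeExperiment <- function(intensity, fraction, subject,
                               missing = is.na(intensity)) {
    stopifnot(is.matrix(intensity), is.matrix(missing),
              all(dim(intensity) == dim(missing)))
    intensity[missing] <- NA_real_
    storage.mode(missing) <- "logical"
    dimnames(missing) <- dimnames(intensity)
    fraction <- factor(as.character(fraction), levels = FRACTION_LEVELS)
    if (anyNA(fraction))
        stop("fraction labels must be one of ", paste(FRACTION_LEVELS, collapse = "/"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity, missing = missing),
        colData = S4Vectors::DataFrame(fraction = fraction,
                                       subject = as.character(subject),
                                       row.names = colnames(intensity)))
    new("ProteomeExperiment", se)
}

#' AnnotationDb: named gene sets grouped by namespace
#'
#' A light container mapping annotation term names to member gene sets
#' (upper-cased gene names), each term carrying a namespace label (`GO`,
#' `disease`, `kinase_substrate` or `custom`). Term names are unique within
#' a namespace and every member set is non-empty.
#'
#' @slot terms named list of character vectors (members, upper case).
#' @slot namespace named character, same names as `terms`.
#' @export
setClass("AnnotationDb",
         representation(terms = "list", namespace = "character"))

ANNOTATION_NAMESPACES <- c("GO", "disease", "kinase_substrate", "custom")

.validAnnotationDb <- function(object) {
    msg <- NULL
    if (!identical(names(object@terms), names(object@namespace)))
        msg <- c(msg, "terms and namespace must share names")
    if (any(lengths(object@terms) == 0L))
        msg <- c(msg, "every term must have at least one member")
    if (!all(object@namespace %in% ANNOTATION_NAMESPACES))
        msg <- c(msg, "unknown namespace label")
    key <- paste(object@namespace, names(object@terms))
    if (anyDuplicated(key))
        msg <- c(msg, "term names must be unique within a namespace")
    if (is.null(msg)) TRUE else msg
}
setValidity("AnnotationDb", .validAnnotationDb)

#' Construct an AnnotationDb
#'
#' @param terms named list of character vectors of gene names.
#' @param namespace single namespace label recycled over terms, or a named
#'   character vector parallel to `terms`.
#' @return an [AnnotationDb-class].
#' @export
AnnotationDb <- function(terms, namespace = "custom") {
    terms <- lapply(terms, function(m) unique(toupper(as.character(m))))
    if (length(namespace) == 1L)
        namespace <- setNames(rep(namespace, length(terms)), names(terms))
    new("AnnotationDb", terms = terms, namespace = namespace[names(terms)])
}

setMethod("show", "ProteomeExperiment", function(object) {
    callNextMethod()
    miss <- mean(SummarizedExperiment::assay(object, "missing"))
    tab <- table(SummarizedExperiment::colData(object)$fraction)
    cat(sprintf("missing: %.1f%% | samples per fraction: %s\n",
                100 * miss,
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
})

setMethod("show", "AnnotationDb", function(object) {
    cat(sprintf("AnnotationDb with %d terms (%s)\n", length(object@terms),
                paste(sprintf("%s: %d", names(table(object@namespace)),
                              table(object@namespace)), collapse = ", ")))
    cat(sprintf("term sizes: %d-%d\n",
                if (length(object@terms)) min(lengths(object@terms)) else 0L,
                if (length(object@terms)) max(lengths(object@terms)) else 0L))
})
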