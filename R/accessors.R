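#' Accessors for ProteomeExperiment and AnnotationDb
#'
#' `intensityValues()` returns the log2 intensity matrix (`NA` where not
#' detected); `missingMask()` the logical not-detected mask;
#' `fractionLabels()` the per-sample fraction factor; `subjectIds()` the
#' per-sample subject ids; `proteinIds()` the row (gene) names;
#' `annotationTerms()` the named member list of an [AnnotationDb-class];
#' `termNamespace()` its namespace labels.
#'
#' @param x a [ProteomeExperiment-class] or [AnnotationDb-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("fractionLabels", function(x) standardGeneric("fractionLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("annotationTerms", function(x) standardGeneric("annotationTerms"))

#' @rdname accessors
#' @export
setGeneric("termNamespace", function(x) standardGeneric("termNamespace"))

#' @rdname accessors
setMethod("intensityValues", "ProteomeExperiment", function(x)
    SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
setMethod("missingMask", "ProteomeExperiment", function(x)
    SummarizedExperiment::assay(x, "missing"))

#' @rdname accessors
setMethod("fractionLabels", "ProteomeExperiment", function(x)
    SummarizedExperiment::colData(x)$fraction)

#' @rdname accessors
setMethod("subjectIds", "ProteomeExperiment", function(x)
    setNames(SummarizedExperiment::colData(x)$subject, colnames(x)))

#' @rdname accessors
setMethod("proteinIds", "ProteomeExperiment", function(x) rownames(x))

#' @rdname accessors
setMethod("annotationTerms", "AnnotationDb", function(x) x@terms)

#' @rdname accessors
setMethod("termNamespace", "AnnotationDb", function(x) x@namespace)
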