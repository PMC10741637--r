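#' Read a protein-group intensity matrix with sample metadata
#'
#' Reads a tab-separated protein-group table (first column = gene name,
#' remaining columns = raw intensities per sample) together with a sample
#' metadata table (columns `sample_id`, `fraction`, `subject`). Zeros,
#' empty cells and `NaN` tokens are treated as not detected — label-free
#' zeros mean non-detection, not zero abundance — and all detected values
#' are log2-transformed. Row order is preserved.
#'
#' @param path TSV of raw intensities with a header row of sample ids.
#' @param metadata_path TSV mapping every sample id to a fraction
#'   (`Tot`/`Mv`/`Ex`) and subject id.
#' @return a [ProteomeExperiment-class].
#' @export
readProteinMatrix <- function(path, metadata_path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character", na.strings = NULL)
    if (ncol(tab) < 2L) stop("matrix file needs a protein column plus samples")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate protein id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    meta <- utils::read.delim(metadata_path, check.names = FALSE)
    need <- c("sample_id", "fraction", "subject")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns ", paste(need, collapse = ", "))
    samples <- colnames(tab)[-1L]
    absent <- setdiff(samples, meta$sample_id)
    if (length(absent))
        stop("sample(s) absent from metadata: ", paste(absent, collapse = ", "))
    meta <- meta[match(samples, meta$sample_id), ]

    raw <- matrix(NA_real_, nrow(tab), length(samples),
                  dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
        cell <- trimws(tab[[j + 1L]])
        blank <- cell == "" | toupper(cell) == "NAN"
        val <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(val) & !blank)
        if (length(bad))
            stop(sprintf("non-numeric cell '%s' at protein '%s', sample '%s'",
                         cell[bad[1L]], ids[bad[1L]], samples[j]))
        val[blank | val == 0] <- NA_real_
        raw[, j] <- val
    }
    ProteomeExperiment(log2(raw), fraction = meta$fraction,
                       subject = meta$subject)
}

#' Write a ProteomeExperiment back to TSV
#'
#' Inverse of [readProteinMatrix()]: intensities are written on the raw
#' scale (`2^log2`), missing entries as `0`, plus the sample metadata
#' table. `readProteinMatrix()` on the two files reproduces the object up
#' to floating-point round trip.
#'
#' @param x a [ProteomeExperiment-class].
#' @param path,metadata_path output TSV paths.
#' @return invisibly, `path`.
#' @export
writeProteinMatrix <- function(x, path, metadata_path) {
    raw <- 2^intensityValues(x)
    raw[missingMask(x)] <- 0
    out <- data.frame(protein = rownames(x), raw, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- data.frame(sample_id = colnames(x),
                       fraction = as.character(fractionLabels(x)),
                       subject = as.character(subjectIds(x)))
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term<TAB>description<TAB>member...`. Members are
#' upper-cased and de-duplicated within a term. A line with fewer than
#' three fields is an error (with its line number); a term whose member
#' list is empty after trimming is skipped with a warning; a repeated term
#' name within the namespace is an error.
#'
#' @param path GMT file.
#' @param namespace one of `GO`, `disease`, `kinase_substrate`, `custom`.
#' @return an [AnnotationDb-class].
#' @export
readGmt <- function(path, namespace = "custom") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    terms <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                         i, length(f)))
        members <- unique(toupper(trimws(f[-(1:2)])))
        members <- members[nzchar(members)]
        if (!length(members)) {
            warning(sprintf("GMT line %d ('%s'): empty member list, skipped",
                            i, f[1L]))
            next
        }
        if (f[1L] %in% names(terms))
            stop(sprintf("duplicate term '%s' (line %d)", f[1L], i))
        terms[[f[1L]]] <- members
    }
    AnnotationDb(terms, namespace = namespace)
}

#' Write an AnnotationDb as GMT
#'
#' @param db an [AnnotationDb-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(db, path) {
    lines <- vapply(names(annotationTerms(db)), function(tn) {
        paste(c(tn, termNamespace(db)[[tn]], annotationTerms(db)[[tn]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Three-set Venn partition of protein identifiers
#'
#' Splits three sets into the seven non-empty regions of a 3-set Venn
#' diagram and reports, per set, its share of the union (one decimal, the
#' convention used when summarising fraction overlap).
#'
#' @param setA,setB,setC character vectors of protein ids.
#' @param labels names of the three sets.
#' @return a `VennPartition`: list with `region_counts` (named integer over
#'   `A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`), `set_labels`,
#'   `union_size`, `set_sizes` and `set_pct` (percent of union, 1 decimal).
#' @examples
#' vennPartition(c("a", "b"), c("b", "c"), "c")$region_counts
#' @export
vennPartition <- function(setA, setB, setC, labels = c("A", "B", "C")) {
    A <- unique(as.character(setA)); B <- unique(as.character(setB))
    C <- unique(as.character(setC))
    u <- union(union(A, B), C)
    inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
    counts <- c(
        A_only = sum(inA & !inB & !inC),
        B_only = sum(!inA & inB & !inC),
        C_only = sum(!inA & !inB & inC),
        AB = sum(inA & inB & !inC),
        AC = sum(inA & !inB & inC),
        BC = sum(!inA & inB & inC),
        ABC = sum(inA & inB & inC))
    sizes <- c(length(A), length(B), length(C))
    names(sizes) <- labels
    structure(list(region_counts = counts, set_labels = labels,
                   union_size = length(u), set_sizes = sizes,
                   set_pct = round(100 * sizes / max(length(u), 1L), 1)),
              class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
    cat(sprintf("VennPartition [%s] union=%d\n",
                paste(x$set_labels, collapse = ", "), x$union_size))
    print(x$region_counts)
    invisible(x)
}

#' Read / write an ELISA plate table
#'
#' TSV with columns `well`, `absorbance`, `role` (one of `sample`,
#' `uncoated_background`, `blank`, `reference_standard`), `group`
#' (`CTR`/`PA`/`MB`, empty for non-sample wells), `fraction`
#' (`Tot`/`Mv`/`Ex`) and `subject`.
#'
#' @param path TSV path.
#' @return `readElisaTable`: a data.frame of wells.
#' @export
readElisaTable <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             na.strings = c("", "NA"))
    need <- c("well", "absorbance", "role", "group", "fraction", "subject")
    if (!all(need %in% colnames(tab)))
        stop("ELISA table must have columns ", paste(need, collapse = ", "))
    roles <- c("sample", "uncoated_background", "blank", "reference_standard")
    if (!all(tab$role %in% roles))
        stop("unknown well role(s): ",
             paste(setdiff(tab$role, roles), collapse = ", "))
    if (any(tab$absorbance < 0, na.rm = TRUE))
        stop("absorbance must be non-negative")
    is_sample <- tab$role == "sample"
    if (!all(tab$group[is_sample] %in% ELISA_GROUPS))
        stop("sample wells must carry a group label in ",
             paste(ELISA_GROUPS, collapse = "/"))
    tab
}

#' @rdname readElisaTable
#' @param tab a well data.frame as returned by [simulateElisaCohort()].
#' @export
writeElisaTable <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    invisible(path)
}
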