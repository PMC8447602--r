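#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<-
NULL

#' Sample annotation for an AP-MS experiment
#'
#' Maps each measured sample (one LC-MS/MS run) to the identity of the tagged
#' bait protein it was pulled down with, the treatment condition, the
#' activation time point in minutes (0 = untreated), the biological replicate
#' index, and an optional background control group label.
#'
#' @slot .Data inherited from [S4Vectors::DataFrame] with required columns
#'   `sample_id`, `bait_id`, `condition`, `time_min`, `replicate` and the
#'   optional column `control_group`.
#'
#' @seealso [readSampleAnnotation()]
#' @export
setClass("SampleAnnotation", contains = "DFrame")

.validSampleAnnotation <- function(object) {
    msg <- character()
    req <- c("sample_id", "bait_id", "condition", "time_min", "replicate")
    miss <- setdiff(req, colnames(object))
    if (length(miss))
        return(paste0("missing required column(s): ",
                      paste(miss, collapse = ", ")))
    if (anyDuplicated(object$sample_id))
        msg <- c(msg, paste0("duplicated sample_id: ",
                             paste(unique(object$sample_id[
                                 duplicated(object$sample_id)]),
                                 collapse = ", ")))
    if (!is.numeric(object$time_min) || anyNA(object$time_min))
        msg <- c(msg, "time_min must be numeric and non-missing")
    else if (any(object$time_min < 0))
        msg <- c(msg, "time_min must be non-negative")
    if (!is.numeric(object$replicate) || anyNA(object$replicate) ||
        any(object$replicate < 1))
        msg <- c(msg, "replicate must be a positive integer")
    cell <- paste(object$bait_id, object$condition, object$time_min,
                  sep = "\r")
    if (any(vapply(split(object$replicate, cell), anyDuplicated, 0L) > 0))
        msg <- c(msg, "replicate indices must be unique within each (bait_id, condition, time_min) cell")
    if (length(msg)) msg else TRUE
}
setValidity("SampleAnnotation", .validSampleAnnotation)

#' Construct a SampleAnnotation
#'
#' @param df a `data.frame` or `DataFrame` with columns `sample_id`,
#'   `bait_id`, `condition`, `time_min`, `replicate` and optionally
#'   `control_group`.
#' @return a validated [SampleAnnotation-class] object, rows in input order,
#'   row names set to `sample_id`.
#' @examples
#' ann <- SampleAnnotation(data.frame(
#'     sample_id = c("s1", "s2"), bait_id = "TRAF2",
#'     condition = "untreated", time_min = 0, replicate = 1:2))
#' @export
SampleAnnotation <- function(df) {
    df <- as.data.frame(df)
    if (!"control_group" %in% colnames(df))
        df$control_group <- NA_character_
    df$sample_id <- as.character(df$sample_id)
    df$bait_id <- as.character(df$bait_id)
    df$condition <- as.character(df$condition)
    df$replicate <- as.integer(df$replicate)
    out <- new("SampleAnnotation", DataFrame(df, row.names = df$sample_id))
    validObject(out)
    out
}

#' @describeIn SampleAnnotation sample identifiers, in annotation order.
#' @param x a `SampleAnnotation`.
#' @export
sampleIDs <- function(x) as.character(x$sample_id)

#' @describeIn SampleAnnotation unique bait identifiers.
#' @export
baitIDs <- function(x) unique(as.character(x$bait_id))

setMethod("show", "SampleAnnotation", function(object) {
    cat(sprintf("SampleAnnotation: %d samples, %d baits, %d time point(s)\n",
                nrow(object), length(baitIDs(object)),
                length(unique(object$time_min))))
    callNextMethod()
})

#' Raw protein-group quantification container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding raw (linear-scale)
#' LFQ intensities in assay `"lfq"`, one row per protein group and one column
#' per sample. A zero intensity encodes "not quantified" (kept as 0 here;
#' converted to a missing value by [log2Transform()]). Row metadata carries
#' the identification flags used by [filterIdentifications()]:
#' `gene_name`, `peptide_count` (razor + unique), `is_contaminant`,
#' `is_reverse`, `only_identified_by_site`.
#'
#' @seealso [readProteinGroups()], [log2Transform()]
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

.validProteinQuant <- function(object) {
    msg <- character()
    if (!"lfq" %in% assayNames(object))
        return("assay 'lfq' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "protein_id row names must be present and unique")
    req <- c("gene_name", "peptide_count", "is_contaminant", "is_reverse",
             "only_identified_by_site")
    miss <- setdiff(req, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    v <- assay(object, "lfq")
    if (any(v < 0, na.rm = TRUE))
        msg <- c(msg, "raw LFQ intensities must be non-negative")
    if (length(msg)) msg else TRUE
}
setValidity("ProteinQuant", .validProteinQuant)

#' Construct a ProteinQuant
#'
#' @param lfq numeric matrix of raw LFQ intensities (proteins x samples);
#'   0 encodes non-detection. Row names are protein ids.
#' @param annotation a [SampleAnnotation-class]; its `sample_id`s must equal
#'   `colnames(lfq)` (same order).
#' @param rowData data.frame of per-protein metadata (`gene_name`,
#'   `peptide_count`, `is_contaminant`, `is_reverse`,
#'   `only_identified_by_site`); missing columns are filled with defaults.
#' @return a [ProteinQuant-class].
#' @export
ProteinQuant <- function(lfq, annotation, rowData = NULL) {
    stopifnot(is.matrix(lfq))
    if (!identical(colnames(lfq), sampleIDs(annotation)))
        stop("lfq column names must match the annotation sample_ids in order")
    n <- nrow(lfq)
    rd <- DataFrame(
        gene_name = character(n), peptide_count = rep(NA_integer_, n),
        is_contaminant = logical(n), is_reverse = logical(n),
        only_identified_by_site = logical(n), row.names = rownames(lfq))
    if (!is.null(rowData))
        for (cn in colnames(rowData)) rd[[cn]] <- rowData[[cn]]
    out <- new("ProteinQuant", SummarizedExperiment(
        assays = list(lfq = lfq), rowData = rd,
        colData = as(annotation, "DFrame")))
    validObject(out)
    out
}

#' @describeIn ProteinQuant raw LFQ intensity matrix (0 = not quantified).
#' @param x a `ProteinQuant`.
#' @export
lfq <- function(x) assay(x, "lfq")

#' Extract the sample annotation of an AP-MS container
#'
#' @param x a [ProteinQuant-class] or [LogIntensities-class].
#' @return the [SampleAnnotation-class] stored in `colData(x)`.
#' @export
sampleAnnotation <- function(x) {
    new("SampleAnnotation", colData(x))
}

setMethod("show", "ProteinQuant", function(object) {
    v <- assay(object, "lfq")
    cat(sprintf(
        "ProteinQuant: %d protein groups x %d samples (%.1f%% quantified)\n",
        nrow(object), ncol(object), 100 * mean(v > 0)))
    callNextMethod()
})

#' Log2 intensity matrix with missingness and imputation masks
#'
#' A [SummarizedExperiment::SummarizedExperiment] with three aligned assays:
#' `log2` (log2 LFQ intensities), `missing` (logical, TRUE where the raw
#' intensity was 0, i.e. not quantified) and `imputed` (logical, TRUE where a
#' value was filled in by [imputeMissing()]). Invariants: every imputed cell
#' is a missing cell, and values are finite wherever a cell is observed or
#' imputed.
#'
#' @seealso [log2Transform()], [imputeMissing()], [filterValidValues()]
#' @export
setClass("LogIntensities", contains = "SummarizedExperiment")

.validLogIntensities <- function(object) {
    msg <- character()
    need <- c("log2", "missing", "imputed")
    miss <- setdiff(need, assayNames(object))
    if (length(miss))
        return(paste0("missing assay(s): ", paste(miss, collapse = ", ")))
    m <- assay(object, "missing"); i <- assay(object, "imputed")
    v <- assay(object, "log2")
    if (!is.logical(m) || !is.logical(i))
        return("'missing' and 'imputed' assays must be logical")
    if (any(i & !m))
        msg <- c(msg, "imputed cells must be a subset of missing cells")
    defined <- !m | i
    if (any(!is.finite(v[defined])))
        msg <- c(msg, "values must be finite wherever observed or imputed")
    if (length(msg)) msg else TRUE
}
setValidity("LogIntensities", .validLogIntensities)

#' Construct a LogIntensities
#'
#' @param values numeric matrix of log2 intensities; cells that are missing
#'   and not imputed may be `NA`.
#' @param missing logical matrix, TRUE where originally not quantified.
#' @param imputed logical matrix, TRUE where filled by imputation (subset of
#'   `missing`).
#' @param annotation a [SampleAnnotation-class] matching the columns.
#' @param rowData optional per-feature metadata.
#' @return a [LogIntensities-class].
#' @export
LogIntensities <- function(values, missing, imputed = NULL,
                           annotation, rowData = NULL) {
    if (is.null(imputed))
        imputed <- matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values))
    if (!identical(colnames(values), sampleIDs(annotation)))
        stop("column names must match the annotation sample_ids in order")
    dimnames(missing) <- dimnames(values)
    dimnames(imputed) <- dimnames(values)
    args <- list(assays = list(log2 = values, missing = missing,
                               imputed = imputed),
                 colData = as(annotation, "DFrame"))
    if (!is.null(rowData)) args$rowData <- rowData
    out <- new("LogIntensities", do.call(SummarizedExperiment, args))
    validObject(out)
    out
}

#' @describeIn LogIntensities log2 intensity matrix (`NA` where missing and
#'   not imputed).
#' @param x a `LogIntensities`.
#' @export
logIntensities <- function(x) assay(x, "log2")

#' @describeIn LogIntensities logical matrix of originally-missing cells.
#' @export
missingMask <- function(x) assay(x, "missing")

#' @describeIn LogIntensities logical matrix of imputed cells.
#' @export
imputedMask <- function(x) assay(x, "imputed")

#' @describeIn LogIntensities matrix of originally observed values only
#'   (`NA` at every missing cell, imputed or not).
#' @export
observedValues <- function(x) {
    v <- assay(x, "log2")
    v[assay(x, "missing")] <- NA_real_
    v
}

setMethod("show", "LogIntensities", function(object) {
    m <- assay(object, "missing"); i <- assay(object, "imputed")
    cat(sprintf(
        "LogIntensities: %d features x %d samples (%.1f%% missing, %.1f%% imputed)\n",
        nrow(object), ncol(object), 100 * mean(m), 100 * mean(i)))
    callNextMethod()
})
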