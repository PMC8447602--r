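#' @importFrom utils read.delim write.table
NULL

.read_tsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, na.strings = c("NA", ""),
               colClasses = NA)
}

# "+" marks (MaxQuant) or boolean literals; anything else is FALSE
.parse_flag <- function(x) {
    if (is.logical(x)) return(!is.na(x) & x)
    x <- trimws(as.character(x))
    !is.na(x) & x %in% c("+", "TRUE", "True", "true", "1")
}

.leading_id <- function(x) sub(";.*$", "", as.character(x))

# Resolve intensity columns: "<prefix><sample_id>" preferred, plain
# sample_id accepted; error lists the absentees.
.intensity_columns <- function(header, sample_ids, prefix) {
    pref <- paste0(prefix, sample_ids)
    use <- ifelse(pref %in% header, pref,
                  ifelse(sample_ids %in% header, sample_ids, NA))
    if (anyNA(use))
        stop("annotation sample(s) absent from table header: ",
             paste(sample_ids[is.na(use)], collapse = ", "))
    use
}

#' Read a sample annotation table
#'
#' Reads a tab-separated table with columns `sample_id`, `bait_id`,
#' `condition`, `time_min`, `replicate` and optionally `control_group`.
#'
#' @param path path to the TSV file.
#' @return a [SampleAnnotation-class].
#' @export
readSampleAnnotation <- function(path) {
    df <- .read_tsv(path)
    req <- c("sample_id", "bait_id", "condition", "time_min", "replicate")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("annotation table lacks required column(s): ",
             paste(miss, collapse = ", "))
    tm <- suppressWarnings(as.numeric(df$time_min))
    if (anyNA(tm))
        stop("non-numeric time_min value(s): ",
             paste(unique(df$time_min[is.na(tm)]), collapse = ", "))
    df$time_min <- tm
    SampleAnnotation(df)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantification table. Required
#' columns: `"Protein IDs"`, `"Razor + unique peptides"`, and one intensity
#' column per annotated sample, named either `"<prefix><sample_id>"`
#' (default prefix `"LFQ intensity "`) or plainly `<sample_id>`. The flag
#' columns `"Potential contaminant"`, `"Reverse"` and
#' `"Only identified by site"` are parsed from `"+"` marks or boolean
#' literals when present; the id prefixes `CON__` and `REV__` also set the
#' contaminant/reverse flags. Zero intensities are preserved as 0 (the
#' MaxQuant encoding of "not quantified"); [log2Transform()] converts them
#' to missing values. Unknown columns are ignored.
#'
#' @param path path to the TSV file.
#' @param annotation a [SampleAnnotation-class]; sample order is taken from
#'   it, never from the file.
#' @param intensity_prefix prefix of the intensity columns.
#' @return a [ProteinQuant-class] with one row per protein group (row name =
#'   leading protein id of the group).
#' @export
readProteinGroups <- function(path, annotation,
                              intensity_prefix = "LFQ intensity ") {
    df <- .read_tsv(path)
    req <- c("Protein IDs", "Razor + unique peptides")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("proteinGroups table lacks required column(s): ",
             paste(miss, collapse = ", "))
    sids <- sampleIDs(annotation)
    cols <- .intensity_columns(colnames(df), sids, intensity_prefix)
    ids <- .leading_id(df[["Protein IDs"]])
    if (anyDuplicated(ids))
        stop("duplicated leading protein id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    lfq <- as.matrix(df[, cols, drop = FALSE])
    mode(lfq) <- "double"
    lfq[is.na(lfq)] <- 0
    dimnames(lfq) <- list(ids, sids)
    flag <- function(col) if (col %in% colnames(df))
        .parse_flag(df[[col]]) else logical(nrow(df))
    rd <- DataFrame(
        gene_name = if ("Gene names" %in% colnames(df))
            .leading_id(df[["Gene names"]]) else ids,
        peptide_count = as.integer(df[["Razor + unique peptides"]]),
        is_contaminant = flag("Potential contaminant") |
            startsWith(ids, "CON__"),
        is_reverse = flag("Reverse") | startsWith(ids, "REV__"),
        only_identified_by_site = flag("Only identified by site"),
        row.names = ids)
    rd$gene_name[is.na(rd$gene_name)] <- ""
    ProteinQuant(lfq, annotation, rowData = rd)
}

#' Read a MaxQuant-style modification-site table
#'
#' Reads a tab-separated site-level table for one modification type
#' (e.g. the `Phospho (STY)Sites.txt` dialect). Required columns:
#' a protein column (`"Protein"` or `"Proteins"`, leading id used),
#' `"Position"`, and per-sample intensity columns (default prefix
#' `"Intensity "`). Rows lacking a position are rejected with a row-level
#' warning. Duplicate (protein, position) rows are kept: aggregation to
#' unique sites happens downstream in [normalizePTMToProtein()].
#'
#' @param path path to the TSV file.
#' @param annotation a [SampleAnnotation-class].
#' @param mod_type modification label recorded on every row, e.g.
#'   `"phospho"`, `"acetyl"`, `"methyl"`.
#' @param intensity_prefix prefix of the intensity columns.
#' @return a `data.frame` (one row per site-level peptide evidence) with
#'   columns `peptide_id`, `protein_id`, `mod_type`, `site_position`,
#'   `residue`, then one numeric intensity column per sample (0 = not
#'   detected), in annotation order.
#' @export
readModifiedPeptideSites <- function(path, annotation, mod_type,
                                     intensity_prefix = "Intensity ") {
    df <- .read_tsv(path)
    prot_col <- intersect(c("Protein", "Proteins"), colnames(df))[1]
    if (is.na(prot_col) || !"Position" %in% colnames(df))
        stop("site table lacks required column(s): ",
             paste(setdiff(c("Protein(s)", "Position"),
                           c(if (!is.na(prot_col)) "Protein(s)",
                             if ("Position" %in% colnames(df)) "Position")),
                   collapse = ", "))
    sids <- sampleIDs(annotation)
    cols <- .intensity_columns(colnames(df), sids, intensity_prefix)
    pos <- suppressWarnings(as.numeric(df[["Position"]]))
    bad <- which(is.na(pos) | pos < 1)
    if (length(bad)) {
        warning("dropping ", length(bad),
                " site row(s) with missing/invalid Position (rows: ",
                paste(bad, collapse = ", "), ")")
        df <- df[-bad, , drop = FALSE]
        pos <- pos[-bad]
    }
    inten <- as.matrix(df[, cols, drop = FALSE])
    mode(inten) <- "double"
    inten[is.na(inten)] <- 0
    colnames(inten) <- sids
    out <- data.frame(
        peptide_id = if ("id" %in% colnames(df)) as.character(df[["id"]])
            else sprintf("%s_%s_%d_r%s", .leading_id(df[[prot_col]]),
                         mod_type, as.integer(pos), seq_len(nrow(df))),
        protein_id = .leading_id(df[[prot_col]]),
        mod_type = mod_type,
        site_position = as.integer(pos),
        residue = if ("Amino acid" %in% colnames(df))
            as.character(df[["Amino acid"]]) else NA_character_,
        stringsAsFactors = FALSE, check.names = FALSE)
    cbind(out, as.data.frame(inten, check.names = FALSE))
}

# full-precision numeric serialization so that write -> read round-trips
# bit-exactly
.fmt_num <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
    out
}

#' Write tables in the dialects the readers consume
#'
#' `writeProteinGroups()` writes a [ProteinQuant-class] as a
#' MaxQuant-style proteinGroups TSV (flags as `"+"` marks, intensities under
#' `"LFQ intensity <sample_id>"` at full precision), so that
#' [readProteinGroups()] reproduces the object bit-exactly.
#'
#' @param x object to write.
#' @param path output file path.
#' @param intensity_prefix intensity column prefix.
#' @return `path`, invisibly.
#' @export
writeProteinGroups <- function(x, path,
                               intensity_prefix = "LFQ intensity ") {
    stopifnot(is(x, "ProteinQuant"))
    rd <- rowData(x)
    mark <- function(b) ifelse(b, "+", "")
    df <- data.frame(
        `Protein IDs` = rownames(x),
        `Gene names` = rd$gene_name,
        `Razor + unique peptides` = rd$peptide_count,
        `Potential contaminant` = mark(rd$is_contaminant),
        `Reverse` = mark(rd$is_reverse),
        `Only identified by site` = mark(rd$only_identified_by_site),
        check.names = FALSE, stringsAsFactors = FALSE)
    v <- lfq(x)
    for (j in seq_len(ncol(v)))
        df[[paste0(intensity_prefix, colnames(v)[j])]] <- .fmt_num(v[, j])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProteinGroups
#' @export
writeSampleAnnotation <- function(x, path) {
    stopifnot(is(x, "SampleAnnotation"))
    df <- as.data.frame(x)[, c("sample_id", "bait_id", "condition",
                               "time_min", "replicate", "control_group")]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProteinGroups
#' @param mod_table a modified-peptide `data.frame` as returned by
#'   [readModifiedPeptideSites()].
#' @param intensity_prefix intensity column prefix.
#' @export
writeModifiedPeptideSites <- function(mod_table, path,
                                      intensity_prefix = "Intensity ") {
    meta <- c("peptide_id", "protein_id", "mod_type", "site_position",
              "residue")
    sids <- setdiff(colnames(mod_table), meta)
    df <- data.frame(
        id = mod_table$peptide_id,
        Protein = mod_table$protein_id,
        Position = mod_table$site_position,
        `Amino acid` = mod_table$residue,
        check.names = FALSE, stringsAsFactors = FALSE)
    for (s in sids)
        df[[paste0(intensity_prefix, s)]] <- .fmt_num(mod_table[[s]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a result table as TSV with full numeric precision
#'
#' Column order is preserved as given; numeric columns are serialized with
#' 17 significant digits so values survive a write/read round trip.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
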