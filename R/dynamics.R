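#' @importFrom stats median
NULL

# raw-scale LFQ view with NA for non-detections
.raw_na <- function(pq) {
    v <- lfq(pq)
    v[v == 0] <- NA_real_
    v
}

#' Normalize prey intensities to the bait intensity
#'
#' Divides each prey protein's raw LFQ intensity by the bait protein's raw
#' LFQ intensity in the same sample, removing loading artifacts:
#' `prey_normalized = LFQ(prey) / LFQ(bait)`, computed on linear (non-log)
#' intensities. Samples in which the bait itself was not quantified yield
#' missing normalized values for every prey and are reported in the
#' `flagged_samples` attribute.
#'
#' @param pq a [ProteinQuant-class] (raw intensities; 0 = not quantified).
#' @param bait_protein row id of the bait protein.
#' @param preys row ids to normalize; defaults to all rows except the bait.
#' @return a numeric matrix (preys x samples) of ratios, with attribute
#'   `flagged_samples` naming samples where the bait was missing.
#' @export
normalizePreyToBait <- function(pq, bait_protein, preys = NULL) {
    stopifnot(is(pq, "ProteinQuant"))
    if (!bait_protein %in% rownames(pq))
        stop("bait protein row '", bait_protein, "' absent from the table")
    v <- .raw_na(pq)
    if (is.null(preys)) preys <- setdiff(rownames(pq), bait_protein)
    miss <- setdiff(preys, rownames(pq))
    if (length(miss))
        stop("prey row(s) absent: ", paste(miss, collapse = ", "))
    b <- v[bait_protein, ]
    out <- sweep(v[preys, , drop = FALSE], 2, b, "/")
    attr(out, "flagged_samples") <- colnames(v)[is.na(b)]
    out
}

#' Normalize modification-site intensities to protein abundance
#'
#' Aggregates peptide-level rows to unique modification sites (summed
#' intensity per (protein, modification, position) and sample) and divides
#' each site's intensity by the raw LFQ intensity of its protein in the same
#' sample: `site_normalized = Intensity(site) / LFQ(protein)`. Sites are
#' retained only if the normalized value is valid in at least
#' `min_valid_per_timepoint` replicates of at least one time point. No
#' imputation is ever applied to these ratios. Sites whose protein row is
#' absent from `pq` are skipped with a warning.
#'
#' @param mod_table a modified-peptide `data.frame` as returned by
#'   [readModifiedPeptideSites()].
#' @param pq a [ProteinQuant-class] providing protein-level intensities; its
#'   annotation supplies the time points.
#' @param min_valid_per_timepoint minimum valid replicates required in at
#'   least one time point (default 3).
#' @return a numeric matrix (sites x samples) of ratios; row names are
#'   `"<protein>_<mod_type>_<position>"`, with attributes `site_info`
#'   (data.frame of protein_id, mod_type, site_position) and
#'   `skipped_proteins`.
#' @export
normalizePTMToProtein <- function(mod_table, pq,
                                  min_valid_per_timepoint = 3L) {
    stopifnot(is(pq, "ProteinQuant"))
    ann <- sampleAnnotation(pq)
    sids <- sampleIDs(ann)
    if (!all(sids %in% colnames(mod_table)))
        stop("modification table lacks intensity column(s): ",
             paste(setdiff(sids, colnames(mod_table)), collapse = ", "))
    skip <- setdiff(unique(mod_table$protein_id), rownames(pq))
    if (length(skip))
        warning("skipping site(s) of protein(s) without a protein row: ",
                paste(skip, collapse = ", "))
    tab <- mod_table[!mod_table$protein_id %in% skip, , drop = FALSE]
    if (!nrow(tab)) return(matrix(numeric(0), 0, length(sids),
                                  dimnames = list(NULL, sids)))
    site <- sprintf("%s_%s_%d", tab$protein_id, tab$mod_type,
                    tab$site_position)
    inten <- as.matrix(tab[, sids, drop = FALSE])
    inten[inten == 0] <- NA_real_
    agg <- rowsum(ifelse(is.na(inten), 0, inten), site, reorder = FALSE)
    any_obs <- rowsum((!is.na(inten)) + 0, site, reorder = FALSE) > 0
    agg[!any_obs] <- NA_real_
    prot <- .raw_na(pq)[tab$protein_id[!duplicated(site)], , drop = FALSE]
    ratio <- agg / prot
    tp <- ann$time_min
    valid_ok <- vapply(unique(tp), function(t) {
        rowSums(!is.na(ratio[, tp == t, drop = FALSE])) >=
            min_valid_per_timepoint
    }, logical(nrow(ratio)))
    if (is.null(dim(valid_ok)))
        valid_ok <- matrix(valid_ok, nrow = nrow(ratio))
    keep <- apply(valid_ok, 1, any)
    out <- ratio[keep, , drop = FALSE]
    info <- tab[!duplicated(site), c("protein_id", "mod_type",
                                     "site_position")]
    attr(out, "site_info") <- info[keep, , drop = FALSE]
    attr(out, "skipped_proteins") <- skip
    out
}

#' Per-time-point significance of dynamic features
#'
#' For each feature (normalized PPI or PTM ratio) and each activated time
#' point, performs a two-sided two-sample Student's t-test of the feature's
#' values against the untreated (time 0) values. By default tests run on
#' log2 ratios, which symmetrizes up- and down-regulation; set
#' `log_ratios = FALSE` to test raw ratios. Only observed values enter the
#' tests; each compared group needs at least `min_valid` of them. No
#' multiple-testing correction is applied: a feature is significant if any
#' time point has p below `alpha`.
#'
#' @param values numeric matrix (features x samples) of normalized ratios
#'   (`NA` = missing), e.g. from [normalizePreyToBait()] or
#'   [normalizePTMToProtein()].
#' @param annotation a [SampleAnnotation-class] covering the columns.
#' @param alpha per-test significance level (default 0.05).
#' @param log_ratios test on log2-transformed ratios (default TRUE).
#' @param min_valid minimum observed values per compared group (default 2).
#' @return a list with `per_timepoint` (long data.frame: `feature_id`,
#'   `time_min`, `p_value`, `log2_change`) and `summary` (data.frame:
#'   `feature_id`, `min_p`, `significant_any_time`).
#' @export
timecourseSignificance <- function(values, annotation, alpha = 0.05,
                                   log_ratios = TRUE, min_valid = 2L) {
    sids <- sampleIDs(annotation)
    values <- values[, sids, drop = FALSE]
    tp <- annotation$time_min
    if (!any(tp == 0)) stop("no time-0 (untreated) samples in annotation")
    act <- sort(unique(tp[tp > 0]))
    v <- if (log_ratios) log2(values) else values
    rows <- rownames(values)
    res <- do.call(rbind, lapply(act, function(t) {
        a <- v[, tp == t, drop = FALSE]
        z <- v[, tp == 0, drop = FALSE]
        p <- rep(NA_real_, nrow(v)); ch <- rep(NA_real_, nrow(v))
        for (i in seq_len(nrow(v))) {
            xi <- a[i, !is.na(a[i, ])]; zi <- z[i, !is.na(z[i, ])]
            if (length(xi) < min_valid || length(zi) < min_valid) next
            tt <- .row_pooled_t(rbind(c(xi, zi)), seq_along(xi),
                                length(xi) + seq_along(zi))
            p[i] <- tt$p; ch[i] <- tt$difference
        }
        data.frame(feature_id = rows, time_min = t, p_value = p,
                   log2_change = ch, stringsAsFactors = FALSE)
    }))
    minp <- vapply(split(res$p_value, res$feature_id), function(p)
        if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE), numeric(1))
    minp <- minp[rows]
    summary <- data.frame(feature_id = rows, min_p = unname(minp),
                          significant_any_time =
                              !is.na(minp) & minp < alpha,
                          stringsAsFactors = FALSE)
    rownames(res) <- rownames(summary) <- NULL
    list(per_timepoint = res, summary = summary)
}
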