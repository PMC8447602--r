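# in-code fixtures shared across test files

make_annotation <- function(n_baits = 2, replicates = 4,
                            timepoints = 0, baits = NULL) {
    if (is.null(baits)) baits <- sprintf("BAIT%02d", seq_len(n_baits))
    df <- do.call(rbind, lapply(baits, function(b)
        do.call(rbind, lapply(timepoints, function(t) data.frame(
            sample_id = sprintf("%s_t%d_r%d", b, t, seq_len(replicates)),
            bait_id = b,
            condition = ifelse(t == 0, "untreated", "activated"),
            time_min = t, replicate = seq_len(replicates),
            stringsAsFactors = FALSE)))))
    SampleAnnotation(df)
}

# LogIntensities straight from a numeric matrix; NA cells are missing, and
# by default every missing cell counts as imputed so downstream testing
# preconditions (fully imputed matrix) hold
make_logintensities <- function(values, annotation, observed = NULL,
                                impute_missing_cells = TRUE) {
    miss <- is.na(values)
    if (!is.null(observed)) miss <- !observed
    v <- values
    imp <- if (impute_missing_cells) miss else matrix(FALSE, nrow(values),
                                                      ncol(values))
    if (impute_missing_cells && any(miss & is.na(values)))
        stop("fixture: provide values for cells marked imputed")
    LogIntensities(v, miss, imp, annotation = annotation)
}

make_protein_quant <- function(lfq_mat, annotation, peptide_count = 2L,
                               is_contaminant = FALSE, is_reverse = FALSE,
                               only_by_site = FALSE) {
    n <- nrow(lfq_mat)
    rd <- S4Vectors::DataFrame(
        gene_name = rownames(lfq_mat),
        peptide_count = rep_len(as.integer(peptide_count), n),
        is_contaminant = rep_len(is_contaminant, n),
        is_reverse = rep_len(is_reverse, n),
        only_identified_by_site = rep_len(only_by_site, n),
        row.names = rownames(lfq_mat))
    ProteinQuant(lfq_mat, annotation, rowData = rd)
}

write_protein_groups_fixture <- function(path, ids, intensities,
                                         sample_ids, peptides = 3) {
    header <- c("Protein IDs", "Gene names", "Razor + unique peptides",
                paste0("LFQ intensity ", sample_ids))
    rows <- vapply(seq_along(ids), function(i)
        paste(c(ids[i], ids[i], peptides,
                format(intensities[i, ], scientific = FALSE)),
              collapse = "\t"), character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
    path
}

write_annotation_fixture <- function(path, annotation) {
    writeSampleAnnotation(annotation, path)
}

# small synthetic interactome input files for pipeline tests
write_interactome_inputs <- function(dir, seed = 3) {
    cfg <- simulationConfig(n_baits = 4, n_background = 120,
                            interactors_per_bait = 4, seed = seed)
    sim <- generateAPMSDataset(cfg)
    dr <- applyMNARMissingness(sim$protein_quant, cfg)
    pg <- file.path(dir, "proteinGroups.tsv")
    an <- file.path(dir, "annotation.tsv")
    kp <- file.path(dir, "known.tsv")
    writeProteinGroups(dr$protein_quant, pg)
    writeSampleAnnotation(sim$annotation, an)
    writeLines(c("protein_a\tprotein_b", "BAIT01\tINT_BAIT01_01"), kp)
    list(protein_groups = pg, annotation = an, known_pairs = kp,
         truth = sim$truth)
}

# brute-force permutation-FDR oracle: plain loops over every distinct
# relabeling other than the observed grouping and its mirror, the q
# definition applied literally
oracle_perm_q <- function(X, n1) {
    n <- ncol(X)
    sel <- combn(n, n1)
    keep <- !apply(sel, 2, function(idx)
        all(idx <= n1) || (n - n1 == n1 && all(idx > n1)))
    sel <- sel[, keep, drop = FALSE]
    tstat <- function(i1) {
        apply(X, 1, function(r) {
            o <- oracle_pooled_t(r[i1], r[setdiff(seq_len(n), i1)])
            if (is.nan(o$t)) 0 else abs(o$t)
        })
    }
    obs <- tstat(seq_len(n1))
    perms <- sapply(seq_len(ncol(sel)), function(b) tstat(sel[, b]))
    q <- vapply(seq_along(obs), function(i) {
        cperm <- mean(colSums(perms >= obs[i]))
        min(1, cperm / sum(obs >= obs[i]))
    }, numeric(1))
    ord <- order(obs, decreasing = TRUE)
    q[ord] <- cummax(q[ord])
    q
}

# independent pooled-variance t oracle (textbook formula, scalar arithmetic)
oracle_pooled_t <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2),
         difference = mean(x) - mean(y))
}
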