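#' @importFrom stats rnorm sd
NULL

# run expr under a local, seeded RNG stream without touching global state
.with_seed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

# deterministic per-stage child seed from one global seed (kept < 2^31)
.child_seed <- function(seed, stage) {
    as.integer((as.numeric(seed) * 7919 + 104729 * stage) %% 2147483647)
}

#' Filter protein identifications
#'
#' Removes decoy (reverse), contaminant and only-identified-by-site protein
#' groups, and protein groups identified with fewer than `min_peptides`
#' razor + unique peptides. Row order of the survivors is preserved.
#'
#' @param x a [ProteinQuant-class].
#' @param min_peptides minimum razor + unique peptide count; the default 2
#'   implements the "identified with more than one peptide" rule.
#' @return the filtered [ProteinQuant-class] (possibly zero rows).
#' @export
filterIdentifications <- function(x, min_peptides = 2L) {
    stopifnot(is(x, "ProteinQuant"))
    rd <- rowData(x)
    keep <- !rd$is_contaminant & !rd$is_reverse &
        !rd$only_identified_by_site &
        !is.na(rd$peptide_count) & rd$peptide_count >= min_peptides
    x[keep, ]
}

#' Log2-transform raw LFQ intensities
#'
#' Zero intensities (the "not quantified" encoding) become missing cells;
#' positive intensities become their log2. Negative intensities are an
#' error.
#'
#' @param x a [ProteinQuant-class].
#' @return a [LogIntensities-class] with `imputed` all FALSE.
#' @export
log2Transform <- function(x) {
    stopifnot(is(x, "ProteinQuant"))
    v <- lfq(x)
    if (any(v < 0, na.rm = TRUE)) stop("negative intensities are not allowed")
    miss <- v == 0
    out <- log2(v)
    out[miss] <- NA_real_
    LogIntensities(out, miss, annotation = sampleAnnotation(x),
                   rowData = rowData(x))
}

#' Filter features on valid values per group
#'
#' Keeps features quantified in strictly more than `min_fraction` of the
#' samples of at least one group (the ">60% of replicates of at least one
#' cell line" rule; groups default to bait cell lines). Imputed cells do not
#' count as valid.
#'
#' @param x a [LogIntensities-class].
#' @param group_by name of the annotation column defining the groups
#'   (default `"bait_id"`).
#' @param min_fraction required valid fraction; kept iff fraction
#'   `> min_fraction` (strict) in at least one group.
#' @return the filtered [LogIntensities-class].
#' @export
filterValidValues <- function(x, group_by = "bait_id", min_fraction = 0.6) {
    stopifnot(is(x, "LogIntensities"))
    g <- colData(x)[[group_by]]
    if (is.null(g) || anyNA(g))
        stop("every sample must be assigned to a group via column '",
             group_by, "'")
    g <- as.character(g)
    if (any(table(g) == 0)) stop("group with zero samples")
    valid <- !missingMask(x)
    frac <- vapply(split(seq_len(ncol(x)), g),
                   function(j) rowMeans(valid[, j, drop = FALSE]),
                   numeric(nrow(x)))
    if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(x))
    keep <- apply(frac, 1, max) > min_fraction
    x[keep, ]
}

#' Impute missing values from a downshifted Gaussian
#'
#' Fills missing cells per sample (column) with independent draws from a
#' normal distribution centred on that sample's detection limit: for a
#' column with observed mean `m` and observed standard deviation `s`, draws
#' come from `Normal(m - downshift * s, (width * s)^2)`. This mimics the
#' left-censored, missing-not-at-random structure of LFQ data, placing
#' imputed values in the low-intensity tail.
#'
#' @param x a [LogIntensities-class] (log2 scale).
#' @param width standard deviation of the imputation distribution in
#'   observed-sd units (default 0.3).
#' @param downshift shift of the imputation mean below the observed mean, in
#'   observed-sd units (default 1.8).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a [LogIntensities-class] with every formerly missing cell filled
#'   and flagged in the `imputed` mask; observed cells are untouched.
#' @export
imputeMissing <- function(x, width = 0.3, downshift = 1.8, seed = 1L) {
    stopifnot(is(x, "LogIntensities"))
    v <- logIntensities(x)
    miss <- missingMask(x) & !imputedMask(x)
    n_obs <- colSums(!missingMask(x))
    if (any(n_obs < 2))
        stop("column(s) with fewer than 2 observed values: ",
             paste(colnames(x)[n_obs < 2], collapse = ", "))
    if (!any(miss)) return(x)
    imp <- imputedMask(x)
    .with_seed(seed, {
        for (j in seq_len(ncol(v))) {
            mj <- which(miss[, j])
            if (!length(mj)) next
            obs <- v[!missingMask(x)[, j], j]
            m <- mean(obs); s <- sd(obs)
            v[mj, j] <- rnorm(length(mj), mean = m - downshift * s,
                              sd = width * s)
            imp[mj, j] <- TRUE
        }
    })
    LogIntensities(v, missingMask(x), imp,
                   annotation = sampleAnnotation(x), rowData = rowData(x))
}
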