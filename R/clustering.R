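#' @importFrom stats loess predict quantile
NULL

#' Build z-scored time-course profiles
#'
#' Filters features for at least `min_valid_fraction` valid (non-missing)
#' normalized values across all contributing samples, computes the median of
#' each time point, and z-scores the medians across time points. Constant
#' profiles (zero standard deviation across time points) have no defined
#' z-score and are removed with a warning.
#'
#' @param values numeric matrix (features x samples) of normalized ratios
#'   (`NA` = missing).
#' @param annotation a [SampleAnnotation-class] supplying the time points;
#'   at least 3 distinct time points are required.
#' @param min_valid_fraction minimum valid fraction per feature
#'   (default 0.7, i.e. "at least 70%": kept iff fraction >= 0.7).
#' @return a numeric matrix (features x time points) of z-scored medians;
#'   column names are the time points in minutes, ascending.
#' @export
buildZScoredProfiles <- function(values, annotation,
                                 min_valid_fraction = 0.7) {
    sids <- sampleIDs(annotation)
    values <- values[, sids, drop = FALSE]
    tp <- sort(unique(annotation$time_min))
    if (length(tp) < 3) stop("need at least 3 time points")
    keep <- rowMeans(!is.na(values)) >= min_valid_fraction
    values <- values[keep, , drop = FALSE]
    med <- vapply(tp, function(t) {
        apply(values[, annotation$time_min == t, drop = FALSE], 1,
              median, na.rm = TRUE)
    }, numeric(nrow(values)))
    if (is.null(dim(med))) med <- matrix(med, nrow = nrow(values))
    dimnames(med) <- list(rownames(values), tp)
    m <- rowMeans(med)
    s <- apply(med, 1, sd)
    const <- !is.finite(s) | s == 0 | anyNA(med) | rowSums(is.na(med)) > 0
    const <- const | apply(med, 1, function(r) anyNA(r))
    if (any(const)) {
        warning("removing ", sum(const),
                " feature(s) with constant or incomplete profiles")
        med <- med[!const, , drop = FALSE]
        m <- m[!const]; s <- s[!const]
    }
    (med - m) / s
}

#' Cluster z-scored profiles by Pearson correlation
#'
#' Average-linkage hierarchical clustering on the distance `1 - r` between
#' z-scored profiles, cut into `k` clusters. Cluster labels are renumbered
#' by descending cluster size, ties broken by the earliest peak time of the
#' cluster's mean profile, so labels are deterministic.
#'
#' @param z matrix of z-scored profiles from [buildZScoredProfiles()].
#' @param k number of clusters (default 7).
#' @return an integer vector of cluster labels in 1..k, named by feature,
#'   with attribute `k`.
#' @export
clusterProfiles <- function(z, k = 7L) {
    if (k < 2 || k > nrow(z))
        stop("k must be between 2 and the number of profiles (", nrow(z), ")")
    d <- as.dist(1 - cor(t(z)))
    hc <- hclust(d, method = "average")
    g <- cutree(hc, k = k)
    size <- table(g)
    tp <- as.numeric(colnames(z))
    peak <- vapply(seq_len(k), function(cl) {
        tp[which.max(colMeans(z[g == cl, , drop = FALSE]))]
    }, numeric(1))
    ord <- order(-as.integer(size[as.character(seq_len(k))]), peak)
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    out <- relabel[g]
    names(out) <- rownames(z)
    attr(out, "k") <- as.integer(k)
    out
}

#' Summarize one co-regulation cluster
#'
#' Per time point: the median z-scored value over cluster members with a
#' bootstrap confidence band of the median, plus a locally weighted
#' regression (loess, `y ~ x`) curve fitted through all member points.
#'
#' @param z matrix of z-scored profiles.
#' @param assignment labels from [clusterProfiles()].
#' @param cluster_label which cluster to summarize.
#' @param ci_level confidence level of the band (default 0.95).
#' @param smoother_span loess span (default 0.75).
#' @param n_boot bootstrap replicates for the band (default 500).
#' @param seed seed for the bootstrap.
#' @return a `data.frame` with one row per time point: `time_min`, `median`,
#'   `lower`, `upper`, `smoothed`, plus attribute `n` (member count).
#' @export
summarizeCluster <- function(z, assignment, cluster_label, ci_level = 0.95,
                             smoother_span = 0.75, n_boot = 500L,
                             seed = 1L) {
    members <- names(assignment)[assignment == cluster_label]
    if (!length(members)) stop("unknown or empty cluster: ", cluster_label)
    zm <- z[members, , drop = FALSE]
    tp <- as.numeric(colnames(z))
    med <- apply(zm, 2, median)
    alpha <- 1 - ci_level
    if (nrow(zm) > 1) {
        band <- .with_seed(seed, {
            boot <- replicate(n_boot, {
                idx <- sample.int(nrow(zm), replace = TRUE)
                apply(zm[idx, , drop = FALSE], 2, median)
            })
            apply(boot, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2))
        })
        lower <- band[1, ]; upper <- band[2, ]
    } else {
        lower <- upper <- med
    }
    pts <- data.frame(x = rep(tp, each = nrow(zm)), y = as.vector(zm))
    smoothed <- tryCatch({
        fit <- loess(y ~ x, data = pts, span = smoother_span, degree = 1)
        as.numeric(predict(fit, newdata = data.frame(x = tp)))
    }, error = function(e) med, warning = function(w) med)
    out <- data.frame(time_min = tp, median = unname(med),
                      lower = unname(lower), upper = unname(upper),
                      smoothed = smoothed)
    attr(out, "n") <- nrow(zm)
    out
}
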