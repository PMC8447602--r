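#' @importFrom stats pt cor hclust cutree as.dist
#' @importFrom utils combn
NULL

# Row-wise two-sample Student t (pooled variance) between column sets.
# Degenerate rows (pooled variance 0): t = 0 / p = 1 when the means agree,
# t = +/-Inf / p = 0 when they differ.
.row_pooled_t <- function(X, idx1, idx2) {
    n1 <- length(idx1); n2 <- length(idx2)
    stopifnot(n1 >= 2, n2 >= 2)
    X1 <- X[, idx1, drop = FALSE]; X2 <- X[, idx2, drop = FALSE]
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- m1 - m2
    t <- d / se
    t[se == 0 & d == 0] <- 0
    t[se == 0 & d != 0] <- sign(d[se == 0 & d != 0]) * Inf
    p <- 2 * pt(-abs(t), df)
    list(difference = d, t = t, p = p, df = df)
}

# |t| for B relabelings at once: `member` is an n x B logical matrix marking
# group-1 membership (column sums all n1). Returns features x B matrix.
.perm_abs_t <- function(X, member, n1) {
    n <- ncol(X); n2 <- n - n1
    M <- matrix(as.numeric(member), nrow = n)
    S1 <- X %*% M
    Q1 <- (X * X) %*% M
    tot <- rowSums(X); tot2 <- rowSums(X * X)
    S2 <- tot - S1; Q2 <- tot2 - Q1
    m1 <- S1 / n1; m2 <- S2 / n2
    v1 <- pmax(Q1 - n1 * m1 * m1, 0) / (n1 - 1)
    v2 <- pmax(Q2 - n2 * m2 * m2, 0) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- m1 - m2
    # the one-pass sums cancel catastrophically on (near-)constant rows, so
    # degenerate cells are detected at a relative tolerance, not at exact 0
    tol <- 1e-7 * sqrt(tot2 / n)
    zero_se <- se < tol
    zero_d <- abs(d) < tol
    at <- abs(d) / se
    at[zero_se & zero_d] <- 0
    at[zero_se & !zero_d] <- Inf
    at
}

#' Assign pull-down samples to background control groups
#'
#' Clusters sample intensity profiles by Pearson correlation (average-linkage
#' hierarchical clustering on the distance `1 - r`) and cuts the tree into
#' control groups. Within a control group, each bait is tested against the
#' complement formed by all other baits' samples, so every group must contain
#' at least two distinct baits. Correlations use cells quantified in both
#' samples of a pair (observed or imputed); at least 10 shared cells are
#' required per pair.
#'
#' @param x a [LogIntensities-class].
#' @param n_groups number of control groups, or `"auto"` to pick the cut
#'   with the best mean silhouette width over 2..min(6, #baits - 1).
#' @param min_shared minimum shared quantified cells per sample pair.
#' @return a `data.frame` with columns `sample_id` and `group_id`
#'   (`"group1"`, `"group2"`, ...), one row per sample, annotation order.
#' @export
buildControlGroups <- function(x, n_groups = "auto", min_shared = 10L) {
    stopifnot(is(x, "LogIntensities"))
    if (ncol(x) < 2) stop("need at least 2 samples")
    ann <- sampleAnnotation(x)
    baits <- baitIDs(ann)
    v <- logIntensities(x)
    v[missingMask(x) & !imputedMask(x)] <- NA_real_
    shared <- crossprod(!is.na(v))
    if (any(shared < min_shared))
        stop("sample pair(s) share fewer than ", min_shared,
             " quantified cells; impute missing values first")
    r <- cor(v, use = "pairwise.complete.obs")
    d <- as.dist(1 - r)
    hc <- hclust(d, method = "average")
    grp_for_k <- function(k) cutree(hc, k = k)
    valid_groups <- function(g) {
        all(vapply(split(as.character(ann$bait_id), g),
                   function(b) length(unique(b)) >= 2, logical(1)))
    }
    if (identical(n_groups, "auto")) {
        if (length(baits) < 3) {
            g <- rep(1L, ncol(x))
        } else {
            ks <- 2:min(6, length(baits) - 1)
            sil <- vapply(ks, function(k) {
                g <- grp_for_k(k)
                if (!valid_groups(g)) return(-Inf)
                mean(cluster::silhouette(g, d)[, "sil_width"])
            }, numeric(1))
            g <- if (all(!is.finite(sil))) rep(1L, ncol(x))
                 else grp_for_k(ks[which.max(sil)])
        }
    } else {
        n_groups <- as.integer(n_groups)
        if (n_groups > length(baits))
            stop("n_groups exceeds the number of baits (", length(baits), ")")
        g <- if (n_groups == 1L) rep(1L, ncol(x)) else grp_for_k(n_groups)
        if (!valid_groups(g))
            stop("control group with fewer than 2 distinct baits; ",
                 "reduce n_groups")
    }
    data.frame(sample_id = sampleIDs(ann),
               group_id = paste0("group", as.integer(g)),
               stringsAsFactors = FALSE)
}

.bait_and_complement <- function(x, bait, groups) {
    ann <- sampleAnnotation(x)
    if (!bait %in% ann$bait_id)
        stop("bait '", bait, "' not present in the annotation")
    sids <- sampleIDs(ann)
    bait_s <- sids[ann$bait_id == bait]
    if (is.null(groups)) {
        comp_s <- setdiff(sids, bait_s)
    } else {
        gid <- groups$group_id[match(bait_s, groups$sample_id)]
        gid <- unique(gid)
        if (length(gid) != 1)
            stop("samples of bait '", bait,
                 "' span multiple control groups")
        members <- groups$sample_id[groups$group_id == gid]
        comp_s <- setdiff(members, bait_s)
    }
    if (!length(comp_s))
        stop("complement group for bait '", bait, "' is empty")
    list(bait = bait_s, complement = comp_s)
}

#' Test one bait against its control-group complement
#'
#' For every feature, performs a two-sided two-sample Student's t-test
#' (pooled variance) of the bait's samples against all other samples of the
#' bait's control group ("complement" mode), on the imputed log2 matrix.
#' The reported difference is bait mean minus complement mean (log2 units).
#' Features with fewer than `min_valid` originally observed (non-imputed)
#' values among the bait samples are marked untestable: imputed cells are
#' pseudo-data and do not support an interaction call.
#'
#' @param x a [LogIntensities-class] with no unimputed missing cells.
#' @param bait bait identifier (must appear in the annotation).
#' @param groups control-group assignment from [buildControlGroups()], or
#'   `NULL` to use all other samples as the complement.
#' @param min_valid minimum observed values required in the bait group
#'   (default 10).
#' @return a `data.frame` with one row per feature: `bait_id`, `protein_id`,
#'   `log2_difference`, `t_statistic`, `p_value`, `n_valid_bait`,
#'   `n_valid_complement`, `testable`.
#' @export
baitVsComplementTest <- function(x, bait, groups = NULL, min_valid = 10L) {
    stopifnot(is(x, "LogIntensities"))
    if (any(missingMask(x) & !imputedMask(x)))
        stop("matrix has unimputed missing cells; run imputeMissing() first")
    gs <- .bait_and_complement(x, bait, groups)
    if (length(gs$bait) < 2 || length(gs$complement) < 2)
        stop("need at least 2 samples in bait and complement groups")
    v <- logIntensities(x)
    res <- .row_pooled_t(v, match(gs$bait, colnames(v)),
                         match(gs$complement, colnames(v)))
    obs <- !missingMask(x)
    nv_b <- rowSums(obs[, gs$bait, drop = FALSE])
    nv_c <- rowSums(obs[, gs$complement, drop = FALSE])
    data.frame(bait_id = bait, protein_id = rownames(x),
               log2_difference = unname(res$difference),
               t_statistic = unname(res$t), p_value = unname(res$p),
               n_valid_bait = unname(nv_b), n_valid_complement = unname(nv_c),
               testable = unname(nv_b >= min_valid),
               stringsAsFactors = FALSE)
}

#' Permutation-based FDR for bait-vs-complement tests
#'
#' Estimates a q-value for every feature by recomputing |t| under random
#' relabelings of the samples between the two groups (group sizes
#' preserved). For a feature with observed statistic magnitude `c`,
#' `q = min(1, mean permuted count of |t| >= c / observed count of
#' |t| >= c)`, then enforced monotone non-increasing in |t|. Relabelings
#' identical to the observed grouping (or its mirror for equal group sizes)
#' are not permutations of it and are excluded. When the number of distinct
#' relabelings is at most `n_permutations`, all of them are enumerated
#' exhaustively, making the estimate exact on small designs.
#'
#' @param tests result of [baitVsComplementTest()].
#' @param x the [LogIntensities-class] the tests were computed on.
#' @param group1,group2 character vectors of sample ids of the two groups.
#' @param n_permutations number of random relabelings (default 250).
#' @param seed integer seed; identical seeds give identical q-values.
#' @return `tests` with a `q_value` column appended.
#' @export
permutationFDR <- function(tests, x, group1, group2,
                           n_permutations = 250L, seed = 1L) {
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    v <- logIntensities(x)
    i1 <- match(group1, colnames(v)); i2 <- match(group2, colnames(v))
    if (anyNA(i1) || anyNA(i2)) stop("unknown sample id in group1/group2")
    X <- v[tests$protein_id, c(i1, i2), drop = FALSE]
    n1 <- length(i1); n <- n1 + length(i2)
    total <- choose(n, n1)
    # relabelings equal to the observed grouping (or, for equal group sizes,
    # its mirror image) are not permutations of it and are excluded
    is_identity <- function(idx) {
        all(idx <= n1) || (n - n1 == n1 && all(idx > n1))
    }
    if (is.finite(total) && total <= n_permutations) {
        sel <- combn(n, n1)
        sel <- sel[, !apply(sel, 2, is_identity), drop = FALSE]
        member <- matrix(FALSE, n, ncol(sel))
        member[cbind(as.vector(sel),
                     rep(seq_len(ncol(sel)), each = n1))] <- TRUE
    } else {
        member <- .with_seed(seed, {
            m <- matrix(FALSE, n, n_permutations)
            for (b in seq_len(n_permutations)) {
                idx <- sample.int(n, n1)
                while (is_identity(idx)) idx <- sample.int(n, n1)
                m[idx, b] <- TRUE
            }
            m
        })
    }
    B <- ncol(member)
    perm_abs <- .perm_abs_t(X, member, n1)
    obs_abs <- abs(tests$t_statistic)
    sp <- sort(as.vector(perm_abs))
    so <- sort(obs_abs)
    cnt_perm <- length(sp) - findInterval(obs_abs, sp, left.open = TRUE)
    cnt_obs <- length(so) - findInterval(obs_abs, so, left.open = TRUE)
    q <- pmin(1, (cnt_perm / B) / cnt_obs)
    ord <- order(obs_abs, tests$protein_id, decreasing = c(TRUE, FALSE),
                 method = "radix")
    q[ord] <- cummax(q[ord])
    tests$q_value <- q
    tests
}

#' Call significant interactors
#'
#' A feature is a significant interactor of its bait iff its permutation
#' q-value is below `fdr`, its linear fold enrichment `2^log2_difference`
#' strictly exceeds `enrichment`, and it is testable (at least `min_valid`
#' observed values in the bait group). Results are ranked by ascending q,
#' then descending difference, ties broken by protein id.
#'
#' @param tests result of [permutationFDR()] (must carry `q_value`).
#' @param fdr FDR threshold (default 0.01).
#' @param enrichment linear fold-enrichment threshold (default 2; the
#'   companion log2-difference threshold is `log2(enrichment)`).
#' @param min_valid minimum observed bait-group values (default 10).
#' @return a `data.frame` of all tested features ordered by rank, with
#'   `fold_enrichment`, `significant` and `rank` columns appended.
#' @export
callInteractors <- function(tests, fdr = 0.01, enrichment = 2,
                            min_valid = 10L) {
    if (is.null(tests$q_value)) stop("run permutationFDR() first")
    out <- tests
    out$fold_enrichment <- 2^out$log2_difference
    out$testable <- out$n_valid_bait >= min_valid
    out$significant <- out$q_value < fdr &
        out$fold_enrichment > enrichment & out$testable
    ord <- order(out$q_value, -out$log2_difference, out$protein_id,
                 method = "radix")
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' One-call interactor screen for a single bait
#'
#' Convenience wrapper chaining [baitVsComplementTest()], [permutationFDR()]
#' and [callInteractors()] with the published defaults (two-tailed Student's
#' t-test, permutation FDR < 0.01 with 250 randomizations, enrichment > 2,
#' minimum 10 valid values in the bait group).
#'
#' @inheritParams baitVsComplementTest
#' @inheritParams callInteractors
#' @param n_permutations number of relabelings.
#' @param seed integer seed.
#' @return see [callInteractors()].
#' @export
screenBait <- function(x, bait, groups = NULL, fdr = 0.01, enrichment = 2,
                       min_valid = 10L, n_permutations = 250L, seed = 1L) {
    gs <- .bait_and_complement(x, bait, groups)
    tests <- baitVsComplementTest(x, bait, groups, min_valid = min_valid)
    tests <- permutationFDR(tests, x, gs$bait, gs$complement,
                            n_permutations = n_permutations, seed = seed)
    callInteractors(tests, fdr = fdr, enrichment = enrichment,
                    min_valid = min_valid)
}

#' Differential abundance between two whole-proteome groups
#'
#' Same machinery as interactor calling, with the whole-proteome defaults:
#' permutation-based FDR < 0.05 with 250 randomizations, enrichment > 2,
#' and a minimum of two valid values in the first group. The difference is
#' reported as group A mean minus group B mean.
#'
#' @param x a [LogIntensities-class] with no unimputed missing cells.
#' @param groupA,groupB character vectors of sample ids.
#' @param fdr,enrichment,min_valid,n_permutations,seed see
#'   [callInteractors()] / [permutationFDR()].
#' @return see [callInteractors()]; `bait_id` holds the label `"groupA"`.
#' @export
wholeProteomeDiff <- function(x, groupA, groupB, fdr = 0.05, enrichment = 2,
                              min_valid = 2L, n_permutations = 250L,
                              seed = 1L) {
    stopifnot(is(x, "LogIntensities"))
    if (any(missingMask(x) & !imputedMask(x)))
        stop("matrix has unimputed missing cells; run imputeMissing() first")
    v <- logIntensities(x)
    i1 <- match(groupA, colnames(v)); i2 <- match(groupB, colnames(v))
    if (anyNA(i1) || anyNA(i2)) stop("unknown sample id in groupA/groupB")
    res <- .row_pooled_t(v, i1, i2)
    obs <- !missingMask(x)
    nv_a <- rowSums(obs[, groupA, drop = FALSE])
    nv_b <- rowSums(obs[, groupB, drop = FALSE])
    tests <- data.frame(bait_id = "groupA", protein_id = rownames(x),
                        log2_difference = unname(res$difference),
                        t_statistic = unname(res$t),
                        p_value = unname(res$p),
                        n_valid_bait = unname(nv_a),
                        n_valid_complement = unname(nv_b),
                        testable = unname(nv_a >= min_valid),
                        stringsAsFactors = FALSE)
    tests <- permutationFDR(tests, x, groupA, groupB,
                            n_permutations = n_permutations, seed = seed)
    callInteractors(tests, fdr = fdr, enrichment = enrichment,
                    min_valid = min_valid)
}
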