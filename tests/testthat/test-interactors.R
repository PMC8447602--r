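test_that("bait-vs-complement t matches the closed-form pooled oracle", {
    ann <- make_annotation(baits = c("B1", "B2"), replicates = 4)
    bait_vals <- c(26, 26, 27, 27); comp_vals <- c(20, 20, 21, 21)
    v <- rbind(EX = c(bait_vals, comp_vals),
               FLAT = rep(22, 8),
               NOISY = c(21.2, 23.9, 22.5, 20.8, 23.1, 21.7, 22.2, 24.0))
    colnames(v) <- sampleIDs(ann)
    li <- make_logintensities(v, ann)
    res <- baitVsComplementTest(li, "B1", min_valid = 3)
    ex <- res[res$protein_id == "EX", ]
    o <- oracle_pooled_t(bait_vals, comp_vals)
    expect_equal(ex$log2_difference, 6.0)
    expect_equal(ex$t_statistic, o$t)
    expect_equal(ex$p_value, o$p)
    # cross-check against stats::t.test as an independent implementation
    tt <- t.test(bait_vals, comp_vals, var.equal = TRUE)
    expect_equal(ex$t_statistic, unname(tt$statistic))
    expect_equal(ex$p_value, tt$p.value)
    # identical values in both groups: difference 0, p = 1
    fl <- res[res$protein_id == "FLAT", ]
    expect_equal(fl$log2_difference, 0)
    expect_equal(fl$p_value, 1)
    on <- oracle_pooled_t(v["NOISY", 1:4], v["NOISY", 5:8])
    expect_equal(res$t_statistic[res$protein_id == "NOISY"], o2 <- on$t)
})

test_that("proteins short of valid bait values are untestable", {
    ann <- make_annotation(baits = c("B1", "B2"), replicates = 15)
    set.seed(1)
    v <- matrix(rnorm(2 * 30, 22), 2, 30,
                dimnames = list(c("sparse", "full"), sampleIDs(ann)))
    observed <- matrix(TRUE, 2, 30, dimnames = dimnames(v))
    observed["sparse", 1:7] <- FALSE   # 8 of 15 observed in bait group
    li <- make_logintensities(v, ann, observed = observed)
    res <- baitVsComplementTest(li, "B1", min_valid = 10)
    expect_false(res$testable[res$protein_id == "sparse"])
    expect_true(res$testable[res$protein_id == "full"])
    expect_equal(res$n_valid_bait[res$protein_id == "sparse"], 8)
})

test_that("permutation FDR on a 3-vs-3 design equals exhaustive enumeration", {
    ann <- make_annotation(baits = c("B1", "B2"), replicates = 3)
    set.seed(5)
    v <- matrix(rnorm(12 * 6, 22), 12, 6,
                dimnames = list(sprintf("P%02d", 1:12), sampleIDs(ann)))
    v[1, 1:3] <- v[1, 1:3] + 4
    v[2, 1:3] <- v[2, 1:3] + 2
    li <- make_logintensities(v, ann)
    tests <- baitVsComplementTest(li, "B1", min_valid = 3)
    g1 <- sampleIDs(ann)[1:3]; g2 <- sampleIDs(ann)[4:6]
    # n_permutations of 250 covers all choose(6,3) = 20 relabelings, so the
    # exhaustive path is taken and any seed gives the same answer
    r1 <- permutationFDR(tests, li, g1, g2, n_permutations = 250, seed = 1)
    r2 <- permutationFDR(tests, li, g1, g2, n_permutations = 250, seed = 99)
    expect_identical(r1$q_value, r2$q_value)
    expect_equal(r1$q_value, oracle_perm_q(v, 3), tolerance = 1e-12)
})

test_that("q-values are monotone in |t|, bounded, and seed-reproducible", {
    ann <- make_annotation(baits = c("B1", "B2", "B3"), replicates = 4)
    for (s in c(3, 17)) {
        set.seed(s)
        v <- matrix(rnorm(60 * 12, 24, 1), 60, 12,
                    dimnames = list(sprintf("P%02d", 1:60), sampleIDs(ann)))
        li <- make_logintensities(v, ann)
        tests <- baitVsComplementTest(li, "B1", min_valid = 3)
        g1 <- sampleIDs(ann)[1:4]; g2 <- sampleIDs(ann)[5:12]
        q <- permutationFDR(tests, li, g1, g2, seed = s)$q_value
        expect_true(all(q >= 0 & q <= 1))
        ord <- order(abs(tests$t_statistic), decreasing = TRUE)
        expect_true(all(diff(q[ord]) >= 0))
        q2 <- permutationFDR(tests, li, g1, g2, seed = s)$q_value
        expect_identical(q, q2)
    }
})

test_that("a clear top hit gets q = 0 under sampled permutations", {
    ann <- make_annotation(baits = c("B1", "B2"), replicates = 10)
    set.seed(2)
    v <- matrix(rnorm(30 * 20, 24, 0.3), 30, 20,
                dimnames = list(sprintf("P%02d", 1:30), sampleIDs(ann)))
    v[1, 1:10] <- v[1, 1:10] + 8
    li <- make_logintensities(v, ann)
    tests <- baitVsComplementTest(li, "B1", min_valid = 3)
    res <- permutationFDR(tests, li, sampleIDs(ann)[1:10],
                          sampleIDs(ann)[11:20], seed = 4)
    expect_equal(res$q_value[res$protein_id == "P01"], 0)
})

test_that("swapping group roles negates difference and t but keeps p and q", {
    ann <- make_annotation(baits = c("B1", "B2"), replicates = 3)
    set.seed(8)
    v <- matrix(rnorm(15 * 6, 22), 15, 6,
                dimnames = list(sprintf("P%02d", 1:15), sampleIDs(ann)))
    li <- make_logintensities(v, ann)
    g1 <- sampleIDs(ann)[1:3]; g2 <- sampleIDs(ann)[4:6]
    a <- permutationFDR(baitVsComplementTest(li, "B1", min_valid = 3),
                        li, g1, g2, seed = 1)
    b <- permutationFDR(baitVsComplementTest(li, "B2", min_valid = 3),
                        li, g2, g1, seed = 1)
    expect_equal(a$log2_difference, -b$log2_difference)
    expect_equal(a$t_statistic, -b$t_statistic)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$q_value, b$q_value)
})

test_that("tests are feature-wise independent given labels", {
    ann <- make_annotation(baits = c("B1", "B2"), replicates = 4)
    set.seed(11)
    v <- matrix(rnorm(10 * 8, 24), 10, 8,
                dimnames = list(sprintf("P%02d", 1:10), sampleIDs(ann)))
    li <- make_logintensities(v, ann)
    p_before <- baitVsComplementTest(li, "B1", min_valid = 3)$p_value
    # append an all-missing-then-imputed feature
    v2 <- rbind(v, IMP = rnorm(8, 18, 0.5))
    observed <- rbind(matrix(TRUE, 10, 8), IMP = rep(FALSE, 8))
    li2 <- make_logintensities(v2, ann, observed = observed)
    p_after <- baitVsComplementTest(li2, "B1", min_valid = 3)$p_value
    expect_equal(p_after[1:10], p_before)
})

test_that("interactor calls are conjunctive in q, enrichment and validity", {
    base <- data.frame(
        bait_id = "B1", protein_id = c("lowfold", "good", "badq", "sparse"),
        log2_difference = c(log2(1.5), 2, 3, 3),
        t_statistic = c(5, 8, 2, 8), p_value = c(1e-4, 1e-6, 0.1, 1e-6),
        n_valid_bait = c(12, 12, 12, 4), n_valid_complement = 12,
        testable = TRUE,
        q_value = c(0.005, 0.005, 0.2, 0.001), stringsAsFactors = FALSE)
    out <- callInteractors(base, fdr = 0.01, enrichment = 2, min_valid = 10)
    sig <- out$protein_id[out$significant]
    expect_identical(sig, "good")  # fold 1.5 fails, q 0.2 fails, 4 valid fails
    expect_equal(out$fold_enrichment, 2^out$log2_difference)
    expect_identical(out$rank, seq_len(nrow(out)))
    expect_true(!is.unsorted(out$q_value))
})

test_that("control grouping recovers correlation blocks and validates input", {
    ann <- make_annotation(baits = c("A1", "A2", "B1", "B2"), replicates = 3)
    set.seed(21)
    latent1 <- rnorm(300, 24, 2); latent2 <- rnorm(300, 24, 2)
    block <- rep(c(1, 2), each = 6)
    v <- sapply(block, function(b)
        (if (b == 1) latent1 else latent2) + rnorm(300, 0, 0.5))
    dimnames(v) <- list(sprintf("P%03d", 1:300), sampleIDs(ann))
    li <- make_logintensities(v, ann)
    g <- buildControlGroups(li, n_groups = 2)
    expect_identical(g$sample_id, sampleIDs(ann))
    expect_equal(length(unique(g$group_id)), 2L)
    expect_true(all(tapply(g$group_id, block, function(x)
        length(unique(x)) == 1)))
    expect_false(g$group_id[1] == g$group_id[7])
    # auto cut maximizes mean silhouette: brute-force oracle over 2..3
    d <- as.dist(1 - cor(v))
    hc <- hclust(d, method = "average")
    sil <- sapply(2:3, function(k)
        mean(cluster::silhouette(cutree(hc, k), d)[, "sil_width"]))
    g_auto <- buildControlGroups(li, n_groups = "auto")
    expect_equal(length(unique(g_auto$group_id)), c(2:3)[which.max(sil)])
    # identical samples, one group requested -> a single group
    v1 <- matrix(rep(rnorm(50, 24), 6), 50, 6,
                 dimnames = list(sprintf("Q%02d", 1:50),
                                 sampleIDs(ann)[1:6]))
    ann6 <- make_annotation(baits = c("A1", "A2"), replicates = 3)
    li1 <- make_logintensities(v1, ann6)
    g1 <- buildControlGroups(li1, n_groups = 1)
    expect_equal(length(unique(g1$group_id)), 1L)
    expect_error(buildControlGroups(li1, n_groups = 5),
                 "exceeds the number of baits")
    # pairs sharing under 10 observed cells suggest imputation
    obs <- matrix(TRUE, 50, 6, dimnames = dimnames(v1))
    obs[6:50, 1] <- FALSE
    li_sparse <- make_logintensities(v1, ann6, observed = obs,
                                     impute_missing_cells = FALSE)
    expect_error(buildControlGroups(li_sparse, n_groups = 1),
                 "impute")
})

test_that("whole-proteome differential calling finds only the shifted protein", {
    ann <- make_annotation(baits = c("WT", "KO"), replicates = 3)
    set.seed(31)
    v <- matrix(rnorm(40 * 6, 24, 0.2), 40, 6,
                dimnames = list(sprintf("P%02d", 1:40), sampleIDs(ann)))
    gA <- sampleIDs(ann)[1:3]; gB <- sampleIDs(ann)[4:6]
    # identical proteomes: nothing significant
    v_id <- v; v_id[, 4:6] <- v[, 1:3]
    li_id <- make_logintensities(v_id, ann)
    out0 <- wholeProteomeDiff(li_id, gA, gB, seed = 2)
    expect_equal(sum(out0$significant), 0L)
    # one protein shifted by 3 log2 units in group A
    v[1, 1:3] <- v[1, 1:3] + 3
    li <- make_logintensities(v, ann)
    out <- wholeProteomeDiff(li, gA, gB, seed = 2)
    expect_identical(out$protein_id[out$significant], "P01")
    # min_valid = 2 admits proteins observed only twice in group A
    observed <- matrix(TRUE, 40, 6, dimnames = dimnames(v))
    observed[1, 1] <- FALSE
    li2 <- make_logintensities(v, ann, observed = observed)
    out2 <- wholeProteomeDiff(li2, gA, gB, seed = 2)
    expect_true(out2$testable[out2$protein_id == "P01"])
    expect_equal(out2$n_valid_bait[out2$protein_id == "P01"], 2)
})

test_that("permutation FDR controls the null false-positive fraction", {
    # exchangeable null: all samples i.i.d.; fraction with q < 0.01 stays
    # around or below 1% on average
    ann <- make_annotation(baits = c("B1", "B2", "B3"), replicates = 4)
    fracs <- vapply(1:20, function(s) {
        set.seed(1000 + s)
        v <- matrix(rnorm(150 * 12, 24), 150, 12,
                    dimnames = list(sprintf("P%03d", 1:150),
                                    sampleIDs(ann)))
        li <- make_logintensities(v, ann)
        tests <- baitVsComplementTest(li, "B1", min_valid = 3)
        q <- permutationFDR(tests, li, sampleIDs(ann)[1:4],
                            sampleIDs(ann)[5:12], seed = s)$q_value
        mean(q < 0.01)
    }, numeric(1))
    expect_lte(mean(fracs), 0.01 + 2 * sd(fracs) / sqrt(length(fracs)))
})
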