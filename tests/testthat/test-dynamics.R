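test_that("prey-to-bait normalization follows the ratio formula", {
    ann <- make_annotation(baits = "B1", replicates = 2)
    m <- rbind(BAIT = c(2^22, 0), PREY1 = c(2^22, 2^20),
               PREY2 = c(2^20, 2^21))
    colnames(m) <- sampleIDs(ann)
    pq <- make_protein_quant(m, ann)
    r <- normalizePreyToBait(pq, "BAIT")
    expect_equal(r["PREY1", 1], 1.0)     # prey equal to bait -> 1
    expect_equal(r["PREY2", 1], 0.25)    # 2^20 / 2^22
    # bait missing in sample 2: every prey missing there, sample flagged
    expect_true(all(is.na(r[, 2])))
    expect_identical(attr(r, "flagged_samples"), sampleIDs(ann)[2])
    expect_error(normalizePreyToBait(pq, "NOPE"), "absent")
})

test_that("normalization is scale-equivariant (loading-artifact removal)", {
    ann <- make_annotation(baits = "B1", replicates = 3)
    set.seed(6)
    m <- matrix(2^rnorm(12, 22), 4, 3,
                dimnames = list(c("BAIT", paste0("P", 1:3)),
                                sampleIDs(ann)))
    pq <- make_protein_quant(m, ann)
    r1 <- normalizePreyToBait(pq, "BAIT")
    m2 <- sweep(m, 2, c(3.7, 0.2, 11), "*")  # per-sample loading factors
    r2 <- normalizePreyToBait(make_protein_quant(m2, ann), "BAIT")
    expect_equal(r1, r2)
})

test_that("PTM normalization enforces the 3-valid-replicates rule without imputation", {
    ann <- make_annotation(baits = "B1", replicates = 4,
                           timepoints = c(0, 5, 15, 30))
    ids <- c("PROT1", "PROT2")
    m <- matrix(2^20, 2, 16, dimnames = list(ids, sampleIDs(ann)))
    pq <- make_protein_quant(m, ann)
    sids <- sampleIDs(ann)
    inten <- function(pattern_valid) {
        x <- numeric(16); names(x) <- sids
        x[pattern_valid] <- 2^20
        x
    }
    tp <- ann$time_min
    # site A: 2 valid replicates at every time point -> dropped
    vA <- unlist(lapply(c(0, 5, 15, 30), function(t) which(tp == t)[1:2]))
    # site B: 3/4 valid at 15 min only -> retained
    vB <- which(tp == 15)[1:3]
    mod <- data.frame(peptide_id = c("a", "b"),
                      protein_id = c("PROT1", "PROT2"),
                      mod_type = "phospho", site_position = c(10L, 20L),
                      residue = "S", stringsAsFactors = FALSE)
    mod <- cbind(mod, rbind(inten(vA), inten(vB)))
    out <- normalizePTMToProtein(mod, pq)
    expect_identical(rownames(out), "PROT2_phospho_20")
    # site intensity equal to protein intensity -> ratio 1, and missing cells
    # stay missing (never imputed)
    expect_equal(unname(out[1, vB]), rep(1, 3))
    expect_true(all(is.na(out[1, -vB])))
    # sites of proteins without a protein row are skipped with a warning
    mod2 <- mod; mod2$protein_id[2] <- "GHOST"
    expect_warning(out2 <- normalizePTMToProtein(mod2, pq), "GHOST")
    expect_equal(nrow(out2), 0L)
})

test_that("peptide rows mapping to one site are summed before normalization", {
    ann <- make_annotation(baits = "B1", replicates = 4)
    pq <- make_protein_quant(
        matrix(2^20, 1, 4, dimnames = list("PROT1", sampleIDs(ann))), ann)
    mod <- data.frame(peptide_id = c("a", "b"), protein_id = "PROT1",
                      mod_type = "phospho", site_position = 10L,
                      residue = "S", stringsAsFactors = FALSE)
    inten <- matrix(2^19, 2, 4, dimnames = list(NULL, sampleIDs(ann)))
    out <- normalizePTMToProtein(cbind(mod, inten), pq,
                                 min_valid_per_timepoint = 3)
    expect_equal(nrow(out), 1L)
    expect_equal(unname(out[1, ]), rep(1, 4))  # (2^19 + 2^19) / 2^20
})

test_that("time-course significance matches a closed-form t oracle", {
    ann <- make_annotation(baits = "B1", replicates = 4,
                           timepoints = c(0, 15, 30))
    set.seed(13)
    base <- rnorm(4, 1, 0.1)
    # 4-fold shift at 30 min, CV ~10%, 4 vs 4 replicates
    vals <- rbind(
        up30 = c(base, rnorm(4, 1, 0.1), 4 * rnorm(4, 1, 0.1)),
        stable = rep(c(1.0, 1.1, 0.9, 1.05), 3))
    colnames(vals) <- sampleIDs(ann)
    res <- timecourseSignificance(vals, ann)
    p30 <- res$per_timepoint$p_value[
        res$per_timepoint$feature_id == "up30" &
        res$per_timepoint$time_min == 30]
    o <- oracle_pooled_t(log2(vals["up30", ann$time_min == 30]),
                         log2(vals["up30", ann$time_min == 0]))
    expect_equal(p30, o$p)
    expect_lt(p30, 0.05)
    expect_true(res$summary$significant_any_time[
        res$summary$feature_id == "up30"])
    # identical distributions at 0 and 15 min: high p, and a feature
    # significant at any single time point is flagged
    pstable <- res$per_timepoint$p_value[
        res$per_timepoint$feature_id == "stable"]
    expect_true(all(pstable > 0.9))
    expect_false(res$summary$significant_any_time[
        res$summary$feature_id == "stable"])
    expect_error(timecourseSignificance(
        vals[, ann$time_min > 0, drop = FALSE],
        ann[ann$time_min > 0, ]), "time-0")
})

test_that("significance results are invariant to feature ordering", {
    ann <- make_annotation(baits = "B1", replicates = 3,
                           timepoints = c(0, 5, 15))
    set.seed(14)
    vals <- matrix(2^rnorm(9 * 5, 0, 0.5), 5, 9,
                   dimnames = list(paste0("F", 1:5), sampleIDs(ann)))
    a <- timecourseSignificance(vals, ann)
    b <- timecourseSignificance(vals[5:1, ], ann)
    merged <- merge(a$summary, b$summary, by = "feature_id")
    expect_equal(merged$min_p.x, merged$min_p.y)
})
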