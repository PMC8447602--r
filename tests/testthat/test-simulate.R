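test_that("generator is deterministic and matches its construction arithmetic", {
    cfg <- simulationConfig(n_baits = 3, n_background = 50,
                            interactors_per_bait = 4, seed = 5)
    a <- generateAPMSDataset(cfg)
    b <- generateAPMSDataset(cfg)
    expect_identical(lfq(a$protein_quant), lfq(b$protein_quant))
    expect_identical(a$truth, b$truth)
    # truth covers every generated feature; counting oracle for disjoint sets
    expect_equal(nrow(a$truth), 50 + 3 * (1 + 4))
    expect_setequal(a$truth$protein_id, rownames(a$protein_quant))
    expect_true(all(a$truth$true_log2_effect[
        a$truth$role == "background"] == 0))
    # zero noise: bait-vs-complement difference equals log2_effect exactly
    cfg0 <- simulationConfig(n_baits = 3, n_background = 50,
                             interactors_per_bait = 4, replicate_sd = 0,
                             seed = 5)
    sim0 <- generateAPMSDataset(cfg0)
    v <- log2(lfq(sim0$protein_quant))
    own <- sim0$annotation$bait_id == "BAIT02"
    d <- rowMeans(v[, own]) - rowMeans(v[, !own])
    expect_equal(unname(d["INT_BAIT02_01"]), cfg0$log2_effect)
    expect_equal(unname(d["BAIT02"]), cfg0$bait_self_effect)
    expect_equal(unname(d["BG0001"]), 0)
})

test_that("interactor overlap creates shared preys", {
    cfg <- simulationConfig(n_baits = 2, n_background = 10,
                            interactors_per_bait = 4,
                            interactor_overlap = 0.5, seed = 3)
    sim <- generateAPMSDataset(cfg)
    shared <- sim$truth[sim$truth$role == "true_interactor" &
                        grepl(";", sim$truth$bait_id), ]
    expect_equal(nrow(shared), 2L)
    expect_equal(nrow(sim$truth), 10 + 2 * (1 + 4) - 2)
})

test_that("MNAR dropout follows the logistic intensity model", {
    cfg <- simulationConfig(n_baits = 2, n_background = 1500,
                            interactors_per_bait = 2, seed = 9)
    sim <- generateAPMSDataset(cfg)
    dr <- applyMNARMissingness(sim$protein_quant, cfg)
    v <- log2(lfq(sim$protein_quant))
    # dropout is enriched in the lowest intensity decile vs the highest
    qs <- quantile(v, c(0.1, 0.9))
    low <- mean(dr$dropped[v <= qs[1]])
    high <- mean(dr$dropped[v >= qs[2]])
    expect_gt(low, high)
    # cells near the midpoint drop at about 50%
    near <- abs(v - cfg$mnar_midpoint) < 0.1
    if (sum(near) > 200)
        expect_equal(mean(dr$dropped[near]), 0.5, tolerance = 0.15)
    # slope 0: uniform dropout probability 0.5 at any intensity
    cfg0 <- simulationConfig(n_baits = 2, n_background = 1500,
                             interactors_per_bait = 2, mnar_slope = 0,
                             seed = 9)
    dr0 <- applyMNARMissingness(sim$protein_quant, cfg0)
    expect_equal(mean(dr0$dropped), 0.5, tolerance = 0.02)
    expect_equal(cor(as.numeric(dr0$dropped), as.numeric(v)), 0,
                 tolerance = 0.02)
    # seeded: same config, same dropout
    dr2 <- applyMNARMissingness(sim$protein_quant, cfg)
    expect_identical(dr$dropped, dr2$dropped)
})

test_that("background replicates reproduce the high-correlation regime", {
    sim <- generateAPMSDataset(simulationConfig(
        n_baits = 4, n_background = 800, interactors_per_bait = 5,
        seed = 23))
    v <- log2(lfq(sim$protein_quant))
    bg <- v[sim$truth$protein_id[sim$truth$role == "background"], ]
    r <- cor(bg)
    expect_gt(min(r[upper.tri(r)]), 0.9)
})

test_that("generator output passes the reader round trip and preprocessing", {
    cfg <- simulationConfig(n_baits = 2, n_background = 60,
                            interactors_per_bait = 3, seed = 31)
    sim <- generateAPMSDataset(cfg)
    dr <- applyMNARMissingness(sim$protein_quant, cfg)
    pg <- withr::local_tempfile(fileext = ".tsv")
    an <- withr::local_tempfile(fileext = ".tsv")
    writeProteinGroups(dr$protein_quant, pg)
    writeSampleAnnotation(sim$annotation, an)
    ann <- readSampleAnnotation(an)
    pq <- readProteinGroups(pg, ann)
    expect_identical(lfq(pq), lfq(dr$protein_quant))
    li <- imputeMissing(filterValidValues(log2Transform(
        filterIdentifications(pq))), seed = 2)
    expect_false(any(missingMask(li) & !imputedMask(li)))
})

test_that("time-course generator encodes profile classes faithfully", {
    cfg <- simulationConfig(n_baits = 1, n_background = 20,
                            interactors_per_bait = 8, dynamic_fraction = 1,
                            replicate_sd = 0, n_ptm_sites = 6,
                            profile_classes = c("early_up", "late_up",
                                                "down", "flat"),
                            seed = 77)
    tc <- generateTimecourseDataset(cfg)
    tc2 <- generateTimecourseDataset(cfg)
    expect_identical(lfq(tc$protein_quant), lfq(tc2$protein_quant))
    expect_identical(tc$mod_table, tc2$mod_table)
    r <- normalizePreyToBait(tc$protein_quant, "BAIT01",
                             grep("^INT", rownames(tc$protein_quant),
                                  value = TRUE))
    ann <- tc$annotation
    med <- sapply(sort(unique(ann$time_min)), function(t)
        apply(r[, ann$time_min == t, drop = FALSE], 1, median))
    cls <- setNames(tc$truth$profile_class, tc$truth$protein_id)
    # flat class, zero noise: constant normalized medians
    flat <- names(cls)[cls == "flat" & grepl("^INT", names(cls))]
    expect_true(all(abs(med[flat, ] / med[flat, 1] - 1) < 1e-9))
    # late_up rises monotonically, down falls
    lu <- names(cls)[cls == "late_up" & grepl("^INT", names(cls))][1]
    expect_true(all(diff(med[lu, ]) > 0))
    dn <- names(cls)[cls == "down" & grepl("^INT", names(cls))][1]
    expect_true(all(diff(med[dn, ]) < 0))
    # early_up peaks at the first activated time point
    eu <- names(cls)[cls == "early_up" & grepl("^INT", names(cls))][1]
    expect_equal(which.max(med[eu, ]), 2L)
    expect_error(simulationConfig(profile_classes = "sideways"),
                 "unknown profile class")
})
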