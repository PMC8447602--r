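#' Benchmark interactor calling against synthetic ground truth
#'
#' Runs the full calling procedure — synthetic data generation,
#' intensity-dependent dropout, identification filtering, log2 transform,
#' valid-value filtering, detection-limit imputation, control grouping and
#' per-bait permutation-FDR screening — over a series of seeds and scores
#' the calls against the generator's truth. A called (bait, prey) pair is a
#' true positive if the prey is a spiked interactor of that bait or the
#' bait's own row; anything else is a false positive. The per-seed false
#' discovery proportion is false positives / total calls (0 when nothing is
#' called); recall is counted over spiked interactor pairs only.
#'
#' On a 4-replicate-per-bait design a bait group can hold at most 4 observed
#' values, so the benchmark's `min_valid` defaults to 3 — the >60%-of-4
#' analogue of the 10-valid-value rule used for designs with 16 samples per
#' bait.
#'
#' @param cfg a [simulationConfig()]; its seed is replaced per run.
#' @param seeds integer vector of generator seeds.
#' @param fdr,enrichment,min_valid,n_permutations calling parameters.
#' @param n_groups control groups for [buildControlGroups()] (default 1:
#'   the generator's baits share one background population).
#' @return a `data.frame` with one row per seed: `seed`, `n_called`,
#'   `n_false`, `fdp`, `recall`.
#' @export
benchmarkInteractorCalling <- function(cfg = simulationConfig(),
                                       seeds = 1:20, fdr = 0.01,
                                       enrichment = 2, min_valid = 3L,
                                       n_permutations = 250L,
                                       n_groups = 1L) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    res <- lapply(seeds, function(s) {
        cfg$seed <- as.integer(s)
        sim <- generateAPMSDataset(cfg)
        drop <- applyMNARMissingness(sim$protein_quant, cfg)
        pq <- filterIdentifications(drop$protein_quant)
        li <- log2Transform(pq)
        li <- filterValidValues(li)
        li <- imputeMissing(li, seed = .child_seed(s, 2L))
        groups <- buildControlGroups(li, n_groups = n_groups)
        baits <- baitIDs(sim$annotation)
        calls <- do.call(rbind, lapply(seq_along(baits), function(i)
            screenBait(li, baits[i], groups, fdr = fdr,
                       enrichment = enrichment, min_valid = min_valid,
                       n_permutations = n_permutations,
                       seed = .child_seed(s, 10L + i))))
        sig <- calls[calls$significant, , drop = FALSE]
        truth <- sim$truth
        owners <- strsplit(truth$bait_id, ";", fixed = TRUE)
        names(owners) <- truth$protein_id
        n_called <- nrow(sig)
        is_true <- if (n_called) mapply(function(b, p) {
            p == b || (p %in% names(owners) && b %in% owners[[p]] &&
                       truth$role[match(p, truth$protein_id)] ==
                           "true_interactor")
        }, sig$bait_id, sig$protein_id) else logical(0)
        n_false <- sum(!is_true)
        # total spiked (bait, interactor) pairs, counting shared preys once
        # per owning bait
        total_true <- sum(lengths(
            owners[truth$role == "true_interactor"]))
        n_recovered <- if (n_called) sum(is_true & sig$bait_id !=
                                             sig$protein_id) else 0L
        data.frame(seed = s, n_called = n_called, n_false = n_false,
                   fdp = if (n_called) n_false / n_called else 0,
                   recall = n_recovered / total_true)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
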