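#' @importFrom stats plogis runif
NULL

#' Configuration of the synthetic AP-MS data generator
#'
#' Defines the study conditions the generator emulates: a panel of tagged
#' baits pulled down in replicate against a shared population of background
#' binders, with spiked true interactors, bait self-enrichment, log-normal
#' replicate noise, intensity-dependent (missing-not-at-random) dropout,
#' and — for time-course designs — dynamic profile classes for preys and
#' modification sites.
#'
#' @param n_baits number of bait pull-downs (default 20).
#' @param n_background number of shared background binder proteins
#'   (default 2000).
#' @param interactors_per_bait spiked true interactors per bait (default 15).
#' @param log2_effect mean bait-vs-complement enrichment of true interactors,
#'   log2 units (default 3).
#' @param bait_self_effect log2 self-enrichment of the bait's own row in its
#'   samples (default 6).
#' @param replicate_sd replicate noise standard deviation, log2 units
#'   (default 0.3).
#' @param background_mean,background_sd log2 mean and sd of baseline protein
#'   abundances (defaults 24 and 2).
#' @param replicates biological replicates per bait or per time point
#'   (default 4).
#' @param timepoints activation time points in minutes (default
#'   `c(0, 5, 15, 30)`; 0 = untreated).
#' @param dynamic_fraction fraction of preys/sites given a non-flat
#'   time-course class (default 0.5).
#' @param profile_classes candidate dynamic classes, a subset of
#'   `"early_up"`, `"late_up"`, `"down"`, `"flat"`.
#' @param dynamic_log2_amplitude peak log2 amplitude of dynamic trajectories
#'   (default 2, i.e. up to 4-fold).
#' @param mnar_midpoint log2 intensity at which dropout probability is 50%
#'   (default 20).
#' @param mnar_slope steepness of the logistic dropout curve (default 1).
#' @param n_ptm_sites modification sites generated in time-course mode
#'   (default 40).
#' @param interactor_overlap fraction of interactors shared with the next
#'   bait's set, to exercise shared-prey network logic (default 0).
#' @param seed integer seed.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(n_baits = 20L, n_background = 2000L,
                             interactors_per_bait = 15L, log2_effect = 3,
                             bait_self_effect = 6, replicate_sd = 0.3,
                             background_mean = 24, background_sd = 2,
                             replicates = 4L,
                             timepoints = c(0, 5, 15, 30),
                             dynamic_fraction = 0.5,
                             profile_classes = c("early_up", "late_up",
                                                 "down", "flat"),
                             dynamic_log2_amplitude = 2,
                             mnar_midpoint = 20, mnar_slope = 1,
                             n_ptm_sites = 40L, interactor_overlap = 0,
                             seed = 1L) {
    cfg <- list(n_baits = as.integer(n_baits),
                n_background = as.integer(n_background),
                interactors_per_bait = as.integer(interactors_per_bait),
                log2_effect = log2_effect,
                bait_self_effect = bait_self_effect,
                replicate_sd = replicate_sd,
                background_mean = background_mean,
                background_sd = background_sd,
                replicates = as.integer(replicates),
                timepoints = sort(unique(as.numeric(timepoints))),
                dynamic_fraction = dynamic_fraction,
                profile_classes = profile_classes,
                dynamic_log2_amplitude = dynamic_log2_amplitude,
                mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
                n_ptm_sites = as.integer(n_ptm_sites),
                interactor_overlap = interactor_overlap,
                seed = as.integer(seed))
    with(cfg, {
        if (n_baits < 1 || n_background < 1 || interactors_per_bait < 0 ||
            replicates < 1 || n_ptm_sites < 0)
            stop("all counts must be positive")
        if (dynamic_fraction < 0 || dynamic_fraction > 1)
            stop("dynamic_fraction must be in [0, 1]")
        if (interactor_overlap < 0 || interactor_overlap > 1)
            stop("interactor_overlap must be in [0, 1]")
        if (replicate_sd < 0) stop("replicate_sd must be non-negative")
        bad <- setdiff(profile_classes,
                       c("early_up", "late_up", "down", "flat"))
        if (length(bad))
            stop("unknown profile class(es): ", paste(bad, collapse = ", "))
    })
    structure(cfg, class = "SimulationConfig")
}

# feature layout shared by both generators
.sim_features <- function(cfg) {
    baits <- sprintf("BAIT%02d", seq_len(cfg$n_baits))
    bg <- sprintf("BG%04d", seq_len(cfg$n_background))
    ints <- lapply(seq_len(cfg$n_baits), function(b)
        sprintf("INT_%s_%02d", baits[b], seq_len(cfg$interactors_per_bait)))
    if (cfg$interactor_overlap > 0 && cfg$n_baits > 1) {
        n_share <- round(cfg$interactor_overlap * cfg$interactors_per_bait)
        if (n_share > 0)
            for (b in seq_len(cfg$n_baits - 1))
                ints[[b + 1]][seq_len(n_share)] <- ints[[b]][
                    cfg$interactors_per_bait - seq_len(n_share) + 1]
    }
    list(baits = baits, background = bg, interactors = ints)
}

.sim_truth <- function(cfg, fs) {
    int_ids <- unique(unlist(fs$interactors))
    owner <- lapply(int_ids, function(id) {
        fs$baits[vapply(fs$interactors, function(s) id %in% s, logical(1))]
    })
    data.frame(
        protein_id = c(fs$baits, int_ids, fs$background),
        role = c(rep("bait", length(fs$baits)),
                 rep("true_interactor", length(int_ids)),
                 rep("background", length(fs$background))),
        bait_id = c(fs$baits,
                    vapply(owner, paste, character(1), collapse = ";"),
                    rep(NA_character_, length(fs$background))),
        true_log2_effect = c(rep(cfg$bait_self_effect, length(fs$baits)),
                             rep(cfg$log2_effect, length(int_ids)),
                             rep(0, length(fs$background))),
        profile_class = NA_character_, stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-bait AP-MS dataset with known truth
#'
#' All proteins share a latent log2 baseline abundance profile (drawn once
#' per protein), which induces the high inter-sample correlation of
#' background binders; replicate noise is additive on the log2 scale. Each
#' bait's own row is up-shifted by `bait_self_effect` and its true
#' interactors by `log2_effect`, in that bait's samples only. Intensities
#' are exponentiated to the linear LFQ scale. Deterministic given the
#' config seed.
#'
#' @param cfg a [simulationConfig()].
#' @return a list with `protein_quant` (a [ProteinQuant-class]),
#'   `annotation` (a [SampleAnnotation-class]) and `truth` (a `data.frame`
#'   with `protein_id`, `role`, `bait_id`, `true_log2_effect`,
#'   `profile_class`).
#' @export
generateAPMSDataset <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    fs <- .sim_features(cfg)
    truth <- .sim_truth(cfg, fs)
    ids <- truth$protein_id
    ann <- SampleAnnotation(do.call(rbind, lapply(
        seq_along(fs$baits), function(b) data.frame(
            sample_id = sprintf("%s_r%d", fs$baits[b],
                                seq_len(cfg$replicates)),
            bait_id = fs$baits[b], condition = "untreated", time_min = 0,
            replicate = seq_len(cfg$replicates),
            stringsAsFactors = FALSE))))
    sids <- sampleIDs(ann)
    lfq <- .with_seed(cfg$seed, {
        base <- rnorm(length(ids), cfg$background_mean, cfg$background_sd)
        m <- matrix(base, length(ids), length(sids),
                    dimnames = list(ids, sids))
        for (b in seq_along(fs$baits)) {
            own <- ann$bait_id == fs$baits[b]
            m[fs$baits[b], own] <- m[fs$baits[b], own] + cfg$bait_self_effect
            m[fs$interactors[[b]], own] <-
                m[fs$interactors[[b]], own, drop = FALSE] + cfg$log2_effect
        }
        if (cfg$replicate_sd > 0)
            m <- m + rnorm(length(m), 0, cfg$replicate_sd)
        pep <- sample(2:30, length(ids), replace = TRUE)
        list(m = 2^m, pep = pep)
    })
    rd <- DataFrame(gene_name = ids, peptide_count = as.integer(lfq$pep),
                    is_contaminant = FALSE, is_reverse = FALSE,
                    only_identified_by_site = FALSE, row.names = ids)
    list(protein_quant = ProteinQuant(lfq$m, ann, rowData = rd),
         annotation = ann, truth = truth)
}

#' Apply intensity-dependent (MNAR) dropout
#'
#' Sets each cell to 0 ("not quantified") independently with probability
#' `logistic((mnar_midpoint - log2 intensity) * mnar_slope)`, so that
#' low-abundance measurements drop out preferentially — the structure the
#' downshifted-Gaussian imputation assumes. With `mnar_slope = 0` the
#' dropout probability is uniformly 0.5.
#'
#' @param pq a [ProteinQuant-class] with positive linear intensities.
#' @param cfg a [simulationConfig()] supplying `mnar_midpoint`,
#'   `mnar_slope` and the seed (used as `seed + 1` so dropout is independent
#'   of generation noise).
#' @param seed optional explicit seed overriding the config-derived one.
#' @return a list with `protein_quant` (zeros inserted) and `dropped`
#'   (logical matrix of dropout indicators).
#' @export
applyMNARMissingness <- function(pq, cfg, seed = NULL) {
    stopifnot(is(pq, "ProteinQuant"), inherits(cfg, "SimulationConfig"))
    v <- lfq(pq)
    if (any(v <= 0)) stop("intensities must be positive before dropout")
    if (is.null(seed)) seed <- .child_seed(cfg$seed, 1L)
    p <- plogis((cfg$mnar_midpoint - log2(v)) * cfg$mnar_slope)
    dropped <- .with_seed(seed,
        matrix(runif(length(v)) < p, nrow(v), ncol(v),
               dimnames = dimnames(v)))
    v[dropped] <- 0
    out <- ProteinQuant(v, sampleAnnotation(pq), rowData = rowData(pq))
    list(protein_quant = out, dropped = dropped)
}

# log2 trajectory offsets per class over the time grid
.class_trajectory <- function(class, tp, amp) {
    act <- tp[tp > 0]
    traj <- numeric(length(tp))
    if (class == "flat" || !length(act)) return(traj)
    switch(class,
        early_up = {
            peak <- act[1]
            traj[tp == peak] <- amp
            later <- tp > peak
            if (any(later))
                traj[later] <- amp * (1 - seq_len(sum(later)) /
                                          (sum(later) + 1))
        },
        late_up = {
            traj[tp > 0] <- amp * seq_along(act) / length(act)
        },
        down = {
            traj[tp > 0] <- -amp * seq_along(act) / length(act)
        },
        stop("unknown profile class: ", class))
    traj
}

#' Generate a synthetic activation time course with dynamic PPIs and PTMs
#'
#' Simulates one bait pulled down in replicate at each time point. A
#' `dynamic_fraction` of the bait's true interactors is assigned a dynamic
#' profile class defining a multiplicative trajectory over the time course
#' (`early_up`: peak at the first activated time point then decay;
#' `late_up`: monotone rise; `down`: monotone fall; `flat`: constant); the
#' rest stay flat. Modification-site intensities are generated as protein
#' intensity x occupancy trajectory x noise, so a site is dynamic relative
#' to its protein.
#'
#' @param cfg a [simulationConfig()] (needs >= 3 time points).
#' @return a list with `protein_quant`, `annotation`, `mod_table` (a
#'   modified-peptide `data.frame` in the [readModifiedPeptideSites()]
#'   layout) and `truth` (with per-feature `profile_class`; PTM sites appear
#'   as `"<protein>_<mod>_<pos>"` rows with role `"ptm_site"`).
#' @export
generateTimecourseDataset <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    tp <- cfg$timepoints
    if (length(tp) < 3) stop("need at least 3 time points")
    bait <- "BAIT01"
    preys <- sprintf("INT_%s_%02d", bait, seq_len(cfg$interactors_per_bait))
    bg <- sprintf("BG%04d", seq_len(cfg$n_background))
    ids <- c(bait, preys, bg)
    ann <- SampleAnnotation(do.call(rbind, lapply(tp, function(t)
        data.frame(sample_id = sprintf("t%03d_r%d", t,
                                       seq_len(cfg$replicates)),
                   bait_id = bait,
                   condition = ifelse(t == 0, "untreated", "activated"),
                   time_min = t, replicate = seq_len(cfg$replicates),
                   stringsAsFactors = FALSE))))
    sids <- sampleIDs(ann)
    res <- .with_seed(cfg$seed, {
        base <- rnorm(length(ids), cfg$background_mean, cfg$background_sd)
        names(base) <- ids
        base[bait] <- cfg$background_mean + cfg$bait_self_effect
        base[preys] <- base[preys] + cfg$log2_effect
        n_dyn <- round(cfg$dynamic_fraction * length(preys))
        classes <- rep("flat", length(preys))
        dyn_classes <- setdiff(cfg$profile_classes, "flat")
        if (n_dyn > 0 && length(dyn_classes))
            classes[seq_len(n_dyn)] <- rep_len(dyn_classes, n_dyn)
        names(classes) <- preys
        m <- matrix(base, length(ids), length(sids),
                    dimnames = list(ids, sids))
        for (p in preys) {
            traj <- .class_trajectory(classes[p], tp,
                                      cfg$dynamic_log2_amplitude)
            m[p, ] <- m[p, ] + traj[match(ann$time_min, tp)]
        }
        if (cfg$replicate_sd > 0)
            m <- m + rnorm(length(m), 0, cfg$replicate_sd)
        lin <- 2^m
        # modification sites on randomly chosen carrier proteins
        n_sites <- cfg$n_ptm_sites
        carriers <- sample(c(bait, preys), n_sites, replace = TRUE)
        site_pos <- sample.int(500, n_sites)
        site_class <- if (length(cfg$profile_classes))
            sample(cfg$profile_classes, n_sites, replace = TRUE)
            else rep("flat", n_sites)
        occ <- 0.25
        site_int <- matrix(0, n_sites, length(sids),
                           dimnames = list(NULL, sids))
        for (s in seq_len(n_sites)) {
            traj <- .class_trajectory(site_class[s], tp,
                                      cfg$dynamic_log2_amplitude)
            noise <- if (cfg$replicate_sd > 0)
                rnorm(length(sids), 0, cfg$replicate_sd) else 0
            site_int[s, ] <- lin[carriers[s], ] * occ *
                2^(traj[match(ann$time_min, tp)] + noise)
        }
        pep <- sample(2:30, length(ids), replace = TRUE)
        list(lin = lin, pep = pep, classes = classes,
             carriers = carriers, site_pos = site_pos,
             site_class = site_class, site_int = site_int)
    })
    rd <- DataFrame(gene_name = ids, peptide_count = as.integer(res$pep),
                    is_contaminant = FALSE, is_reverse = FALSE,
                    only_identified_by_site = FALSE, row.names = ids)
    pq <- ProteinQuant(res$lin, ann, rowData = rd)
    mod <- data.frame(
        peptide_id = sprintf("pep%03d", seq_len(cfg$n_ptm_sites)),
        protein_id = as.character(res$carriers),
        mod_type = rep("phospho", cfg$n_ptm_sites),
        site_position = as.integer(res$site_pos),
        residue = rep("S", cfg$n_ptm_sites),
        stringsAsFactors = FALSE)
    mod <- cbind(mod, as.data.frame(res$site_int, check.names = FALSE))
    truth <- data.frame(
        protein_id = c(ids, sprintf("%s_phospho_%d", res$carriers,
                                    res$site_pos)),
        role = c("bait", rep("true_interactor", length(preys)),
                 rep("background", length(bg)),
                 rep("ptm_site", cfg$n_ptm_sites)),
        bait_id = bait,
        true_log2_effect = c(cfg$bait_self_effect,
                             rep(cfg$log2_effect, length(preys)),
                             rep(0, length(bg)),
                             rep(0, cfg$n_ptm_sites)),
        profile_class = c(NA_character_, unname(res$classes),
                          rep("flat", length(bg)), res$site_class),
        stringsAsFactors = FALSE)
    list(protein_quant = pq, annotation = ann, mod_table = mod,
         truth = truth)
}
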