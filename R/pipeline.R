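#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
#' @importFrom utils packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_config <- function(config) {
    if (is.character(config) && length(config) == 1) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a list or a YAML path")
    config
}

.check_inputs <- function(config, required) {
    for (key in required) {
        p <- config[[key]]
        if (is.null(p)) stop("config validation: missing path '", key, "'")
        if (!file.exists(p))
            stop("config validation: '", key, "' does not exist: ", p)
    }
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.write_manifest <- function(dir, stage_params, inputs) {
    manifest <- list(
        package = "apmsflow",
        version = as.character(packageVersion("apmsflow")),
        parameters = stage_params,
        inputs = lapply(inputs, function(p)
            list(path = p, md5 = unname(md5sum(p)))))
    write_json(manifest, file.path(dir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the interactor-calling workflow end to end
#'
#' Reads the annotation and proteinGroups tables, filters identifications,
#' log2-transforms, filters valid values, imputes missing values, assigns
#' control groups, screens every bait against its complement with the
#' permutation FDR, assembles the network (annotated against an optional
#' offline known-interaction list), and writes all result tables plus a run
#' manifest (parameters, seed, package version, input checksums). Re-running
#' with the same config reproduces every table bit-exactly.
#'
#' @param config a named list or path to a YAML file. Required keys:
#'   `protein_groups`, `annotation`, `output_dir`. Optional keys with
#'   defaults: `known_pairs`, `seed` (1), `min_peptides` (2),
#'   `min_valid_fraction` (0.6), `impute_width` (0.3),
#'   `impute_downshift` (1.8), `n_groups` ("auto"), `fdr` (0.01),
#'   `enrichment` (2), `min_valid` (10), `n_permutations` (250),
#'   `intensity_prefix` ("LFQ intensity ").
#' @return the output directory path, invisibly. Files written:
#'   `filtered_matrix.tsv`, `control_groups.tsv`, `volcano_<bait>.tsv`,
#'   `significant_interactors.tsv`, `network_edges.tsv`, `network.graphml`,
#'   `manifest.json`.
#' @export
runInteractome <- function(config) {
    config <- .load_config(config)
    .check_inputs(config, c("protein_groups", "annotation"))
    if (!is.null(config$known_pairs)) .check_inputs(config, "known_pairs")
    out <- config$output_dir
    if (is.null(out)) stop("config validation: missing 'output_dir'")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(config$seed %||% 1L)
    params <- list(
        seed = seed,
        min_peptides = config$min_peptides %||% 2L,
        min_valid_fraction = config$min_valid_fraction %||% 0.6,
        impute_width = config$impute_width %||% 0.3,
        impute_downshift = config$impute_downshift %||% 1.8,
        n_groups = config$n_groups %||% "auto",
        fdr = config$fdr %||% 0.01,
        enrichment = config$enrichment %||% 2,
        min_valid = config$min_valid %||% 10L,
        n_permutations = config$n_permutations %||% 250L)
    ann <- .stage("read_annotation", readSampleAnnotation(config$annotation))
    pq <- .stage("read_protein_groups", readProteinGroups(
        config$protein_groups, ann,
        intensity_prefix = config$intensity_prefix %||% "LFQ intensity "))
    pq <- .stage("filter_identifications",
                 filterIdentifications(pq, params$min_peptides))
    li <- .stage("log2_transform", log2Transform(pq))
    li <- .stage("filter_valid_values",
                 filterValidValues(li, min_fraction =
                                       params$min_valid_fraction))
    li <- .stage("impute_missing", imputeMissing(
        li, width = params$impute_width, downshift = params$impute_downshift,
        seed = .child_seed(seed, 2L)))
    groups <- .stage("build_control_groups",
                     buildControlGroups(li, n_groups = params$n_groups))
    baits <- baitIDs(sampleAnnotation(li))
    calls <- .stage("interactor_calling", do.call(rbind, lapply(
        seq_along(baits), function(i) screenBait(
            li, baits[i], groups, fdr = params$fdr,
            enrichment = params$enrichment, min_valid = params$min_valid,
            n_permutations = params$n_permutations,
            seed = .child_seed(seed, 10L + i)))))
    net <- .stage("build_network", buildNetwork(calls, baits = baits))
    if (!is.null(config$known_pairs))
        net <- .stage("annotate_known",
                      annotateKnown(net, readKnownPairs(config$known_pairs)))
    .stage("write_outputs", {
        mat <- as.data.frame(logIntensities(li), check.names = FALSE)
        writeResultTable(cbind(protein_id = rownames(li), mat),
                         file.path(out, "filtered_matrix.tsv"))
        writeResultTable(groups, file.path(out, "control_groups.tsv"))
        for (b in baits)
            writeResultTable(calls[calls$bait_id == b, ],
                             file.path(out, paste0("volcano_", b, ".tsv")))
        writeResultTable(calls[calls$significant, ],
                         file.path(out, "significant_interactors.tsv"))
        writeEdgeList(net, file.path(out, "network_edges.tsv"))
        writeNetworkGraphML(net, file.path(out, "network.graphml"))
        .write_manifest(out, params, c(
            protein_groups = config$protein_groups,
            annotation = config$annotation,
            known_pairs = config$known_pairs))
    })
    invisible(out)
}

#' Run the time-course dynamics workflow end to end
#'
#' Normalizes prey intensities to the bait and modification-site intensities
#' to their proteins, tests every feature per activated time point against
#' time 0, builds z-scored profiles, clusters them into `k_clusters`
#' co-regulation clusters, and writes tidy result tables plus a run
#' manifest.
#'
#' @param config a named list or YAML path. Required keys: `protein_groups`
#'   (raw table; normalization runs on linear intensities), `annotation`,
#'   `output_dir`. Optional: `sites` (modification-site table; omitting it
#'   yields a PPI-only run with a warning), `mod_type` ("phospho"),
#'   `interactors` (TSV with `bait_id`/`protein_id`, e.g. a
#'   `significant_interactors.tsv`; default: all non-bait rows), `bait`
#'   (default: the single bait in the annotation), `alpha` (0.05),
#'   `min_valid_per_timepoint` (3), `min_valid_fraction` (0.7),
#'   `k_clusters` (7), `seed` (1), `intensity_prefix`.
#' @return the output directory, invisibly. Files written:
#'   `dynamic_features.tsv` (tidy: feature_id, kind, time_min, replicate,
#'   normalized_value), `timepoint_significance.tsv`,
#'   `feature_summary.tsv`, `zscored_profiles.tsv`, `clusters.tsv`,
#'   `cluster_summary.tsv`, `manifest.json`.
#' @export
runDynamics <- function(config) {
    config <- .load_config(config)
    .check_inputs(config, c("protein_groups", "annotation"))
    if (!is.null(config$sites)) .check_inputs(config, "sites")
    if (!is.null(config$interactors)) .check_inputs(config, "interactors")
    out <- config$output_dir
    if (is.null(out)) stop("config validation: missing 'output_dir'")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(config$seed %||% 1L)
    params <- list(seed = seed, alpha = config$alpha %||% 0.05,
                   mod_type = config$mod_type %||% "phospho",
                   min_valid_per_timepoint =
                       config$min_valid_per_timepoint %||% 3L,
                   min_valid_fraction = config$min_valid_fraction %||% 0.7,
                   k_clusters = config$k_clusters %||% 7L)
    ann <- .stage("read_annotation", readSampleAnnotation(config$annotation))
    pq <- .stage("read_protein_groups", readProteinGroups(
        config$protein_groups, ann,
        intensity_prefix = config$intensity_prefix %||% "LFQ intensity "))
    bait <- config$bait %||% {
        b <- baitIDs(ann)
        if (length(b) != 1)
            stop("config validation: several baits in annotation; set 'bait'")
        b
    }
    preys <- if (!is.null(config$interactors)) {
        tab <- .read_tsv(config$interactors)
        unique(tab$protein_id[tab$bait_id == bait | is.na(tab$bait_id)])
    } else setdiff(rownames(pq), bait)
    preys <- setdiff(intersect(preys, rownames(pq)), bait)
    ppi <- .stage("normalize_prey_to_bait",
                  normalizePreyToBait(pq, bait, preys))
    feats <- list(PPI = ppi)
    if (!is.null(config$sites)) {
        mod <- .stage("read_sites", readModifiedPeptideSites(
            config$sites, ann, params$mod_type,
            intensity_prefix = config$site_intensity_prefix %||%
                "Intensity "))
        ptm <- .stage("normalize_ptm_to_protein", normalizePTMToProtein(
            mod, pq, min_valid_per_timepoint =
                params$min_valid_per_timepoint))
        if (nrow(ptm)) feats$PTM <- ptm
    } else {
        warning("no modification-site table supplied: PPI-only run")
    }
    sig <- .stage("timecourse_significance", lapply(
        feats, timecourseSignificance, annotation = ann,
        alpha = params$alpha))
    combined <- do.call(rbind, unname(feats))
    z <- .stage("build_zscored_profiles", buildZScoredProfiles(
        combined, ann, min_valid_fraction = params$min_valid_fraction))
    cl <- NULL
    if (nrow(z) >= max(2, params$k_clusters))
        cl <- .stage("cluster_profiles",
                     clusterProfiles(z, k = params$k_clusters))
    .stage("write_outputs", {
        tidy <- do.call(rbind, lapply(names(feats), function(kind) {
            v <- feats[[kind]]
            data.frame(feature_id = rep(rownames(v), ncol(v)),
                       kind = kind,
                       sample_id = rep(colnames(v), each = nrow(v)),
                       time_min = rep(ann$time_min, each = nrow(v)),
                       replicate = rep(ann$replicate, each = nrow(v)),
                       normalized_value = as.vector(v),
                       stringsAsFactors = FALSE)
        }))
        writeResultTable(tidy, file.path(out, "dynamic_features.tsv"))
        writeResultTable(
            do.call(rbind, lapply(names(sig), function(kind)
                cbind(kind = kind, sig[[kind]]$per_timepoint))),
            file.path(out, "timepoint_significance.tsv"))
        writeResultTable(
            do.call(rbind, lapply(names(sig), function(kind)
                cbind(kind = kind, sig[[kind]]$summary))),
            file.path(out, "feature_summary.tsv"))
        writeResultTable(cbind(feature_id = rownames(z),
                               as.data.frame(z, check.names = FALSE)),
                         file.path(out, "zscored_profiles.tsv"))
        if (!is.null(cl)) {
            writeResultTable(data.frame(feature_id = names(cl),
                                        cluster = as.integer(cl)),
                             file.path(out, "clusters.tsv"))
            summ <- do.call(rbind, lapply(seq_len(attr(cl, "k")),
                function(lab) {
                    s <- summarizeCluster(z, cl, lab,
                                          seed = .child_seed(seed, 30L + lab))
                    cbind(cluster = lab, n = attr(s, "n"), s)
                }))
            writeResultTable(summ, file.path(out, "cluster_summary.tsv"))
        }
        .write_manifest(out, params, c(
            protein_groups = config$protein_groups,
            annotation = config$annotation, sites = config$sites,
            interactors = config$interactors))
    })
    invisible(out)
}
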