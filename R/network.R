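#' @importFrom igraph graph_from_data_frame V V<- E vertex_attr edge_attr
#'   degree write_graph vcount ecount as_data_frame
NULL

#' Assemble the multi-bait interaction network
#'
#' Builds a graph with one node per distinct protein (baits and significant
#' preys) and one edge per significant (bait, prey) pair, carrying the log2
#' enrichment difference and the q-value. Preys called by several baits
#' appear once, so shared interactions connect the individual pull-down
#' experiments. Node order is deterministic (baits sorted, then preys
#' sorted). Node attributes: `role` (`"bait"`, `"prey"`, or `"both"` when a
#' bait is also called as another bait's prey) and `novelty` (`"bait"` for
#' baits; `"novel"` until [annotateKnown()] is applied).
#'
#' @param calls an interactor table (e.g. rows of [callInteractors()]
#'   results combined over baits) with columns `bait_id`, `protein_id`,
#'   `log2_difference`, `q_value`, `significant`.
#' @param baits bait ids to include as nodes even without significant
#'   interactors; defaults to the baits present in `calls`.
#' @return an [igraph::igraph] object.
#' @export
buildNetwork <- function(calls, baits = unique(calls$bait_id)) {
    sig <- calls[calls$significant, , drop = FALSE]
    edges <- data.frame(from = sig$bait_id, to = sig$protein_id,
                        log2_difference = sig$log2_difference,
                        q_value = sig$q_value, stringsAsFactors = FALSE)
    baits <- sort(unique(as.character(baits)))
    preys <- sort(setdiff(unique(sig$protein_id), baits))
    nodes <- data.frame(name = c(baits, preys), stringsAsFactors = FALSE)
    # a bait node that is also another bait's significant prey is "both"
    prey_of_other <- vapply(nodes$name, function(p) {
        any(sig$protein_id == p & sig$bait_id != p)
    }, logical(1))
    nodes$role <- ifelse(nodes$name %in% baits,
                         ifelse(prey_of_other, "both", "bait"), "prey")
    nodes$novelty <- ifelse(nodes$name %in% baits, "bait", "novel")
    graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Read an offline known-interaction list
#'
#' Two-column tab-separated file of unordered protein-id pairs (header
#' optional: a first line `protein_a<TAB>protein_b` is recognized and
#' skipped). Malformed rows (fewer than two non-empty fields) raise an error
#' naming the line.
#'
#' @param path path to the TSV.
#' @return a `data.frame` with columns `protein_a`, `protein_b`.
#' @export
readKnownPairs <- function(path) {
    lines <- readLines(path)
    start <- 1L
    if (length(lines) &&
        identical(tolower(strsplit(lines[1], "\t")[[1]][1:2]),
                  c("protein_a", "protein_b")))
        start <- 2L
    rows <- lapply(seq_along(lines), function(i) {
        if (i < start || !nzchar(trimws(lines[i]))) return(NULL)
        f <- strsplit(lines[i], "\t")[[1]]
        f <- trimws(f)
        if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]))
            stop("malformed known-pair row at line ", i, ": ", lines[i])
        data.frame(protein_a = f[1], protein_b = f[2],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(protein_a = character(), protein_b = character())
    out
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Annotate known versus novel interactors
#'
#' Labels each prey node `"known"` if at least one of its calling (bait,
#' prey) pairs occurs — in either orientation — in the supplied reference
#' list of known interactions, and `"novel"` otherwise. Bait nodes keep the
#' label `"bait"`. Topology is never altered and re-annotation is
#' idempotent.
#'
#' @param network an [igraph::igraph] from [buildNetwork()].
#' @param known_pairs a `data.frame` of unordered pairs, e.g. from
#'   [readKnownPairs()].
#' @return the network with updated `novelty` node attributes.
#' @export
annotateKnown <- function(network, known_pairs) {
    keys <- if (nrow(known_pairs))
        .pair_key(as.character(known_pairs[[1]]),
                  as.character(known_pairs[[2]])) else character()
    el <- as_data_frame(network, what = "edges")
    known_prey <- unique(c(
        el$to[.pair_key(el$from, el$to) %in% keys],
        el$from[.pair_key(el$from, el$to) %in% keys]))
    nov <- vertex_attr(network, "novelty")
    role <- vertex_attr(network, "role")
    nm <- V(network)$name
    nov <- ifelse(role == "bait" | nov == "bait", "bait",
                  ifelse(nm %in% known_prey, "known", "novel"))
    V(network)$novelty <- nov
    network
}

#' Export the network
#'
#' `writeEdgeList()` writes a plain TSV (`bait_id`, `prey_id`,
#' `log2_difference`, `q_value`); `writeNetworkGraphML()` writes GraphML.
#'
#' @param network an [igraph::igraph] from [buildNetwork()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
    el <- as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("bait_id", "prey_id")
    writeResultTable(el, path)
}

#' @rdname writeEdgeList
#' @export
writeNetworkGraphML <- function(network, path) {
    write_graph(network, path, format = "graphml")
    invisible(path)
}
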