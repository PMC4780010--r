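#' Build the evidence-filtered interaction graph
#'
#' Constructs a simple undirected graph from a protein-protein
#' interaction edge list. Duplicate records of the same unordered pair
#' are merged with their evidence counts summed, self-loops are dropped,
#' and only edges supported by at least `min_evidence` pieces of
#' experimental evidence are retained (default 2). Nodes incident to no
#' retained edge do not appear in the graph.
#'
#' @param edges Data frame with columns `node_a`, `node_b`,
#'   `evidence_count`.
#' @param min_evidence Minimum summed evidence count per retained edge.
#' @return An [igraph][igraph::igraph-package] undirected graph with an
#'   `evidence` edge attribute.
#' @export
build_graph <- function(edges, min_evidence = 2L) {
  assert_columns(edges, c("node_a", "node_b", "evidence_count"), "edges")
  bad <- !is.finite(edges$evidence_count) | edges$evidence_count < 1
  if (any(bad)) {
    stop("malformed edge record(s) at line(s): ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  ev <- edges$evidence_count[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  total <- tapply(ev, key, sum)
  pairs <- do.call(rbind, strsplit(names(total), "\r", fixed = TRUE))
  retained <- as.vector(total) >= min_evidence
  d <- data.frame(from = pairs[retained, 1L], to = pairs[retained, 2L],
                  evidence = as.vector(total)[retained],
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(d, directed = FALSE)
}

#' Expand seed genes to their first-neighbor subnetwork
#'
#' Maps the seed genes onto the interactome, reports seeds absent from
#' it, and returns the subgraph induced by the mapped seeds together with
#' all their direct neighbors (optionally restricted to a node
#' whitelist, e.g. brain-expressed genes).
#'
#' @param graph An igraph graph from [build_graph()].
#' @param seeds Character vector of seed gene symbols.
#' @param restrict_to Optional character vector; neighbors outside this
#'   set are not added (mapped seeds are always kept).
#' @return List with `mapped_seeds`, `unmapped_seeds`, and `subnetwork`
#'   (the induced igraph subgraph).
#' @export
expand_seeds <- function(graph, seeds, restrict_to = NULL) {
  nodes <- igraph::V(graph)$name
  seeds <- unique(seeds)
  mapped <- sort(intersect(seeds, nodes))
  unmapped <- sort(setdiff(seeds, nodes))
  nbrs <- character(0)
  if (length(mapped) > 0L) {
    nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(graph, mapped),
                                 function(v) nodes[as.integer(v)])))
  }
  if (!is.null(restrict_to)) nbrs <- intersect(nbrs, restrict_to)
  members <- sort(union(mapped, nbrs))
  list(mapped_seeds = mapped, unmapped_seeds = unmapped,
       subnetwork = igraph::induced_subgraph(graph, members))
}

#' Local clustering coefficient
#'
#' `C(v) = 2 T(v) / (d(v) (d(v) - 1))` where `T(v)` is the number of
#' edges among the neighbors of `v` and `d(v)` its degree; nodes with
#' degree below 2 have `C = 0` by convention.
#'
#' @param graph An igraph graph.
#' @param nodes Optional character vector of node names (default: all).
#' @return Named numeric vector of clustering coefficients in \[0, 1\].
#' @export
clustering_coefficient <- function(graph, nodes = NULL) {
  all_nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- all_nodes
  missing <- setdiff(nodes, all_nodes)
  if (length(missing) > 0L) {
    stop("node(s) absent from graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cc <- igraph::transitivity(graph, type = "localundirected",
                             vids = nodes, isolates = "zero")
  setNames(cc, nodes)
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness on the unweighted undirected graph
#' (Brandes accumulation), endpoints excluded, each unordered pair
#' counted once, normalized by `2 / ((n - 1)(n - 2))` so a node lying on
#' every geodesic of every pair scores 1.
#'
#' @param graph An igraph graph.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(graph) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  if (n == 0L) stop("graph is empty", call. = FALSE)
  if (n < 3L) return(setNames(rep(0, n), nodes))
  b <- igraph::betweenness(graph, directed = FALSE, normalized = TRUE,
                           weights = NA)
  setNames(as.numeric(b), nodes)
}

#' Brokering centrality
#'
#' Identifies hubs whose neighbors are mutually unconnected:
#' `brokering(v) = (d(v) / d_max) * (1 - C(v))` with `d_max` the maximum
#' degree in the graph and `C` the local clustering coefficient. The
#' score lies in \[0, 1\]; a star center scores 1, a clique vertex 0.
#' The definition is isolated here so an alternative brokering formula
#' can be swapped in.
#'
#' @param graph An igraph graph.
#' @return Named numeric vector of brokering values.
#' @export
brokering <- function(graph) {
  nodes <- igraph::V(graph)$name
  if (length(nodes) == 0L) stop("graph is empty", call. = FALSE)
  d <- igraph::degree(graph)
  d_max <- max(d)
  if (d_max == 0) return(setNames(rep(0, length(nodes)), nodes))
  cc <- clustering_coefficient(graph)
  setNames(as.numeric((d / d_max) * (1 - cc)), nodes)
}

#' Top-ranked nodes for a centrality measure
#'
#' Returns the `ceiling(fraction * n)` nodes with the largest values.
#' Ties at the cutoff are broken by lexicographic node name, so the
#' classification is deterministic.
#'
#' @param values Named numeric vector of per-node metric values.
#' @param fraction Fraction of nodes to classify (default 0.05, the
#'   top 5%).
#' @return Character vector of node names.
#' @export
classify_top <- function(values, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1, length(values) >= 1L)
  n_top <- ceiling(fraction * length(values))
  ord <- order(-values, names(values))
  names(values)[ord[seq_len(n_top)]]
}

#' Per-node topology table with broker/bottleneck classification
#'
#' Computes degree, clustering coefficient, normalized betweenness and
#' brokering centrality for every node, and flags the top `top_fraction`
#' by brokering as brokers and by betweenness as bottlenecks.
#'
#' @param graph An igraph graph.
#' @param seeds Character vector of seed gene symbols (flagged in the
#'   output).
#' @param top_fraction Fraction classified as brokers/bottlenecks
#'   (default 0.05).
#' @return Data frame: `node`, `degree`, `clustering`, `betweenness`,
#'   `brokering`, `is_broker`, `is_bottleneck`, `is_seed`.
#' @export
node_metrics <- function(graph, seeds = character(), top_fraction = 0.05) {
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  cc <- clustering_coefficient(graph)
  btw <- betweenness_centrality(graph)
  brk <- brokering(graph)
  brokers <- classify_top(brk, top_fraction)
  bottlenecks <- classify_top(btw, top_fraction)
  out <- data.frame(node = nodes, degree = as.integer(deg[nodes]),
                    clustering = cc[nodes], betweenness = btw[nodes],
                    brokering = brk[nodes],
                    is_broker = nodes %in% brokers,
                    is_bottleneck = nodes %in% bottlenecks,
                    is_seed = nodes %in% seeds,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Centrality of the seed genes
#'
#' Summarizes how many seed genes fall into the broker and bottleneck
#' classes — in disease interactomes the variant-carrying genes are often
#' peripheral rather than central.
#'
#' @param metrics A node metrics table from [node_metrics()].
#' @return List: `n_seeds`, `frac_broker`, `frac_bottleneck`,
#'   `frac_central` (broker or bottleneck).
#' @export
seed_centrality_report <- function(metrics) {
  assert_columns(metrics, c("node", "is_broker", "is_bottleneck", "is_seed"),
                 "metrics")
  s <- metrics[metrics$is_seed, , drop = FALSE]
  n <- nrow(s)
  list(n_seeds = n,
       frac_broker = if (n) mean(s$is_broker) else NA_real_,
       frac_bottleneck = if (n) mean(s$is_bottleneck) else NA_real_,
       frac_central = if (n) mean(s$is_broker | s$is_bottleneck) else NA_real_)
}
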