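# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations from first principles; they never call
# the implementation they check.

# Row-by-row evaluation of the three written triage predicates.
oracle_triage <- function(records, brain_genes, min_depth = 10L) {
  hits <- list(DN_MODHIGH = integer(0), RARE_RECESSIVE = integer(0),
               VRARE_HIGH_HET = integer(0))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$gt_child == "missing" || r$gt_father == "missing" ||
        r$gt_mother == "missing") next
    depth_ok <- r$dp_child >= min_depth && r$dp_father >= min_depth &&
      r$dp_mother >= min_depth
    if (!depth_ok || !(r$gene %in% brain_genes)) next
    impact <- if (r$consequence %in% c("nonsense", "splice_site")) "HIGH"
      else if (r$consequence == "missense") "MODERATE" else "other"
    freq <- if (is.na(r$maf_max)) "novel"
      else if (r$maf_max > 0.05) "common"
      else if (r$maf_max >= 0.01) "rare" else "very_rare"
    if (r$gt_child %in% c("het", "hom_alt") && r$gt_father == "hom_ref" &&
        r$gt_mother == "hom_ref" && impact %in% c("MODERATE", "HIGH")) {
      hits$DN_MODHIGH <- c(hits$DN_MODHIGH, i)
    }
    if (r$gt_child == "hom_alt" && r$gt_father == "het" &&
        r$gt_mother == "het" && impact == "MODERATE" && freq == "rare") {
      hits$RARE_RECESSIVE <- c(hits$RARE_RECESSIVE, i)
    }
    one_het <- (r$gt_father == "het" && r$gt_mother == "hom_ref") ||
      (r$gt_mother == "het" && r$gt_father == "hom_ref")
    if (r$gt_child == "het" && one_het && impact == "HIGH" &&
        freq %in% c("very_rare", "novel")) {
      hits$VRARE_HIGH_HET <- c(hits$VRARE_HIGH_HET, i)
    }
  }
  hits
}

# Per-base set intersection of two 1-based closed intervals.
oracle_overlaps <- function(a, b, min_fraction = 0) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(FALSE)
  shared <- length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
  shared >= 1 && shared / (a$end - a$start + 1) >= min_fraction
}

# Geodesic-counting betweenness by explicit BFS and path enumeration,
# pair-normalized, endpoints excluded.
oracle_betweenness <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] > 0)) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- dist[s, u] + 1
            sigma[s, v] <- sigma[s, v] + sigma[s, u]
            nxt <- c(nxt, v)
          } else if (dist[s, v] == dist[s, u] + 1) {
            sigma[s, v] <- sigma[s, v] + sigma[s, u]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) bc <- bc * 2 / ((n - 1) * (n - 2))
  stats::setNames(bc, rownames(A))
}

# Neighbor-pair enumeration clustering coefficient.
oracle_clustering <- function(graph, node) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  nb <- which(A[node, ] > 0)
  d <- length(nb)
  if (d < 2) return(0)
  t <- 0
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) if (A[nb[i], nb[j]] > 0) t <- t + 1
  }
  t / choose(d, 2)
}

# Textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact combinatorial upper tail of the hypergeometric distribution.
oracle_hypergeom_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# First-neighborhood union by adjacency-matrix scan.
oracle_neighborhood <- function(graph, seeds) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  nodes <- rownames(A)
  mapped <- intersect(seeds, nodes)
  out <- mapped
  for (s in mapped) out <- union(out, nodes[A[s, ] > 0])
  sort(out)
}

# A small Erdos-Renyi graph with named nodes (letters + digits).
random_test_graph <- function(n, p = 0.2) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}
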