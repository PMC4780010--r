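edges_df <- function(a, b, ev) {
  data.frame(node_a = a, node_b = b, evidence_count = ev,
             stringsAsFactors = FALSE)
}

test_that("graph construction filters by evidence and merges duplicates", {
  e <- edges_df(c("A", "A", "B", "B", "C"),
                c("B", "B", "C", "B", "D"),
                c(1, 1, 1, 5, 2))
  g <- build_graph(e, min_evidence = 2)
  # A-B merged to evidence 2; B-C evidence 1 dropped; B-B self-loop dropped
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_identical(as.integer(igraph::ecount(g)), 2L)
  expect_false(igraph::are_adjacent(g, "B", "C"))
  expect_true(igraph::are_adjacent(g, "A", "B"))
  # idempotence: rebuilding from the built edges changes nothing
  el <- igraph::as_edgelist(g)
  e2 <- edges_df(el[, 1], el[, 2], igraph::E(g)$evidence)
  g2 <- build_graph(e2, min_evidence = 2)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_error(build_graph(edges_df("A", "B", 0)), "malformed")
})

test_that("seed expansion reports unmapped seeds and equals the neighborhood oracle", {
  e <- edges_df(c("A", "B", "C", "D"), c("B", "C", "D", "E"), rep(3, 4))
  g <- build_graph(e)
  ex <- expand_seeds(g, c("B", "ZZZ"))
  expect_identical(ex$unmapped_seeds, "ZZZ")
  expect_setequal(igraph::V(ex$subnetwork)$name, c("A", "B", "C"))
  set.seed(17)
  for (i in 1:20) {
    g <- random_test_graph(sample(5:25, 1), 0.25)
    seeds <- sample(igraph::V(g)$name, sample(1:4, 1))
    ex <- expand_seeds(g, seeds)
    expect_identical(sort(igraph::V(ex$subnetwork)$name),
                     oracle_neighborhood(g, seeds))
    # independence of seed order
    ex2 <- expand_seeds(g, rev(seeds))
    expect_identical(sort(igraph::V(ex$subnetwork)$name),
                     sort(igraph::V(ex2$subnetwork)$name))
  }
  # whitelist restricts added neighbors but keeps mapped seeds
  g <- build_graph(e)
  exw <- expand_seeds(g, "B", restrict_to = "C")
  expect_setequal(igraph::V(exw$subnetwork)$name, c("B", "C"))
})

test_that("clustering coefficient: triangle 1, star center 0, oracle on random graphs", {
  tri <- build_graph(edges_df(c("A", "B", "C"), c("B", "C", "A"), rep(2, 3)))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  star <- build_graph(edges_df(rep("hub", 4), paste0("leaf", 1:4), rep(2, 4)))
  expect_equal(unname(clustering_coefficient(star, "hub")), 0)
  expect_error(clustering_coefficient(star, "absent"), "absent")
  set.seed(23)
  for (i in 1:15) {
    g <- random_test_graph(sample(5:20, 1), 0.3)
    cc <- clustering_coefficient(g)
    for (v in sample(igraph::V(g)$name, 3)) {
      expect_equal(unname(cc[v]),
                   oracle_clustering(g, which(igraph::V(g)$name == v)))
    }
  }
})

test_that("betweenness: path and clique anchors, enumeration oracle on random graphs", {
  path3 <- build_graph(edges_df(c("a", "b"), c("b", "c"), rep(2, 2)))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))
  k4 <- build_graph(edges_df(c("a", "a", "a", "b", "b", "c"),
                             c("b", "c", "d", "c", "d", "d"), rep(2, 6)))
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  set.seed(29)
  for (i in 1:20) {
    g <- random_test_graph(sample(5:30, 1), 0.2)
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-10)
  }
})

test_that("brokering is in [0,1], extremal on stars and cliques, monotone in degree", {
  star <- build_graph(edges_df(rep("hub", 5), paste0("l", 1:5), rep(2, 5)))
  bk <- brokering(star)
  expect_equal(unname(bk["hub"]), 1)
  tri <- build_graph(edges_df(c("A", "B", "C"), c("B", "C", "A"), rep(2, 3)))
  expect_equal(unname(brokering(tri)), rep(0, 3))
  set.seed(37)
  for (i in 1:10) {
    g <- random_test_graph(15, 0.3)
    bk <- brokering(g)
    expect_true(all(bk >= 0 & bk <= 1))
    cc <- clustering_coefficient(g)
    expect_equal(unname(bk[cc == 1]),
                 rep(0, sum(cc == 1)))
  }
  # planted broker (star hub) outranks a clique hub of equal degree
  e <- rbind(edges_df(rep("broker", 5), paste0("s", 1:5), rep(2, 5)),
             edges_df(rep("cliquehub", 5), paste0("k", 1:5), rep(2, 5)),
             edges_df(c("k1", "k1", "k2"), c("k2", "k3", "k3"), rep(2, 3)))
  g <- build_graph(e)
  bk <- brokering(g)
  expect_gt(bk["broker"], bk["cliquehub"])
})

test_that("top-fraction classification uses the ceiling and lexicographic ties", {
  v100 <- setNames(100:1, sprintf("n%03d", 1:100))
  expect_length(classify_top(v100, 0.05), 5)
  v10 <- setNames(10:1, sprintf("n%02d", 1:10))
  expect_length(classify_top(v10, 0.05), 1)
  ties <- setNames(rep(1, 10), sprintf("x%02d", 10:1))
  expect_identical(classify_top(ties, 0.3), c("x01", "x02", "x03"))
})

test_that("seed centrality report is plain set arithmetic", {
  star <- build_graph(edges_df(rep("hub", 19), paste0("l", 1:19), rep(2, 19)))
  m <- node_metrics(star, seeds = paste0("l", 1:4), top_fraction = 0.05)
  expect_identical(sum(m$is_broker), 1L)
  rep_leaves <- seed_centrality_report(m)
  expect_identical(rep_leaves$n_seeds, 4L)
  expect_equal(rep_leaves$frac_central, 0)   # seeds are all leaves
  m_hub <- node_metrics(star, seeds = "hub", top_fraction = 0.05)
  expect_equal(seed_centrality_report(m_hub)$frac_central, 1)
  set.seed(41)
  g <- random_test_graph(40, 0.15)
  seeds <- sample(igraph::V(g)$name, 8)
  m <- node_metrics(g, seeds = seeds)
  r <- seed_centrality_report(m)
  central <- m$node[m$is_broker | m$is_bottleneck]
  expect_equal(r$frac_central, length(intersect(seeds, central)) / 8)
})
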