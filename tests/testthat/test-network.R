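test_that("network construction collapses directions and keeps attributes", {
  rules <- data.frame(
    antecedent = c("a", "b", "b"), consequent = c("b", "a", "c"),
    support = c(40, 40, 20), confidence = c(50, 80, 40),
    lift = c(1.0, 1.0, 1.3), stringsAsFactors = FALSE)
  g <- build_network(rules)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)  # duplicate a-b collapsed
  d <- degree_centrality(g)
  expect_equal(unname(d[c("a", "b", "c")]), c(1L, 2L, 1L))
  # prevalence recovered from the rule identities:
  # support(b) = 100 * 40 / 80, support(c) = 40 / 1.3
  prev <- stats::setNames(igraph::V(g)$prevalence, igraph::V(g)$name)
  expect_equal(unname(prev["b"]), 50)
  expect_equal(unname(prev["c"]), 40 / 1.3, tolerance = 1e-12)
})

test_that("a single rule gives two nodes of degree one", {
  rules <- data.frame(antecedent = "a", consequent = "b", support = 10,
                      confidence = 50, lift = 2)
  g <- build_network(rules)
  expect_equal(unname(degree_centrality(g)), c(1L, 1L))
})

test_that("degree centrality is raw counts on triangles and stars", {
  tri <- data.frame(antecedent = c("a", "a", "b"),
                    consequent = c("b", "c", "c"),
                    support = 10, confidence = 50, lift = 2)
  expect_true(all(degree_centrality(build_network(tri)) == 2))
  star <- data.frame(antecedent = "hub", consequent = sprintf("l%d", 1:5),
                     support = 10, confidence = 50, lift = 2)
  d <- degree_centrality(build_network(star))
  expect_equal(unname(d["hub"]), 5L)
  expect_true(all(d[names(d) != "hub"] == 1L))
})

test_that("handshake lemma holds on mined networks", {
  px <- generate_prescriptions(toy_planted_spec(seed = 2))
  g <- build_network(mine_pair_rules(px))
  expect_equal(sum(degree_centrality(g)), 2 * igraph::ecount(g))
})

test_that("two disjoint cliques split into two clusters with Q = 0.5", {
  cl <- function(p, w) {
    pairs <- t(combn(p, 2))
    data.frame(antecedent = pairs[, 1], consequent = pairs[, 2],
               support = w, confidence = 50, lift = 2,
               stringsAsFactors = FALSE)
  }
  rules <- rbind(cl(c("a1", "a2", "a3"), 10), cl(c("b1", "b2", "b3"), 10))
  g <- build_network(rules)
  asg <- detect_clusters(g)
  expect_equal(max(asg$membership), 2)
  expect_equal(asg$modularity, 0.5, tolerance = 1e-12)
  # agrees with igraph's own modularity for the same partition
  expect_equal(asg$modularity,
               igraph::modularity(g, asg$membership[igraph::V(g)$name],
                                  weights = igraph::E(g)$support),
               tolerance = 1e-12)
})

test_that("a complete graph stays one cluster at Q = 0", {
  pairs <- t(combn(sprintf("n%d", 1:5), 2))
  rules <- data.frame(antecedent = pairs[, 1], consequent = pairs[, 2],
                      support = 10, confidence = 50, lift = 2)
  asg <- detect_clusters(build_network(rules))
  expect_equal(max(asg$membership), 1)
  expect_equal(asg$modularity, 0, tolerance = 1e-12)
})

test_that("partition quality is never below the one-cluster baseline", {
  for (s in 1:5) {
    px <- generate_prescriptions(toy_planted_spec(seed = s, n = 1500))
    g <- build_network(top_rules(mine_pair_rules(px), 50))
    asg <- detect_clusters(g)
    expect_gte(asg$modularity, 0)
  }
})

test_that("clustering is invariant to rule order", {
  px <- generate_prescriptions(toy_planted_spec(seed = 4))
  rules <- mine_pair_rules(px)
  g1 <- build_network(rules)
  set.seed(1)
  g2 <- build_network(rules[sample.int(nrow(rules)), ])
  a1 <- detect_clusters(g1)$membership
  a2 <- detect_clusters(g2)$membership
  expect_equal(a1[sort(names(a1))], a2[sort(names(a2))])
})

test_that("greedy partition matches igraph's CNM on a clean planted graph", {
  px <- generate_prescriptions(toy_planted_spec(seed = 6))
  g <- build_network(mine_pair_rules(px))
  ours <- detect_clusters(g)$membership
  theirs <- igraph::membership(
    igraph::cluster_fast_greedy(g, weights = igraph::E(g)$support))
  expect_equal(mclust::adjustedRandIndex(
    ours[igraph::V(g)$name], as.integer(theirs)), 1)
})

test_that("isolated dyads form their own clusters", {
  px <- generate_prescriptions(toy_planted_spec(seed = 8, n = 3000))
  g <- build_network(top_rules(mine_pair_rules(px), 100))
  asg <- detect_clusters(g)
  expect_true(all(c("C1", "C2") %in% names(asg$membership)))
  k <- asg$membership["C1"]
  expect_equal(asg$membership[["C2"]], k[[1]])
  expect_equal(sort(names(asg$membership)[asg$membership == k[[1]]]),
               c("C1", "C2"))
})

test_that("core selection maximizes degree, then prevalence, then name", {
  # two nodes with equal degree, prevalence 20 vs 10 -> the 20 one
  rules <- data.frame(antecedent = c("a", "b"), consequent = c("x", "x"),
                      support = c(2, 2), confidence = c(10, 20),
                      lift = c(1.5, 1.5), stringsAsFactors = FALSE)
  g <- build_network(rules)  # prevalence: a = 20, b = 10, x from b-rule
  asg <- detect_clusters(g)
  core <- identify_core(g, asg)
  memb <- asg$membership
  expect_equal(unname(core[as.character(memb[["x"]])]), "x")  # degree 2
  # strict dominance case
  prev <- stats::setNames(igraph::V(g)$prevalence, igraph::V(g)$name)
  expect_gt(prev[["a"]], prev[["b"]])
})

test_that("cluster tables flag exactly one core per cluster", {
  px <- generate_prescriptions(toy_planted_spec(seed = 10, n = 3000))
  g <- build_network(top_rules(mine_pair_rules(px), 100))
  asg <- detect_clusters(g)
  ct <- cluster_table(g, asg)
  per <- tapply(ct$is_core, ct$cluster, sum)
  expect_true(all(per == 1))
  expect_setequal(ct$herb, names(asg$membership))
})
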