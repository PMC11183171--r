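test_that("summary metrics match hand computations on canonical graphs", {
  k3 <- signed_network(toy_nodes(c("a", "b", "c")),
                       toy_edges(c("a", "a", "b"), c("b", "c", "c")))
  m <- summary_metrics(k3)
  expect_equal(m$average_degree, 2)
  expect_equal(m$density, 1)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$diameter, 1)

  p4 <- signed_network(toy_nodes(paste0("n", 1:4)),
                       toy_edges(c("n1", "n2", "n3"), c("n2", "n3", "n4")))
  mp <- summary_metrics(p4)
  expect_equal(mp$average_path_length, 10 / 6, tolerance = 1e-12)
  expect_equal(mp$diameter, 3)
  expect_equal(mp$clustering_coefficient, 0)

  expect_error(summary_metrics(signed_network(toy_nodes(character()), NULL)),
               "empty")
})

test_that("average degree and density identities hold for inferred networks", {
  tr <- simulate_ground_truth(c(bacteria = 12), edge_density = 0.1, seed = 8)
  tab <- simulate_abundances(tr, n_samples = 60, selection_strength = 0, seed = 8)
  net <- stars_select(tab$bacteria, n_subsamples = 10, seed = 8)
  m <- summary_metrics(net)
  expect_equal(m$average_degree, 2 * m$edge_count / m$node_count, tolerance = 1e-9)
  expect_equal(m$density,
               2 * m$edge_count / (m$node_count * (m$node_count - 1)),
               tolerance = 1e-9)
  expect_gte(m$clustering_coefficient, 0)
  expect_lte(m$clustering_coefficient, 1)
})

test_that("module detection separates components and maximizes modularity on the bridge toy", {
  tri2 <- signed_network(
    toy_nodes(c("a", "b", "c", "x", "y", "z")),
    toy_edges(c("a", "a", "b", "x", "x", "y"), c("b", "c", "c", "y", "z", "z")))
  mem <- detect_modules(tri2)
  expect_equal(length(unique(mem)), 2)
  expect_equal(length(unique(mem[c("a", "b", "c")])), 1)
  expect_equal(length(unique(mem[c("x", "y", "z")])), 1)
  expect_identical(mem, detect_modules(tri2))

  net <- two_cliques_bridge()
  mem2 <- detect_modules(net)
  g <- as_igraph(net)
  ids <- net$nodes$id
  # exhaustive search over all partitions of the 8 nodes
  best <- max(vapply(all_partitions(8), function(p)
    igraph::modularity(g, setNames(p, ids)[ids]), numeric(1)))
  got <- igraph::modularity(g, mem2[ids])
  expect_equal(got, best, tolerance = 1e-12)
  # the optimum splits at the bridge
  expect_equal(length(unique(mem2[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(mem2[paste0("b", 1:4)])), 1)
  expect_false(mem2["a1"] == mem2["b1"])

  # edgeless network: every node its own module
  iso <- signed_network(toy_nodes(c("u", "v")), NULL)
  expect_equal(unname(detect_modules(iso)), c(1L, 2L))
  expect_equal(summary_metrics(iso)$modularity, 0)
})

test_that("Zi-Pi follows the within/among-module connectivity definitions and thresholds", {
  net <- two_cliques_bridge()
  roles <- zi_pi(net)
  # bridge endpoint: degree 4, three edges within its module, one across
  a4 <- roles[roles$taxon == "a4", ]
  expect_equal(a4$P, 1 - (3 / 4)^2 - (1 / 4)^2)
  # interior clique node: all edges within the module
  a1 <- roles[roles$taxon == "a1", ]
  expect_equal(a1$P, 0)

  # one module: every P is 0 and nobody is a connector
  k3 <- signed_network(toy_nodes(c("a", "b", "c")),
                       toy_edges(c("a", "a", "b"), c("b", "c", "c")))
  r3 <- zi_pi(k3, modules = setNames(rep(1L, 3), c("a", "b", "c")))
  expect_true(all(r3$P == 0))
  expect_false(any(r3$role == "connector"))
  expect_true(all(r3$Z == 0))   # equal within-degrees: sd-zero rule

  # the role map is a pure function of (Z, P) with the quoted thresholds
  role_rule <- function(Z, P) {
    ifelse(Z > 2.5 & P > 0.62, "network_hub",
    ifelse(Z > 2.5, "module_hub",
    ifelse(P > 0.62, "connector", "peripheral")))
  }
  tr <- simulate_ground_truth(c(bacteria = 40), edge_density = 0.08, seed = 9)
  roles2 <- zi_pi(tr$true_network)
  expect_identical(roles2$role, role_rule(roles2$Z, roles2$P))
  m <- length(unique(roles2$module))
  expect_true(all(roles2$P >= 0 & roles2$P <= 1 - 1 / m + 1e-12))
})

test_that("hub centrality matches the principal-eigenvector solution and flags keystones", {
  star <- star_network(3)
  sc <- hub_centrality(star)
  expect_equal(unname(sc["hub"]), 1)
  expect_equal(unname(sc[paste0("l", 1:3)]), rep(1 / sqrt(3), 3),
               tolerance = 1e-9)
  expect_identical(keystones(sc), "hub")

  k4 <- signed_network(toy_nodes(paste0("v", 1:4)),
                       {p <- t(combn(paste0("v", 1:4), 2)); toy_edges(p[, 1], p[, 2])})
  expect_true(all(abs(hub_centrality(k4) - 1) < 1e-9))
  expect_equal(length(keystones(hub_centrality(k4))), 4)

  empty <- signed_network(toy_nodes(c("a", "b")), NULL)
  expect_true(all(hub_centrality(empty) == 0))
  expect_equal(length(keystones(hub_centrality(empty))), 0)

  # relabeling permutes but does not change the score multiset
  net <- two_cliques_bridge()
  sc1 <- sort(unname(hub_centrality(net)))
  nodes2 <- net$nodes[sample(nrow(net$nodes)), ]
  net2 <- signed_network(nodes2, net$edges)
  expect_equal(sc1, sort(unname(hub_centrality(net2))), tolerance = 1e-12)
})

test_that("sample subnetworks are induced subgraphs with brute-force-checked metrics", {
  net <- signed_network(
    toy_nodes(paste0("t", 1:5)),
    toy_edges(c("t1", "t2", "t3", "t3", "t4"),
              c("t2", "t3", "t4", "t5", "t5")))
  all_ab <- setNames(rep(1, 5), paste0("t", 1:5))
  expect_identical(sample_subnetwork(net, all_ab)$edges, net$edges)

  # drop the cut-ish vertex t3: brute-force induced edge set
  ab <- all_ab; ab["t3"] <- 0
  sub <- sample_subnetwork(net, ab)
  manual <- net$edges[net$edges$from != "t3" & net$edges$to != "t3", ]
  expect_identical(sub$edges$from, manual$from)
  expect_equal(nrow(sub$edges), 2)

  # two adjacent taxa: one edge, density 1
  two <- sample_subnetwork(net, c(t1 = 1, t2 = 3))
  m <- summary_metrics(two)
  expect_equal(m$edge_count, 1)
  expect_equal(m$density, 1)

  # per-sample table, including an empty sample row
  counts <- rbind(S1 = c(1, 1, 1, 1, 1), S2 = c(1, 2, 0, 1, 1), S3 = c(0, 0, 0, 0, 0))
  colnames(counts) <- paste0("t", 1:5)
  counts <- counts + 0
  counts["S3", ] <- 0
  tab <- suppressWarnings(toy_abund(counts))
  sm <- subnetwork_metrics(net, tab)
  expect_equal(nrow(sm), 3)
  expect_equal(sm$node_count[3], 0)
  expect_equal(sm$edge_count[3], 0)
})

test_that("biotic association scores follow the relative-abundance product rule", {
  net <- signed_network(
    data.frame(id = c("A", "B", "C"),
               kingdom = c("bacteria", "bacteria", "am_fungi")),
    data.frame(from = c("A", "B"), to = c("B", "C"),
               sign = c(1L, -1L), weight = c(1, 1)))
  counts <- rbind(S1 = c(A = 5, B = 3, C = 2))
  tab <- toy_abund(counts)
  tab$kingdom[] <- c("bacteria", "bacteria", "am_fungi")
  sc <- biotic_association_scores(tab, net)
  expect_equal(sc$ppa, 0.5 * 0.3)
  expect_equal(sc$pna, 0.3 * 0.2)

  # absent shared endpoint: both zero
  counts2 <- rbind(S1 = c(A = 5, B = 0, C = 2))
  sc2 <- biotic_association_scores(toy_abund(counts2), net)
  expect_equal(sc2$ppa, 0)
  expect_equal(sc2$pna, 0)

  # kingdom-pair scope keeps only cross-kingdom edges
  sc3 <- biotic_association_scores(tab, net, scope = c("bacteria", "am_fungi"))
  expect_equal(sc3$ppa, 0)
  expect_equal(sc3$pna, 0.3 * 0.2)
  expect_equal(attr(sc3, "scope"), "am_fungi-bacteria")

  # scope with no edges: warning and zeros
  expect_warning(sc4 <- biotic_association_scores(tab, net,
                                                  scope = c("rhizobia", "am_fungi")),
                 "no edges")
  expect_true(all(sc4$ppa == 0 & sc4$pna == 0))

  # invariance to a global rescaling of one sample's absolute abundances
  counts3 <- rbind(S1 = c(A = 5, B = 3, C = 2), S2 = c(A = 50, B = 30, C = 20))
  sc5 <- biotic_association_scores(toy_abund(counts3), net)
  expect_equal(sc5$ppa[1], sc5$ppa[2])
  expect_equal(sc5$pna[1], sc5$pna[2])
})
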