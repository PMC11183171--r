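test_that("generated phylogenies are valid rooted binary trees, deterministic by seed", {
  expect_error(generate_phylogeny(1, seed = 1), "n_tips")

  t2 <- generate_phylogeny(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)

  ta <- generate_phylogeny(50, seed = 7)
  tb <- generate_phylogeny(50, seed = 7)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  expect_true(all(ta$edge.length > 0))
  expect_true(sum(ape::node.depth.edgelength(ta)[seq_len(50)]) > 0)
})

test_that("pairwise tip distances satisfy the four-point condition", {
  tree <- generate_phylogeny(12, seed = 7)
  D <- cophenetic(tree)
  quartets <- combn(12, 4)
  for (q in seq_len(ncol(quartets))) {
    v <- quartets[, q]
    s <- sort(c(D[v[1], v[2]] + D[v[3], v[4]],
                D[v[1], v[3]] + D[v[2], v[4]],
                D[v[1], v[4]] + D[v[2], v[3]]))
    expect_lt(s[3] - s[2], 1e-8)   # the two largest sums are equal
  }
})

test_that("planted precision matrices are positive definite with the promised sign structure", {
  tr <- simulate_ground_truth(c(bacteria = 10), edge_density = 0.1, seed = 3)
  ev <- eigen(tr$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(isSymmetric(tr$precision))
  expect_true(all(diag(tr$precision) > 0))

  # edge sign equals the sign of the implied partial correlation
  om <- tr$precision
  for (i in seq_len(nrow(tr$true_network$edges))) {
    e <- tr$true_network$edges[i, ]
    expect_equal(e$sign, sign(-om[e$from, e$to]))
  }
  # edge support is exactly the off-diagonal support
  expect_equal(nrow(tr$true_network$edges), sum(om[upper.tri(om)] != 0))

  # forced positive signs
  trp <- simulate_ground_truth(c(bacteria = 12), edge_density = 0.15,
                               positive_fraction = 1, seed = 3)
  expect_true(all(trp$true_network$edges$sign == 1))

  # vanishing density: diagonal precision, empty network
  tr0 <- simulate_ground_truth(c(bacteria = 10), edge_density = 1e-9, seed = 3)
  expect_equal(nrow(tr0$true_network$edges), 0)
  expect_true(all(tr0$precision[upper.tri(tr0$precision)] == 0))

  expect_error(simulate_ground_truth(c(bacteria = 10), edge_density = 0.5),
               "edge_density")
})

test_that("abundance simulation is deterministic and respects the slope design", {
  tr <- simulate_ground_truth(seed = 2)
  a1 <- simulate_abundances(tr, seed = 11)
  a2 <- simulate_abundances(tr, seed = 11)
  expect_identical(a1$bacteria$counts, a2$bacteria$counts)
  expect_identical(names(a1), c("bacteria", "rhizobia", "am_fungi"))
  expect_equal(nrow(a1$bacteria$counts), 18)
  expect_equal(as.integer(table(a1$bacteria$metadata$position)), rep(6L, 3))
  expect_true(all(a1$bacteria$counts >= 0))
})

test_that("selection scenario produces within-position compositional coherence", {
  trees_ids <- split(paste0("B", sprintf("%03d", 1:60)), rep("bacteria", 60))
  st <- simulate_study(scenario = "selection", seed = 11)
  d <- bray_curtis(st$tables$bacteria)
  pos <- st$tables$bacteria$metadata$position
  ut <- which(upper.tri(d), arr.ind = TRUE)
  same <- pos[ut[, 1]] == pos[ut[, 2]]
  vals <- d[upper.tri(d)]
  expect_lt(mean(vals[same]), mean(vals[!same]))
})

test_that("a strong positive planted edge shows up as positive CLR correlation", {
  tr <- simulate_ground_truth(c(bacteria = 10), edge_density = 0.1,
                              positive_fraction = 1, seed = 5)
  tab <- simulate_abundances(tr, n_samples = 300, selection_strength = 0,
                             abund_sd = 1, seed = 5)
  clr <- clr_transform(tab$bacteria)
  e <- tr$true_network$edges[which.max(tr$true_network$edges$weight), ]
  expect_gt(cor(clr[, e$from], clr[, e$to]), 0)
})

test_that("degenerate limit: no latent noise and no position effects gives identical composition", {
  tr <- simulate_ground_truth(c(bacteria = 8), edge_density = 0.05, seed = 4)
  tab <- simulate_abundances(tr, latent_sd = 0, selection_strength = 0,
                             depth = 1e7, depth_cv = 0, seed = 4)
  rel <- tab$bacteria$counts / rowSums(tab$bacteria$counts)
  spread <- apply(rel, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 0.005)   # only Poisson noise remains at high depth
})

test_that("simulated functions have the fixed 12-function layout and planted effects", {
  st <- simulate_study(seed = 1)
  expect_s3_class(st$functions, "function_table")
  expect_equal(dim(unclass(st$functions)), c(18, 12))
  expect_setequal(colnames(st$functions), names(service_groups()))

  # noiseless limit with a single nonzero coefficient: perfect rank agreement
  tr <- st$truth
  tr$effect_coefficients <- c(am_richness = 1, ppa = 0, pna = 0)
  fn <- simulate_functions(st$tables, tr, noise_sd = 0, seed = 9)
  am_rich <- rowSums(st$tables$am_fungi$counts > 0)
  expect_equal(suppressWarnings(cor(fn[, "DOC"], am_rich, method = "spearman")), 1)

  # determinism
  fn2 <- simulate_functions(st$tables, tr, noise_sd = 0, seed = 9)
  expect_identical(unclass(fn), unclass(fn2))
})
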