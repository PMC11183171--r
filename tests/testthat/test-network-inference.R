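test_that("ASV filtering applies strict prevalence and mean relative-abundance rules", {
  # 18 samples: present in 5 passes (5 > 4.5), present in 4 fails
  x <- matrix(0, 18, 3, dimnames = list(sprintf("S%02d", 1:18), c("keep", "drop", "base")))
  x[1:5, "keep"] <- 10
  x[1:4, "drop"] <- 10
  x[, "base"] <- 100
  tab <- toy_abund(x)
  f <- filter_asvs(tab)
  expect_setequal(colnames(f$counts), c("keep", "base"))

  # all-zero taxon is removed
  x2 <- cbind(x, zero = 0)
  expect_false("zero" %in% colnames(filter_asvs(toy_abund(x2))$counts))

  # mean relative abundance 4e-6 < 1e-5 is removed despite full prevalence
  y <- matrix(1e6, 4, 2, dimnames = list(paste0("S", 1:4), c("big", "tiny")))
  y[, "tiny"] <- 4 + .Machine$double.eps
  ft <- filter_asvs(toy_abund(y))
  expect_setequal(colnames(ft$counts), "big")

  # every taxon too rare: empty-result error
  z <- diag(4)
  dimnames(z) <- list(paste0("S", 1:4), paste0("t", 1:4))
  expect_error(filter_asvs(toy_abund(z)), "all taxa")
})

test_that("kingdom tables merge by sample id with disjoint taxa", {
  set.seed(6)
  a <- toy_abund(matrix(rpois(36, 5), 6, 6,
                        dimnames = list(paste0("S", 1:6), paste0("B", 1:6))))
  b <- toy_abund(matrix(rpois(18, 5), 6, 3,
                        dimnames = list(paste0("S", 1:6), paste0("F", 1:3))),
                 kingdom = "am_fungi")
  m <- merge_kingdom_tables(list(a, b))
  expect_equal(ncol(m$counts), 9)
  expect_equal(unname(m$kingdom[c("B1", "F1")]), c("bacteria", "am_fungi"))

  # sample order is aligned by id
  b_rev <- abund_table(b$counts[6:1, ], b$kingdom, b$metadata)
  m2 <- merge_kingdom_tables(list(a, b_rev))
  expect_identical(m$counts, m2$counts)

  expect_error(merge_kingdom_tables(list(a, a)), "duplicate taxon")
  expect_identical(merge_kingdom_tables(list(a)), a)
})

test_that("CLR transform closes, centers, and is scale invariant", {
  expect_equal(as.numeric(clr_transform(rbind(c(1, 1, 1, 1)))), rep(0, 4))
  expect_equal(as.numeric(clr_transform(rbind(c(2, 8)))),
               c(-log(2), log(2)), tolerance = 1e-12)

  set.seed(7)
  x <- matrix(rpois(60, 20), 6, 10)
  clr <- clr_transform(x)
  expect_true(all(abs(rowSums(clr)) < 1e-9))

  # multiplying one sample's abundances by a constant changes nothing
  x2 <- x + 1   # avoid zeros so no pseudocount interferes
  x3 <- x2; x3[2, ] <- x3[2, ] * 1000
  expect_equal(clr_transform(x2), clr_transform(x3), tolerance = 1e-12)

  expect_error(clr_transform(rbind(c(0, 0, 0))), "zero total")
})

test_that("neighborhood selection recovers a latent Gaussian chain and edge signs", {
  omega <- diag(3)
  omega[1, 2] <- omega[2, 1] <- -0.4
  omega[2, 3] <- omega[3, 2] <- -0.4
  x <- latent_sample(omega, 500, seed = 11)
  e <- neighborhood_fit(x, lambda = 0.05)
  expect_setequal(edge_key(e), c("t1 t2", "t2 t3"))
  # partial-correlation oracle agrees on the support
  pc <- -stats::cov2cor(solve(cov(x)))
  expect_true(all(abs(pc["t1", "t3"]) < abs(pc["t1", "t2"])))

  # full shrinkage: no edges at or above lambda_max
  expect_equal(nrow(neighborhood_fit(x, lambda_max(x))), 0)

  # strongly negative partial correlation gives a negative edge
  om2 <- diag(2); om2[1, 2] <- om2[2, 1] <- 0.45
  y <- latent_sample(om2, 400, seed = 12)
  e2 <- neighborhood_fit(y, lambda = 0.05)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$sign, -1L)

  expect_error(neighborhood_fit(matrix(0, 6, 3), 0.1), "zero variance")
  expect_error(neighborhood_fit(matrix(c(NA, rnorm(17)), 6, 3), 0.1), "non-finite")
})

test_that("StARS selects a stable network close to the planted truth and records provenance", {
  tr <- simulate_ground_truth(c(bacteria = 10), edge_density = 0.1, seed = 5)
  tab <- simulate_abundances(tr, n_samples = 300, selection_strength = 0,
                             abund_sd = 1, seed = 5)
  net <- stars_select(tab$bacteria, rule = "and", seed = 5)
  tk <- edge_key(tr$true_network$edges)
  ek <- edge_key(net$edges)
  hamming <- sum(!ek %in% tk) + sum(!tk %in% ek)
  expect_lte(hamming, 2)
  expect_equal(nrow(net$nodes), 10)
  expect_true(is.finite(net$provenance$selected_lambda))
  expect_equal(length(net$provenance$instability),
               length(net$provenance$lambda_path))
  expect_true(all(diff(net$provenance$monotonized) >= 0))

  # deterministic given the seed
  net2 <- stars_select(tab$bacteria, rule = "and", seed = 5)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$provenance$selected_lambda, net2$provenance$selected_lambda)

  # impossible threshold falls back to the largest lambda with a warning
  expect_warning(
    net3 <- stars_select(tab$bacteria, instability_threshold = 0,
                         n_subsamples = 5, seed = 5),
    "largest lambda")
  expect_equal(net3$provenance$selected_index, 1L)
  expect_false(is.null(net3$provenance$warning))
})

test_that("the inferred edge set is invariant to taxon ordering", {
  tr <- simulate_ground_truth(c(bacteria = 8), edge_density = 0.15, seed = 6)
  tab <- simulate_abundances(tr, n_samples = 120, selection_strength = 0,
                             abund_sd = 1, seed = 6)
  clr <- clr_transform(tab$bacteria)
  perm <- sample(ncol(clr))
  path <- default_lambda_path(clr, length = 10)
  e1 <- neighborhood_fit(clr, path[6])
  e2 <- neighborhood_fit(clr[, perm], path[6])
  expect_setequal(edge_key(e1), edge_key(e2))
})
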