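test_that("betaMNTD matches hand values and the brute-force double-loop oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(beta_mntd(c(A = 1), c(A = 1), tree), 0)
  expect_equal(beta_mntd(c(A = 1), c(C = 1), tree), 4)

  set.seed(10)
  tree2 <- generate_phylogeny(12, seed = 21)
  D <- cophenetic(tree2)
  comm <- matrix(rpois(6 * 12, 3), 6, 12,
                 dimnames = list(paste0("s", 1:6), tree2$tip.label))
  comm[comm == 0 & row(comm) == 1] <- 1   # keep sample 1 non-empty
  for (a in 1:5) for (b in (a + 1):6) {
    if (all(comm[a, ] == 0) || all(comm[b, ] == 0)) next
    expect_equal(beta_mntd(comm[a, ], comm[b, ], tree2),
                 unname(bmntd_oracle(comm[a, ], comm[b, ], D)),
                 tolerance = 1e-12)
  }
  # matrix form agrees with the scalar form
  keep <- rowSums(comm) > 0
  M <- beta_mntd_matrix(comm[keep, ], tree2)
  expect_equal(M[1, 2], beta_mntd(comm[1, ], comm[2, ], tree2), tolerance = 1e-12)
  expect_true(isSymmetric(M))

  expect_error(beta_mntd(c(A = 0), c(C = 1), tree), "empty")
})

test_that("betaMNTD agrees with the independent comdistnt implementation", {
  skip_if_not_installed("picante")
  set.seed(11)
  tree <- generate_phylogeny(15, seed = 31)
  comm <- matrix(rpois(8 * 15, 2), 8, 15,
                 dimnames = list(paste0("s", 1:8), tree$tip.label))
  comm[rowSums(comm) == 0, 1] <- 1
  ours <- beta_mntd_matrix(comm, tree)
  ref <- as.matrix(picante::comdistnt(comm, cophenetic(tree),
                                      abundance.weighted = TRUE))
  expect_equal(unname(ours), unname(ref[rownames(comm), rownames(comm)]),
               tolerance = 1e-9)
})

test_that("betaNTI matches an independent shuffle-loop reimplementation", {
  tree <- generate_phylogeny(8, seed = 41)
  set.seed(12)
  comm <- matrix(rpois(4 * 8, 2) + rbinom(32, 1, 0.3), 4, 8,
                 dimnames = list(paste0("s", 1:4), tree$tip.label))
  comm[rowSums(comm) == 0, 1] <- 1
  res <- suppressWarnings(beta_nti(comm, tree, n_null = 100, seed = 13))

  # independent reimplementation: same documented RNG contract, pure-R betaMNTD
  D <- cophenetic(tree)[colnames(comm), colnames(comm)]
  obs <- outer(1:4, 1:4, Vectorize(function(a, b)
    if (a == b) 0 else unname(bmntd_oracle(comm[a, ], comm[b, ], D))))
  nulls <- array(NA_real_, c(4, 4, 100))
  set.seed(13)
  for (k in 1:100) {
    perm <- sample.int(8)
    Dp <- D[perm, perm]
    dimnames(Dp) <- dimnames(D)
    nulls[, , k] <- outer(1:4, 1:4, Vectorize(function(a, b)
      if (a == b) 0 else unname(bmntd_oracle(comm[a, ], comm[b, ], Dp))))
  }
  mu <- apply(nulls, c(1, 2), mean)
  sdv <- apply(nulls, c(1, 2), sd)
  want <- (obs - mu) / sdv
  for (a in 1:3) for (b in (a + 1):4) {
    if (is.na(res$bnti[a, b])) expect_lt(sdv[a, b], 1e-10) else
      expect_equal(res$bnti[a, b], want[a, b], tolerance = 1e-12)
  }
})

test_that("betaNTI degenerate pairs are reported missing and branch scaling cancels", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  comm <- rbind(s1 = c(A = 2, B = 1, C = 0, D = 0),
                s2 = c(A = 2, B = 1, C = 0, D = 0))
  # identical communities: observed and all nulls coincide -> missing value
  expect_warning(res <- beta_nti(comm, tree, n_null = 100, seed = 1),
                 "undefined")
  expect_true(is.na(res$bnti[1, 2]))

  tree2 <- generate_phylogeny(10, seed = 51)
  set.seed(14)
  comm2 <- matrix(rpois(5 * 10, 2), 5, 10,
                  dimnames = list(paste0("s", 1:5), tree2$tip.label))
  comm2[rowSums(comm2) == 0, 1] <- 1
  tree3 <- tree2
  tree3$edge.length <- tree3$edge.length * 7.5
  r1 <- suppressWarnings(beta_nti(comm2, tree2, n_null = 100, seed = 2))
  r2 <- suppressWarnings(beta_nti(comm2, tree3, n_null = 100, seed = 2))
  expect_equal(r1$bnti, r2$bnti, tolerance = 1e-9)
})

test_that("RC_Bray is bounded, deterministic, and extreme for identical pairs", {
  set.seed(15)
  comm <- matrix(rpois(6 * 20, 1.5), 6, 20)
  comm[rowSums(comm) == 0, 1] <- 1
  comm[2, ] <- comm[1, ]   # identical pair
  rc <- rc_bray(comm, n_null = 200, seed = 3)
  vals <- rc[upper.tri(rc)]
  expect_true(all(vals >= -1 & vals <= 1))
  expect_lt(rc[1, 2], -0.9)
  expect_identical(rc, rc_bray(comm, n_null = 200, seed = 3))
  expect_error(rc_bray(rbind(c(0, 0), c(1, 1)), n_null = 100), "zero total")
})

test_that("assembly classification applies the QPEN threshold rules exactly", {
  lab <- function(b, r) {
    m <- matrix(c(0, b, b, 0), 2)
    rcm <- matrix(c(0, r, r, 0), 2)
    classify_assembly(m, rcm)$pairs$process
  }
  expect_equal(lab(3, 0), "variable_selection")
  expect_equal(lab(-3, 0), "homogeneous_selection")
  expect_equal(lab(0, 0.99), "dispersal_limitation")
  expect_equal(lab(0, -0.99), "homogenizing_dispersal")
  expect_equal(lab(0, 0), "drift")
  # boundary equalities fall to the stochastic / drift side
  expect_equal(lab(2, 0.99), "dispersal_limitation")
  expect_equal(lab(-2, 0), "drift")
  expect_equal(lab(0, 0.95), "drift")
  expect_equal(lab(0, -0.95), "drift")

  # fractions sum to one; missing betaNTI pairs are excluded and counted
  b <- matrix(rnorm(25, sd = 3), 5, 5); b <- (b + t(b)) / 2
  r <- matrix(runif(25, -1, 1), 5, 5); r <- (r + t(r)) / 2
  b[1, 2] <- b[2, 1] <- NA
  cl <- classify_assembly(b, r)
  expect_equal(sum(cl$fractions), 1, tolerance = 1e-12)
  expect_equal(cl$n_excluded, 1)
  expect_equal(cl$n_pairs, 10)
})
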