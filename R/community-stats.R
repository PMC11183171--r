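#' Bray-Curtis distance matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa.
#'
#' @param table an [abund_table] or non-negative samples x taxa matrix with
#'   no all-zero samples.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  x <- if (inherits(table, "abund_table")) table$counts else as.matrix(table)
  if (any(!is.finite(x)) || any(x < 0)) stop("abundances must be non-negative")
  if (any(rowSums(x) == 0)) stop("sample(s) with zero total abundance")
  as.matrix(vegan::vegdist(x, method = "bray"))
}

perm_test_result <- function(statistic, p_value, n_permutations, seed, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   n_permutations = n_permutations, seed = seed),
              list(...)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

align_dist <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  d
}

#' Mantel test between two distance matrices
#'
#' Correlation of the lower triangles (Spearman by default, the convention
#' of the driver screens here), with significance from simultaneous
#' row/column permutation of one matrix.  The p-value uses the
#' `(1 + exceedances) / (1 + n_permutations)` estimator and is never 0.
#'
#' @param dist_a,dist_b distance matrices over the same samples (>= 4).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return A `perm_test` with the Mantel r as statistic.
#' @export
mantel_test <- function(dist_a, dist_b, method = c("spearman", "pearson"),
                        n_permutations = 999, seed = 1) {
  method <- match.arg(method)
  a <- align_dist(dist_a); b <- align_dist(dist_b)
  if (!all(dim(a) == dim(b))) stop("distance matrices must match")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("sample sets do not match")
    b <- b[rownames(a), rownames(a)]
  }
  if (nrow(a) < 4) stop("need at least 4 samples for a Mantel test")
  set.seed(seed)
  mt <- vegan::mantel(as.dist(a), as.dist(b), method = method,
                      permutations = n_permutations)
  perm_test_result(unname(mt$statistic), mt$signif, n_permutations, seed,
                   method = method)
}

#' PERMANOVA (permutational multivariate ANOVA) on a distance matrix
#'
#' Pseudo-F from the Gower-centered partition of total and within-group
#' sums of squared distances, with free permutation of group labels.
#'
#' @param dist distance matrix.
#' @param grouping factor (or vector) of group levels, aligned with the
#'   distance matrix (by names if named); >= 2 levels, each with >= 2
#'   samples.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return A `perm_test` with fields `statistic` (pseudo-F), `R2`,
#'   `p_value`.
#' @export
permanova <- function(dist, grouping, n_permutations = 999, seed = 1) {
  d <- align_dist(dist)
  g <- align_grouping(grouping, d)
  tab <- table(g)
  if (length(tab) < 2) stop("grouping must have at least 2 levels")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  df <- data.frame(g = g)
  set.seed(seed)
  res <- vegan::adonis2(as.dist(d) ~ g, data = df,
                        permutations = n_permutations)
  perm_test_result(res$F[1], res$`Pr(>F)`[1], n_permutations, seed,
                   R2 = res$R2[1])
}

align_grouping <- function(grouping, d) {
  if (!is.null(names(grouping)) && !is.null(rownames(d))) {
    if (!setequal(names(grouping), rownames(d)))
      stop("grouping names do not match the distance matrix")
    grouping <- grouping[rownames(d)]
  }
  if (length(grouping) != nrow(d))
    stop("grouping length does not match the distance matrix")
  factor(grouping)
}

#' Constrained principal coordinate analysis (CPCoA)
#'
#' Principal-coordinate embedding of the distances (Lingoes correction
#' applied when negative eigenvalues arise) followed by redundancy analysis
#' on group indicator variables.  Reports the fraction of total variance
#' constrained by the grouping and a permutation p-value.
#'
#' @inheritParams permanova
#' @param n_axes number of constrained axis score columns to return.
#' @return List with `scores` (centered site scores on the constrained
#'   axes), `constrained_fraction`, `p_value`, `eigenvalues`,
#'   `n_permutations`, `seed`.
#' @export
constrained_pcoa <- function(dist, grouping, n_permutations = 999, seed = 1,
                             n_axes = 2) {
  d <- align_dist(dist)
  g <- align_grouping(grouping, d)
  tab <- table(g)
  if (length(tab) < 2) stop("grouping must have at least 2 levels")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  df <- data.frame(g = g)
  cap <- vegan::capscale(as.dist(d) ~ g, data = df, add = "lingoes")
  frac <- cap$CCA$tot.chi / cap$tot.chi
  set.seed(seed)
  an <- stats::anova(cap, permutations = n_permutations)
  k <- min(n_axes, ncol(cap$CCA$u))
  sc <- vegan::scores(cap, display = "sites", choices = seq_len(k),
                      scaling = 1)
  list(scores = sc, constrained_fraction = unname(frac),
       p_value = an$`Pr(>F)`[1],
       eigenvalues = cap$CCA$eig,
       n_permutations = n_permutations, seed = seed)
}

#' Variation partitioning between two predictor sets (distance-based RDA)
#'
#' Partitions the variance of a response distance matrix between predictor
#' sets A and B using adjusted R-squared from distance-based redundancy
#' analysis: `unique_a = adjR2(A+B) - adjR2(B)`, `shared = adjR2(A) +
#' adjR2(B) - adjR2(A+B)`, `residual = 1 - adjR2(A+B)`.  Fractions may be
#' slightly negative (an adjusted-R2 artifact) and are reported unclipped.
#'
#' @param response_dist distance matrix.
#' @param predictors_a,predictors_b numeric sample x k matrices (B may be
#'   `NULL` for the single-set reduction); full column rank after
#'   centering.
#' @param n_permutations permutations for the full-model test.
#' @param seed integer RNG seed.
#' @return List with `fractions` (`unique_a`, `shared`, `unique_b`,
#'   `residual`), `adj_r2_full`, `p_value`, `n_permutations`, `seed`.
#' @export
variation_partitioning <- function(response_dist, predictors_a,
                                   predictors_b = NULL,
                                   n_permutations = 999, seed = 1) {
  d <- align_dist(response_dist)
  A <- as.matrix(predictors_a)
  if (is.null(colnames(A))) colnames(A) <- paste0("a", seq_len(ncol(A)))
  B <- if (!is.null(predictors_b) && NCOL(predictors_b) > 0)
    as.matrix(predictors_b) else NULL
  if (!is.null(B) && is.null(colnames(B)))
    colnames(B) <- paste0("b", seq_len(ncol(B)))
  X <- if (is.null(B)) A else cbind(A, B)
  if (nrow(X) != nrow(d)) stop("predictors do not match the distance matrix")
  if (nrow(d) <= ncol(X) + 1)
    stop("need more samples than predictors plus one")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrX$pivot[seq(qrX$rank + 1, ncol(Xc))]]
    stop("collinear predictor column(s): ", paste(bad, collapse = ", "))
  }
  dd <- as.dist(d)
  set.seed(seed)
  full <- vegan::dbrda(dd ~ ., data = as.data.frame(X))
  p_full <- stats::anova(full, permutations = n_permutations)$`Pr(>F)`[1]
  adj_full <- vegan::RsquareAdj(full)$adj.r.squared
  if (is.null(B)) {
    fractions <- c(unique_a = adj_full, shared = 0, unique_b = 0,
                   residual = 1 - adj_full)
  } else {
    vp <- vegan::varpart(dd, A, B)
    f <- vp$part$indfract$Adj.R.square
    fractions <- c(unique_a = f[1], shared = f[2], unique_b = f[3],
                   residual = f[4])
  }
  list(fractions = fractions, adj_r2_full = adj_full, p_value = p_full,
       n_permutations = n_permutations, seed = seed)
}
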