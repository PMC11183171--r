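#' Prevalence / relative-abundance filter for dominant ASVs
#'
#' Keeps taxa present (abundance > 0) in strictly more than
#' `min_prevalence` of the samples AND with mean within-sample relative
#' abundance strictly greater than `min_rel_abund`.  Relative abundance is
#' computed within the table at hand, so for cross-kingdom analyses the
#' filter is applied per kingdom before merging.
#'
#' @param table an [abund_table].
#' @param min_prevalence prevalence fraction threshold (default 0.25,
#'   i.e. present in more than 25% of samples).
#' @param min_rel_abund mean relative-abundance threshold (default 1e-5,
#'   i.e. exceeding 0.001%).
#' @return Filtered [abund_table].
#' @export
filter_asvs <- function(table, min_prevalence = 0.25, min_rel_abund = 1e-5) {
  stopifnot(inherits(table, "abund_table"))
  x <- table$counts
  if (ncol(x) == 0) stop("empty table")
  tot <- rowSums(x)
  if (any(tot == 0)) stop("sample(s) with zero total abundance")
  prev_ok <- colSums(x > 0) > min_prevalence * nrow(x)
  rel <- x / tot
  abund_ok <- colMeans(rel) > min_rel_abund
  keep <- prev_ok & abund_ok
  if (!any(keep)) stop("filtering removed all taxa")
  abund_table(x[, keep, drop = FALSE], table$kingdom[keep], table$metadata)
}

#' Centered log-ratio transform
#'
#' Per sample: add a pseudocount (only when the matrix contains zeros),
#' close to proportions, take logs, and subtract the sample mean log, so
#' every output row sums to zero.  The transform is invariant to a global
#' rescaling of any sample's abundances, which is what makes the downstream
#' network compositionally robust.
#'
#' Pseudocount rule: `"fixed"` adds 1 (appropriate for counts);
#' `"half-min"` adds half the smallest positive value in the table
#' (appropriate for non-integer absolute abundances).  `"auto"` picks
#' `"fixed"` for integer-valued tables and `"half-min"` otherwise.
#'
#' @param table an [abund_table] or a non-negative samples x taxa matrix.
#' @param pseudocount_rule `"auto"`, `"fixed"` or `"half-min"`.
#' @return Samples x taxa real matrix with rows summing to zero.
#' @export
clr_transform <- function(table, pseudocount_rule = c("auto", "fixed", "half-min")) {
  pseudocount_rule <- match.arg(pseudocount_rule)
  x <- if (inherits(table, "abund_table")) table$counts else as.matrix(table)
  if (any(!is.finite(x)) || any(x < 0)) stop("abundances must be non-negative and finite")
  if (any(rowSums(x) == 0)) stop("sample(s) with zero total abundance")
  if (any(x == 0)) {
    pc <- switch(pseudocount_rule,
                 fixed = 1,
                 `half-min` = min(x[x > 0]) / 2,
                 auto = if (all(x == round(x))) 1 else min(x[x > 0]) / 2)
    x <- x + pc
  }
  lx <- log(x / rowSums(x))
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(if (inherits(table, "abund_table")) table$counts else table)
  out
}

#' Largest useful L1 penalty for the neighborhood regressions
#'
#' The maximum absolute empirical cross-covariance between CLR profiles
#' (1/n scaling, matching the glmnet objective); at or above this penalty
#' every neighborhood regression is empty.
#'
#' @param clr CLR matrix (samples x taxa).
#' @return Scalar lambda_max.
#' @export
lambda_max <- function(clr) {
  xc <- scale(clr, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / nrow(xc)
  diag(S) <- 0
  max(abs(S))
}

#' Default penalty path: 30 log-spaced values over two decades
#'
#' @param clr CLR matrix.
#' @param length number of path values.
#' @param min_ratio smallest lambda as a fraction of [lambda_max()].
#' @return Decreasing numeric vector.
#' @export
default_lambda_path <- function(clr, length = 30, min_ratio = 0.01) {
  lmax <- lambda_max(clr)
  if (lmax <= 0) stop("degenerate input: no covariance among taxa")
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = length))
}

# Directed neighborhood-selection coefficients along a penalty path.
# Returns a p x p x L array B with B[i, j, l] the lasso coefficient of
# taxon i in the regression of taxon j's CLR profile, at lambda_path[l].
neighborhood_coefs <- function(clr, lambda_path) {
  clr <- as.matrix(clr)
  if (any(!is.finite(clr))) stop("non-finite values in CLR matrix")
  n <- nrow(clr); p <- ncol(clr)
  if (n <= 2) stop("need more than 2 samples")
  if (p < 2) stop("need at least 2 taxa")
  if (all(apply(clr, 2, var) == 0))
    stop("degenerate input: all taxa have zero variance")
  if (is.unsorted(rev(lambda_path))) stop("lambda_path must be decreasing")
  L <- length(lambda_path)
  single <- L == 1L
  path <- if (single) lambda_path * c(16, 8, 4, 2, 1) else lambda_path
  B <- array(0, dim = c(p, p, L),
             dimnames = list(colnames(clr), colnames(clr), NULL))
  for (j in seq_len(p)) {
    y <- clr[, j]
    if (var(y) == 0) next
    x <- clr[, -j, drop = FALSE]
    if (p == 2L) {
      # univariate lasso in closed form (glmnet needs >= 2 predictors)
      xc <- x[, 1] - mean(x[, 1]); yc <- y - mean(y)
      cxy <- sum(xc * yc) / n; vx <- sum(xc * xc) / n
      beta <- matrix(vapply(path, function(l) {
        if (vx == 0) 0 else sign(cxy) * max(0, abs(cxy) - l) / vx
      }, numeric(1)), nrow = 1)
    } else {
      fit <- glmnet::glmnet(x, y, family = "gaussian", lambda = path,
                            standardize = FALSE, intercept = TRUE,
                            thresh = 1e-9)
      beta <- as.matrix(fit$beta)
      if (ncol(beta) < length(path))
        beta <- cbind(beta, matrix(beta[, ncol(beta)], nrow(beta),
                                   length(path) - ncol(beta)))
    }
    B[-j, j, ] <- if (single) beta[, length(path), drop = FALSE] else beta
  }
  B
}

# Symmetrize one lambda-slice of directed coefficients into a signed edge
# table.  OR rule: an edge exists if either regression selects it (AND:
# both).  Sign and weight come from the mean of the two directed
# coefficients; an exact zero mean drops the edge.
edges_from_coefs <- function(Bl, rule = c("or", "and")) {
  rule <- match.arg(rule)
  sel <- if (rule == "or") (Bl != 0) | (t(Bl) != 0) else (Bl != 0) & (t(Bl) != 0)
  M <- (Bl + t(Bl)) / 2
  sel <- sel & upper.tri(sel) & M != 0
  idx <- which(sel, arr.ind = TRUE)
  data.frame(from = rownames(Bl)[idx[, 1]], to = colnames(Bl)[idx[, 2]],
             sign = as.integer(sign(M[sel])), weight = abs(M[sel]),
             stringsAsFactors = FALSE)
}

#' Signed neighborhood-selection network at a single penalty
#'
#' L1-penalized regression of each taxon's CLR profile on all others
#' (Meinshausen-Buhlmann neighborhood selection); edges are symmetrized
#' with the OR rule by default, signed by the mean of the two directed
#' coefficients.
#'
#' @param clr CLR matrix (samples x taxa) from [clr_transform()].
#' @param lambda non-negative L1 penalty (glmnet scaling, i.e. 1/(2n) RSS).
#' @param rule symmetrization rule, `"or"` (default) or `"and"`.
#' @return data.frame of signed edges (`from`, `to`, `sign`, `weight`).
#' @export
neighborhood_fit <- function(clr, lambda, rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (lambda < 0) stop("lambda must be non-negative")
  B <- neighborhood_coefs(clr, lambda_path = lambda)
  edges_from_coefs(B[, , 1], rule = rule)
}

#' StARS stability selection of the network penalty
#'
#' Fits the neighborhood-selection path on random subsamples (without
#' replacement), measures edge-selection instability `mean(2 theta (1 -
#' theta))` at each penalty, monotonizes the instability along the
#' decreasing path, and selects the smallest penalty whose monotonized
#' instability stays at or below the threshold.  The final network is the
#' full-data fit at the selected penalty; every taxon of the input is a
#' node (isolated taxa included).  If no penalty satisfies the threshold
#' the largest penalty is used and a warning is recorded in the
#' provenance.
#'
#' @param table an [abund_table] (CLR-transformed internally) or a CLR
#'   matrix.
#' @param lambda_path decreasing penalty path; default
#'   [default_lambda_path()].
#' @param n_subsamples number of subsamples (default 50).
#' @param subsample_fraction fraction of samples per subsample (default 0.8).
#' @param instability_threshold StARS instability bound (default 0.05).
#' @param rule symmetrization rule passed to the fits.
#' @param seed integer RNG seed (subsampling).
#' @return A [signed_network] whose provenance records the path,
#'   instabilities, selected lambda, subsample settings and seed.
#' @export
stars_select <- function(table, lambda_path = NULL, n_subsamples = 50,
                         subsample_fraction = 0.8,
                         instability_threshold = 0.05,
                         rule = c("or", "and"), seed = 1) {
  rule <- match.arg(rule)
  if (n_subsamples < 2) stop("n_subsamples must be >= 2")
  is_tab <- inherits(table, "abund_table")
  clr <- if (is_tab) clr_transform(table) else as.matrix(table)
  kingdom <- if (is_tab) unname(table$kingdom) else rep(NA_character_, ncol(clr))
  lambda_path <- lambda_path %||% default_lambda_path(clr)
  n <- nrow(clr); p <- ncol(clr); L <- length(lambda_path)
  b <- max(3, floor(subsample_fraction * n))
  ut <- upper.tri(matrix(0, p, p))

  set.seed(seed)
  freq <- matrix(0, sum(ut), L)
  for (s in seq_len(n_subsamples)) {
    idx <- sample.int(n, b)
    B <- neighborhood_coefs(clr[idx, , drop = FALSE], lambda_path)
    nz <- B != 0
    sel <- nz | aperm(nz, c(2, 1, 3))
    if (rule == "and") sel <- nz & aperm(nz, c(2, 1, 3))
    for (l in seq_len(L)) freq[, l] <- freq[, l] + sel[, , l][ut]
  }
  theta <- freq / n_subsamples
  instability <- colMeans(2 * theta * (1 - theta))
  monotonized <- cummax(instability)
  ok <- monotonized <= instability_threshold
  fallback <- !any(ok)
  l_sel <- if (fallback) 1L else max(which(ok))

  B_full <- neighborhood_coefs(clr, lambda_path)
  edges <- edges_from_coefs(B_full[, , l_sel], rule = rule)
  nodes <- data.frame(id = colnames(clr), kingdom = kingdom,
                      stringsAsFactors = FALSE)
  prov <- list(method = "mb-stars", lambda_path = lambda_path,
               selected_lambda = lambda_path[l_sel],
               selected_index = l_sel,
               instability = instability, monotonized = monotonized,
               instability_threshold = instability_threshold,
               n_subsamples = n_subsamples,
               subsample_fraction = subsample_fraction,
               symmetrization = rule, seed = seed,
               warning = if (fallback)
                 "no lambda met the instability threshold; largest lambda used"
               else NULL)
  if (fallback)
    warning("StARS: no lambda met the instability threshold; using the largest lambda")
  signed_network(nodes, edges, provenance = prov)
}
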