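#' Abundance-weighted beta mean nearest taxon distance (betaMNTD)
#'
#' For two communities a and b:
#' `0.5 * (sum_i f_ai min_j d_ij + sum_j f_bj min_i d_ij)`, where f are the
#' within-community relative abundances and d the phylogenetic (cophenetic)
#' distances.  A taxon present in both communities has nearest distance 0.
#'
#' @param comm_a,comm_b named non-negative abundance vectors; every taxon
#'   with nonzero abundance must be a tip of the tree.
#' @param tree rooted `phylo` tree with branch lengths.
#' @return Non-negative scalar.
#' @export
beta_mntd <- function(comm_a, comm_b, tree) {
  pa <- comm_a[comm_a > 0]; pb <- comm_b[comm_b > 0]
  if (!length(pa) || !length(pb)) stop("empty community")
  taxa <- unique(c(names(pa), names(pb)))
  if (is.null(names(pa)) || !all(taxa %in% tree$tip.label))
    stop("communities must be named by tree tips")
  D <- cophenetic(tree)[taxa, taxa, drop = FALSE]
  comm <- matrix(0, 2, length(taxa), dimnames = list(c("a", "b"), taxa))
  comm["a", names(pa)] <- pa
  comm["b", names(pb)] <- pb
  bmntd_pairwise_cpp(comm, D)[1, 2]
}

#' Pairwise betaMNTD over a community matrix
#'
#' @param comm samples x taxa abundance matrix; column names must be tips
#'   of the tree and every sample must be non-empty.
#' @param tree rooted `phylo` tree covering the taxa.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
beta_mntd_matrix <- function(comm, tree) {
  comm <- as.matrix(comm)
  if (is.null(colnames(comm)) || !all(colnames(comm) %in% tree$tip.label))
    stop("community columns must be named by tree tips")
  if (any(rowSums(comm > 0) == 0)) stop("empty community")
  D <- cophenetic(tree)[colnames(comm), colnames(comm)]
  out <- bmntd_pairwise_cpp(comm, D)
  dimnames(out) <- list(rownames(comm), rownames(comm))
  out
}

#' beta nearest taxon index (betaNTI) with taxa-shuffle nulls
#'
#' Null distribution of betaMNTD obtained by shuffling taxon labels across
#' all tree tips (permuting rows/columns of the cophenetic matrix); the
#' same `n_null` shuffles are applied to every sample pair.  betaNTI is the
#' z-score `(observed - null mean) / null sd`.  Pairs with zero null
#' standard deviation are reported as `NA` with a warning (not silently 0).
#' Deterministic given `seed`: the k-th shuffle is the k-th
#' `sample.int(n_taxa)` draw after `set.seed(seed)`.
#'
#' Because betaNTI is a z-score it is invariant to multiplying all branch
#' lengths by a constant.
#'
#' @param comm samples x taxa abundance matrix (>= 2 samples).
#' @param tree rooted `phylo` covering the taxa.
#' @param n_null number of randomizations (>= 100; the study-design default
#'   is 1000).
#' @param seed integer RNG seed.
#' @return List with `bnti` (pairwise matrix, `NA` diagonal), `bmntd`,
#'   `null_mean`, `null_sd`, `n_null`, `seed`.
#' @export
beta_nti <- function(comm, tree, n_null = 1000, seed = 1) {
  comm <- as.matrix(comm)
  if (nrow(comm) < 2) stop("need at least 2 samples")
  if (n_null < 100) stop("n_null must be >= 100")
  tips <- colnames(comm)
  if (is.null(tips) || !all(tips %in% tree$tip.label))
    stop("community columns must be named by tree tips")
  D <- cophenetic(tree)[tips, tips]
  obs <- bmntd_pairwise_cpp(comm, D)
  p <- ncol(comm)
  s1 <- s2 <- matrix(0, nrow(comm), nrow(comm))
  set.seed(seed)
  for (k in seq_len(n_null)) {
    perm <- sample.int(p)
    nb <- bmntd_pairwise_cpp(comm, D[perm, perm])
    s1 <- s1 + nb
    s2 <- s2 + nb * nb
  }
  m <- s1 / n_null
  v <- (s2 - n_null * m * m) / (n_null - 1)
  v[v < 0] <- 0
  sdv <- sqrt(v)
  bnti <- (obs - m) / sdv
  bnti[sdv <= 1e-12] <- NA
  diag(bnti) <- NA
  dimnames(bnti) <- dimnames(obs) <- dimnames(m) <- dimnames(sdv) <-
    list(rownames(comm), rownames(comm))
  if (anyNA(bnti[upper.tri(bnti)]))
    warning("betaNTI undefined (zero null sd) for ",
            sum(is.na(bnti[upper.tri(bnti)])), " pair(s)")
  list(bnti = bnti, bmntd = obs, null_mean = m, null_sd = sdv,
       n_null = n_null, seed = seed)
}

#' Bray-Curtis-based Raup-Crick (RC_Bray) with probabilistic-assembly nulls
#'
#' Null communities are assembled per sample by drawing the observed
#' richness without replacement with occurrence probability proportional to
#' occupancy across samples, then filling abundances proportional to the
#' regional relative abundances of the drawn taxa, scaled to the sample's
#' observed total.  `RC = 2 * (fraction of null BC below observed + 0.5 *
#' ties) - 1`, in `[-1, 1]`.  Deterministic given `seed`.
#'
#' @param comm samples x taxa non-negative abundance matrix; no all-zero
#'   samples.
#' @param n_null number of randomizations (>= 100; default 1000).
#' @param seed integer RNG seed.
#' @return Pairwise RC matrix (`NA` diagonal).
#' @export
rc_bray <- function(comm, n_null = 1000, seed = 1) {
  comm <- as.matrix(comm)
  if (any(!is.finite(comm)) || any(comm < 0)) stop("abundances must be non-negative")
  if (any(rowSums(comm) == 0)) stop("sample(s) with zero total abundance")
  if (n_null < 100) stop("n_null must be >= 100")
  n <- nrow(comm); p <- ncol(comm)
  occ <- colSums(comm > 0)
  reg <- colSums(comm) / sum(comm)
  rich <- rowSums(comm > 0)
  tot <- rowSums(comm)
  obs <- as.matrix(vegan::vegdist(comm, method = "bray"))
  less <- ties <- matrix(0, n, n)
  eps <- 1e-12
  set.seed(seed)
  for (k in seq_len(n_null)) {
    nullm <- matrix(0, n, p)
    for (s in seq_len(n)) {
      ch <- sample.int(p, rich[s], prob = occ)
      w <- reg[ch]
      nullm[s, ch] <- w / sum(w) * tot[s]
    }
    nb <- as.matrix(vegan::vegdist(nullm, method = "bray"))
    less <- less + (nb < obs - eps)
    ties <- ties + (abs(nb - obs) <= eps)
  }
  rc <- 2 * ((less + 0.5 * ties) / n_null) - 1
  diag(rc) <- NA
  dimnames(rc) <- dimnames(obs)
  rc
}

#' Five-process classification of community assembly (QPEN)
#'
#' Pure threshold rules on the pair-wise (betaNTI, RC_Bray) values:
#' betaNTI > 2 -> variable selection; betaNTI < -2 -> homogeneous
#' selection; otherwise RC > 0.95 -> dispersal limitation, RC < -0.95 ->
#' homogenizing dispersal, |RC| <= 0.95 -> drift.  Boundary equalities
#' resolve toward the stochastic / drift side (strict inequalities).
#' Pairs with missing betaNTI are excluded from the fractions and counted.
#'
#' @param bnti pairwise betaNTI matrix (or the list from [beta_nti()]).
#' @param rc pairwise RC_Bray matrix from [rc_bray()], same samples.
#' @return Object of class `assembly_classification`: list with `pairs`
#'   (long data.frame: sample_a, sample_b, bnti, rc, process), `fractions`
#'   (named, sums to 1 over classified pairs), `n_pairs`, `n_excluded`.
#' @export
classify_assembly <- function(bnti, rc) {
  if (is.list(bnti) && !is.null(bnti$bnti)) bnti <- bnti$bnti
  bnti <- as.matrix(bnti); rc <- as.matrix(rc)
  if (!all(dim(bnti) == dim(rc))) stop("matrices must cover the same pairs")
  idx <- which(upper.tri(bnti), arr.ind = TRUE)
  b <- bnti[upper.tri(bnti)]; r <- rc[upper.tri(rc)]
  process <- ifelse(is.na(b), NA_character_,
             ifelse(b > 2, "variable_selection",
             ifelse(b < -2, "homogeneous_selection",
             ifelse(r > 0.95, "dispersal_limitation",
             ifelse(r < -0.95, "homogenizing_dispersal", "drift")))))
  processes <- c("variable_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  counts <- table(factor(process, levels = processes))
  n_classified <- sum(counts)
  fractions <- if (n_classified > 0) as.numeric(counts) / n_classified
               else rep(NA_real_, 5)
  names(fractions) <- processes
  ids <- rownames(bnti) %||% as.character(seq_len(nrow(bnti)))
  pairs <- data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                      bnti = b, rc = r, process = process,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, fractions = fractions,
                 n_pairs = nrow(pairs),
                 n_excluded = sum(is.na(process))),
            class = "assembly_classification")
}

#' @export
print.assembly_classification <- function(x, ...) {
  cat("<assembly_classification> ", x$n_pairs, " pairs (",
      x$n_excluded, " excluded)\n", sep = "")
  print(round(x$fractions, 3))
  invisible(x)
}

#' End-to-end assembly quantification for one community table
#'
#' Convenience wrapper: betaNTI and RC_Bray on the same community matrix,
#' then the five-process classification.
#'
#' @param table an [abund_table] or samples x taxa matrix.
#' @param tree `phylo` covering the taxa (pruned internally).
#' @param n_null randomizations for both null models.
#' @param seed integer RNG seed (both null models derive from it).
#' @return An `assembly_classification` with the betaNTI result attached
#'   as attribute `bnti_result`.
#' @export
quantify_assembly <- function(table, tree, n_null = 1000, seed = 1) {
  comm <- if (inherits(table, "abund_table")) table$counts else as.matrix(table)
  comm <- comm[, colSums(comm) > 0, drop = FALSE]
  tree <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(comm)))
  comm <- comm[, tree$tip.label, drop = FALSE]
  bn <- beta_nti(comm, tree, n_null = n_null, seed = seed)
  rc <- rc_bray(comm, n_null = n_null, seed = seed + 1)
  out <- classify_assembly(bn, rc)
  attr(out, "bnti_result") <- bn
  out
}
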