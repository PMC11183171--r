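#' Simulate a rooted phylogeny for one microbial kingdom
#'
#' Coalescent topology (`ape::rcoal`) with strictly positive branch lengths.
#' Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @param labels optional tip labels (length `n_tips`); defaults to
#'   `t1..tn`.
#' @return An `ape::phylo` rooted binary tree.
#' @export
generate_phylogeny <- function(n_tips, seed, labels = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  n_tips <- as.integer(n_tips)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tips))
  if (length(labels) != n_tips) stop("labels must have length n_tips")
  set.seed(seed)
  tree <- ape::rcoal(n_tips, tip.label = labels)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  tree
}

#' Plant a sparse signed cross-kingdom association network
#'
#' Builds a sparse symmetric positive-definite precision matrix over all
#' simulated taxa on the latent Gaussian scale.  Off-diagonal support defines
#' the true signed network: an edge (i, j) exists iff the precision entry is
#' nonzero, with sign equal to the sign of the implied partial correlation
#' (-Omega_ij / sqrt(Omega_ii * Omega_jj)) and weight its magnitude.
#' Cross-kingdom edges are allowed.  Positive definiteness is enforced by
#' shifting the diagonal past the most negative eigenvalue and rescaling to
#' unit diagonal, the standard construction in graphical-model simulations.
#'
#' When `scenario = "selection"` and kingdom trees are supplied, per-taxon
#' habitat optima (slope-position preferences) evolve by Brownian motion on
#' each tree, so preferences are phylogenetically conserved; otherwise optima
#' are i.i.d. standard normal.
#'
#' @param n_taxa named integer vector of taxa per kingdom, e.g.
#'   `c(bacteria = 60, rhizobia = 25, am_fungi = 20)`.
#' @param edge_density fraction of all taxon pairs carrying a true edge
#'   (0 < density <= 0.2).
#' @param positive_fraction expected proportion of positive-sign edges.
#' @param scenario `"selection"` or `"neutral"`; controls how habitat
#'   optima are generated (and is carried to [simulate_abundances()]).
#' @param trees optional named list of `phylo` trees per kingdom whose tip
#'   labels are the taxon ids; required for phylogenetically conserved
#'   optima under the selection scenario.
#' @param effect_coefficients named effect sizes (per standardized
#'   predictor) used by [simulate_functions()]: `am_richness`, `ppa`, `pna`.
#' @param partial_cor range of absolute partial-correlation magnitudes the
#'   planted edges aim for (before the positive-definiteness rescaling).
#' @param seed integer RNG seed.
#' @return An object of class `ground_truth`: list with `precision`,
#'   `true_network` (a [signed_network]), `taxa`, `habitat_optima`,
#'   `scenario`, `effect_coefficients`, `seed`.
#' @export
simulate_ground_truth <- function(n_taxa = c(bacteria = 60, rhizobia = 25, am_fungi = 20),
                                  edge_density = 0.05,
                                  positive_fraction = 0.6,
                                  scenario = c("selection", "neutral"),
                                  trees = NULL,
                                  effect_coefficients = c(am_richness = 1, ppa = 0.8, pna = 0.8),
                                  partial_cor = c(0.3, 0.5),
                                  seed = 1) {
  scenario <- match.arg(scenario)
  if (edge_density <= 0 || edge_density > 0.2)
    stop("edge_density must be in (0, 0.2]")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  if (is.null(names(n_taxa)))
    stop("n_taxa must be named by kingdom")
  p <- sum(n_taxa)
  ids <- taxon_ids(n_taxa)
  kingdom <- rep(names(n_taxa), n_taxa)
  names(kingdom) <- ids

  set.seed(seed)
  n_pairs <- p * (p - 1) / 2
  m <- round(edge_density * n_pairs)
  if (m > n_pairs) stop("infeasible edge density")
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  if (m > 0) {
    ut <- which(upper.tri(B))
    sel <- sample(ut, m)
    signs <- ifelse(runif(m) < positive_fraction, 1, -1)
    mags <- runif(m, partial_cor[1], partial_cor[2])
    # positive partial correlation <=> negative precision entry
    B[sel] <- -signs * mags
    B <- B + t(B)
  }
  ev_min <- if (m > 0) min(eigen(B, symmetric = TRUE, only.values = TRUE)$values) else 0
  diag(B) <- abs(ev_min) + 0.15
  omega <- B / sqrt(diag(B) %o% diag(B))   # unit diagonal, PD preserved

  pcor <- -omega / sqrt(diag(omega) %o% diag(omega))
  idx <- which(omega != 0 & upper.tri(omega), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      sign = as.integer(sign(pcor[idx])),
                      weight = abs(pcor[idx]),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, kingdom = unname(kingdom), stringsAsFactors = FALSE)
  net <- signed_network(nodes, edges,
                        provenance = list(source = "planted", seed = seed,
                                          edge_density = edge_density,
                                          positive_fraction = positive_fraction))

  optima <- rnorm(p)
  names(optima) <- ids
  if (scenario == "selection" && !is.null(trees)) {
    for (k in names(n_taxa)) {
      tr <- trees[[k]]
      if (is.null(tr)) next
      tk <- ids[kingdom == k]
      if (!all(tk %in% tr$tip.label))
        stop("tree for kingdom ", k, " does not cover its taxa")
      x <- ape::rTraitCont(tr, model = "BM", sigma = 1)[tk]
      optima[tk] <- as.numeric(scale(x))   # z-scored within kingdom
    }
  }

  structure(list(precision = omega, true_network = net,
                 taxa = nodes, habitat_optima = optima,
                 scenario = scenario,
                 effect_coefficients = effect_coefficients,
                 seed = seed),
            class = "ground_truth")
}

taxon_ids <- function(n_taxa) {
  prefix <- c(bacteria = "B", rhizobia = "R", am_fungi = "F")
  unlist(lapply(names(n_taxa), function(k) {
    sprintf("%s%03d", prefix[[k]] %||% toupper(substr(k, 1, 1)), seq_len(n_taxa[[k]]))
  }), use.names = FALSE)
}

#' The 3-position x 6-replicate slope sampling design
#'
#' Sample metadata for `n_samples` plots split equally over the three slope
#' positions, with a physical coordinate (meters downslope) used by the
#' neutral dispersal scenario: positions are 20 m apart and replicate plots
#' spread over 10 m within a position.
#'
#' @param n_samples number of samples, a multiple of 3 (default 18).
#' @return data.frame with `sample_id`, `position`, `plot`, `pos_score`
#'   (top = 1, middle = 2, bottom = 3) and `coord` (m downslope).
#' @export
slope_design <- function(n_samples = 18) {
  if (n_samples %% 3 != 0) stop("n_samples must be a multiple of 3")
  reps <- n_samples / 3
  position <- rep(c("top", "middle", "bottom"), each = reps)
  pos_score <- rep(1:3, each = reps)
  within <- rep(seq(0, 10, length.out = reps), times = 3)
  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             position = position,
             plot = sprintf("P%02d", seq_len(n_samples)),
             pos_score = pos_score,
             coord = (pos_score - 1) * 20 + within,
             stringsAsFactors = FALSE)
}

#' Simulate per-kingdom abundance tables from planted ground truth
#'
#' Latent log-abundances are multivariate normal with covariance equal to
#' the inverse of the planted precision matrix, plus per-taxon intercepts
#' and a scenario term.  Under `"selection"`, a phylogenetically conserved
#' habitat-preference term (`selection_strength * optimum_i * centered
#' position score`) shifts taxa along the slope; under `"neutral"` it is
#' replaced by per-taxon spatially autocorrelated plot effects with
#' exponential distance decay along the slope (dispersal limitation, no
#' phylogenetic structure).  Counts are Poisson draws on
#' `exp(latent) * depth`, with sequencing/profiling depth varying
#' log-normally (~20% CV) across samples, preserving absolute-abundance
#' semantics.
#'
#' @param truth a `ground_truth` from [simulate_ground_truth()].
#' @param n_samples number of samples (multiple of 3; default 18).
#' @param depth target mean total abundance per sample.
#' @param scenario overrides `truth$scenario` if given.
#' @param selection_strength latent-scale effect of one unit of habitat
#'   optimum per centered position score.
#' @param dispersal_sd latent sd of the spatial plot effects (neutral).
#' @param dispersal_range e-folding distance (m) of the spatial correlation.
#' @param latent_sd multiplier on the latent interaction noise.
#' @param abund_sd sd of the per-taxon log-abundance intercepts; the
#'   default 2 (natural-log scale) gives the orders-of-magnitude
#'   rank-abundance spread and sparse occupancy typical of ASV tables.
#' @param depth_cv coefficient of variation of per-sample depth.
#' @param seed integer RNG seed.
#' @return Named list of [abund_table], one per kingdom.
#' @export
simulate_abundances <- function(truth, n_samples = 18, depth = 2e4,
                                scenario = NULL,
                                selection_strength = 4,
                                dispersal_sd = 1.5, dispersal_range = 20,
                                latent_sd = 1, abund_sd = 2, depth_cv = 0.2,
                                seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  scenario <- scenario %||% truth$scenario
  design <- slope_design(n_samples)
  ids <- truth$taxa$id
  p <- length(ids)

  set.seed(seed)
  sigma <- chol2inv(chol(truth$precision))
  U <- chol(sigma)
  eps <- (matrix(rnorm(n_samples * p), n_samples, p) %*% U) * latent_sd

  mu <- rnorm(p, 0, abund_sd)                # taxon intercepts (log scale)
  z <- sweep(eps, 2, mu, `+`)

  if (scenario == "selection") {
    pscore <- design$pos_score - 2           # centered: -1, 0, 1
    z <- z + selection_strength * (pscore %o% truth$habitat_optima)
  } else {
    d <- as.matrix(stats::dist(design$coord))
    K <- exp(-d / dispersal_range)
    Uk <- chol(K + diag(1e-8, n_samples))
    spatial <- crossprod(Uk, matrix(rnorm(n_samples * p), n_samples, p)) * dispersal_sd
    z <- z + spatial
  }

  lam <- exp(z)
  sdlog <- sqrt(log(1 + depth_cv^2))
  depth_s <- depth * rlnorm(n_samples, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  lam <- lam / rowSums(lam) * depth_s     # each sample scaled to its depth
  counts <- matrix(rpois(n_samples * p, as.vector(lam)), n_samples, p,
                   dimnames = list(design$sample_id, ids))

  meta <- design[, c("sample_id", "position", "plot")]
  kingdom <- setNames(truth$taxa$kingdom, truth$taxa$id)
  out <- lapply(unique(kingdom), function(k) {
    abund_table(counts[, names(kingdom)[kingdom == k], drop = FALSE],
                kingdom[kingdom == k], meta)
  })
  names(out) <- unique(kingdom)
  out
}

#' Simulate the 12-function ecosystem function table
#'
#' Each function is a linear combination of three standardized per-sample
#' predictors -- AM-fungal richness, community-level positive association
#' strength (PPA), and negative association strength (PNA), the latter two
#' computed from the planted true network -- with coefficients from
#' `truth$effect_coefficients`, a function-specific sign pattern (AM
#' richness and PPA support every function; PNA suppresses every function),
#' and additive Gaussian noise.
#'
#' @param tables named list of [abund_table] sharing sample ids (must
#'   include `am_fungi`).
#' @param truth the `ground_truth` the tables were simulated from.
#' @param noise_sd sd of the additive noise.
#' @param seed integer RNG seed.
#' @return A [function_table] (samples x 12).
#' @export
simulate_functions <- function(tables, truth, noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!"am_fungi" %in% names(tables)) stop("tables must include am_fungi")
  merged <- merge_kingdom_tables(tables)
  n <- nrow(merged$counts)
  am_rich <- rowSums(tables$am_fungi$counts > 0)
  assoc <- biotic_association_scores(merged, truth$true_network)
  zs <- function(x) if (sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  X <- cbind(am_richness = zs(am_rich), ppa = zs(assoc$ppa), pna = zs(assoc$pna))
  co <- truth$effect_coefficients[colnames(X)]
  co[is.na(co)] <- 0
  fn <- names(service_groups())
  sign_pattern <- matrix(1, nrow = length(fn), ncol = 3,
                         dimnames = list(fn, colnames(X)))
  sign_pattern[, "pna"] <- -1
  set.seed(seed)
  mat <- matrix(0, n, length(fn), dimnames = list(rownames(merged$counts), fn))
  for (f in fn) {
    mat[, f] <- X %*% (co * sign_pattern[f, ]) + rnorm(n, 0, noise_sd)
  }
  function_table(mat)
}

#' Simulate a complete slope study with planted ground truth
#'
#' Convenience wrapper: kingdom phylogenies, planted signed network and
#' habitat optima, per-kingdom abundance tables under the chosen assembly
#' scenario, and the 12-function table.  Sub-seeds are derived from `seed`
#' by small fixed offsets so a single integer reproduces the whole study.
#'
#' @inheritParams simulate_ground_truth
#' @inheritParams simulate_abundances
#' @inheritParams simulate_functions
#' @param ... passed on to [simulate_abundances()].
#' @return List with `trees`, `truth`, `tables`, `functions`, `design`.
#' @export
simulate_study <- function(n_taxa = c(bacteria = 60, rhizobia = 25, am_fungi = 20),
                           n_samples = 18,
                           edge_density = 0.05, positive_fraction = 0.6,
                           scenario = c("selection", "neutral"),
                           depth = 2e4, noise_sd = 0.5, seed = 1, ...) {
  scenario <- match.arg(scenario)
  ids <- split(taxon_ids(n_taxa), rep(names(n_taxa), n_taxa))
  trees <- lapply(seq_along(n_taxa), function(i) {
    generate_phylogeny(n_taxa[[i]], seed = seed + i, labels = ids[[names(n_taxa)[i]]])
  })
  names(trees) <- names(n_taxa)
  truth <- simulate_ground_truth(n_taxa, edge_density, positive_fraction,
                                 scenario, trees = trees, seed = seed + 4)
  tables <- simulate_abundances(truth, n_samples = n_samples, depth = depth,
                                seed = seed + 5, ...)
  functions <- simulate_functions(tables, truth, noise_sd = noise_sd,
                                  seed = seed + 6)
  list(trees = trees, truth = truth, tables = tables, functions = functions,
       design = slope_design(n_samples))
}
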