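#' Topological summary of a network
#'
#' Node and edge counts (positive/negative), average degree `2E/N`, density
#' `2E/(N(N-1))`, average path length and diameter computed on the
#' unweighted graph over connected node pairs only, global average of local
#' clustering coefficients (nodes of degree < 2 count as 0), and the
#' modularity of the detected module partition.  For an edgeless network the
#' path-based and clustering metrics are reported as 0.
#'
#' @param network a [signed_network].
#' @param seed seed passed to [detect_modules()].
#' @return One-row data.frame with the metrics.
#' @export
summary_metrics <- function(network, seed = 1) {
  stopifnot(inherits(network, "signed_network"))
  n <- nrow(network$nodes); e <- nrow(network$edges)
  if (n < 1) stop("empty node set")
  g <- as_igraph(network)
  if (e > 0) {
    apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE,
                                 weights = NA)
    diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE,
                             weights = NA)
    clust <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
    mem <- detect_modules(network, seed = seed)
    mod <- igraph::modularity(g, mem[network$nodes$id], weights = NULL)
  } else {
    apl <- diam <- clust <- mod <- 0
  }
  data.frame(node_count = n, edge_count = e,
             positive_edges = sum(network$edges$sign > 0),
             negative_edges = sum(network$edges$sign < 0),
             average_degree = if (n > 0) 2 * e / n else 0,
             average_path_length = apl,
             diameter = diam,
             density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
             clustering_coefficient = clust,
             modularity = mod)
}

#' Detect network modules (greedy modularity maximization)
#'
#' Unweighted fast-greedy modularity optimization; deterministic given the
#' seed.  Every node is assigned exactly one module; nodes of an edgeless
#' network each get their own module.
#'
#' @param network a [signed_network].
#' @param seed integer RNG seed (recorded; the greedy optimizer itself is
#'   deterministic).
#' @return Named integer vector: taxon id -> module id.
#' @export
detect_modules <- function(network, seed = 1) {
  stopifnot(inherits(network, "signed_network"))
  ids <- network$nodes$id
  if (nrow(network$edges) == 0)
    return(setNames(seq_along(ids), ids))
  set.seed(seed)
  g <- as_igraph(network)
  cl <- igraph::cluster_fast_greedy(igraph::simplify(g), weights = NULL)
  mem <- igraph::membership(cl)
  setNames(as.integer(mem), names(mem))[ids]
}

#' Zi-Pi node roles: within-module connectivity and participation
#'
#' For node i with degree `k_i` and `kappa_im` edges into module m:
#' `Z_i = (kappa_i,own - mean kappa over own module) / sd kappa over own
#' module` (Z = 0 when the module sd is 0 or the node is isolated) and
#' `P_i = 1 - sum_m (kappa_im / k_i)^2` (P = 0 for isolated nodes).  Roles:
#' module hubs (Z > 2.5, P < 0.62), network hubs (Z > 2.5, P > 0.62),
#' connectors (Z < 2.5, P > 0.62), peripherals otherwise; boundary
#' equalities fall to the module-hub / peripheral side of each rule.
#'
#' @param network a [signed_network].
#' @param modules module assignment from [detect_modules()]; computed if
#'   missing.
#' @param seed seed for module detection when `modules` is missing.
#' @return data.frame with `taxon`, `module`, `degree`, `Z`, `P`, `role`.
#' @export
zi_pi <- function(network, modules = NULL, seed = 1) {
  stopifnot(inherits(network, "signed_network"))
  modules <- modules %||% detect_modules(network, seed = seed)
  ids <- network$nodes$id
  if (!all(ids %in% names(modules))) stop("modules must cover all nodes")
  modules <- modules[ids]
  g <- as_igraph(network)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- A[ids, ids, drop = FALSE]
  mod_f <- factor(modules)
  ind <- matrix(0, length(ids), nlevels(mod_f))
  ind[cbind(seq_along(ids), as.integer(mod_f))] <- 1
  kappa <- A %*% ind                      # n x m: edges from node into module
  k <- rowSums(A)
  own <- kappa[cbind(seq_along(ids), as.integer(mod_f))]
  Z <- numeric(length(ids))
  for (m in levels(mod_f)) {
    mem <- which(mod_f == m)
    mu <- mean(own[mem]); s <- sd(own[mem])
    Z[mem] <- if (is.na(s) || s == 0) 0 else (own[mem] - mu) / s
  }
  P <- ifelse(k > 0, 1 - rowSums((kappa / pmax(k, 1))^2), 0)
  role <- ifelse(Z > 2.5 & P > 0.62, "network_hub",
          ifelse(Z > 2.5, "module_hub",
          ifelse(P > 0.62, "connector", "peripheral")))
  data.frame(taxon = ids, module = as.integer(mod_f), degree = k,
             Z = Z, P = P, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kleinberg hub-centrality scores and keystone taxa
#'
#' On an undirected graph the HITS hub score equals the principal
#' eigenvector of the unsigned adjacency matrix.  Scores are computed per
#' connected component (principal eigenvector scaled by the component's
#' leading eigenvalue, so denser components score higher) and normalized
#' globally so the maximum over all nodes is 1; isolated nodes score 0.
#' Keystone taxa are nodes with score at or above the threshold.
#'
#' @param network a [signed_network].
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
hub_centrality <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  ids <- network$nodes$id
  score <- setNames(numeric(length(ids)), ids)
  if (nrow(network$edges) == 0) return(score)
  g <- as_igraph(network)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A[A > 0] <- 1
  comp <- igraph::components(g)
  for (cc in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == cc]
    if (length(vs) < 2) next
    Ac <- A[vs, vs, drop = FALSE]
    if (all(Ac == 0)) next
    e <- eigen(Ac, symmetric = TRUE)
    v <- abs(e$vectors[, 1])
    score[vs] <- v / max(v) * e$values[1]
  }
  mx <- max(score)
  if (mx > 0) score <- score / mx
  score
}

#' @rdname hub_centrality
#' @param scores output of [hub_centrality()].
#' @param threshold keystone score threshold (default 0.7).
#' @return `keystones()`: character vector of keystone taxon ids.
#' @export
keystones <- function(scores, threshold = 0.7) {
  names(scores)[scores >= threshold]
}

#' Induced subnetwork of the taxa present in one sample
#'
#' @param network a [signed_network].
#' @param sample_abundances named abundance vector; taxa missing from the
#'   vector count as absent.
#' @return The induced [signed_network] on taxa with abundance > 0.
#' @export
sample_subnetwork <- function(network, sample_abundances) {
  stopifnot(inherits(network, "signed_network"))
  ab <- sample_abundances[network$nodes$id]
  ab[is.na(ab)] <- 0
  present <- network$nodes$id[ab > 0]
  nodes <- network$nodes[network$nodes$id %in% present, , drop = FALSE]
  edges <- network$edges[network$edges$from %in% present &
                         network$edges$to %in% present, , drop = FALSE]
  signed_network(nodes, edges,
                 provenance = c(network$provenance, list(subnetwork = TRUE)))
}

#' Per-sample subnetwork topology
#'
#' Induces each sample's subnetwork and summarizes it; a sample with no
#' present network taxa gets a row of zeros.
#'
#' @param network a [signed_network].
#' @param table an [abund_table] covering the network's taxa.
#' @return data.frame: one row per sample with [summary_metrics()] columns.
#' @export
subnetwork_metrics <- function(network, table) {
  stopifnot(inherits(table, "abund_table"))
  out <- lapply(rownames(table$counts), function(s) {
    sub <- sample_subnetwork(network, table$counts[s, ])
    if (nrow(sub$nodes) == 0) {
      z <- summary_metrics(signed_network(
        data.frame(id = "dummy", kingdom = "bacteria"), NULL))
      z[1, ] <- 0
      z
    } else {
      summary_metrics(sub)
    }
  })
  cbind(data.frame(sample_id = rownames(table$counts),
                   stringsAsFactors = FALSE),
        do.call(rbind, out))
}

#' Community-level positive / negative biotic-association scores
#'
#' For sample s, `PPA_s` is the sum over positive in-scope edges (i, j) of
#' `r_si * r_sj`, with r the within-sample relative abundance over all taxa
#' in the table; `PNA_s` is the analogue over negative edges.  Edges with
#' an absent endpoint contribute 0, and both scores are invariant to a
#' global rescaling of a sample's absolute abundances.
#'
#' @param table an [abund_table]; must cover the network's taxa.
#' @param network a [signed_network].
#' @param scope optional length-2 character vector of kingdoms; only edges
#'   joining that (unordered) kingdom pair are counted.  `NULL` counts all
#'   edges.
#' @return data.frame with `sample_id`, `ppa`, `pna` and a `scope`
#'   attribute.
#' @export
biotic_association_scores <- function(table, network, scope = NULL) {
  stopifnot(inherits(table, "abund_table"), inherits(network, "signed_network"))
  if (!all(network$nodes$id %in% colnames(table$counts)))
    stop("network taxa must be a subset of the table's taxa")
  edges <- network$edges
  if (!is.null(scope)) {
    if (length(scope) != 2) stop("scope must name a kingdom pair")
    kg <- setNames(network$nodes$kingdom, network$nodes$id)
    pair <- paste(sort(scope), collapse = "|")
    keep <- paste(pmin(kg[edges$from], kg[edges$to]),
                  pmax(kg[edges$from], kg[edges$to]), sep = "|") == pair
    edges <- edges[keep, , drop = FALSE]
  }
  scope_label <- if (is.null(scope)) "all" else paste(sort(scope), collapse = "-")
  rel <- table$counts / rowSums(table$counts)
  n <- nrow(rel)
  ppa <- pna <- numeric(n)
  if (nrow(edges) == 0) {
    warning("scope selects no edges; association scores are all zero")
  } else {
    prod_mat <- rel[, edges$from, drop = FALSE] * rel[, edges$to, drop = FALSE]
    pos <- edges$sign > 0
    if (any(pos)) ppa <- rowSums(prod_mat[, pos, drop = FALSE])
    if (any(!pos)) pna <- rowSums(prod_mat[, !pos, drop = FALSE])
  }
  out <- data.frame(sample_id = rownames(rel), ppa = ppa, pna = pna,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scope") <- scope_label
  out
}
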