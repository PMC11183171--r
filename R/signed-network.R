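#' Undirected signed weighted network over taxa
#'
#' @param nodes data.frame with columns `id` (unique taxon ids) and
#'   `kingdom`.
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1),
#'   `weight` (finite, positive); undirected, no self-loops, no duplicates.
#' @param provenance list of free-form records (selected lambda, seed, ...).
#' @return Object of class `signed_network`.
#' @export
signed_network <- function(nodes, edges, provenance = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kingdom") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!is.null(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to", "sign", "weight") %in% names(edges)))
  if (nrow(edges)) {
    if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id))
      stop("edge endpoint not among declared nodes")
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
    if (any(!is.finite(edges$weight))) stop("edge weights must be finite")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  np <- sum(x$edges$sign > 0); nn <- sum(x$edges$sign < 0)
  cat("<signed_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", np, " positive, ", nn, " negative)\n", sep = "")
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' @param network a [signed_network].
#' @return Undirected `igraph` graph with `sign` and `weight` edge
#'   attributes and a `kingdom` vertex attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  v <- data.frame(name = network$nodes$id, kingdom = network$nodes$kingdom,
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = v)
}

#' Write / read a signed network as a TSV edge list with a node table
#'
#' @param network a [signed_network].
#' @param edge_path path for the edge list TSV (`from`, `to`, `sign`,
#'   `weight`).
#' @param node_path path for the node TSV (`id`, `kingdom`).
#' @export
write_network_tsv <- function(network, edge_path, node_path) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(network)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(edge_path, node_path) {
  edges <- read.delim(edge_path, stringsAsFactors = FALSE)
  nodes <- read.delim(node_path, stringsAsFactors = FALSE)
  signed_network(nodes, edges)
}
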