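# Shared fixtures built in code.

edge_key <- function(edges) paste(pmin(edges$from, edges$to),
                                  pmax(edges$from, edges$to))

toy_nodes <- function(ids, kingdom = "bacteria") {
  data.frame(id = ids, kingdom = rep_len(kingdom, length(ids)),
             stringsAsFactors = FALSE)
}

toy_edges <- function(from, to, sign = 1, weight = 1) {
  data.frame(from = from, to = to, sign = as.integer(rep_len(sign, length(from))),
             weight = rep_len(weight, length(from)), stringsAsFactors = FALSE)
}

# two K4 cliques joined by a single bridge edge a4 - b1
two_cliques_bridge <- function() {
  cl <- function(v) {
    p <- t(combn(v, 2))
    toy_edges(p[, 1], p[, 2])
  }
  a <- paste0("a", 1:4); b <- paste0("b", 1:4)
  signed_network(toy_nodes(c(a, b)), rbind(cl(a), cl(b), toy_edges("a4", "b1")))
}

star_network <- function(n_leaves = 3) {
  leaves <- paste0("l", seq_len(n_leaves))
  signed_network(toy_nodes(c("hub", leaves)), toy_edges(rep("hub", n_leaves), leaves))
}

toy_abund <- function(counts, kingdom = "bacteria") {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("S%02d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("T%02d", seq_len(ncol(counts)))
  reps <- ceiling(n / 3)
  meta <- data.frame(sample_id = rownames(counts),
                     position = rep(c("top", "middle", "bottom"), each = reps)[seq_len(n)],
                     plot = sprintf("P%02d", seq_len(n)))
  abund_table(counts, rep_len(kingdom, ncol(counts)), meta)
}

# latent Gaussian sampler with a known precision matrix
latent_sample <- function(omega, n, seed) {
  set.seed(seed)
  U <- chol(solve(omega))
  x <- matrix(rnorm(n * ncol(omega)), n) %*% U
  colnames(x) <- paste0("t", seq_len(ncol(omega)))
  x
}

# independent pure-R betaMNTD oracle: exhaustive double loop over taxa
bmntd_oracle <- function(comm_a, comm_b, D) {
  pa <- comm_a[comm_a > 0]; pb <- comm_b[comm_b > 0]
  fa <- pa / sum(pa); fb <- pb / sum(pb)
  ta <- 0
  for (i in names(fa)) {
    mn <- Inf
    for (j in names(fb)) mn <- min(mn, D[i, j])
    ta <- ta + fa[[i]] * mn
  }
  tb <- 0
  for (j in names(fb)) {
    mn <- Inf
    for (i in names(fa)) mn <- min(mn, D[i, j])
    tb <- tb + fb[[j]] * mn
  }
  0.5 * (ta + tb)
}

# all set partitions of 1..n via restricted growth strings (for exhaustive
# modularity search at toy sizes)
all_partitions <- function(n) {
  out <- list()
  grow <- function(a, k) {
    i <- length(a) + 1
    if (i > n) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (v in seq_len(k + 1)) grow(c(a, v), max(k, v))
  }
  grow(integer(), 0L)
  out
}
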