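#' Write / read abundance tables as TSV (taxa rows, samples columns)
#'
#' The abundance TSV has columns `taxon_id`, `kingdom`, then one column per
#' sample; the metadata TSV has `sample_id`, `position`, `plot`.
#'
#' @param table an [abund_table].
#' @param path abundance TSV path.
#' @param meta_path metadata TSV path (optional for writing; required for
#'   reading).
#' @export
write_abundance_tsv <- function(table, path, meta_path = NULL) {
  stopifnot(inherits(table, "abund_table"))
  df <- data.frame(taxon_id = colnames(table$counts),
                   kingdom = unname(table$kingdom),
                   t(table$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write.table(table$metadata, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(table)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path, meta_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "kingdom") %in% names(df)))
    stop("abundance TSV needs taxon_id and kingdom columns: ", path)
  if (anyDuplicated(df$taxon_id)) stop("duplicated taxon ids in ", path)
  samples <- setdiff(names(df), c("taxon_id", "kingdom"))
  counts <- t(as.matrix(df[, samples, drop = FALSE]))
  colnames(counts) <- df$taxon_id
  if (any(is.na(suppressWarnings(as.numeric(counts)))))
    stop("non-numeric abundance values in ", path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(rownames(counts) %in% meta$sample_id))
    stop("metadata is missing sample(s) present in ", path)
  meta <- meta[meta$sample_id %in% rownames(counts), , drop = FALSE]
  abund_table(counts, setNames(df$kingdom, df$taxon_id), meta)
}

#' Read an abundance table from a BIOM file
#'
#' Requires the `biomformat` package.  Sample metadata is supplied as a
#' separate TSV as in [read_abundance_tsv()].
#'
#' @param path BIOM file path.
#' @param meta_path metadata TSV path.
#' @param kingdom single kingdom label for all taxa, or a named vector.
#' @export
read_abundance_biom <- function(path, meta_path, kingdom) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  counts <- t(as.matrix(biomformat::biom_data(b)))   # biom stores taxa x samples
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (length(kingdom) == 1) kingdom <- setNames(rep(kingdom, ncol(counts)),
                                                colnames(counts))
  abund_table(counts, kingdom, meta)
}

#' Read and validate a Newick tree
#'
#' Parses the file with `ape::read.tree` and checks that every edge
#' carries a positive branch length.
#'
#' @param path Newick file path.
#' @return An `ape::phylo`.
#' @export
read_newick_checked <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("missing branch length(s) in ", path)
  if (any(tree$edge.length < 0)) stop("negative branch length(s) in ", path)
  tree
}

#' Read the pipeline's inputs from standard-format files
#'
#' @param abundance_paths named character vector (kingdom -> abundance TSV).
#' @param meta_path sample metadata TSV.
#' @param function_path optional function-table TSV (samples x functions,
#'   first column `sample_id`).
#' @param tree_paths optional named vector (kingdom -> Newick path).
#' @param allow_subset if `TRUE`, tables are cut down to the common sample
#'   set instead of failing on a mismatch.
#' @return List with `tables`, `functions` (or NULL), `trees` (or NULL).
#' @export
read_inputs <- function(abundance_paths, meta_path, function_path = NULL,
                        tree_paths = NULL, allow_subset = FALSE) {
  tables <- lapply(abundance_paths, read_abundance_tsv, meta_path = meta_path)
  names(tables) <- names(abundance_paths)
  ids <- Reduce(intersect, lapply(tables, function(t) rownames(t$counts)))
  full <- vapply(tables, function(t) setequal(rownames(t$counts), ids),
                 logical(1))
  if (!all(full)) {
    if (!allow_subset) stop("sample ids differ across tables; ",
                            length(ids), " in common")
    tables <- lapply(tables, function(t)
      abund_table(t$counts[ids, , drop = FALSE], t$kingdom,
                  t$metadata[t$metadata$sample_id %in% ids, , drop = FALSE]))
  }
  functions <- NULL
  if (!is.null(function_path)) {
    fd <- read.delim(function_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(fd)) stop("function TSV needs a sample_id column")
    m <- as.matrix(fd[, setdiff(names(fd), "sample_id"), drop = FALSE])
    rownames(m) <- fd$sample_id
    if (!all(ids %in% rownames(m))) stop("function table is missing samples")
    functions <- function_table(m[ids, , drop = FALSE])
  }
  trees <- if (!is.null(tree_paths)) lapply(tree_paths, read_newick_checked)
  list(tables = tables, functions = functions, trees = trees)
}

#' Write a function table (with sample ids) as TSV
#' @param functions a [function_table] or matrix with sample row names.
#' @param path output TSV path.
#' @export
write_function_tsv <- function(functions, path) {
  df <- data.frame(sample_id = rownames(functions),
                   unclass(as.matrix(functions)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(functions)
}

#' Pipeline configuration
#'
#' A config fully determines a run: simulation parameters (or input paths),
#' filter thresholds, network-selection settings, null-model and
#' permutation settings, and every seed.
#'
#' @param ... overrides of the defaults below.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_taxa = c(bacteria = 60, rhizobia = 25, am_fungi = 20),
    n_samples = 18,
    scenario = "selection",
    edge_density = 0.05,
    positive_fraction = 0.6,
    depth = 2e4,
    noise_sd = 0.5,
    min_prevalence = 0.25,
    min_rel_abund = 1e-5,
    lambda_path_length = 20,
    n_subsamples = 30,
    subsample_fraction = 0.8,
    instability_threshold = 0.05,
    n_null = 1000,
    n_permutations = 999,
    n_dims = 3,
    seed = 1,
    outdir = NULL,
    inputs = NULL)  # optional list(abundance_paths, meta_path, ...)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the end-to-end slope microbiota analysis
#'
#' Orchestrates: simulate (or read) inputs -> multifunctionality ->
#' per-kingdom filtering -> single- and cross-kingdom network inference ->
#' topology, node roles, keystones, per-sample subnetworks and biotic
#' association scores -> assembly null models -> permutation statistics.
#' If `config$outdir` is set, all result tables are written as TSV plus a
#' JSON manifest recording the config, its hash and every seed; a stage
#' failure is re-signalled with the stage name and partial results are
#' persisted under `<outdir>/failed`.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) the report bundle: a named list of all results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  # the hash covers everything that determines the analysis (not the
  # output location)
  analysis_cfg <- unclass(config)[setdiff(names(config), "outdir")]
  bundle <- list(config = config, config_hash = rlang::hash(analysis_cfg))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$outdir)) {
        fdir <- file.path(config$outdir, "failed")
        dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
        writeLines(c(paste("failed stage:", name), conditionMessage(e),
                     paste("completed:", paste(names(bundle), collapse = ", "))),
                   file.path(fdir, "FAILED.txt"))
      }
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- inputs ----------------------------------------------------------
  bundle$study <- stage("inputs", {
    if (is.null(config$inputs)) {
      simulate_study(n_taxa = config$n_taxa, n_samples = config$n_samples,
                     edge_density = config$edge_density,
                     positive_fraction = config$positive_fraction,
                     scenario = config$scenario, depth = config$depth,
                     noise_sd = config$noise_sd, seed = config$seed)
    } else {
      inp <- do.call(read_inputs, config$inputs)
      list(trees = inp$trees, truth = NULL, tables = inp$tables,
           functions = inp$functions)
    }
  })
  tables <- bundle$study$tables
  trees <- bundle$study$trees
  meta <- tables[[1]]$metadata
  position <- setNames(meta$position, meta$sample_id)

  # -- multifunctionality ---------------------------------------------
  if (!is.null(bundle$study$functions)) {
    bundle$multifunctionality <- stage("multifunctionality",
      multifunctionality(bundle$study$functions, n_dims = config$n_dims))
  }

  # -- filtering and network inference --------------------------------
  bundle$filtered <- stage("filter", lapply(tables, filter_asvs,
    min_prevalence = config$min_prevalence,
    min_rel_abund = config$min_rel_abund))
  f <- bundle$filtered
  net_inputs <- list(bacteria = f["bacteria"],
                     rhizobia = f["rhizobia"],
                     bacteria_am = f[c("bacteria", "am_fungi")],
                     rhizobia_am = f[c("rhizobia", "am_fungi")])
  net_inputs <- net_inputs[!vapply(net_inputs, function(x) anyNA(names(x)),
                                   logical(1))]
  bundle$networks <- stage("network_inference", {
    out <- list()
    for (nm in names(net_inputs)) {
      tab <- merge_kingdom_tables(unname(net_inputs[[nm]]))
      clr <- clr_transform(tab)
      out[[nm]] <- stars_select(
        tab,
        lambda_path = default_lambda_path(clr, length = config$lambda_path_length),
        n_subsamples = config$n_subsamples,
        subsample_fraction = config$subsample_fraction,
        instability_threshold = config$instability_threshold,
        seed = config$seed)
    }
    out
  })

  # -- topology, roles, keystones, associations ------------------------
  bundle$topology <- stage("topology", {
    tab <- do.call(rbind, lapply(names(bundle$networks), function(nm)
      cbind(network = nm, summary_metrics(bundle$networks[[nm]],
                                          seed = config$seed))))
    rownames(tab) <- NULL
    tab
  })
  bundle$edge_shares <- stage("edge_shares",
    lapply(bundle$networks, cross_kingdom_edge_share))
  bundle$node_roles <- stage("node_roles", lapply(bundle$networks, function(net) {
    roles <- zi_pi(net, seed = config$seed)
    sc <- hub_centrality(net)
    roles$hub_score <- sc[roles$taxon]
    roles$keystone <- roles$taxon %in% keystones(sc)
    roles
  }))
  bundle$subnetworks <- stage("subnetworks", {
    lapply(names(bundle$networks), function(nm) {
      tab <- merge_kingdom_tables(unname(net_inputs[[nm]]))
      subnetwork_metrics(bundle$networks[[nm]], tab)
    }) |> setNames(names(bundle$networks))
  })
  bundle$associations <- stage("associations", {
    out <- list()
    if (!is.null(bundle$networks$bacteria_am)) {
      tab <- merge_kingdom_tables(unname(net_inputs$bacteria_am))
      out$ppa_b_amf <- biotic_association_scores(
        tab, bundle$networks$bacteria_am, scope = c("bacteria", "am_fungi"))
    }
    if (!is.null(bundle$networks$rhizobia_am)) {
      tab <- merge_kingdom_tables(unname(net_inputs$rhizobia_am))
      out$ppa_rpob_amf <- biotic_association_scores(
        tab, bundle$networks$rhizobia_am, scope = c("rhizobia", "am_fungi"))
    }
    out
  })

  # -- assembly null models -------------------------------------------
  if (!is.null(trees)) {
    bundle$assembly <- stage("assembly", {
      out <- list()
      # entire-community null models (no dominance filtering)
      for (k in intersect(c("bacteria", "rhizobia"), names(tables))) {
        out[[k]] <- quantify_assembly(tables[[k]], trees[[k]],
                                      n_null = config$n_null,
                                      seed = config$seed)
      }
      out
    })
  }

  # -- permutation statistics -----------------------------------------
  bundle$stats <- stage("stats", {
    out <- list()
    for (k in names(bundle$filtered)) {
      d <- bray_curtis(bundle$filtered[[k]])
      out[[paste0("permanova_", k)]] <-
        permanova(d, position, config$n_permutations, seed = config$seed)
      out[[paste0("cpcoa_", k)]] <-
        constrained_pcoa(d, position, config$n_permutations, seed = config$seed)
    }
    if (!is.null(bundle$study$functions)) {
      fd <- as.matrix(stats::dist(z_standardize(bundle$study$functions)))
      db <- bray_curtis(bundle$filtered$bacteria)
      out$mantel_function_bacteria <-
        mantel_test(fd, db, n_permutations = config$n_permutations,
                    seed = config$seed)
      assoc <- bundle$associations[[1]]
      if (!is.null(assoc)) {
        abiotic <- cbind(pos_score = as.integer(factor(
          position, levels = c("top", "middle", "bottom"))))
        am_rich <- rowSums(tables$am_fungi$counts > 0)
        biotic <- cbind(am_richness = am_rich, ppa = assoc$ppa, pna = assoc$pna)
        out$varpart_bacteria <- variation_partitioning(
          db, abiotic, biotic, config$n_permutations, seed = config$seed)
      }
    }
    out
  })

  if (!is.null(config$outdir)) stage("write", write_bundle(bundle, config))
  invisible(bundle)
}

#' Cross-kingdom edge share of a signed network
#'
#' Counts within- and between-kingdom edges and the percentage of edges
#' joining different kingdoms.
#'
#' @param network a [signed_network].
#' @return List with `edge_counts` (by kingdom pair) and
#'   `cross_kingdom_pct`.
#' @export
cross_kingdom_edge_share <- function(network) {
  e <- network$edges
  if (nrow(e) == 0)
    return(list(edge_counts = table(character()), cross_kingdom_pct = NA_real_))
  kg <- setNames(network$nodes$kingdom, network$nodes$id)
  pair <- paste(pmin(kg[e$from], kg[e$to]), pmax(kg[e$from], kg[e$to]),
                sep = "-")
  counts <- table(pair)
  cross <- kg[e$from] != kg[e$to]
  list(edge_counts = counts,
       cross_kingdom_pct = 100 * sum(cross) / nrow(e))
}

write_bundle <- function(bundle, config) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write.table(df, file.path(out, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  for (k in names(bundle$study$tables))
    write_abundance_tsv(bundle$study$tables[[k]],
                        file.path(out, paste0("abundance_", k, ".tsv")),
                        file.path(out, "metadata.tsv"))
  if (!is.null(bundle$study$functions))
    write_function_tsv(bundle$study$functions, file.path(out, "functions.tsv"))
  if (!is.null(bundle$study$trees))
    for (k in names(bundle$study$trees))
      ape::write.tree(bundle$study$trees[[k]],
                      file.path(out, paste0("tree_", k, ".nwk")))
  if (!is.null(bundle$multifunctionality)) {
    mf <- bundle$multifunctionality
    wt(data.frame(sample_id = names(mf$average_mf),
                  average_mf = mf$average_mf,
                  mf$dim_scores, check.names = FALSE), "multifunctionality.tsv")
    wt(data.frame(axis = seq_along(mf$explained_variance),
                  explained_pct = 100 * mf$explained_variance),
       "multifun_axes.tsv")
  }
  wt(bundle$topology, "network_topology.tsv")
  for (nm in names(bundle$networks))
    write_network_tsv(bundle$networks[[nm]],
                      file.path(out, paste0("edges_", nm, ".tsv")),
                      file.path(out, paste0("nodes_", nm, ".tsv")))
  for (nm in names(bundle$node_roles))
    wt(bundle$node_roles[[nm]], paste0("node_roles_", nm, ".tsv"))
  for (nm in names(bundle$subnetworks))
    wt(bundle$subnetworks[[nm]], paste0("subnetwork_metrics_", nm, ".tsv"))
  for (nm in names(bundle$associations))
    wt(bundle$associations[[nm]], paste0("associations_", nm, ".tsv"))
  if (!is.null(bundle$assembly)) {
    for (k in names(bundle$assembly)) {
      wt(bundle$assembly[[k]]$pairs, paste0("assembly_pairs_", k, ".tsv"))
      wt(data.frame(process = names(bundle$assembly[[k]]$fractions),
                    fraction = bundle$assembly[[k]]$fractions),
         paste0("assembly_fractions_", k, ".tsv"))
    }
  }
  stats_df <- do.call(rbind, lapply(names(bundle$stats), function(nm) {
    s <- bundle$stats[[nm]]
    data.frame(analysis = nm,
               statistic = if (!is.null(s$statistic)) s$statistic
                           else s$adj_r2_full %||% s$constrained_fraction,
               p_value = s$p_value, stringsAsFactors = FALSE)
  }))
  wt(stats_df, "stats_results.tsv")
  manifest <- list(package = "rhizonet",
                   version = as.character(utils::packageVersion("rhizonet")),
                   config = unclass(config)[setdiff(names(config), "outdir")],
                   config_hash = bundle$config_hash,
                   seeds = list(master = config$seed),
                   networks = lapply(bundle$networks, function(n)
                     n$provenance[c("selected_lambda", "seed", "warning")]))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

#' Write planted ground truth as a JSON sidecar
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(scenario = truth$scenario,
         seed = truth$seed,
         effect_coefficients = as.list(truth$effect_coefficients),
         edges = truth$true_network$edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
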