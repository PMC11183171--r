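#!/usr/bin/env Rscript

# Community assembly (QPEN): abundance-weighted betaMNTD, betaNTI against
# taxa-shuffle nulls, Bray-Curtis Raup-Crick against probabilistic-assembly
# nulls, and the five-process classification, for the bacterial and
# rhizobial communities (entire community, no dominance filter).

suppressPackageStartupMessages(library(rhizonet))

dat <- "results/data"; out <- "results"
seed <- 101
n_null <- 1000   # the study-design default

for (k in c("bacteria", "rhizobia")) {
  tab <- read_abundance_tsv(file.path(dat, paste0("abundance_", k, ".tsv")),
                            file.path(dat, "metadata.tsv"))
  tree <- read_newick_checked(file.path(dat, paste0("tree_", k, ".nwk")))
  cl <- suppressWarnings(quantify_assembly(tab, tree, n_null = n_null,
                                           seed = seed))
  write.table(cl$pairs, file.path(out, paste0("assembly_pairs_", k, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(process = names(cl$fractions),
                         fraction = cl$fractions),
              file.path(out, paste0("assembly_fractions_", k, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s (%d pairs, %d excluded, %d nulls):\n", k, cl$n_pairs,
              cl$n_excluded, n_null))
  print(round(cl$fractions, 3))
  det <- sum(cl$fractions[c("variable_selection", "homogeneous_selection")])
  cat(sprintf("  deterministic %.2f vs drift %.2f under the planted selection scenario\n",
              det, cl$fractions[["drift"]]))
}
cat("Phylogenetic turnover power grows with richness: at this compact\n")
cat("60-taxon community the selection signal can be partial; the\n")
cat("richness-200 scenario-recovery check lives in the acceptance suite.\n")
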