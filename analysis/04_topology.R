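#!/usr/bin/env Rscript

# Network topology: summary table across the four networks, cross-kingdom
# edge shares, Zi-Pi node roles and hub-centrality keystones on the
# cross-kingdom networks, per-sample subnetwork metrics, and per-sample
# positive/negative biotic-association scores (PPA/PNA) for the
# bacteria-AM and rhizobia-AM kingdom pairs.

suppressPackageStartupMessages(library(rhizonet))

dat <- "results/data"; out <- "results"
tabs <- lapply(c(bacteria = "bacteria", rhizobia = "rhizobia",
                 am_fungi = "am_fungi"), function(k)
  read_abundance_tsv(file.path(dat, paste0("abundance_", k, ".tsv")),
                     file.path(dat, "metadata.tsv")))
filtered <- lapply(tabs, filter_asvs)
nets <- lapply(c(bacteria = "bacteria", rhizobia = "rhizobia",
                 bacteria_am = "bacteria_am", rhizobia_am = "rhizobia_am"),
               function(nm) read_network_tsv(
                 file.path(out, paste0("edges_", nm, ".tsv")),
                 file.path(out, paste0("nodes_", nm, ".tsv"))))

topo <- do.call(rbind, lapply(names(nets), function(nm)
  cbind(network = nm, summary_metrics(nets[[nm]]))))
write.table(topo, file.path(out, "network_topology.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Topological characteristics:\n")
print(topo[, c("network", "node_count", "edge_count", "average_degree",
               "density", "clustering_coefficient", "modularity")],
      row.names = FALSE, digits = 3)

for (nm in c("bacteria_am", "rhizobia_am")) {
  sh <- cross_kingdom_edge_share(nets[[nm]])
  cat(sprintf("%s: %.1f%% of edges are cross-kingdom\n", nm,
              sh$cross_kingdom_pct))
  roles <- zi_pi(nets[[nm]])
  sc <- hub_centrality(nets[[nm]])
  roles$hub_score <- sc[roles$taxon]
  roles$keystone <- roles$taxon %in% keystones(sc)
  write.table(roles, file.path(out, paste0("node_roles_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ks <- roles$taxon[roles$keystone]
  cat(sprintf("  keystones (hub score >= 0.7): %s\n",
              if (length(ks)) paste(ks, collapse = ", ") else "none"))
  cat(sprintf("  roles: %s\n",
              paste(names(table(roles$role)), table(roles$role),
                    collapse = ", ")))
}

merged_b <- merge_kingdom_tables(list(filtered$bacteria, filtered$am_fungi))
merged_r <- merge_kingdom_tables(list(filtered$rhizobia, filtered$am_fungi))
assoc_b <- biotic_association_scores(merged_b, nets$bacteria_am,
                                     scope = c("bacteria", "am_fungi"))
assoc_r <- biotic_association_scores(merged_r, nets$rhizobia_am,
                                     scope = c("rhizobia", "am_fungi"))
names(assoc_b)[2:3] <- c("PPA_B_AMF", "PNA_B_AMF")
names(assoc_r)[2:3] <- c("PPA_rpoB_AMF", "PNA_rpoB_AMF")
assoc <- merge(assoc_b, assoc_r, by = "sample_id")
write.table(assoc, file.path(out, "biotic_associations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PPA/PNA written for %d samples; mean PPA_B_AMF %.4f, PNA_B_AMF %.4f\n",
            nrow(assoc), mean(assoc$PPA_B_AMF), mean(assoc$PNA_B_AMF)))

sub <- subnetwork_metrics(nets$bacteria_am, merged_b)
write.table(sub, file.path(out, "subnetwork_metrics_bacteria_am.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Per-sample subnetworks: %.0f-%.0f nodes, mean density %.3f\n",
            min(sub$node_count), max(sub$node_count), mean(sub$density)))
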